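test_that("stratified folds preserve class ratios and training sets are
           fold complements", {
  labels <- rep(c(TRUE, FALSE), c(35, 27))
  sp <- stratified_training_sets(labels, n_splits = 5, seed = 0)
  expect_length(sp$folds, 62)
  for (s in 1:5) {
    fold <- which(sp$folds == s)
    expect_equal(sum(labels[fold]), 7)           # 35 positives over 5 folds
    expect_true(sum(!labels[fold]) %in% 5:6)     # 27 negatives over 5 folds
    expect_setequal(sp$training[[s]], setdiff(seq_len(62), fold))
    expect_true(length(sp$training[[s]]) %in% 49:50)
  }
  # folds partition the cohort
  expect_setequal(unlist(lapply(1:5, function(s) which(sp$folds == s))),
                  seq_len(62))
  # any two training sets share three folds of samples
  shared <- length(intersect(sp$training[[1]], sp$training[[2]]))
  expect_true(shared %in% 36:38)

  sp2 <- stratified_training_sets(labels, n_splits = 5, seed = 0)
  expect_identical(sp, sp2)
  sp3 <- stratified_training_sets(labels, n_splits = 5, seed = 1)
  expect_false(identical(sp$folds, sp3$folds))

  expect_error(stratified_training_sets(rep(TRUE, 10)), "class")
  expect_error(stratified_training_sets(c(rep(TRUE, 3), rep(FALSE, 20)),
                                        n_splits = 5), "at least")
})

test_that("KW ranking reproduces the closed-form example and the stated
           tie-break", {
  x <- cbind(a = c(1, 2, 3, 4, 5, 6))
  g <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  rl <- kw_rank(x, g)
  expect_equal(rl$H, 3.857142857, tolerance = 1e-9)
  expect_equal(rl$p, 0.04953461, tolerance = 1e-6)

  # identical columns tie on H; the smaller original column index wins
  x2 <- cbind(later = c(1, 2, 3, 9, 8, 7), dup1 = c(5, 1, 2, 9, 9, 3),
              dup2 = c(5, 1, 2, 9, 9, 3))
  rl2 <- kw_rank(x2, g)
  i1 <- which(rl2$variable_id == "dup1")
  i2 <- which(rl2$variable_id == "dup2")
  expect_equal(rl2$H[i1], rl2$H[i2])
  expect_lt(i1, i2)

  # constant variable: H defined as 0, ranked last
  x3 <- cbind(signal = c(1, 2, 3, 10, 11, 12), flat = rep(7, 6))
  rl3 <- kw_rank(x3, g)
  expect_equal(rl3$H[rl3$variable_id == "flat"], 0)
  expect_identical(rl3$variable_id[2], "flat")

  expect_error(kw_rank(x, rep(TRUE, 6)), "both classes")
})

test_that("KW H agrees with a brute-force mid-rank oracle and with the
           reference implementation", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(6:30, 1)
    g <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(g) || all(g)) next
    # mix continuous and heavily tied discrete variables
    x <- if (i %% 2 == 0) rnorm(n) else rpois(n, 2)
    h_pkg <- kw_rank(cbind(v = x), g)$H
    expect_equal(h_pkg, oracle_kw_h(x, g), tolerance = 1e-10)
    if (length(unique(x)) > 1) {
      expect_equal(h_pkg,
                   unname(kruskal.test(x, factor(g))$statistic),
                   tolerance = 1e-10)
    }
  }
})

test_that("H-to-p is the chi-square upper tail and decreases in H", {
  expect_equal(round(h_to_p(7.33), 3), 0.007)
  expect_equal(round(h_to_p(10.06), 3), 0.002)
  expect_equal(round(h_to_p(5.14), 3), 0.023)
  expect_equal(h_to_p(0), 1)
  h <- seq(0, 20, by = 0.5)
  expect_true(all(diff(h_to_p(h)) < 0))
  expect_error(h_to_p(-1), "non-negative")
})

test_that("elbow detection finds breakpoints and declines on lines", {
  # straight line: no knee
  expect_true(is.na(elbow_k(1:100, seq(10, 1, length.out = 100))))
  # flat at 10 then dropping linearly after k = 150
  x <- 1:300
  y <- c(rep(10, 150), 10 - cumsum(rep(0.05, 150)))
  expect_equal(elbow_k(x, y, curve = "concave"), 150, tolerance = 2)
  # convex decay: knee at the bend of a piecewise-linear curve
  y2 <- c(10 - cumsum(rep(0.2, 40)), rep(2, 260) - (1:260) * 1e-4)
  expect_equal(elbow_k(x, y2, curve = "convex"), 40, tolerance = 3)
  expect_error(elbow_k(1:2, c(2, 1)), "3 points")
  expect_error(elbow_k(1:5, c(1, 2, 3, 4, 5)), "non-increasing")
  # mean_topk_curve is non-increasing by construction
  toy <- make_toy_matrix()
  rl <- kw_rank(toy$x, toy$labels)
  curve <- mean_topk_curve(rl)
  expect_true(all(diff(curve$mean_top_h) <= 1e-12))
  expect_true(is.na(elbow_k(curve)) || elbow_k(curve) >= 1)
})

test_that("consensus formation: limit cases, median ranking, tie-break", {
  toy <- make_toy_matrix()
  rl <- kw_rank(toy$x, toy$labels)
  same <- lapply(1:5, function(s) rl)
  cons <- form_consensus(same, k = 10)
  expect_identical(cons$variable_id, rl$variable_id[1:10])
  expect_equal(cons$median_H, rl$H[1:10])

  # pairwise-disjoint top-k lists give an empty consensus
  m <- 25
  ids <- sprintf("v%03d", 1:m)
  make_list <- function(ord) {
    structure(
      data.frame(rank = 1:m, variable_id = ids[ord], H = seq(m, 1),
                 p = h_to_p(seq(m, 1)), column_index = ord,
                 stringsAsFactors = FALSE),
      class = c("ranked_list", "data.frame")
    )
  }
  rot <- lapply(0:4, function(s) make_list(c((s * 5 + 1):m, seq_len(s * 5))))
  cons0 <- form_consensus(rot, k = 5)
  expect_equal(nrow(cons0), 0)

  # median H across five splits
  h_vals <- c(7.0, 7.33, 7.5, 6.9, 8.0)
  lists <- lapply(h_vals, function(h) {
    l <- make_list(1:m)
    l$H[1] <- h
    l
  })
  cons1 <- form_consensus(lists, k = 3)
  expect_equal(cons1$median_H[cons1$variable_id == ids[1]], 7.33)

  expect_error(form_consensus(list(make_list(1:m),
                                   make_list(1:m)[1:10, ]), k = 5),
               "universe")
})

test_that("consensus grows monotonically in k and ignores column
           permutations up to relabeling", {
  set.seed(7)
  toy <- make_toy_matrix(n = 40, m = 60, n_signal = 6, shift = 1.5)
  sp <- stratified_training_sets(toy$labels, 5, seed = 0)
  rl <- lapply(1:5, function(s) kw_rank(toy$x, toy$labels,
                                        sp$training[[s]], s))
  sizes <- vapply(c(5, 10, 20, 40, 60), function(k) {
    nrow(form_consensus(rl, k = k))
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
  for (k in c(5, 20)) {
    c_small <- form_consensus(rl, k = k)$variable_id
    c_big <- form_consensus(rl, k = k + 15)$variable_id
    expect_true(all(c_small %in% c_big))
  }

  # permuting columns permutes ids but not membership (no exact H ties here)
  perm <- sample(ncol(toy$x))
  xp <- toy$x[, perm]
  rlp <- lapply(1:5, function(s) kw_rank(xp, toy$labels,
                                         sp$training[[s]], s))
  expect_setequal(form_consensus(rlp, k = 20)$variable_id,
                  form_consensus(rl, k = 20)$variable_id)
})

test_that("group summaries reproduce the abs-percent-difference formula
           including the undefined case", {
  expect_equal(round(abs_pct_median_diff(46, 27)), 41)
  expect_equal(round(abs_pct_median_diff(-4.52, 3.81)), 184)
  expect_true(is.na(abs_pct_median_diff(0, 5)))

  x <- cbind(a = c(1, 2, 3, 10, 11, 12), b = c(0, 0, 0, 5, 6, 7))
  g <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  gs <- group_summaries(x, g, c("a", "b"))
  expect_equal(gs$median_hand, c(2, 0))
  expect_equal(gs$median_no_hand, c(11, 6))
  expect_equal(gs$iqr_hand[1], 1)  # Q3 - Q1 with interpolated quantiles
  expect_equal(gs$abs_pct_median_diff[1], abs(2 - 11) / 2 * 100)
  expect_identical(gs$abs_pct_label[2], "UNDEF")
  expect_error(group_summaries(x, rep(TRUE, 6), "a"), "non-empty")
  expect_error(group_summaries(x, g, "nope"), "unknown variable")
})
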