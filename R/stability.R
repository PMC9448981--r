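#' Jaccard similarity of two variable sets
#'
#' @param a,b Character (or atomic) vectors treated as sets.
#' @return `|a n b| / |a u b|`, in `[0, 1]`.
#' @export
#' @examples
#' jaccard(1:100, 59:158)  # 42 shared of 158 -> 0.266
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) stop("both sets are empty")
  length(intersect(a, b)) / u
}

#' Normalized top-k Kendall distance with penalty parameter
#'
#' Order-disagreement metric between two top-k ranked lists drawn from a
#' larger universe, following the standard case analysis for partial lists:
#' \itemize{
#'   \item both elements in both lists: penalty 1 if their relative order
#'     differs, else 0;
#'   \item both elements in one list, exactly one in the other: penalty 1
#'     when the orders are contradictory (the element ranked worse is the one
#'     that made the other list), else 0;
#'   \item one element exclusive to each list: penalty 1 (each list places
#'     its own member ahead);
#'   \item both elements missing from one list: relative order undetermined,
#'     penalty `p` (the neutral approach is `p = 0.5`).
#' }
#' The total is normalized by the distance between two disjoint lists of
#' length k (`k^2 + 2 p * choose(k, 2)`), so identical lists score 0 and
#' disjoint lists score 1 for every `p`. Note this is a distance, not a
#' correlation: small values mean similar lists.
#'
#' @param a,b Character vectors: ranked lists of equal length k with no
#'   internal duplicates (position 1 = best rank).
#' @param p Penalty for undetermined pairs, in `[0, 1]` (default 0.5).
#' @return Normalized distance in `[0, 1]`.
#' @export
topk_kendall <- function(a, b, p = 0.5) {
  assert_scalar_number(p, "p", lower = 0, upper = 1)
  k <- length(a)
  if (length(b) != k) stop("lists must have equal length")
  if (k == 0) stop("lists are empty")
  if (anyDuplicated(a) || anyDuplicated(b)) {
    stop("duplicate ids within a list")
  }
  if (k == 1) {
    return(if (identical(as.character(a), as.character(b))) 0 else 1)
  }
  a <- as.character(a)
  b <- as.character(b)
  shared <- intersect(a, b)
  only_a <- setdiff(a, b)
  only_b <- setdiff(b, a)
  z <- length(shared)
  # case 1: discordant pairs among shared elements
  ra <- match(shared, a)
  rb <- match(shared, b)
  disc <- 0L
  if (z >= 2) {
    o <- order(ra)
    rb_o <- rb[o]
    disc <- sum(vapply(seq_len(z - 1), function(i) {
      sum(rb_o[(i + 1):z] < rb_o[i])
    }, numeric(1)))
  }
  # case 2: shared element ranked behind an exclusive element of the same
  # list contradicts the other list, which kept the shared one
  case2 <- 0L
  if (z && length(only_a)) {
    pa_only <- match(only_a, a)
    case2 <- case2 + sum(vapply(ra, function(ps) sum(pa_only < ps),
                                numeric(1)))
  }
  if (z && length(only_b)) {
    pb_only <- match(only_b, b)
    case2 <- case2 + sum(vapply(rb, function(ps) sum(pb_only < ps),
                                numeric(1)))
  }
  # case 3: one element exclusive to each list
  case3 <- length(only_a) * length(only_b)
  # case 4: both elements absent from the other list
  case4 <- p * (choose(length(only_a), 2) + choose(length(only_b), 2))
  total <- disc + case2 + case3 + case4
  max_dist <- k^2 + 2 * p * choose(k, 2)
  total / max_dist
}

#' Null probability of consistent selection across independent lists
#'
#' Probability that one fixed variable lands in all S top-k lists when
#' selection is uniform over M variables and the lists are independent:
#' `(k/M)^S`. With overlapping training sets the realized null selection
#' rate can be substantially larger; see the package vignette.
#'
#' @param k List length; `1 <= k <= M`.
#' @param M Universe size.
#' @param S Number of lists; `S >= 1`.
#' @return Probability in `(0, 1]`.
#' @export
#' @examples
#' null_selection_probability(100, 2601, 5)  # 8.40e-08
null_selection_probability <- function(k, M, S) {
  assert_scalar_number(k, "k", lower = 1, integerish = TRUE)
  assert_scalar_number(M, "M", lower = 1, integerish = TRUE)
  assert_scalar_number(S, "S", lower = 1, integerish = TRUE)
  if (k > M) stop("k must not exceed M")
  (k / M)^S
}

#' Stability report for a set of per-split top-k lists
#'
#' Pairwise Jaccard similarity of the top-k sets, pairwise normalized top-k
#' Kendall distance, mean off-diagonal Jaccard, mean pairwise intersection
#' size, and the analytic null selection probability `(k/M)^S`.
#'
#' @param lists List of S >= 2 `ranked_list` objects (or plain character
#'   vectors already truncated to k) over the same variable universe.
#' @param k List length; defaults to the shortest list.
#' @param p Kendall penalty parameter (default 0.5).
#' @param M Universe size; inferred from `ranked_list` inputs.
#' @return Object of class `stability_report`: list with `jaccard` (S x S),
#'   `kendall` (S x S), `mean_jaccard`, `mean_intersection_size`,
#'   `null_selection_probability`, `k`, `p`, `M`, `S`.
#' @export
stability_report <- function(lists, k = NULL, p = 0.5, M = NULL) {
  S <- length(lists)
  if (S < 2) stop("need at least 2 lists")
  is_rl <- vapply(lists, inherits, logical(1), what = "ranked_list")
  if (all(is_rl)) {
    universe <- sort(lists[[1]]$variable_id)
    for (l in lists) {
      if (!identical(sort(l$variable_id), universe)) {
        stop("ranked lists cover different variable universes")
      }
    }
    M <- M %||% length(universe)
    k <- k %||% min(100L, length(universe))
    tops <- lapply(lists, function(l) l$variable_id[seq_len(k)])
  } else {
    tops <- lapply(lists, as.character)
    k <- k %||% min(lengths(tops))
    tops <- lapply(tops, function(x) x[seq_len(k)])
    if (is.null(M)) M <- length(unique(unlist(tops)))
  }
  jac <- ken <- matrix(0, S, S)
  diag(jac) <- 1
  inter <- numeric(0)
  for (i in seq_len(S - 1)) {
    for (j in (i + 1):S) {
      jac[i, j] <- jac[j, i] <- jaccard(tops[[i]], tops[[j]])
      ken[i, j] <- ken[j, i] <- topk_kendall(tops[[i]], tops[[j]], p = p)
      inter <- c(inter, length(intersect(tops[[i]], tops[[j]])))
    }
  }
  structure(
    list(
      jaccard = jac,
      kendall = ken,
      mean_jaccard = mean(jac[upper.tri(jac)]),
      mean_intersection_size = mean(inter),
      null_selection_probability = null_selection_probability(k, M, S),
      k = k, p = p, M = M, S = S
    ),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report> S=", x$S, " lists, k=", x$k, ", M=", x$M,
      "\n  mean pairwise Jaccard: ", round(x$mean_jaccard, 3),
      "\n  mean intersection size: ", round(x$mean_intersection_size, 1),
      "\n  null selection probability (k/M)^S: ",
      format(x$null_selection_probability, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Write a stability report as JSON
#'
#' @param report A `stability_report`.
#' @param path Output JSON path.
#' @export
write_stability_json <- function(report, path) {
  obj <- unclass(report)
  obj$jaccard <- unname(obj$jaccard)
  obj$kendall <- unname(obj$kendall)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Heat-map of the pairwise Jaccard matrix
#'
#' Base-graphics rendering of the pairwise top-k Jaccard similarities with
#' the pairwise intersection sizes annotated in each cell.
#'
#' @param report A `stability_report`.
#' @param ... Passed to [graphics::image()].
#' @export
plot_jaccard_heatmap <- function(report, ...) {
  S <- report$S
  jac <- report$jaccard
  graphics::image(seq_len(S), seq_len(S), t(jac[S:1, ]),
                  col = grDevices::hcl.colors(25, "Blues 3", rev = TRUE),
                  zlim = c(0, 1), axes = FALSE,
                  xlab = "split", ylab = "split",
                  main = sprintf("Pairwise Jaccard of top-%d lists",
                                 report$k), ...)
  graphics::axis(1, at = seq_len(S), labels = seq_len(S))
  graphics::axis(2, at = seq_len(S), labels = S:1)
  n_shared <- round(jac / (1 + jac) * 2 * report$k)  # |A n B| from Jaccard
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      graphics::text(j, S - i + 1, n_shared[i, j], cex = 0.9)
    }
  }
  invisible(report)
}
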