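#' Stratified training sets for split-consensus screening
#'
#' Partitions the cohort into `n_splits` disjoint folds, preserving the
#' HAND/no-HAND ratio in each fold to within one participant, and returns the
#' complement of each fold as that split's training set (so each training set
#' holds `(S-1)/S` of the cohort and any two training sets overlap in `S-2`
#' folds). Fold assignment is deterministic given the seed.
#'
#' @param labels Logical or 0/1 vector of HAND status.
#' @param n_splits Number of folds/splits S (default 5).
#' @param seed Integer seed (default 0).
#' @return List with `folds` (integer fold id per participant) and
#'   `training` (list of S integer index vectors).
#' @export
stratified_training_sets <- function(labels, n_splits = 5, seed = 0) {
  labels <- as.logical(labels)
  if (anyNA(labels)) stop("labels must be binary without NA")
  S <- as.integer(n_splits)
  if (S < 2) stop("n_splits must be at least 2")
  n_by <- table(labels)
  if (length(n_by) < 2L || any(n_by < S)) {
    stop("each class needs at least n_splits = ", S, " members")
  }
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in c(TRUE, FALSE)) {
      idx <- sample(which(labels == cl))
      # seed-controlled rotation decides which folds receive the remainder
      fold_order <- sample.int(S)
      folds[idx] <- rep(fold_order, length.out = length(idx))
    }
  })
  training <- lapply(seq_len(S), function(s) which(folds != s))
  list(folds = folds, training = training)
}

# Kruskal-Wallis H for one variable: mid-ranks with the standard tie
# correction; a constant variable (all ranks tied) is defined to have H = 0.
kw_h_single <- function(x, g_idx, n_groups) {
  n <- length(x)
  r <- rank(x)
  tie <- rle(sort(x))$lengths
  corr <- 1 - sum(tie^3 - tie) / (n^3 - n)
  if (corr <= 0) return(0)
  rs <- vapply(seq_len(n_groups), function(k) sum(r[g_idx == k]), numeric(1))
  ns <- tabulate(g_idx, n_groups)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  max(0, h / corr)
}

#' Upper-tail p-value for a Kruskal-Wallis H statistic
#'
#' Chi-square approximation with `n_groups - 1` degrees of freedom, the
#' standard reference distribution for the KW statistic.
#'
#' @param h Non-negative H statistic (vectorized).
#' @param n_groups Number of groups (default 2).
#' @return Upper-tail probability, strictly decreasing in `h`.
#' @export
#' @examples
#' h_to_p(7.33)  # ~0.0068
h_to_p <- function(h, n_groups = 2) {
  if (any(h < 0)) stop("H must be non-negative")
  stats::pchisq(h, df = n_groups - 1, lower.tail = FALSE)
}

#' Rank all variables of one training set by Kruskal-Wallis H
#'
#' Computes the univariate KW H value of every feature-matrix column against
#' the binary HAND label on the given training rows, and ranks variables in
#' descending H. Ties are broken in favour of the variable with the smaller
#' original column index (the earlier variable in the assembled dataset).
#' Constant variables get H = 0 and sort to the bottom.
#'
#' @param fm A `vdt_feature_matrix` (or plain numeric matrix with column
#'   names, in which case column order defines the tie-break index).
#' @param labels Binary HAND labels for all rows of `fm`.
#' @param training Integer row indices of the training set (default: all
#'   rows).
#' @param split_id Identifier stored on the result.
#' @return Object of class `ranked_list`: data frame with columns `rank`,
#'   `variable_id`, `H`, `p`, `column_index`, ordered by rank, plus
#'   attribute `split_id`.
#' @export
kw_rank <- function(fm, labels, training = NULL, split_id = 1L) {
  if (inherits(fm, "vdt_feature_matrix")) {
    values <- fm$values
    col_index <- fm$meta$column_index
  } else {
    values <- fm
    col_index <- seq_len(ncol(values))
  }
  labels <- as.logical(labels)
  if (length(labels) != nrow(values)) stop("labels/matrix size mismatch")
  if (is.null(training)) training <- seq_len(nrow(values))
  g <- labels[training]
  if (!any(g) || all(g)) stop("training set must contain both classes")
  g_idx <- as.integer(g) + 1L
  sub <- values[training, , drop = FALSE]
  H <- apply(sub, 2, kw_h_single, g_idx = g_idx, n_groups = 2L)
  ord <- order(-H, col_index)
  out <- data.frame(
    rank = seq_along(ord),
    variable_id = colnames(values)[ord],
    H = unname(H[ord]),
    p = h_to_p(unname(H[ord]), 2),
    column_index = col_index[ord],
    stringsAsFactors = FALSE
  )
  attr(out, "split_id") <- split_id
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Mean H of the top-k variables as a function of k
#'
#' The diminishing-returns curve monitored when choosing the list length k:
#' for each k, the mean KW H value of that split's k top-ranked variables.
#' The curve is non-increasing in k.
#'
#' @param ranked A `ranked_list`.
#' @param k_max Largest k to evaluate (default `min(1000, M)`).
#' @return Data frame with columns `k` and `mean_top_h`.
#' @export
mean_topk_curve <- function(ranked, k_max = min(1000L, nrow(ranked))) {
  k <- seq_len(min(k_max, nrow(ranked)))
  data.frame(k = k, mean_top_h = cumsum(ranked$H[k]) / k)
}

#' Knee (elbow) point of a decreasing convex curve
#'
#' Kneedle-style knee detection for the `mean_topk_curve` shape (decreasing,
#' convex configuration): the curve is normalized to the unit square, flipped
#' to the concave-increasing orientation, and the knee is the x at the first
#' local maximum of the difference curve `y - x` that beats the sensitivity
#' threshold before the difference decays. Advisory only: the pipeline's k
#' stays config-driven.
#'
#' @param x,y Curve coordinates; `y` non-increasing, at least 3 points.
#'   A data frame from [mean_topk_curve()] may be given as `x`.
#' @param sensitivity Kneedle sensitivity S (default 1).
#' @param curve Shape of the decreasing curve: `"convex"` (default; drops
#'   fast then flattens, the `mean_topk_curve` shape) or `"concave"` (flat
#'   then drops).
#' @return The x value of the knee, or `NA` when no knee exists (e.g. a
#'   straight line).
#' @export
elbow_k <- function(x, y = NULL, sensitivity = 1,
                    curve = c("convex", "concave")) {
  curve <- match.arg(curve)
  if (is.data.frame(x)) {
    y <- x$mean_top_h
    x <- x$k
  }
  if (length(x) < 3) stop("curve needs at least 3 points")
  if (any(diff(y) > 1e-9)) stop("curve must be non-increasing in k")
  if (max(y) == min(y)) return(NA_real_)
  # map the decreasing curve onto the concave-increasing orientation the
  # difference heuristic expects
  if (curve == "convex") {
    xt <- x
    yt <- max(y) - y
    back <- function(i) x[i]
  } else {
    xt <- rev(max(x) - x)
    yt <- rev(y)
    back <- function(i) x[length(x) - i + 1L]
  }
  xn <- (xt - min(xt)) / (max(xt) - min(xt))
  yn <- (yt - min(yt)) / (max(yt) - min(yt))
  d <- yn - xn
  n <- length(d)
  i_mid <- 2:(n - 1)
  lmx <- i_mid[d[i_mid] >= d[i_mid - 1] & d[i_mid] >= d[i_mid + 1] &
                 d[i_mid] > 0]
  if (!length(lmx)) return(NA_real_)
  thresh <- d[lmx] - sensitivity * mean(diff(xn))
  for (j in seq_along(lmx)) {
    i <- lmx[j]
    upto <- if (j < length(lmx)) lmx[j + 1] else n
    seg <- d[(i + 1):upto]
    if (any(seg < thresh[j])) {
      return(back(i))
    }
  }
  NA_real_
}

#' Form the split consensus of top-k ranked lists
#'
#' The consensus is the set intersection of the S splits' top-k prefixes
#' (possibly empty). Each surviving variable is assigned the median H and
#' median p across all S splits and the consensus is ordered by descending
#' median H, ties broken by smaller original column index.
#'
#' @param lists List of `ranked_list` objects over the same variable
#'   universe.
#' @param k List length (default 100).
#' @return Object of class `consensus`: data frame with columns `rank`,
#'   `variable_id`, `median_H`, `median_p`, `column_index`, plus attribute
#'   `k`.
#' @export
form_consensus <- function(lists, k = 100) {
  stopifnot(length(lists) >= 2)
  universe <- sort(lists[[1]]$variable_id)
  for (l in lists) {
    if (!identical(sort(l$variable_id), universe)) {
      stop("ranked lists cover different variable universes")
    }
  }
  k <- min(k, length(universe))
  tops <- lapply(lists, function(l) l$variable_id[seq_len(k)])
  ids <- Reduce(intersect, tops)
  h_mat <- vapply(lists, function(l) {
    l$H[match(ids, l$variable_id)]
  }, numeric(length(ids)))
  p_mat <- vapply(lists, function(l) {
    l$p[match(ids, l$variable_id)]
  }, numeric(length(ids)))
  if (length(ids) == 1L) {
    h_mat <- matrix(h_mat, nrow = 1)
    p_mat <- matrix(p_mat, nrow = 1)
  }
  med_h <- if (length(ids)) apply(h_mat, 1, stats::median) else numeric()
  med_p <- if (length(ids)) apply(p_mat, 1, stats::median) else numeric()
  cidx <- lists[[1]]$column_index[match(ids, lists[[1]]$variable_id)]
  ord <- order(-med_h, cidx)
  out <- data.frame(
    rank = seq_along(ord),
    variable_id = ids[ord],
    median_H = med_h[ord],
    median_p = med_p[ord],
    column_index = cidx[ord],
    stringsAsFactors = FALSE
  )
  attr(out, "k") <- k
  class(out) <- c("consensus", "data.frame")
  out
}

#' Group summaries of consensus variables
#'
#' Distributional comparison of each consensus variable between participants
#' with and without HAND: median and IQR (Q3 - Q1, linear-interpolation
#' quantiles) overall and per group, and the absolute percent median
#' difference `|median_present - median_absent| / |median_present| * 100`,
#' undefined (reported `"UNDEF"`, numeric `NA`) when the HAND-group median
#' is zero.
#'
#' @param fm A `vdt_feature_matrix` or numeric matrix with column names.
#' @param labels Binary HAND labels aligned with rows.
#' @param consensus A `consensus` (or character vector of variable ids).
#' @return Data frame with one row per consensus variable: medians, IQRs,
#'   `abs_pct_median_diff` (numeric, `NA` when undefined) and
#'   `abs_pct_label` (formatted, `"UNDEF"` when undefined).
#' @export
group_summaries <- function(fm, labels, consensus) {
  values <- if (inherits(fm, "vdt_feature_matrix")) fm$values else fm
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("both groups must be non-empty")
  ids <- if (is.character(consensus)) consensus else consensus$variable_id
  miss <- setdiff(ids, colnames(values))
  if (length(miss)) stop("unknown variable(s): ", paste(miss, collapse = ", "))
  iqr <- function(v) unname(diff(stats::quantile(v, c(0.25, 0.75))))
  if (!length(ids)) {
    return(data.frame(
      variable_id = character(), median_all = numeric(), iqr_all = numeric(),
      median_hand = numeric(), iqr_hand = numeric(),
      median_no_hand = numeric(), iqr_no_hand = numeric(),
      abs_pct_median_diff = numeric(), abs_pct_label = character(),
      stringsAsFactors = FALSE
    ))
  }
  rows <- lapply(ids, function(id) {
    v <- values[, id]
    mp <- stats::median(v[labels])
    ma <- stats::median(v[!labels])
    pct <- abs_pct_median_diff(mp, ma)
    data.frame(
      variable_id = id,
      median_all = stats::median(v), iqr_all = iqr(v),
      median_hand = mp, iqr_hand = iqr(v[labels]),
      median_no_hand = ma, iqr_no_hand = iqr(v[!labels]),
      abs_pct_median_diff = pct,
      abs_pct_label = if (is.na(pct)) "UNDEF" else
        paste0(round(pct), "%"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Absolute percent median difference
#'
#' `|median_present - median_absent| / |median_present| * 100`; `NA`
#' (undefined) when the HAND-present median is zero.
#'
#' @param median_present,median_absent Group medians (vectorized).
#' @return Numeric percentage, `NA` where undefined.
#' @export
#' @examples
#' abs_pct_median_diff(46, 27)  # 41.3...
abs_pct_median_diff <- function(median_present, median_absent) {
  ifelse(median_present == 0, NA_real_,
         abs(median_present - median_absent) / abs(median_present) * 100)
}

#' Write per-split ranked lists and the consensus table as CSV
#'
#' @param lists List of `ranked_list` objects.
#' @param dir Output directory (created if needed).
#' @export
write_ranked_lists <- function(lists, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(lists)) {
    utils::write.csv(lists[[i]],
                     file.path(dir, sprintf("ranked_split_%d.csv", i)),
                     row.names = FALSE)
  }
  invisible(dir)
}
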