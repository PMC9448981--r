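#' Spearman associations between consensus variables and domain impairment
#'
#' For every (consensus variable, cognitive domain) pair, the Spearman rank
#' correlation between the variable and the binary within-domain impairment
#' flag, with two significance tiers: raw (`p < alpha`) and Bonferroni
#' (`p < alpha / m`, `m` = number of tested cells = variables x domains).
#' Cells where either side is constant are reported as undefined rather than
#' raising an error.
#'
#' @param fm A `vdt_feature_matrix` or numeric matrix with column names.
#' @param consensus A `consensus` object or character vector of variable ids.
#' @param domain_flags Data frame (participants x 7 logical columns) of
#'   within-domain impairment flags, e.g. the `impaired_*` columns of
#'   [score_cohort()].
#' @param alpha Family-wise significance level (default 0.05).
#' @return Data frame with one row per cell: `variable_id`, `domain`, `rho`,
#'   `p_raw`, `significant_raw`, `significant_bonferroni`, `defined`; the
#'   Bonferroni threshold and `m` are attached as attributes.
#' @export
spearman_domain_matrix <- function(fm, consensus, domain_flags,
                                   alpha = 0.05) {
  values <- if (inherits(fm, "vdt_feature_matrix")) fm$values else fm
  ids <- if (is.character(consensus)) consensus else consensus$variable_id
  stopifnot(nrow(domain_flags) == nrow(values))
  m <- length(ids) * ncol(domain_flags)
  if (m == 0) stop("nothing to test")
  thresh <- alpha / m
  rows <- list()
  for (id in ids) {
    v <- values[, id]
    for (d in names(domain_flags)) {
      flag <- as.numeric(domain_flags[[d]])
      if (length(unique(v)) < 2 || length(unique(flag)) < 2) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable_id = id, domain = d, rho = NA_real_, p_raw = NA_real_,
          significant_raw = NA, significant_bonferroni = NA, defined = FALSE,
          stringsAsFactors = FALSE
        )
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(v, flag, method = "spearman", exact = FALSE)
      )
      rows[[length(rows) + 1L]] <- data.frame(
        variable_id = id, domain = d, rho = unname(ct$estimate),
        p_raw = ct$p.value,
        significant_raw = ct$p.value < alpha,
        significant_bonferroni = ct$p.value < thresh,
        defined = TRUE, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "m") <- m
  attr(out, "bonferroni_threshold") <- thresh
  out
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional exact test via the hypergeometric distribution, as used for
#' the impairment-prevalence contrasts between participants with and without
#' HAND.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
exact_test_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("empty margin")
  }
  stats::fisher.test(table)$p.value
}

#' Pearson chi-square test for a 2x2 table, without continuity correction
#'
#' The closed form `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with 1 degree of
#' freedom, used for the drug-use by HAND prevalence contrast.
#'
#' @param table 2x2 matrix of non-negative counts with no zero margin.
#' @return List with `statistic` and `p`.
#' @export
#' @examples
#' chi_square_2x2(matrix(c(13, 22, 10, 17), 2))
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin")
  }
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  n <- sum(table)
  stat <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Rank-sum comparison of two samples
#'
#' Wilcoxon rank-sum (Mann-Whitney) statistic W with a tie-corrected normal
#' approximation, two-sided; used e.g. to compare composite error scores
#' between drug-use groups.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param correct Continuity correction for the normal approximation
#'   (default `FALSE`).
#' @return List with `W` and `p`.
#' @export
rank_sum_w <- function(x, y, correct = FALSE) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = correct)
  )
  list(W = unname(wt$statistic), p = wt$p.value)
}
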