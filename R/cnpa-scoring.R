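#' Cognitive domains and component tests of the neuropsychological battery
#'
#' The comprehensive neuropsychological assessment (CNPA) covers seven
#' cognitive domains, each assessed with at least two component tests. The
#' default battery mirrors the standard HAND assessment: processing speed,
#' attention and working memory, motor function, executive function, language,
#' verbal memory, and visuospatial memory.
#'
#' @return Named list mapping domain identifiers to character vectors of
#'   component test names (the expected column names of a CNPA T-score table).
#' @export
#' @examples
#' names(cnpa_domains())
cnpa_domains <- function() {
  list(
    processing_speed = c(
      "waisiv_coding", "trail_making_a", "stroop_word", "stroop_color"
    ),
    attention_working_memory = c(
      "digit_span_forward", "digit_span_backward", "digit_span_sequencing"
    ),
    motor_function = c(
      "grooved_pegboard_dominant", "grooved_pegboard_nondominant"
    ),
    executive_function = c(
      "trail_making_b", "stroop_color_word", "mwcst_errors"
    ),
    language = c(
      "letter_fluency_fas", "animal_fluency", "boston_naming_30"
    ),
    verbal_memory = c(
      "hvltr_immediate", "hvltr_delayed", "hvltr_recognition"
    ),
    visuospatial_memory = c(
      "bvmtr_immediate", "bvmtr_delayed", "bvmtr_recognition"
    )
  )
}

#' Convert demographically adjusted T-scores to deficit scores
#'
#' Maps a T-score (population mean 50, SD 10) onto the 0--5 deficit scale used
#' to build the Global Deficit Score: scores in the normal range contribute no
#' deficit, and each 5-point band below T = 40 adds one deficit point up to
#' the scale maximum of 5.
#'
#' @param t Numeric vector of T-scores; must be finite.
#' @param bins Numeric vector of 5 descending lower cut points. `t >= bins[1]`
#'   maps to deficit 0, `t >= bins[2]` to 1, and so on; `t < bins[5]` maps
#'   to 5. Default `c(40, 35, 30, 25, 20)`.
#' @return Integer vector of deficit scores in 0--5.
#' @export
#' @examples
#' t_to_deficit(c(55, 39, 10))
t_to_deficit <- function(t, bins = c(40, 35, 30, 25, 20)) {
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("T-scores must be finite numbers")
  }
  if (length(bins) != 5L || is.unsorted(rev(bins), strictly = TRUE)) {
    stop("`bins` must be 5 strictly decreasing cut points")
  }
  # deficit = number of cut points the score falls below
  d <- rowSums(outer(t, bins, `<`))
  as.integer(d)
}

#' Summarize a participant's deficit profile
#'
#' Computes per-test deficit scores, per-domain deficit scores (mean of member
#' tests), the Global Deficit Score (GDS, mean of the seven domain deficits),
#' and the binary classifications: HAND present when GDS >= `gds_cutoff`
#' (default 0.5, cutoff inclusive) and a domain impaired when its domain
#' deficit >= `domain_cutoff` (default 1, inclusive). A coarse three-level
#' severity category derived from the GDS is also reported; it is not used by
#' the selection pipeline.
#'
#' @param t_scores Named numeric vector of T-scores covering every component
#'   test of every domain in `domains`.
#' @param domains Domain structure as returned by [cnpa_domains()].
#' @param bins Deficit cut points, see [t_to_deficit()].
#' @param gds_cutoff GDS threshold for HAND (inclusive).
#' @param domain_cutoff Domain-deficit threshold for within-domain impairment
#'   (inclusive).
#' @param dementia_cutoff GDS threshold separating the severe (dementia-range)
#'   category from milder impairment in the advisory three-level output.
#' @param missing Policy for absent test scores: `"error"` (default) or
#'   `"domain_mean"`, which averages over the tests available within each
#'   domain (a domain with no scores at all is always an error).
#' @return A list of class `deficit_summary` with elements `per_test_deficit`,
#'   `domain_deficit`, `gds`, `hand`, `domain_impaired`, `hand_category`.
#' @export
#' @examples
#' ts <- setNames(rep(55, length(unlist(cnpa_domains()))),
#'                unlist(cnpa_domains()))
#' summarize_deficits(ts)$gds
summarize_deficits <- function(t_scores, domains = cnpa_domains(),
                               bins = c(40, 35, 30, 25, 20),
                               gds_cutoff = 0.5, domain_cutoff = 1,
                               dementia_cutoff = 1.5,
                               missing = c("error", "domain_mean")) {
  missing <- match.arg(missing)
  if (is.null(names(t_scores))) stop("`t_scores` must be named by test")
  lens <- lengths(domains)
  if (any(lens < 2L)) stop("every domain needs at least two component tests")

  per_test <- domain_deficit <- list()
  for (d in names(domains)) {
    tests <- domains[[d]]
    have <- tests[tests %in% names(t_scores)]
    if (length(have) == 0L) stop("domain '", d, "' has no scores")
    if (length(have) < length(tests) && missing == "error") {
      stop("missing T-score(s) for: ",
           paste(setdiff(tests, have), collapse = ", "))
    }
    dd <- t_to_deficit(t_scores[have], bins = bins)
    names(dd) <- have
    per_test[[d]] <- dd
    domain_deficit[[d]] <- mean(dd)
  }
  domain_deficit <- unlist(domain_deficit)
  gds <- mean(domain_deficit)
  category <- if (gds < gds_cutoff) {
    "none"
  } else if (gds < dementia_cutoff) "asymptomatic_or_mild" else "dementia"
  structure(
    list(
      per_test_deficit = unlist(unname(per_test)),
      domain_deficit = domain_deficit,
      gds = gds,
      hand = gds >= gds_cutoff,
      domain_impaired = domain_deficit >= domain_cutoff,
      hand_category = category
    ),
    class = "deficit_summary"
  )
}

#' Score a cohort's T-score table
#'
#' Applies [summarize_deficits()] to every row of a participants-by-tests
#' T-score table.
#'
#' @param cnpa A data frame with a `participant_id` column plus one numeric
#'   column per component test (the format written by the synthetic generator
#'   and read by [read_cnpa_csv()]).
#' @inheritParams summarize_deficits
#' @param ... Passed on to [summarize_deficits()].
#' @return Data frame with one row per participant: seven domain-deficit
#'   columns, `gds`, `hand`, seven `impaired_*` columns and `hand_category`.
#' @export
score_cohort <- function(cnpa, domains = cnpa_domains(), ...) {
  stopifnot(is.data.frame(cnpa), "participant_id" %in% names(cnpa))
  rows <- lapply(seq_len(nrow(cnpa)), function(i) {
    ts <- unlist(cnpa[i, setdiff(names(cnpa), "participant_id")])
    s <- summarize_deficits(ts, domains = domains, ...)
    c(
      list(participant_id = cnpa$participant_id[i]),
      as.list(s$domain_deficit),
      list(gds = s$gds, hand = s$hand),
      stats::setNames(as.list(s$domain_impaired),
                      paste0("impaired_", names(s$domain_impaired))),
      list(hand_category = s$hand_category)
    )
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  rownames(out) <- NULL
  out
}

#' Within-domain impairment prevalence by HAND status
#'
#' Tabulates the percentage of participants impaired in each cognitive domain,
#' overall and split by HAND status, with a two-sided Fisher exact p-value per
#' domain (impairment x HAND).
#'
#' @param scored Output of [score_cohort()].
#' @return Data frame: `domain`, `pct_all`, `pct_hand`, `pct_no_hand`, `p`.
#' @export
domain_prevalence_table <- function(scored) {
  dom <- names(cnpa_domains())
  hand <- scored$hand
  if (all(hand) || !any(hand)) stop("both HAND groups must be present")
  rows <- lapply(dom, function(d) {
    imp <- scored[[paste0("impaired_", d)]]
    tab <- matrix(c(
      sum(imp & hand), sum(!imp & hand),
      sum(imp & !hand), sum(!imp & !hand)
    ), nrow = 2)
    data.frame(
      domain = d,
      pct_all = 100 * mean(imp),
      pct_hand = 100 * mean(imp[hand]),
      pct_no_hand = 100 * mean(imp[!hand]),
      p = exact_test_2x2(tab)
    )
  })
  do.call(rbind, rows)
}

#' Read a CNPA T-score table from CSV
#'
#' @param path CSV with a `participant_id` column and one column per component
#'   test.
#' @param domains Domain structure used to validate the header.
#' @return Data frame suitable for [score_cohort()].
#' @export
read_cnpa_csv <- function(path, domains = cnpa_domains()) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("participant_id", unlist(domains))
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("CNPA table is missing column(s): ", paste(miss, collapse = ", "))
  }
  df
}

#' Write per-participant deficit summaries to CSV
#'
#' @param scored Output of [score_cohort()].
#' @param path Output file.
#' @export
write_deficit_csv <- function(scored, path) {
  utils::write.csv(scored, path, row.names = FALSE)
  invisible(path)
}
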