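#' Validate and normalize a pipeline configuration
#'
#' Accepts a configuration as a nested list or a YAML/JSON file path, checks
#' every field, injects defaults (`selection.k = 100`, `selection.n_splits =
#' 5`, `selection.seed = 0`, `stability.p = 0.5`, `association.alpha =
#' 0.05`), and returns the normalized configuration. All violations are
#' collected and reported together, each naming its field path.
#'
#' Sections: `cohort` (arguments of [cohort_spec()]; used in synthetic mode),
#' `input` (`replay_dir`, `cnpa_csv`; real-data mode, takes precedence when
#' present), `scoring` (`gds_cutoff`, `domain_cutoff`), `error_weights`,
#' `selection` (`n_splits`, `k`, `seed`), `stability` (`p`), `association`
#' (`alpha`), `output_dir`.
#'
#' @param config List, or path to a YAML or JSON file (an empty file yields
#'   the all-defaults configuration).
#' @return Normalized configuration list of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_cfg("config file not found: ", config)
    txt <- paste(readLines(config, warn = FALSE), collapse = "\n")
    config <- if (grepl("^\\s*\\{", txt)) {
      jsonlite::fromJSON(txt, simplifyVector = TRUE)
    } else {
      yaml::yaml.load(txt) %||% list()
    }
  }
  if (!is.list(config)) stop_cfg("config must be a list or a file path")
  errs <- character()
  note <- function(path, msg) errs <<- c(errs, paste0(path, ": ", msg))

  cohort <- config$cohort %||% list()
  spec <- tryCatch(do.call(cohort_spec, cohort), error = function(e) {
    note("cohort", conditionMessage(e))
    NULL
  })

  input <- config$input %||% list()
  if (length(input)) {
    if (is.null(input$replay_dir) || !dir.exists(input$replay_dir)) {
      note("input.replay_dir", "directory does not exist")
    }
    if (is.null(input$cnpa_csv) || !file.exists(input$cnpa_csv)) {
      note("input.cnpa_csv", "file does not exist")
    }
  }

  scoring <- config$scoring %||% list()
  scoring$gds_cutoff <- scoring$gds_cutoff %||% 0.5
  scoring$domain_cutoff <- scoring$domain_cutoff %||% 1
  for (f in c("gds_cutoff", "domain_cutoff")) {
    if (!is.numeric(scoring[[f]]) || length(scoring[[f]]) != 1L ||
        scoring[[f]] < 0) {
      note(paste0("scoring.", f), "must be a non-negative number")
    }
  }

  weights <- config$error_weights %||% unname(default_error_weights())
  if (!is.numeric(weights) || length(weights) != 8L || any(weights < 0)) {
    note("error_weights", "must be 8 non-negative numbers")
  }

  sel <- config$selection %||% list()
  sel$n_splits <- sel$n_splits %||% 5L
  sel$k <- sel$k %||% 100L
  sel$seed <- sel$seed %||% 0L
  if (!is.numeric(sel$k) || length(sel$k) != 1L || sel$k < 1) {
    note("selection.k", "must be a positive integer")
  }
  if (!is.numeric(sel$n_splits) || sel$n_splits < 2) {
    note("selection.n_splits", "must be an integer >= 2")
  }
  if (!is.numeric(sel$seed) || sel$seed != round(sel$seed)) {
    note("selection.seed", "must be an integer")
  }

  stab <- config$stability %||% list()
  stab$p <- stab$p %||% 0.5
  if (!is.numeric(stab$p) || stab$p < 0 || stab$p > 1) {
    note("stability.p", "must be in [0, 1]")
  }

  assoc <- config$association %||% list()
  assoc$alpha <- assoc$alpha %||% 0.05
  if (!is.numeric(assoc$alpha) || assoc$alpha <= 0 || assoc$alpha >= 1) {
    note("association.alpha", "must be in (0, 1)")
  }

  if (length(errs)) {
    stop_cfg("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  }
  structure(
    list(cohort = spec, input = input, scoring = scoring,
         error_weights = stats::setNames(as.numeric(weights), error_types()),
         selection = lapply(sel, as.numeric),
         stability = stab, association = assoc,
         output_dir = config$output_dir %||% NULL),
    class = "pipeline_config"
  )
}

#' Run the full screening pipeline
#'
#' Stages, in data-dependency order: simulate (or load) the cohort, score the
#' CNPA table (GDS -> HAND and domain flags), featurize the replay sessions,
#' rank variables per stratified split and form the top-k consensus (with an
#' advisory elbow estimate per split), compute list-stability diagnostics,
#' and test domain associations of the consensus variables. All tables are
#' written under `out_dir` together with a run manifest; identical
#' configuration and seed reproduce identical files.
#'
#' @param config A `pipeline_config` (or anything [validate_config()]
#'   accepts).
#' @param out_dir Output directory; overrides `config$output_dir`.
#' @param quiet Suppress per-stage log messages.
#' @return (Invisibly) list of class `vdthand_run` with all in-memory stage
#'   results: `cohort`, `scored`, `features`, `ranked`, `elbows`,
#'   `consensus`, `summaries`, `prevalence`, `stability`, `association`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  out_dir <- out_dir %||% config$output_dir
  if (is.null(out_dir)) stop_cfg("output_dir: no output directory given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, ...) {
    if (!quiet) message("[", stage, "] ", ...)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- simulate / load ------------------------------------------------------
  truth <- NULL
  if (length(config$input)) {
    dat <- stage("load", {
      files <- sort(list.files(config$input$replay_dir,
                               pattern = "\\.json$", full.names = TRUE))
      if (!length(files)) stop("no replay files found")
      list(sessions = lapply(files, parse_replay),
           cnpa = read_cnpa_csv(config$input$cnpa_csv))
    })
    say("load", length(dat$sessions), " replay files")
  } else {
    co <- stage("simulate", generate_cohort(config$cohort))
    truth <- co$truth
    dat <- list(sessions = co$sessions, cnpa = co$cnpa)
    say("simulate", length(dat$sessions), " participants (",
        sum(truth$hand_labels), " HAND), ",
        length(truth$informative_variable_ids), " planted variables")
    write_ground_truth(truth, file.path(out_dir, "ground_truth.json"))
  }

  # -- score ----------------------------------------------------------------
  scored <- stage("score", score_cohort(
    dat$cnpa,
    gds_cutoff = config$scoring$gds_cutoff,
    domain_cutoff = config$scoring$domain_cutoff
  ))
  labels <- scored$hand
  say("score", sum(labels), "/", length(labels), " classified HAND-positive")
  write_deficit_csv(scored, file.path(out_dir, "deficit_summary.csv"))
  prevalence <- stage("score", domain_prevalence_table(scored))
  utils::write.csv(prevalence, file.path(out_dir, "domain_prevalence.csv"),
                   row.names = FALSE)

  # -- featurize ------------------------------------------------------------
  fm <- stage("featurize", summarize_variables(
    dat$sessions, error_weights = config$error_weights
  ))
  say("featurize", ncol(fm$values), " variables retained (",
      nrow(fm$dropped), " zero-variance removed)")
  write_feature_csv(fm, file.path(out_dir, "feature_matrix.csv"))

  # -- select ---------------------------------------------------------------
  sel <- config$selection
  M <- ncol(fm$values)
  if (sel$k > M) {
    stop("pipeline stage 'select' failed: selection.k = ", sel$k,
         " exceeds the number of retained variables M = ", M, call. = FALSE)
  }
  splits <- stage("select", stratified_training_sets(
    labels, n_splits = sel$n_splits, seed = sel$seed
  ))
  ranked <- stage("select", lapply(seq_along(splits$training), function(s) {
    kw_rank(fm, labels, training = splits$training[[s]], split_id = s)
  }))
  elbows <- vapply(ranked, function(r) {
    elbow_k(mean_topk_curve(r))
  }, numeric(1))
  say("select", "advisory elbow k per split: ",
      paste(ifelse(is.na(elbows), "none", elbows), collapse = ", "),
      "; using k = ", sel$k)
  consensus <- stage("select", form_consensus(ranked, k = sel$k))
  say("select", nrow(consensus), " variables in the consensus")
  write_ranked_lists(ranked, file.path(out_dir, "ranked_lists"))
  utils::write.csv(consensus, file.path(out_dir, "consensus.csv"),
                   row.names = FALSE)
  summaries <- stage("select", group_summaries(fm, labels, consensus))
  utils::write.csv(summaries, file.path(out_dir, "group_summaries.csv"),
                   row.names = FALSE)

  # -- stability ------------------------------------------------------------
  stab <- stage("stability", stability_report(
    ranked, k = sel$k, p = config$stability$p
  ))
  say("stability", "mean pairwise Jaccard ", round(stab$mean_jaccard, 3),
      ", mean intersection ", round(stab$mean_intersection_size, 1))
  write_stability_json(stab, file.path(out_dir, "stability.json"))

  # -- associate ------------------------------------------------------------
  assoc <- if (nrow(consensus)) {
    flags <- scored[, grep("^impaired_", names(scored)), drop = FALSE]
    names(flags) <- sub("^impaired_", "", names(flags))
    stage("associate", spearman_domain_matrix(
      fm, consensus, flags, alpha = config$association$alpha
    ))
  } else {
    NULL
  }
  if (!is.null(assoc)) {
    utils::write.csv(assoc, file.path(out_dir, "domain_associations.csv"),
                     row.names = FALSE)
    say("associate", sum(assoc$significant_bonferroni, na.rm = TRUE),
        " cells significant after Bonferroni (m = ", attr(assoc, "m"), ")")
  }

  # -- manifest -------------------------------------------------------------
  cfg_path <- file.path(out_dir, "config.json")
  cfg_out <- config
  cfg_out$cohort <- unclass(cfg_out$cohort)
  writeLines(jsonlite::toJSON(unclass(cfg_out), auto_unbox = TRUE,
                              digits = NA, null = "null"), cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("vdthand")),
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = sel$seed,
    n_participants = length(labels),
    n_hand = sum(labels),
    n_variables_computed = M + nrow(fm$dropped),
    n_variables_retained = M,
    n_consensus = nrow(consensus),
    elbow_k_per_split = as.list(ifelse(is.na(elbows), "none", elbows))
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(out_dir, "manifest.json"))

  invisible(structure(
    list(cohort = if (is.null(truth)) dat else
      c(dat, list(truth = truth)),
      scored = scored, features = fm, ranked = ranked, elbows = elbows,
      consensus = consensus, summaries = summaries,
      prevalence = prevalence, stability = stab, association = assoc,
      manifest = manifest),
    class = "vdthand_run"
  ))
}
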