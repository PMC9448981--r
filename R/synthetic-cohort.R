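#' Specification of a synthetic VDT/CNPA cohort
#'
#' Collects the parameters of the synthetic-data generator. Defaults emulate
#' the study conditions: 62 participants with 57% HAND prevalence driving a
#' fixed route recorded at 10 Hz for about 10 minutes. The telemetry scale
#' defaults to a reduced inventory (10 extra channels, 5 zones, ~600 retained
#' variables) suitable for desk-scale runs; the full-scale inventory
#' (22 zones, ~2,600 variables) is reached by raising `n_zones` and
#' `n_channels`.
#'
#' @param n_participants Cohort size (>= 2).
#' @param hand_prevalence Fraction of participants with HAND, in (0, 1). The
#'   number of positives is `round(n_participants * hand_prevalence)`.
#' @param n_channels Number of extra generic telemetry channels beyond the
#'   seven core driving channels (eye-gaze-like channels are modelled this
#'   way).
#' @param n_zones Number of route zones; every session also contains
#'   out-of-zone (`"none"`) samples.
#' @param sample_rate_hz Telemetry sampling rate.
#' @param session_duration_sec Session length in seconds.
#' @param n_informative_variables Number of planted (channel, zone) location
#'   shifts; each designates one `<channel>|median|zone:<z>` feature-matrix
#'   column as ground-truth informative. Must not exceed
#'   `n_channels * n_zones`. Location shifts also move the mean/min/max of
#'   the same cell; the median column is the bookkept representative.
#' @param effect_size Standardized median shift for the HAND group on
#'   informative cells, in units of the channel's noise scale parameter.
#' @param error_rate_hand,error_rate_no_hand Mean event counts per error type
#'   (length 8 in [error_types()] order, or a scalar recycled). Defaults give
#'   the HAND group roughly twice the composite error score of the non-HAND
#'   group, with long-tailed (negative binomial) counts.
#' @param misclassification_rate Probability that a participant's generated
#'   CNPA profile disagrees with the ground-truth label (default 0, making
#'   GDS scoring an exact oracle).
#' @param ar1 Optional within-zone AR(1) coefficient for channel noise
#'   (default 0: stationary independent draws).
#' @param seed Integer master seed; the cohort is a deterministic function of
#'   the spec.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 62,
                        hand_prevalence = 0.57,
                        n_channels = 10,
                        n_zones = 5,
                        sample_rate_hz = 10,
                        session_duration_sec = 600,
                        n_informative_variables = 0,
                        effect_size = 0,
                        error_rate_hand = c(2, 1.5, 2, 0.3, 3, 3, 2, 0.8),
                        error_rate_no_hand = 0.55 *
                          c(2, 1.5, 2, 0.3, 3, 3, 2, 0.8),
                        misclassification_rate = 0,
                        ar1 = 0,
                        seed = 0) {
  assert_scalar_number(n_participants, "n_participants", lower = 2,
                       integerish = TRUE)
  assert_scalar_number(hand_prevalence, "hand_prevalence")
  if (hand_prevalence <= 0 || hand_prevalence >= 1) {
    stop_cfg("hand_prevalence must be strictly between 0 and 1")
  }
  assert_scalar_number(n_channels, "n_channels", lower = 0, integerish = TRUE)
  assert_scalar_number(n_zones, "n_zones", lower = 1, integerish = TRUE)
  assert_scalar_number(sample_rate_hz, "sample_rate_hz", lower = 1e-9)
  assert_scalar_number(session_duration_sec, "session_duration_sec",
                       lower = 1e-9)
  assert_scalar_number(n_informative_variables, "n_informative_variables",
                       lower = 0, integerish = TRUE)
  assert_scalar_number(effect_size, "effect_size", lower = 0)
  assert_scalar_number(misclassification_rate, "misclassification_rate",
                       lower = 0, upper = 1)
  assert_scalar_number(ar1, "ar1", lower = 0, upper = 0.99)
  assert_scalar_number(seed, "seed", integerish = TRUE)
  if (n_informative_variables > n_channels * n_zones) {
    stop_cfg("n_informative_variables exceeds n_channels * n_zones ",
             "planting cells")
  }
  rate8 <- function(x, name) {
    if (length(x) == 1L) x <- rep(x, 8L)
    if (length(x) != 8L || any(x < 0)) {
      stop_cfg(name, " must be a non-negative scalar or length-8 vector")
    }
    stats::setNames(as.numeric(x), error_types())
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      hand_prevalence = hand_prevalence,
      n_channels = as.integer(n_channels),
      n_zones = as.integer(n_zones),
      sample_rate_hz = sample_rate_hz,
      session_duration_sec = session_duration_sec,
      n_informative_variables = as.integer(n_informative_variables),
      effect_size = effect_size,
      error_rate_hand = rate8(error_rate_hand, "error_rate_hand"),
      error_rate_no_hand = rate8(error_rate_no_hand, "error_rate_no_hand"),
      misclassification_rate = misclassification_rate,
      ar1 = ar1,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# Route-level structure shared by every participant: zone layout, posted
# speeds, per-zone channel locations, and channel scale parameters.
# Deterministic in spec$seed.
build_route <- function(spec) {
  with_seed(spec$seed + 1L, {
    n <- round(spec$sample_rate_hz * spec$session_duration_sec)
    Z <- spec$n_zones
    zone_ids <- sprintf("zone_%02d", seq_len(Z))
    block <- floor(n / Z)
    gap <- max(1L, round(0.1 * block))
    zone_track <- rep("none", n)
    for (z in seq_len(Z)) {
      i0 <- (z - 1L) * block
      zone_track[(i0 + gap + 1L):(i0 + block)] <- zone_ids[z]
    }
    extras <- if (spec$n_channels > 0) {
      sprintf("extra_%02d", seq_len(spec$n_channels))
    } else {
      character()
    }
    # channel model: per-zone location mu, participant-effect sd tau,
    # within-session noise sd sigma
    posted <- sample(c(25, 35, 45), Z, replace = TRUE)
    road_heading <- round(stats::runif(Z, 0, 360), 1)
    chans <- list(
      speed_mph = list(mu = posted - 3, tau = 1.5, sigma = 2),
      lane_offset_m = list(mu = stats::runif(Z, -0.2, 0.2), tau = 0.1,
                           sigma = 0.25),
      center_offset_m = list(mu = stats::runif(Z, 0.5, 1.5), tau = 0.3,
                             sigma = 1.2),
      heading_deg = list(mu = road_heading, tau = 0, sigma = 2),
      steering_frac = list(mu = rep(0, Z), tau = 0.01, sigma = 0.05)
    )
    for (ex in extras) {
      chans[[ex]] <- list(mu = stats::runif(Z, -1, 1), tau = 0.5, sigma = 1)
    }
    list(n_samples = n, zone_ids = zone_ids, zone_track = zone_track,
         posted = posted, road_heading = road_heading,
         channels = chans, extras = extras)
  })
}

# pick planted (extra channel, zone) cells; alternating shift signs
plant_cells <- function(spec, route) {
  m <- spec$n_informative_variables
  if (m == 0L) {
    return(data.frame(channel = character(), zone = character(),
                      shift = numeric(), variable_id = character(),
                      stringsAsFactors = FALSE))
  }
  cells <- expand.grid(channel = route$extras, zone = route$zone_ids,
                       stringsAsFactors = FALSE)
  pick <- cells[sample.int(nrow(cells), m), , drop = FALSE]
  sigma <- vapply(pick$channel, function(ch) route$channels[[ch]]$sigma,
                  numeric(1))
  pick$shift <- ifelse(seq_len(m) %% 2 == 1L, 1, -1) *
    spec$effect_size * sigma
  pick$variable_id <- paste(pick$channel, "median",
                            paste0("zone:", pick$zone), sep = "|")
  rownames(pick) <- NULL
  pick
}

# AR(1) noise with stationary sd `sigma`
ar1_noise <- function(n, sigma, phi) {
  w <- stats::rnorm(n, 0, sigma)
  if (phi == 0) return(w)
  as.numeric(stats::filter(w * sqrt(1 - phi^2), phi,
                           method = "recursive", init = w[1]))
}

#' Generate one participant's replay session
#'
#' Channels are stationary location-scale draws per zone around the route's
#' per-zone locations, with a participant-level random offset per channel;
#' HAND participants additionally receive the planted location shifts.
#' Discrete error events are drawn as overdispersed (negative binomial)
#' per-type counts at the group's mean rate and placed uniformly in time.
#'
#' @param spec A [cohort_spec()].
#' @param participant_id Session/participant identifier.
#' @param hand Logical: does this participant carry the planted HAND effects?
#' @param seed Integer seed for this session's draws.
#' @param route Route object; computed from `spec` when omitted (all sessions
#'   of a cohort must share one route).
#' @param shifts Planted-cell table as produced internally by
#'   [generate_cohort()]; applied only when `hand` is `TRUE`.
#' @return A `replay_session`.
#' @export
generate_replay <- function(spec, participant_id = "P001", hand = FALSE,
                            seed = spec$seed, route = NULL, shifts = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(route)) route <- build_route(spec)
  if (is.null(shifts)) shifts <- plant_cells(spec, route)[0, ]
  with_seed(seed, {
    n <- route$n_samples
    zi <- match(route$zone_track, route$zone_ids)  # NA for "none"
    ch <- list()
    for (nm in names(route$channels)) {
      par <- route$channels[[nm]]
      mu_z <- par$mu
      if (hand && nrow(shifts)) {
        sh <- shifts[shifts$channel == nm, , drop = FALSE]
        if (nrow(sh)) {
          idx <- match(sh$zone, route$zone_ids)
          mu_z[idx] <- mu_z[idx] + sh$shift
        }
      }
      # out-of-zone samples continue the neighbouring zone's location
      mu_t <- mu_z[ifelse(is.na(zi), cummax_fill(zi), zi)]
      b <- stats::rnorm(1, 0, par$tau)
      ch[[nm]] <- mu_t + b + ar1_noise(n, par$sigma, spec$ar1)
    }
    posted_t <- route$posted[ifelse(is.na(zi), cummax_fill(zi), zi)]
    road_t <- route$road_heading[ifelse(is.na(zi), cummax_fill(zi), zi)]
    channels <- data.frame(
      speed_mph = ch$speed_mph,
      posted_speed_mph = posted_t,
      lane_offset_m = ch$lane_offset_m,
      center_offset_m = ch$center_offset_m,
      heading_deg = ch$heading_deg %% 360,
      road_heading_deg = road_t,
      steering_frac = ch$steering_frac
    )
    for (ex in route$extras) channels[[ex]] <- ch[[ex]]

    rates <- if (hand) spec$error_rate_hand else spec$error_rate_no_hand
    dur <- n / spec$sample_rate_hz
    ev <- list()
    for (ty in error_types()) {
      cnt <- stats::rnbinom(1, size = 2, mu = rates[[ty]])
      if (cnt > 0) {
        t_ev <- sort(round(stats::runif(cnt, 0, dur - 1e-6), 4))
        z_ev <- route$zone_track[pmin(n, floor(t_ev * spec$sample_rate_hz) + 1L)]
        ev[[ty]] <- data.frame(t_sec = t_ev, type = ty, zone_id = z_ev,
                               stringsAsFactors = FALSE)
      }
    }
    events <- if (length(ev)) do.call(rbind, ev) else
      data.frame(t_sec = numeric(), type = character(), zone_id = character())
    rownames(events) <- NULL
    replay_session(participant_id, spec$sample_rate_hz, channels,
                   route$zone_track, events)
  })
}

# carry the last seen zone index forward (and back-fill a leading gap)
cummax_fill <- function(zi) {
  filled <- zi
  last <- NA_integer_
  for (i in seq_along(zi)) {
    if (!is.na(zi[i])) last <- zi[i]
    filled[i] <- last
  }
  if (anyNA(filled)) filled[is.na(filled)] <- filled[which(!is.na(filled))[1]]
  filled
}

# CNPA T-scores conditional on the target label so that GDS classification
# reproduces it (up to spec$misclassification_rate). HAND profiles impair
# 2-5 whole domains (T in 22-32 -> domain deficits >= 2, GDS >= 4/7);
# non-HAND profiles stay in the normal range with occasional single
# sub-threshold tests (domain deficit <= 0.5, GDS < 0.5).
generate_cnpa_row <- function(as_hand, domains) {
  ts <- list()
  normal_scores <- function(k) pmax(43, round(stats::rnorm(k, 52, 5)))
  if (as_hand) {
    n_imp <- sample(2:5, 1)
    imp <- sample(names(domains), n_imp)
    severe <- stats::runif(1) < 0.17  # dementia-range profile
    for (d in names(domains)) {
      k <- length(domains[[d]])
      ts[[d]] <- if (d %in% imp) {
        if (severe) round(stats::runif(k, 15, 25)) else
          round(stats::runif(k, 22, 32))
      } else {
        normal_scores(k)
      }
    }
  } else {
    for (d in names(domains)) ts[[d]] <- normal_scores(length(domains[[d]]))
    if (stats::runif(1) < 0.3) {
      d <- sample(names(domains), 1)
      v <- ts[[d]]
      v[1] <- round(stats::runif(1, 35, 39))
      ts[[d]] <- v
    }
  }
  out <- unlist(unname(ts))
  names(out) <- unlist(unname(domains))
  out
}

#' Generate a complete synthetic cohort
#'
#' Draws ground-truth HAND labels first, then replay sessions (with planted
#' channel shifts for the HAND group on informative cells) and CNPA T-score
#' profiles conditional on label, so that downstream GDS scoring reproduces
#' the labels exactly when `misclassification_rate` is 0. The whole cohort is
#' a deterministic function of the spec (including its seed).
#'
#' @param spec A [cohort_spec()].
#' @return List of class `synthetic_cohort`: `sessions` (list of
#'   `replay_session`), `cnpa` (data frame of T-scores), `truth` (list with
#'   `hand_labels` — named logical —, `informative_variable_ids`,
#'   `planted_shift` — named numeric —, `planted_cells`), and `spec`.
#' @export
#' @examples
#' co <- generate_cohort(cohort_spec(n_participants = 6, n_zones = 2,
#'                                   n_channels = 2,
#'                                   session_duration_sec = 10))
#' sum(co$truth$hand_labels)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  route <- build_route(spec)
  n <- spec$n_participants
  ids <- sprintf("P%03d", seq_len(n))
  n_pos <- round(n * spec$hand_prevalence)
  if (n_pos == 0L || n_pos == n) {
    stop_cfg("hand_prevalence leaves one group empty at this cohort size")
  }
  setup <- with_seed(spec$seed, {
    labels <- sample(rep(c(TRUE, FALSE), c(n_pos, n - n_pos)))
    cells <- plant_cells(spec, route)
    part_seeds <- sample.int(.Machine$integer.max - 1L, n)
    flip <- stats::runif(n) < spec$misclassification_rate
    cnpa_seed <- sample.int(.Machine$integer.max - 1L, 1)
    list(labels = labels, cells = cells, part_seeds = part_seeds,
         flip = flip, cnpa_seed = cnpa_seed)
  })
  labels <- stats::setNames(setup$labels, ids)
  sessions <- lapply(seq_len(n), function(i) {
    generate_replay(spec, ids[i], hand = labels[i],
                    seed = setup$part_seeds[i], route = route,
                    shifts = setup$cells)
  })
  domains <- cnpa_domains()
  cnpa <- with_seed(setup$cnpa_seed, {
    rows <- lapply(seq_len(n), function(i) {
      as_hand <- xor(labels[i], setup$flip[i])
      generate_cnpa_row(as_hand, domains)
    })
    data.frame(participant_id = ids, do.call(rbind, rows),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  truth <- list(
    hand_labels = labels,
    informative_variable_ids = setup$cells$variable_id,
    planted_shift = stats::setNames(setup$cells$shift,
                                    setup$cells$variable_id),
    planted_cells = setup$cells
  )
  structure(list(sessions = sessions, cnpa = cnpa, truth = truth,
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", length(x$sessions), " participants (",
      sum(x$truth$hand_labels), " HAND), ",
      length(x$truth$informative_variable_ids),
      " planted informative variables\n", sep = "")
  invisible(x)
}

#' Write ground truth as a JSON sidecar
#'
#' @param truth The `truth` element of a [generate_cohort()] result.
#' @param path Output JSON path.
#' @export
write_ground_truth <- function(truth, path) {
  obj <- list(
    hand_labels = as.list(truth$hand_labels),
    informative_variable_ids = truth$informative_variable_ids,
    planted_shift = as.list(truth$planted_shift)
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}
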