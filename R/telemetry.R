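#' Higher-order error types recorded in a replay file
#'
#' The eight discrete error events a VDT session can record. The order is
#' fixed: it defines the order of the weight vector of [vdt_error_score()]
#' and of count columns in the feature matrix.
#'
#' @return Character vector of length 8.
#' @export
error_types <- function() {
  c(
    "vehicle_collision_front", "vehicle_collision_side_rear",
    "static_object_collision", "pedestrian_collision",
    "red_light_error", "stop_sign_error",
    "navigation_error", "teleport"
  )
}

#' Default weights for the composite VDT Error Score
#'
#' The production scoring weights are proprietary; these defaults are a
#' documented stand-in that weights collisions (especially pedestrian
#' collisions) heaviest. Any non-negative length-8 vector in the
#' [error_types()] order may be substituted.
#'
#' @return Named numeric vector of length 8.
#' @export
default_error_weights <- function() {
  stats::setNames(c(5, 5, 3, 10, 2, 2, 1, 4), error_types())
}

# required per-sample channel fields of the replay JSON dialect
.replay_core_channels <- c(
  "speed_mph", "posted_speed_mph", "lane_offset_m", "center_offset_m",
  "heading_deg", "road_heading_deg", "steering_frac"
)

#' Construct a replay session object
#'
#' @param session_id Character identifier.
#' @param sample_rate_hz Sampling rate (Hz).
#' @param channels Data frame of per-sample channel values containing at least
#'   the seven core channels (`speed_mph`, `posted_speed_mph`,
#'   `lane_offset_m`, `center_offset_m`, `heading_deg`, `road_heading_deg`,
#'   `steering_frac`); extra numeric columns are carried as generic channels.
#' @param zone_track Character vector (one entry per sample) of zone
#'   identifiers; `"none"` marks out-of-zone samples.
#' @param events Data frame with columns `t_sec`, `type`, `zone_id`;
#'   `type` must come from [error_types()].
#' @return Object of class `replay_session`.
#' @export
replay_session <- function(session_id, sample_rate_hz, channels, zone_track,
                           events = data.frame(t_sec = numeric(),
                                               type = character(),
                                               zone_id = character())) {
  assert_scalar_number(sample_rate_hz, "sample_rate_hz", lower = 1e-9)
  stopifnot(is.data.frame(channels), is.data.frame(events))
  miss <- setdiff(.replay_core_channels, names(channels))
  if (length(miss)) {
    stop("replay is missing required channel(s): ", paste(miss, collapse = ", "))
  }
  n <- nrow(channels)
  if (length(zone_track) != n) {
    stop("zone_track length must equal the number of samples")
  }
  if (nrow(events)) {
    if (!all(c("t_sec", "type", "zone_id") %in% names(events))) {
      stop("events need columns t_sec, type, zone_id")
    }
    bad <- setdiff(unique(events$type), error_types())
    if (length(bad)) stop("unknown error type(s): ", paste(bad, collapse = ", "))
    dur <- n / sample_rate_hz
    if (any(events$t_sec < 0 | events$t_sec > dur)) {
      stop("event t_sec outside the session time range")
    }
  }
  structure(
    list(session_id = as.character(session_id),
         sample_rate_hz = sample_rate_hz,
         channels = channels,
         zone_track = as.character(zone_track),
         events = events),
    class = "replay_session"
  )
}

#' @export
print.replay_session <- function(x, ...) {
  cat("<replay_session> ", x$session_id, ": ", nrow(x$channels),
      " samples @ ", x$sample_rate_hz, " Hz, ",
      length(setdiff(unique(x$zone_track), "none")), " zones, ",
      nrow(x$events), " events\n", sep = "")
  invisible(x)
}

#' Write a replay session as JSON
#'
#' Serializes the session in the package's replay dialect: a top-level object
#' `{session_id, sample_rate_hz, samples, events}` where each sample carries
#' `t_sec`, the channel values and `zone_id`. Channel values are rounded to 4
#' decimals before writing so that write -> parse -> write round-trips
#' byte-identically.
#'
#' @param session A `replay_session`.
#' @param path Output file.
#' @export
write_replay <- function(session, path) {
  ch <- session$channels
  ch[] <- lapply(ch, function(x) round(x, 4))
  n <- nrow(ch)
  samples <- cbind(
    data.frame(t_sec = round((seq_len(n) - 1) / session$sample_rate_hz, 4)),
    ch,
    data.frame(zone_id = session$zone_track)
  )
  ev <- session$events
  ev$t_sec <- round(ev$t_sec, 4)
  obj <- list(
    session_id = jsonlite::unbox(session$session_id),
    sample_rate_hz = jsonlite::unbox(session$sample_rate_hz),
    samples = samples,
    events = ev
  )
  writeLines(
    jsonlite::toJSON(obj, dataframe = "rows", digits = 8, na = "null"),
    path
  )
  invisible(path)
}

#' Parse a replay JSON file
#'
#' Validates the replay dialect and reconstructs the `replay_session`:
#' required channels must be present and timestamps uniformly spaced at
#' `1/sample_rate_hz`.
#'
#' @param path Path to a replay JSON file.
#' @return A `replay_session`.
#' @export
parse_replay <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop("malformed replay JSON: ",
                                           conditionMessage(e)))
  for (f in c("session_id", "sample_rate_hz", "samples")) {
    if (is.null(obj[[f]])) stop("replay file missing field '", f, "'")
  }
  samples <- obj$samples
  miss <- setdiff(c("t_sec", .replay_core_channels, "zone_id"),
                  names(samples))
  if (length(miss)) {
    stop("replay samples missing field(s): ", paste(miss, collapse = ", "))
  }
  rate <- obj$sample_rate_hz
  t <- samples$t_sec
  if (nrow(samples) > 1) {
    expect_t <- (seq_len(nrow(samples)) - 1) / rate
    if (max(abs(t - expect_t)) > 1e-3 / rate) {
      stop("non-uniform timestamps in field 't_sec'")
    }
  }
  ev <- obj$events
  if (is.null(ev) || length(ev) == 0) {
    ev <- data.frame(t_sec = numeric(), type = character(),
                     zone_id = character())
  }
  chan_cols <- setdiff(names(samples), c("t_sec", "zone_id"))
  replay_session(
    session_id = obj$session_id,
    sample_rate_hz = rate,
    channels = samples[, chan_cols, drop = FALSE],
    zone_track = samples$zone_id,
    events = ev
  )
}

#' Derive kinematic channels from a replay session
#'
#' Produces the derived time series used for featurization, each paired with
#' the zone label of the sample it is anchored to:
#' \describe{
#'   \item{forward_accel_mphps}{forward difference of speed times the sample
#'     rate (mph/sec), anchored to the leading sample.}
#'   \item{forward_jerk_mphps2}{forward difference of acceleration times the
#'     sample rate (mph/sec^2).}
#'   \item{speed_vs_limit_mph}{speed minus posted limit (mph).}
#'   \item{lane_deviation_m}{absolute lane offset (m).}
#'   \item{heading_misalignment_deg}{wrapped absolute difference between
#'     vehicle heading and road heading, in [0, 180] degrees.}
#'   \item{below_limit_10mph / below_limit_15mph}{indicator channels: driving
#'     at least 10 (15) mph below the posted limit; summarized as % time.}
#' }
#' The raw channels (and any extra channels in the replay) are passed through
#' unchanged. `road_heading_deg` is route geometry shared by all sessions and
#' typically drops out at the zero-variance filter.
#'
#' @param session A `replay_session` with at least 3 samples.
#' @return Named list of channel objects `list(values, zone, kind)` with
#'   `kind` either `"continuous"` (five summary statistics) or `"indicator"`
#'   (% time).
#' @export
derive_channels <- function(session) {
  ch <- session$channels
  n <- nrow(ch)
  if (n < 3) stop("session too short: jerk needs at least 3 samples")
  zt <- session$zone_track
  rate <- session$sample_rate_hz

  cont <- function(v, z) list(values = v, zone = z, kind = "continuous")
  ind <- function(v, z) list(values = v, zone = z, kind = "indicator")

  accel <- diff(ch$speed_mph) * rate
  jerk <- diff(accel) * rate
  mis <- abs(ch$heading_deg - ch$road_heading_deg) %% 360
  mis <- ifelse(mis > 180, 360 - mis, mis)
  under <- ch$posted_speed_mph - ch$speed_mph

  out <- list()
  for (nm in names(ch)) out[[nm]] <- cont(ch[[nm]], zt)
  out$forward_accel_mphps <- cont(accel, zt[seq_len(n - 1)])
  out$forward_jerk_mphps2 <- cont(jerk, zt[seq_len(n - 2)])
  out$speed_vs_limit_mph <- cont(ch$speed_mph - ch$posted_speed_mph, zt)
  out$lane_deviation_m <- cont(abs(ch$lane_offset_m), zt)
  out$heading_misalignment_deg <- cont(mis, zt)
  out$below_limit_10mph <- ind(as.numeric(under >= 10), zt)
  out$below_limit_15mph <- ind(as.numeric(under >= 15), zt)
  out
}

#' Composite VDT Error Score
#'
#' Linear combination of the eight higher-order error counts (units: error
#' points).
#'
#' @param counts Non-negative integer vector of length 8 in the
#'   [error_types()] order (names, if present, are checked).
#' @param weights Non-negative numeric vector of length 8.
#' @return Numeric scalar.
#' @export
#' @examples
#' vdt_error_score(c(1, 0, 2, 0, 1, 0, 0, 0))
vdt_error_score <- function(counts, weights = default_error_weights()) {
  if (length(counts) != 8L || length(weights) != 8L) {
    stop("counts and weights must have length 8")
  }
  if (any(counts < 0)) stop("error counts must be non-negative")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (!is.null(names(counts)) &&
      !identical(names(counts), error_types())) {
    stop("named counts must follow the error_types() order")
  }
  sum(as.numeric(counts) * as.numeric(weights))
}

# summary stats for one channel over one scope
.scope_stats <- function(v) {
  c(min = min(v), max = max(v), mean = mean(v),
    median = stats::median(v), sd = stats::sd(v))
}

#' Assemble the feature matrix from a collection of replay sessions
#'
#' For every channel (raw + derived), every summary statistic and every scope
#' (global plus each route zone) one column is computed; indicator channels
#' contribute a single % time column per scope, and the eight error types
#' contribute count columns per scope plus the global composite
#' [vdt_error_score()]. Columns whose value is identical across all
#' participants (zero variance) are removed and logged in the `dropped`
#' element; the surviving columns keep their original column index, which is
#' the tie-breaking order of the screening stage.
#'
#' @param sessions List of `replay_session` objects sharing one route (i.e.
#'   one zone set).
#' @param error_weights Weights for the composite error score.
#' @param drop_zero_variance Remove constant columns (default `TRUE`).
#' @param missing_zone Policy when a session has no samples in some zone:
#'   `"error"` (default; the fixed route guarantees full exposure) or
#'   `"drop"` to discard the affected columns.
#' @return Object of class `vdt_feature_matrix`: list with `values`
#'   (participants x variables numeric matrix), `meta` (data frame:
#'   `variable_id`, `channel`, `stat`, `scope`, `column_index`) and `dropped`
#'   (meta rows of removed columns).
#' @export
summarize_variables <- function(sessions,
                                error_weights = default_error_weights(),
                                drop_zero_variance = TRUE,
                                missing_zone = c("error", "drop")) {
  missing_zone <- match.arg(missing_zone)
  stopifnot(length(sessions) >= 1)
  zones <- sort(setdiff(unique(unlist(
    lapply(sessions, function(s) s$zone_track)
  )), "none"))
  scopes <- c("global", paste0("zone:", zones))
  ids <- vapply(sessions, function(s) s$session_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate session ids")

  per_session <- lapply(sessions, function(s) {
    chans <- derive_channels(s)
    vals <- list()
    for (nm in names(chans)) {
      co <- chans[[nm]]
      stats_of <- function(v) {
        if (co$kind == "indicator") c(pct_time = mean(v)) else .scope_stats(v)
      }
      g <- stats_of(co$values)
      names(g) <- paste(nm, names(g), "global", sep = "|")
      vals[[length(vals) + 1L]] <- g
      for (z in zones) {
        inz <- co$zone == z
        if (!any(inz)) {
          if (missing_zone == "error") {
            stop("session ", s$session_id, " has no samples in zone ", z)
          }
          zs <- stats_of(NA_real_)  # placeholder column, dropped later
          zs[] <- NA_real_
        } else {
          zs <- stats_of(co$values[inz])
        }
        names(zs) <- paste(nm, names(zs), paste0("zone:", z), sep = "|")
        vals[[length(vals) + 1L]] <- zs
      }
    }
    # error counts per type, per scope
    for (ty in error_types()) {
      ev <- s$events[s$events$type == ty, , drop = FALSE]
      cnt <- c(nrow(ev), vapply(zones, function(z) sum(ev$zone_id == z),
                                numeric(1)))
      names(cnt) <- paste(ty, "count", scopes, sep = "|")
      vals[[length(vals) + 1L]] <- cnt
    }
    tot <- vapply(error_types(), function(ty) sum(s$events$type == ty),
                  numeric(1))
    vals[[length(vals) + 1L]] <- c(
      "vdt_error_score|score|global" = vdt_error_score(tot, error_weights)
    )
    unlist(vals)
  })

  first <- names(per_session[[1]])
  values <- do.call(rbind, lapply(per_session, function(v) {
    if (!identical(names(v), first)) stop("sessions yield differing variables")
    v
  }))
  rownames(values) <- ids

  parts <- do.call(rbind, strsplit(first, "|", fixed = TRUE))
  meta <- data.frame(
    variable_id = first, channel = parts[, 1], stat = parts[, 2],
    scope = parts[, 3], column_index = seq_along(first),
    stringsAsFactors = FALSE
  )

  keep <- rep(TRUE, ncol(values))
  if (missing_zone == "drop") keep <- keep & !apply(is.na(values), 2, any)
  if (drop_zero_variance) {
    rng <- apply(values, 2, function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) 0 else max(x) - min(x)
    })
    keep <- keep & (rng > 0)
  }
  structure(
    list(values = values[, keep, drop = FALSE],
         meta = meta[keep, , drop = FALSE],
         dropped = meta[!keep, , drop = FALSE]),
    class = "vdt_feature_matrix"
  )
}

#' @export
print.vdt_feature_matrix <- function(x, ...) {
  cat("<vdt_feature_matrix> ", nrow(x$values), " participants x ",
      ncol(x$values), " variables (", nrow(x$dropped),
      " zero-variance/incomplete columns removed)\n", sep = "")
  invisible(x)
}

#' Write / read a feature matrix as CSV plus a JSON metadata sidecar
#'
#' @param fm A `vdt_feature_matrix`.
#' @param path CSV path; metadata goes to `<path>.meta.json`.
#' @return `read_feature_csv()` returns a `vdt_feature_matrix`.
#' @export
write_feature_csv <- function(fm, path) {
  df <- data.frame(participant_id = rownames(fm$values),
                   fm$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta_path <- paste0(path, ".meta.json")
  writeLines(jsonlite::toJSON(list(meta = fm$meta, dropped = fm$dropped),
                              dataframe = "columns", digits = NA), meta_path)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  side <- jsonlite::fromJSON(paste0(path, ".meta.json"))
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$participant_id
  meta <- as.data.frame(side$meta, stringsAsFactors = FALSE)
  dropped <- as.data.frame(side$dropped, stringsAsFactors = FALSE)
  if (!identical(meta$variable_id, colnames(values))) {
    stop("feature CSV and metadata sidecar disagree on columns")
  }
  structure(list(values = values, meta = meta, dropped = dropped),
            class = "vdt_feature_matrix")
}
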