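#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

stop_cfg <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...), class = c("vdthand_config_error", "error")))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_cfg(name, " must be a single finite number")
  }
  if (integerish && x != round(x)) stop_cfg(name, " must be an integer")
  if (x < lower || x > upper) {
    stop_cfg(name, " must be in [", lower, ", ", upper, "]")
  }
  invisible(x)
}

# %||% as in rlang, without the dependency
`%||%` <- function(a, b) if (is.null(a)) b else a
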