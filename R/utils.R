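# Internal helpers shared across modules.

# Evaluate a function under a temporary RNG state so callers' streams are
# never disturbed. `seed` must be a single finite number below 2^31.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Deterministic per-draw/per-stream seed derivation from one master seed.
# Named substreams keep draw k's randomness fixed when more draws are added.
derive_seed <- function(master, draw, stream) {
  streams <- c(scenario = 1, climate = 2, sealevel = 3, damages = 4,
               coastal = 5, valuation = 6, fixtures = 7)
  s <- streams[[stream]]
  # integer hash kept in double space; all intermediates < 2^53
  h <- (master %% 2147483647) * 2654435
  h <- (h + draw * 97561 + s * 7919) %% 2147483629
  h + 1
}

# Two-sided quantile-anchored transform of a standard normal: monotone map
# with exact 5%/50%/95% quantiles (q05, q50, q95). Log scale keeps the
# variable positive and the spread multiplicative.
qanchor <- function(z, q05, q50, q95, log = FALSE) {
  z95 <- stats::qnorm(0.95)
  if (log) {
    s_lo <- log(q50 / q05) / z95
    s_hi <- log(q95 / q50) / z95
    q50 * exp(z * ifelse(z < 0, s_lo, s_hi))
  } else {
    s_lo <- (q50 - q05) / z95
    s_hi <- (q95 - q50) / z95
    q50 + z * ifelse(z < 0, s_lo, s_hi)
  }
}

check_ordered_anchors <- function(a, name) {
  if (!(a[1] <= a[2] && a[2] <= a[3])) {
    stop("anchor quantiles for '", name, "' are not ordered (q05 <= q50 <= q95): ",
         paste(signif(a, 6), collapse = ", "), call. = FALSE)
  }
  invisible(a)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
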