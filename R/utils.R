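#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Half-away-from-zero rounding (base round() rounds half to even).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Moment coefficient of skewness; NA for < 3 values or zero variance.
moment_skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(NA_real_)
  mean((x - m)^3) / s2^1.5
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  if (positive && x <= 0) stopf("`%s` must be > 0", name)
  invisible(x)
}
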