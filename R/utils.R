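# Run an expression under a fixed RNG state, restoring the caller's state.
# All simulation entry points route their randomness through this so that a
# single integer seed fully determines every generated table.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a distinct sub-seed from a root seed and a stream index, staying
# within 32-bit integer range.
sub_seed <- function(seed, stream) {
  (as.integer(seed) * 1009L + as.integer(stream) * 9973L) %% 2147483647L
}

#' Stationary AR(1) series
#'
#' Generates a mean-zero first-order autoregressive series
#' `x[t] = phi * x[t-1] + e[t]` with Gaussian innovations scaled so the
#' marginal standard deviation equals `sd`. Used as the noise process of the
#' synthetic microclimate generator; exported so its serial-correlation
#' contract can be checked directly.
#'
#' @param n Length of the series.
#' @param phi AR(1) coefficient, `|phi| < 1`.
#' @param sd Marginal standard deviation of the series (not the innovation).
#' @return Numeric vector of length `n`.
#' @examples
#' x <- with(list(), {set.seed(1); ar1_series(1000, 0.7, 1)})
#' @export
ar1_series <- function(n, phi, sd = 1) {
  stopifnot(n >= 1, is.finite(phi), abs(phi) < 1, is.finite(sd), sd >= 0)
  if (sd == 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - phi^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) {
    e <- stats::rnorm(n - 1, 0, innov_sd)
    for (t in 2:n) x[t] <- phi * x[t - 1] + e[t - 1]
  }
  x
}
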