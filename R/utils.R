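#' Shared quantile convention
#'
#' All quantiles in the package (tile thresholds, dynamic contrast thresholds,
#' noise levels, the surface offset percentile) go through this single routine:
#' linear interpolation between order statistics, i.e. `stats::quantile`
#' type 7.
#'
#' @param x numeric vector, must be non-empty and finite.
#' @param p probability (or vector of probabilities) in \[0, 1\].
#' @return numeric vector of quantiles, unnamed.
#' @export
intensity_quantile <- function(x, p) {
  stopifnot(length(x) > 0L, all(is.finite(x)), all(p >= 0 & p <= 1))
  stats::quantile(x, probs = p, type = 7, names = FALSE)
}

#' Invert the empirical type-7 quantile function
#'
#' Given sample `x` and a target value `y`, returns the probability `p` such
#' that the type-7 quantile of `x` at `p` equals `y` (the piecewise-linear
#' empirical CDF inverse). Values outside the sample range clamp to 0 or 1.
#' On flat segments (ties) the right-most matching probability is returned.
#'
#' @param x numeric sample.
#' @param y target quantile value.
#' @return probability in \[0, 1\].
#' @keywords internal
invert_quantile <- function(x, y) {
  v <- sort(x)
  n <- length(v)
  if (n == 1L || y <= v[1L]) return(if (y >= v[n]) 1 else 0)
  if (y >= v[n]) return(1)
  i <- findInterval(y, v)  # largest i with v[i] <= y
  frac <- if (v[i + 1L] > v[i]) (y - v[i]) / (v[i + 1L] - v[i]) else 0
  (i - 1 + frac) / (n - 1)
}

# Evaluate a function under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# round() in R rounds half to even; the formats and shift maps here need
# explicit conventions, so both half-up and half-down are spelled out.
round_half_up <- function(x) floor(x + 0.5)
round_half_down <- function(x) ceiling(x - 0.5)
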