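# Small phantoms used across test files: 60 x 40 x 300 lattice keeps every
# unit test fast while leaving room for hairs above and vessels below the
# surface (true surface must stay within [40, n_z - 100]).

small_phantom <- function(seed = 1L, surface = c(c00 = 120, c10 = 0.3),
                          n_hairs = 0L, noise_sd = 0, n_vessels = 2L, ...) {
  generate_phantom(phantom_spec(
    n_x = 60L, n_y = 40L, n_z = 300L,
    surface_coefficients = surface,
    n_hairs = n_hairs, noise_sd = noise_sd, n_vessels = n_vessels,
    seed = seed, ...))
}

# Plane-only points for the fitting tests.
plane_points <- function(n, c0, cx, cy, seed = 1L, nx = 50, ny = 30) {
  set.seed(seed)
  x <- sample(seq_len(nx), n, replace = TRUE)
  y <- sample(seq_len(ny), n, replace = TRUE)
  surface_point_set(data.frame(
    x = x, y = y, z = c0 + cx * x + cy * y, band = "LF", included = TRUE))
}

# Brute-force weighted Fleiss' kappa: enumerate all ordered rater pairs per
# scan for the observed disagreement and use the pooled marginal category
# distribution for the expected disagreement. Independent of the package's
# vectorized implementation.
brute_force_kappa <- function(ratings, weights) {
  levels <- attr(weights, "levels")
  n <- nrow(ratings)
  d_obs <- numeric(n)
  pi_q <- rep(0, length(levels))
  for (i in seq_len(n)) {
    vals <- ratings[i, ]
    vals <- vals[!is.na(vals)]
    r <- length(vals)
    s <- 0
    for (a in seq_len(r)) for (b in seq_len(r)) if (a != b)
      s <- s + weights[match(vals[a], levels), match(vals[b], levels)]
    d_obs[i] <- s / (r * (r - 1))
    for (v in vals) pi_q[match(v, levels)] <- pi_q[match(v, levels)] + 1 / r
  }
  pi_q <- pi_q / n
  d_exp <- 0
  for (q1 in seq_along(levels)) for (q2 in seq_along(levels))
    d_exp <- d_exp + pi_q[q1] * pi_q[q2] * weights[q1, q2]
  1 - mean(d_obs) / d_exp
}
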