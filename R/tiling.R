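#' Fixed 4 x 4 raster tiling of the lateral domain
#'
#' Tile boundaries derive from the fractions `d = (0, 0.15, 0.5, 0.85, 1)`
#' by `a_j = floor(d_j * n_x + 1/2)` and likewise `b_j` for y. Tile
#' `t = 1..16` covers the half-open box
#' `a_p < x <= a_(p+1)`, `b_q < y <= b_(q+1)` with `p = ((t-1) mod 4) + 1`
#' and `q = ceiling(t/4)`, so the 16 tiles partition the lateral lattice.
#' The outer tiles are narrow (15% of the extent) so that edges and corners
#' still contribute enough surface points to the polynomial fit.
#'
#' @param n_x,n_y lateral lattice dimensions (both >= 4).
#' @return object of class `raster_tiling` with boundary vectors `a`, `b`.
#' @export
compute_tiling <- function(n_x, n_y) {
  stopifnot(n_x >= 4L, n_y >= 4L)
  d <- c(0, 0.15, 0.5, 0.85, 1)
  a <- floor(d * n_x + 0.5)
  b <- floor(d * n_y + 0.5)
  if (any(diff(a) < 1) || any(diff(b) < 1))
    stop("lattice too small for 4 non-empty tiles per axis")
  structure(list(a = a, b = b, n_x = as.integer(n_x), n_y = as.integer(n_y)),
            class = "raster_tiling")
}

#' Tile index of lateral positions
#'
#' @param tiling [compute_tiling()] result.
#' @param x,y lateral coordinates (vectors of equal length) within the
#'   lattice.
#' @return integer vector of tile indices in 1..16.
#' @export
tile_of <- function(tiling, x, y) {
  stopifnot(inherits(tiling, "raster_tiling"), length(x) == length(y))
  if (any(x < 1 | x > tiling$n_x | y < 1 | y > tiling$n_y))
    stop("coordinates outside the lateral lattice")
  px <- findInterval(x, tiling$a, left.open = TRUE)
  qy <- findInterval(y, tiling$b, left.open = TRUE)
  (qy - 1L) * 4L + px
}

# Full n_x x n_y matrix of tile indices.
tile_map <- function(tiling) {
  px <- findInterval(seq_len(tiling$n_x), tiling$a, left.open = TRUE)
  qy <- findInterval(seq_len(tiling$n_y), tiling$b, left.open = TRUE)
  outer(px, (qy - 1L) * 4L, "+")
}

#' Per-column depth search range
#'
#' A surface range restricts, for every z-column, the depth interval inside
#' which surface points may be selected. `shallow` is the detector-side
#' bound (smaller k) and `deep` the skin-side bound. `full_depth_range()`
#' marks the unrestricted range.
#'
#' @param shallow,deep numeric matrices (n_x x n_y) with
#'   `shallow <= deep` columnwise; values are clamped to the depth lattice
#'   on use.
#' @return object of class `surface_range`.
#' @export
surface_range <- function(shallow, deep) {
  stopifnot(is.matrix(shallow), identical(dim(shallow), dim(deep)),
            all(shallow <= deep))
  structure(list(shallow = shallow, deep = deep, full = FALSE),
            class = "surface_range")
}

#' @rdname surface_range
#' @export
full_depth_range <- function() {
  structure(list(shallow = NULL, deep = NULL, full = TRUE),
            class = "surface_range")
}

# Integer per-column depth bounds [lo, hi] clamped to 1..n_z. A non-full
# interval that contains no integer after clamping collapses to the nearest
# single voxel.
range_bounds <- function(range, dims) {
  nz <- dims[3]
  if (range$full) {
    lo <- matrix(1L, dims[1], dims[2])
    hi <- matrix(nz, dims[1], dims[2])
  } else {
    lo <- pmax(1, ceiling(range$shallow))
    hi <- pmin(nz, floor(range$deep))
    bad <- lo > hi
    if (any(bad)) {
      mid <- clamp(round_half_up((range$shallow + range$deep) / 2), 1, nz)
      lo[bad] <- mid[bad]
      hi[bad] <- mid[bad]
    }
    storage.mode(lo) <- "integer"; storage.mode(hi) <- "integer"
  }
  list(lo = lo, hi = hi)
}

#' Depth-restricted maximum intensity projection
#'
#' Per-column maximum of the volume over the depths inside `range`; equals
#' the plain z-MIP when the range is the full depth.
#'
#' @param volume [rsom_volume()].
#' @param range [surface_range()] or [full_depth_range()].
#' @return numeric matrix (n_x x n_y).
#' @export
zmip_restricted <- function(volume, range = full_depth_range()) {
  stopifnot(inherits(volume, "rsom_volume"), inherits(range, "surface_range"))
  d <- dim(volume)
  b <- range_bounds(range, d)
  out <- matrix(-Inf, d[1], d[2])
  for (k in seq_len(d[3])) {
    sl <- volume$values[, , k]
    inside <- b$lo <= k & k <= b$hi
    out[inside] <- pmax(out[inside], sl[inside])
  }
  out
}

#' Tile-local surface-point thresholds
#'
#' For tile `t` the threshold is
#' `th_t = max( (tau/sensitivity) * q_alpha(zMIP_rho restricted to t),
#'              (0.15 * tau/sensitivity) * q_alpha_relaxed(zMIP_rho) )`,
#' where the second term is a global floor that suppresses pure-noise
#' detections in tiles with little or no signal, and
#' `alpha_relaxed = alpha - (1 - alpha)/3`.
#'
#' @param volume single-band [rsom_volume()] (thresholds are band-specific).
#' @param tiling [compute_tiling()].
#' @param range [surface_range()] used for the restricted z-MIP.
#' @param alpha quantile level in (0, 1].
#' @param tau per-iteration threshold multiplier.
#' @param sensitivity global detection sensitivity (larger = lower
#'   thresholds).
#' @return object of class `threshold_set`: fields `th` (16 thresholds),
#'   `alpha`, `alpha_relaxed`.
#' @export
local_thresholds <- function(volume, tiling, range = full_depth_range(),
                             alpha, tau = 1, sensitivity = 1) {
  stopifnot(alpha > 0, alpha <= 1, tau > 0, sensitivity > 0)
  zm <- zmip_restricted(volume, range)
  tm <- tile_map(tiling)
  alpha_relaxed <- alpha - (1 - alpha) / 3
  floor_th <- 0.15 * tau / sensitivity * intensity_quantile(zm, alpha_relaxed)
  th <- vapply(1:16, function(t) {
    vals <- zm[tm == t]
    max(tau / sensitivity * intensity_quantile(vals, alpha), floor_th)
  }, 0)
  structure(list(th = th, alpha = alpha, alpha_relaxed = alpha_relaxed),
            class = "threshold_set")
}

#' Noise window above the current surface estimate
#'
#' The 41-voxel window centred on the detector-side (shallow) boundary of
#' the surface range: per column `[round(shallow) - 20, round(shallow) + 20]`,
#' clamped to the depth lattice on use. The noise level just above the
#' estimated surface is measured inside this window.
#'
#' @param range proper (non-full) [surface_range()].
#' @return [surface_range()] covering the window.
#' @export
noise_window <- function(range) {
  stopifnot(inherits(range, "surface_range"), !range$full)
  centre <- round_half_up(range$shallow)
  surface_range(centre - 20, centre + 20)
}

#' Adaptive quantile level from the noise above the surface
#'
#' Measures the 95th percentile of the z-MIP restricted to the 41-voxel
#' noise window above the surface estimate, clamps it between the
#' sensitivity-scaled `alpha_min`/`alpha_max` quantiles of the full z-MIP,
#' inverts the empirical quantile function at the clamped target, and undoes
#' the threshold relaxation to obtain the iteration's quantile level
#' `alpha_adpt = (3 * alpha_relaxed + 1) / 4`.
#'
#' @param volume single-band [rsom_volume()].
#' @param range proper (non-full) [surface_range()] for the current surface.
#' @param sensitivity global detection sensitivity.
#' @param alpha_min,alpha_max quantile bounds in (0, 1).
#' @return list with `alpha_adpt`, `th_target`, `th_noise`, `th_min`,
#'   `th_max`.
#' @export
adaptive_alpha <- function(volume, range, sensitivity = 1,
                           alpha_min = 0.90, alpha_max = 0.999) {
  stopifnot(inherits(range, "surface_range"), !range$full,
            alpha_min < alpha_max)
  zm_noise <- zmip_restricted(volume, noise_window(range))
  th_noise <- intensity_quantile(zm_noise, 0.95)
  zm <- zmip_restricted(volume, full_depth_range())
  th_min <- intensity_quantile(zm, alpha_min) / sensitivity
  th_max <- intensity_quantile(zm, alpha_max) / sensitivity
  th_target <- min(max(th_noise, th_min), th_max)
  if (max(zm) == min(zm)) {
    warning("degenerate z-MIP (constant); clamping adaptive alpha")
    alpha_relaxed <- alpha_min
  } else {
    alpha_relaxed <- invert_quantile(zm, th_target * sensitivity)
    alpha_relaxed <- clamp(alpha_relaxed, alpha_min, alpha_max)
  }
  list(alpha_adpt = (3 * alpha_relaxed + 1) / 4,
       th_target = th_target, th_noise = th_noise,
       th_min = th_min, th_max = th_max)
}
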