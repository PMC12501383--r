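#' Specification of a synthetic skin phantom
#'
#' Describes a dual-band phantom with known ground truth: a melanin-like
#' sheet (the dominant surface signal) starting at a polynomial depth map
#' `z_true(x, y)`, vessel-like capsules below the sheet (thick in the LF
#' band, thin in the HF band), bright hair-like segments strictly above the
#' sheet, optional Gaussian noise, and isolated bright outlier voxels.
#'
#' The default lattice of 200 x 100 x 500 voxels emulates a 4 mm x 2 mm field
#' scanned at 0.020 mm lateral steps with 4 um depth sampling.
#'
#' @param n_x,n_y,n_z lattice dimensions.
#' @param surface_coefficients named numeric vector of the true-surface
#'   polynomial, names `"cIK"` for the coefficient of `x^I * y^K`
#'   (e.g. `c(c00 = 150, c10 = 0.3)`); total degree at most 3. The evaluated
#'   surface must stay within `[40, n_z - 100]` so there is room for hairs
#'   above and vessels below.
#' @param melanin_intensity intensity of the surface sheet (present in both
#'   bands); the dominant structure by default.
#' @param vessel_intensity_lf,vessel_intensity_hf vessel intensities per band.
#' @param n_vessels vessels rendered per band.
#' @param n_hairs bright line segments above the surface; default intensity
#'   1.5 x melanin to stress outlier exclusion.
#' @param hair_intensity intensity of hair segments (both bands).
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param outlier_fraction fraction of voxels replaced by isolated bright
#'   values (2 x melanin), in `[0, 1)`.
#' @param seed RNG seed; generation is a pure function of spec + seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_x = 200L, n_y = 100L, n_z = 500L,
                         surface_coefficients = c(c00 = 150),
                         melanin_intensity = 100,
                         vessel_intensity_lf = 60,
                         vessel_intensity_hf = 40,
                         n_vessels = 6L, n_hairs = 0L,
                         hair_intensity = 1.5 * melanin_intensity,
                         noise_sd = 0, outlier_fraction = 0,
                         seed = 1L) {
  stopifnot(n_x >= 4L, n_y >= 4L, n_z >= 1L)
  if (is.null(names(surface_coefficients)) ||
      !all(grepl("^c[0-3][0-3]$", names(surface_coefficients))))
    stop("surface_coefficients must be named cIK with I, K in 0..3")
  deg <- vapply(names(surface_coefficients), function(nm)
    as.integer(substr(nm, 2, 2)) + as.integer(substr(nm, 3, 3)), 0L)
  if (any(deg > 3L)) stop("true surface degree must be at most 3")
  if (melanin_intensity <= 0 || vessel_intensity_lf <= 0 ||
      vessel_intensity_hf <= 0 || hair_intensity <= 0)
    stop("intensities must be positive")
  if (n_vessels < 0L || n_hairs < 0L) stop("counts must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop("outlier_fraction must lie in [0, 1)")
  structure(list(
    n_x = as.integer(n_x), n_y = as.integer(n_y), n_z = as.integer(n_z),
    surface_coefficients = surface_coefficients,
    melanin_intensity = melanin_intensity,
    vessel_intensity_lf = vessel_intensity_lf,
    vessel_intensity_hf = vessel_intensity_hf,
    n_vessels = as.integer(n_vessels), n_hairs = as.integer(n_hairs),
    hair_intensity = hair_intensity, noise_sd = noise_sd,
    outlier_fraction = outlier_fraction, seed = as.integer(seed)),
    class = "phantom_spec")
}

eval_surface_coefficients <- function(coefs, x, y) {
  z <- numeric(length(x))
  for (nm in names(coefs)) {
    i <- as.integer(substr(nm, 2, 2)); k <- as.integer(substr(nm, 3, 3))
    z <- z + coefs[[nm]] * x^i * y^k
  }
  z
}

# Stamp spheres of radius r (voxels) around integer centers into linear
# indices of an (nx, ny, nz) array; centers must keep the bounding box inside
# the lattice so linear-index offsets cannot wrap across columns.
capsule_indices <- function(centers, r, nx, ny, nz) {
  g <- seq(-r, r)
  off <- expand.grid(dx = g, dy = g, dz = g)
  off <- off[off$dx^2 + off$dy^2 + off$dz^2 <= r^2, , drop = FALSE]
  off_lin <- off$dx + off$dy * nx + off$dz * nx * ny
  centers[, 1] <- clamp(centers[, 1], 1 + r, nx - r)
  centers[, 2] <- clamp(centers[, 2], 1 + r, ny - r)
  centers[, 3] <- clamp(centers[, 3], 1 + r, nz - r)
  ctr_lin <- centers[, 1] + (centers[, 2] - 1) * nx + (centers[, 3] - 1) * nx * ny
  unique(as.vector(outer(ctr_lin, off_lin, "+")))
}

# Integer centers along the segment p1 -> p2 at roughly unit voxel spacing.
segment_centers <- function(p1, p2) {
  n <- max(2L, ceiling(sqrt(sum((p2 - p1)^2))) + 1L)
  t <- seq(0, 1, length.out = n)
  cbind(round(p1[1] + t * (p2[1] - p1[1])),
        round(p1[2] + t * (p2[2] - p1[2])),
        round(p1[3] + t * (p2[3] - p1[3])))
}

#' Generate a dual-band phantom with ground truth
#'
#' Deterministic given `spec` (including its seed). The melanin sheet spans
#' 2-4 voxels of depth per column starting at the nearest integer depth to
#' `z_true(x, y)`; with zero noise and no hairs, the first voxel of any
#' z-column exceeding half the melanin intensity is exactly that start depth.
#'
#' @param spec [phantom_spec()].
#' @return list with elements `pair` ([scan_pair()]) and `truth`, a
#'   `phantom_truth` object carrying the true surface polynomial and depth
#'   map, the integer sheet start, and hair/vessel voxel masks.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$n_x; ny <- spec$n_y; nz <- spec$n_z
  xg <- seq_len(nx); yg <- seq_len(ny)
  z_true <- outer(xg, yg, function(x, y)
    eval_surface_coefficients(spec$surface_coefficients, x, y))
  if (any(z_true < 40 | z_true > nz - 100))
    stop("true surface leaves the band [40, n_z - 100]; adjust coefficients")

  with_seed(spec$seed, {
    lf <- array(0, dim = c(nx, ny, nz))
    hf <- array(0, dim = c(nx, ny, nz))
    hair_mask <- array(FALSE, dim = c(nx, ny, nz))
    vessel_mask <- array(FALSE, dim = c(nx, ny, nz))

    start <- round_half_up(z_true)
    storage.mode(start) <- "integer"
    thickness <- matrix(sample(2:4, nx * ny, replace = TRUE), nx, ny)
    col_lin <- seq_len(nx * ny)
    for (layer in 0:3) {
      sel <- thickness > layer
      idx <- col_lin[sel] + (start[sel] - 1 + layer) * nx * ny
      idx <- idx[start[sel] + layer <= nz]
      lf[idx] <- spec$melanin_intensity
      hf[idx] <- spec$melanin_intensity
    }

    z_lo <- max(z_true) + 20; z_hi <- nz - 10
    render_vessels <- function(radii) {
      idx_all <- integer(0)
      for (v in seq_len(spec$n_vessels)) {
        p1 <- c(runif(1, 1, nx), runif(1, 1, ny), runif(1, z_lo, z_hi))
        p2 <- c(runif(1, 1, nx), runif(1, 1, ny), runif(1, z_lo, z_hi))
        r <- sample(radii, 1L)
        idx_all <- c(idx_all,
                     capsule_indices(segment_centers(p1, p2), r, nx, ny, nz))
      }
      unique(idx_all)
    }
    if (spec$n_vessels > 0L) {
      idx <- render_vessels(3:6)
      lf[idx] <- pmax(lf[idx], spec$vessel_intensity_lf)
      vessel_mask[idx] <- TRUE
      idx <- render_vessels(1:2)
      hf[idx] <- pmax(hf[idx], spec$vessel_intensity_hf)
      vessel_mask[idx] <- TRUE
    }

    if (spec$n_hairs > 0L) {
      # hairs float in the coupling medium well above the skin (~0.2-0.36 mm)
      hair_hi <- min(z_true) - 45
      hair_lo <- max(5, min(z_true) - 90)
      for (h in seq_len(spec$n_hairs)) {
        p1 <- c(runif(1, 1, nx), runif(1, 1, ny), runif(1, hair_lo, hair_hi))
        p2 <- c(runif(1, 1, nx), runif(1, 1, ny), runif(1, hair_lo, hair_hi))
        idx <- capsule_indices(segment_centers(p1, p2), 1L, nx, ny, nz)
        lf[idx] <- spec$hair_intensity
        hf[idx] <- spec$hair_intensity
        hair_mask[idx] <- TRUE
      }
    }

    if (spec$noise_sd > 0) {
      lf <- lf + array(stats::rnorm(nx * ny * nz, sd = spec$noise_sd),
                       dim = c(nx, ny, nz))
      hf <- hf + array(stats::rnorm(nx * ny * nz, sd = spec$noise_sd),
                       dim = c(nx, ny, nz))
    }

    if (spec$outlier_fraction > 0) {
      n_out <- floor(spec$outlier_fraction * nx * ny * nz)
      if (n_out > 0L) {
        idx <- sample.int(nx * ny * nz, n_out)
        half <- seq_len(n_out) %% 2L == 0L
        lf[idx[half]] <- 2 * spec$melanin_intensity
        hf[idx[!half]] <- 2 * spec$melanin_intensity
      }
    }

    pair <- scan_pair(rsom_volume(lf, "LF"), rsom_volume(hf, "HF"))
    truth <- structure(
      list(surface_coefficients = spec$surface_coefficients,
           true_surface = z_true, surface_start = start,
           hair_mask = hair_mask, vessel_mask = vessel_mask,
           lattice = c(nx, ny, nz)),
      class = "phantom_truth")
    list(pair = pair, truth = truth)
  })
}

#' Evaluate the true surface of a phantom
#'
#' @param truth `phantom_truth` from [generate_phantom()].
#' @param x,y lateral lattice coordinates (vectors of equal length).
#' @return true surface depth `z_true(x, y)` (real, not rounded).
#' @export
evaluate_true_surface <- function(truth, x, y) {
  stopifnot(inherits(truth, "phantom_truth"), length(x) == length(y))
  if (any(x < 1 | x > truth$lattice[1] | y < 1 | y > truth$lattice[2]))
    stop("query outside the lateral lattice")
  eval_surface_coefficients(truth$surface_coefficients, x, y)
}

#' Randomized phantom under the benchmark study conditions
#'
#' Draws one phantom specification from the fixed recovery-study population:
#' a plane tilt of up to +/-30 voxels across the field (split at random
#' between the two lateral directions), centred quadratic bowing of up to 15
#' voxels, 0-3 hairs at 1.5 x melanin intensity, and Gaussian noise with
#' standard deviation 10% of the melanin intensity, on the default
#' 200 x 100 x 500 lattice.
#'
#' @param seed RNG seed; also becomes the generated spec's seed.
#' @return [phantom_spec()].
#' @export
study_phantom_spec <- function(seed) {
  with_seed(seed, {
    nx <- 200L; ny <- 100L
    tilt <- runif(1, -30, 30)
    frac <- runif(1)
    c10 <- tilt * frac / (nx - 1)
    c01 <- tilt * (1 - frac) / (ny - 1)
    bow <- runif(1, -15, 15)       # peak deviation at field centre
    cx <- (nx + 1) / 2
    a <- bow / cx^2                # bow * ((x - cx)/cx)^2, expanded below
    coefs <- c(c00 = 250 + a * cx^2, c10 = c10 - 2 * a * cx, c01 = c01,
               c20 = a)
    phantom_spec(n_x = nx, n_y = ny, n_z = 500L,
                 surface_coefficients = coefs,
                 n_hairs = sample(0:3, 1L),
                 noise_sd = 0.1 * 100,
                 seed = seed)
  })
}
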