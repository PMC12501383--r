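#' Bivariate polynomial surface function
#'
#' `sfit(x, y) = sum over (i,k) of c_ik * x^i * y^k + offset`, with the
#' monomial index set `I = {(i,k): i <= n, k <= m, i + k <= max(n, m)}`
#' enumerated row-major in `i` (i outer, k inner). For numerical
#' conditioning the polynomial is fitted and stored in centred/scaled
#' lateral coordinates; `transform` holds the affine map
#' `x_scaled = (x - xc)/xs`, `y_scaled = (y - yc)/ys`. The offset is 0 until
#' the surface is finalized.
#'
#' @param degree integer pair `(n, m)`.
#' @param terms integer matrix of monomial exponents, columns `i`, `k`.
#' @param coef coefficients in the scaled basis, one per term.
#' @param transform list with `xc`, `xs`, `yc`, `ys`.
#' @param offset final depth offset (voxels).
#' @return object of class `surface_function`.
#' @export
surface_function <- function(degree, terms, coef,
                             transform = list(xc = 0, xs = 1, yc = 0, ys = 1),
                             offset = 0) {
  stopifnot(length(degree) == 2L, is.matrix(terms), ncol(terms) == 2L,
            nrow(terms) == length(coef))
  structure(list(degree = as.integer(degree), terms = terms,
                 coef = as.numeric(coef), transform = transform,
                 offset = offset),
            class = "surface_function")
}

# Monomial exponents for degree (n, m), documented enumeration order.
poly_terms <- function(n, m) {
  g <- expand.grid(k = 0:m, i = 0:n)          # i outer, k inner
  g <- g[g$i + g$k <= max(n, m), c("i", "k")]
  matrix(c(g$i, g$k), ncol = 2L, dimnames = list(NULL, c("i", "k")))
}

poly_design <- function(terms, xs, ys) {
  X <- matrix(1, length(xs), nrow(terms))
  for (t in seq_len(nrow(terms)))
    X[, t] <- xs^terms[t, 1] * ys^terms[t, 2]
  X
}

#' Evaluate a surface function
#'
#' @param sfit [surface_function()].
#' @param x,y lateral coordinates (equal-length vectors).
#' @return surface depth at each position (includes the offset).
#' @export
sf_eval <- function(sfit, x, y) {
  tr <- sfit$transform
  X <- poly_design(sfit$terms, (x - tr$xc) / tr$xs, (y - tr$yc) / tr$ys)
  drop(X %*% sfit$coef) + sfit$offset
}

#' @rdname sf_eval
#' @param n_x,n_y lateral lattice dimensions for dense evaluation.
#' @return `sf_eval_grid` returns the `n_x` x `n_y` matrix of surface depths
#'   over the full lateral lattice.
#' @export
sf_eval_grid <- function(sfit, n_x, n_y) {
  tr <- sfit$transform
  xs <- (seq_len(n_x) - tr$xc) / tr$xs
  ys <- (seq_len(n_y) - tr$yc) / tr$ys
  z <- matrix(0, n_x, n_y)
  for (t in seq_len(nrow(sfit$terms)))
    z <- z + sfit$coef[t] * outer(xs^sfit$terms[t, 1], ys^sfit$terms[t, 2])
  z + sfit$offset
}

#' Candidate surface points
#'
#' A set of per-column first-crossing voxels with per-point band origin and
#' inclusion flags (at most one point per z-column and band).
#'
#' @param df data frame with columns `x`, `y`, `z`, `band`, `included`.
#' @return object of class `surface_point_set` (a data frame).
#' @export
surface_point_set <- function(df) {
  stopifnot(all(c("x", "y", "z", "band", "included") %in% names(df)))
  class(df) <- c("surface_point_set", "data.frame")
  df
}

#' Find surface points by first threshold crossing
#'
#' For each band and each z-column, the shallowest depth inside the search
#' range whose intensity reaches the threshold of the column's raster tile.
#' Columns with no qualifying voxel contribute no point.
#'
#' @param pair [scan_pair()].
#' @param thresholds list with elements `LF` and `HF`, each a
#'   `threshold_set` from [local_thresholds()] computed on the same range.
#' @param range [surface_range()] searched.
#' @param tiling [compute_tiling()].
#' @return [surface_point_set()], all points included.
#' @export
find_surface_points <- function(pair, thresholds, range, tiling) {
  stopifnot(inherits(pair, "scan_pair"),
            all(c("LF", "HF") %in% names(thresholds)))
  d <- dim(pair)
  b <- range_bounds(range, d)
  tm <- tile_map(tiling)
  one_band <- function(vol, ts) {
    th_mat <- matrix(ts$th[tm], d[1], d[2])
    res <- matrix(NA_integer_, d[1], d[2])
    for (k in seq_len(d[3])) {
      hit <- is.na(res) & b$lo <= k & k <= b$hi & vol$values[, , k] >= th_mat
      if (any(hit)) res[hit] <- k
    }
    idx <- which(!is.na(res), arr.ind = TRUE)
    data.frame(x = idx[, 1], y = idx[, 2], z = res[idx],
               band = rep(vol$band, nrow(idx)))
  }
  df <- rbind(one_band(pair$lfr, thresholds$LF),
              one_band(pair$hfr, thresholds$HF))
  df$included <- rep(TRUE, nrow(df))
  surface_point_set(df)
}

#' Degree penalty for polynomial model selection
#'
#' `p(n, m) = 1.01^((m-1)^2 + (n-1)^2)`; multiplies the held-out squared
#' error so that higher degrees must earn their keep.
#'
#' @param n,m polynomial degrees per lateral direction.
#' @return penalty factor >= 1.
#' @export
penalty <- function(n, m) 1.01^((m - 1)^2 + (n - 1)^2)

ls_fit_surface <- function(x, y, z, degree, transform) {
  terms <- poly_terms(degree[1], degree[2])
  X <- poly_design(terms, (x - transform$xc) / transform$xs,
                   (y - transform$yc) / transform$ys)
  fit <- stats::lm.fit(X, z)
  if (any(is.na(fit$coefficients))) return(NULL)  # rank deficient
  surface_function(degree, terms, fit$coefficients, transform)
}

point_transform <- function(x, y) {
  list(xc = (min(x) + max(x)) / 2, xs = max(1, (max(x) - min(x)) / 2),
       yc = (min(y) + max(y)) / 2, ys = max(1, (max(y) - min(y)) / 2))
}

#' Penalized least-squares polynomial fit with degree selection
#'
#' Splits the included points into a seeded train/test partition, fits every
#' candidate degree on the training part by least squares (orthogonal
#' decomposition on centred/scaled coordinates), scores each candidate by
#' `penalty(n, m) * sum of squared test errors`, selects the minimal-cost
#' degree (ties resolved by enumeration order, favouring lower `n`), and
#' refits the winning degree on all included points.
#'
#' @param points [surface_point_set()]; only included points are used.
#' @param candidate_degrees list of `(n, m)` pairs; default: the full grid
#'   `1 <= n, m <= max_degree` in row-major order.
#' @param train_fraction fraction assigned to the training split.
#' @param seed RNG seed for the split.
#' @param max_degree grid bound when `candidate_degrees` is NULL.
#' @return list with `sfit` ([surface_function()]) and `report` (one row per
#'   candidate: degree, cost, skipped flag).
#' @export
fit_polyfit <- function(points, candidate_degrees = NULL,
                        train_fraction = 0.95, seed = 1L, max_degree = 4L) {
  pts <- points[points$included, , drop = FALSE]
  n_pts <- nrow(pts)
  if (is.null(candidate_degrees)) {
    candidate_degrees <- list()
    for (n in seq_len(max_degree)) for (m in seq_len(max_degree))
      candidate_degrees[[length(candidate_degrees) + 1L]] <- c(n, m)
  }
  if (n_pts < 3L) stop("too few surface points for a polynomial fit")
  tr <- point_transform(pts$x, pts$y)
  n_train <- max(1L, round(train_fraction * n_pts))
  idx_train <- with_seed(seed, sample.int(n_pts, n_train))
  is_train <- seq_len(n_pts) %in% idx_train
  report <- data.frame(n = integer(0), m = integer(0), cost = numeric(0),
                       skipped = logical(0))
  best <- NULL; best_cost <- Inf
  for (deg in candidate_degrees) {
    n_terms <- nrow(poly_terms(deg[1], deg[2]))
    sfit <- if (n_train >= n_terms)
      ls_fit_surface(pts$x[is_train], pts$y[is_train], pts$z[is_train],
                     deg, tr) else NULL
    if (is.null(sfit)) {
      report <- rbind(report, data.frame(n = deg[1], m = deg[2], cost = NA,
                                         skipped = TRUE))
      next
    }
    test_err <- if (any(!is_train)) {
      pred <- sf_eval(sfit, pts$x[!is_train], pts$y[!is_train])
      sum((pred - pts$z[!is_train])^2)
    } else 0
    cost <- penalty(deg[1], deg[2]) * test_err
    report <- rbind(report, data.frame(n = deg[1], m = deg[2], cost = cost,
                                       skipped = FALSE))
    if (cost < best_cost) { best <- deg; best_cost <- cost }
  }
  if (is.null(best))
    stop("all candidate degrees were underdetermined; cannot fit surface")
  final <- ls_fit_surface(pts$x, pts$y, pts$z, best, tr)
  if (is.null(final))
    stop("final refit is rank deficient for degree (", best[1], ",",
         best[2], ")")
  list(sfit = final, report = report)
}

#' RANSAC plane fit
#'
#' Standard RANSAC restricted to the linear degree (1,1) model: repeatedly
#' fits a plane to a random minimal sample, counts points within
#' `max_distance` of the plane as inliers, keeps the consensus-maximal model
#' and refits it on its inliers. Falls back to a plain least-squares plane
#' (flagged in the result) if no trial reaches `sample_size` inliers.
#'
#' @param points [surface_point_set()]; only included points are used.
#' @param sample_size minimal sample per trial.
#' @param max_distance inlier distance in depth voxels.
#' @param seed RNG seed; the fit is deterministic given it.
#' @param n_trials number of RANSAC trials.
#' @return list with `sfit` (degree (1,1) [surface_function()]),
#'   `n_inliers`, and `fallback` flag.
#' @export
fit_ransac <- function(points, sample_size = 10L, max_distance = 30,
                       seed = 1L, n_trials = 200L) {
  pts <- points[points$included, , drop = FALSE]
  n_pts <- nrow(pts)
  if (n_pts < sample_size)
    stop("need at least `sample_size` included points for RANSAC")
  tr <- point_transform(pts$x, pts$y)
  best_inl <- NULL; best_count <- -1L
  with_seed(seed, {
    for (trial in seq_len(n_trials)) {
      take <- sample.int(n_pts, sample_size)
      sfit <- ls_fit_surface(pts$x[take], pts$y[take], pts$z[take],
                             c(1L, 1L), tr)
      if (is.null(sfit)) next
      resid <- sf_eval(sfit, pts$x, pts$y) - pts$z
      inl <- abs(resid) <= max_distance
      if (sum(inl) > best_count) { best_count <- sum(inl); best_inl <- inl }
    }
  })
  fallback <- is.null(best_inl) || best_count < sample_size
  use <- if (fallback) rep(TRUE, n_pts) else best_inl
  sfit <- ls_fit_surface(pts$x[use], pts$y[use], pts$z[use], c(1L, 1L), tr)
  if (is.null(sfit))
    stop("RANSAC refit is rank deficient; surface points may be collinear")
  list(sfit = sfit, n_inliers = sum(use), fallback = fallback)
}

#' Exclude outlier surface points around a fitted surface
#'
#' Residuals are `r_j = sfit(x_j, y_j) - z_j` (positive = point above the
#' surface, toward the detector). The acceptance band combines the global
#' residual spread (sample standard deviation `sigma`) with tile-local root
#' second moments `gamma_t` so every raster tile keeps enough points:
#' `h_top = min(max(sigma_top * sigma, gamma_top * gamma), h_abs)` and
#' `h_bot = max(sigma_bot * sigma, gamma_bot * gamma)`; a point survives iff
#' `-h_bot < r < h_top` (strict; the absolute cap `h_abs` removes
#' reflections far above the skin). When the band degenerates to zero width
#' (`sigma = gamma = 0`), exact-fit points are retained. Tiles without
#' residuals inherit `sigma` as their `gamma`.
#'
#' @param points [surface_point_set()]; exclusion operates on the currently
#'   included subset.
#' @param sfit current [surface_function()].
#' @param tiling [compute_tiling()].
#' @param sigma_top,sigma_bot,gamma_top,gamma_bot band multipliers.
#' @param h_abs absolute cap on `h_top` (voxels).
#' @return list with `points` (updated inclusion flags) and `stats`
#'   (residuals of the pre-exclusion set, `sigma`, `gamma_t`, `n_removed`).
#' @export
exclude_outliers <- function(points, sfit, tiling, sigma_top, sigma_bot,
                             gamma_top, gamma_bot, h_abs) {
  stopifnot(nrow(points) > 0L)
  inc <- which(points$included)
  r <- sf_eval(sfit, points$x[inc], points$y[inc]) - points$z[inc]
  if (length(r) < 2L) {
    warning("fewer than 2 residuals; outlier exclusion skipped")
    return(list(points = points,
                stats = list(residuals = r, sigma = NA_real_,
                             gamma_t = rep(NA_real_, 16L), n_removed = 0L)))
  }
  sigma <- stats::sd(r)
  tiles <- tile_of(tiling, points$x[inc], points$y[inc])
  gamma_t <- vapply(1:16, function(t) {
    rt <- r[tiles == t]
    if (length(rt) == 0L) sigma else sqrt(mean(rt^2))
  }, 0)
  g <- gamma_t[tiles]
  h_top <- pmin(pmax(sigma_top * sigma, gamma_top * g), h_abs)
  h_bot <- pmax(sigma_bot * sigma, gamma_bot * g)
  keep <- (-h_bot < r & r < h_top) | (h_top == 0 & h_bot == 0 & r == 0)
  points$included[inc] <- keep
  list(points = points,
       stats = list(residuals = r, sigma = sigma, gamma_t = gamma_t,
                    n_removed = sum(!keep)))
}

#' Feasible depth range around a surface estimate
#'
#' Per column the next iteration may only search
#' `[sfit - theta_top, sfit + theta_bot]` (detector side up to `theta_top`
#' voxels above the estimate, skin side up to `theta_bot` below), clamped to
#' the depth lattice. `Inf` for both thetas yields the full-depth range.
#'
#' @param sfit [surface_function()].
#' @param theta_top,theta_bot half-widths in voxels (may be `Inf`).
#' @param dims lattice dimensions `(n_x, n_y, n_z)`.
#' @return [surface_range()].
#' @export
feasible_range <- function(sfit, theta_top, theta_bot, dims) {
  stopifnot(theta_top > 0, theta_bot > 0)
  if (is.infinite(theta_top) && is.infinite(theta_bot))
    return(full_depth_range())
  s <- sf_eval_grid(sfit, dims[1], dims[2])
  surface_range(s - theta_top, s + theta_bot)
}

#' Finalize a surface with the safety offset
#'
#' Adds `offset = q80(r) + sd(r)/5 + 3` voxels to the surface constant,
#' where `r` are the residuals of the included points under the final fit.
#' The 80th-percentile term places the finalized surface on the offset side
#' of at least 80% of the points; the spread term plus the fixed 3 voxels
#' guard against residual outliers.
#'
#' @param sfit fitted [surface_function()] (offset still 0).
#' @param residuals residual vector `sfit - z` of the included points.
#' @return [surface_function()] with the offset set.
#' @export
finalize_surface <- function(sfit, residuals) {
  if (length(residuals) < 2L) {
    warning("fewer than 2 residuals; using bare safety offset of 3")
    offset <- 3
  } else {
    # population (n-denominator) standard deviation
    s <- sqrt(mean((residuals - mean(residuals))^2))
    offset <- intensity_quantile(residuals, 0.80) + s / 5 + 3
  }
  sfit$offset <- sfit$offset + offset
  sfit
}

fit_by_method <- function(points, rec, config, seed) {
  switch(rec$fit_method,
         RANSAC_linear = fit_ransac(points,
                                    sample_size = config$ransac_sample_size,
                                    max_distance = config$ransac_max_distance,
                                    seed = seed)["sfit"],
         Polyfit_fixed = fit_polyfit(points,
                                     candidate_degrees = list(c(1L, 1L)),
                                     train_fraction = config$train_fraction,
                                     seed = seed)["sfit"],
         Polyfit_dynamic = fit_polyfit(points,
                                       train_fraction = config$train_fraction,
                                       seed = seed,
                                       max_degree = config$max_degree)["sfit"],
         stop("unknown fit method: ", rec$fit_method))
}

#' Iterative skin-surface detection
#'
#' Runs the four building blocks over the configured outer iterations: (a)
#' band-specific tile thresholds on the current feasible range (with the
#' quantile level determined adaptively from the noise above the surface
#' when the schedule says so), (b) first-crossing surface-point selection in
#' both bands, (c) an inner fit/exclude loop (fit method per schedule) that
#' stops as soon as no point is removed, and (d) narrowing of the feasible
#' range for the next iteration. After the last iteration the surface is
#' finalized with the safety offset.
#'
#' @param pair [scan_pair()].
#' @param config [detection_config()].
#' @return list of class `surface_detection` with `surface` (the finalized
#'   [surface_function()]), `points` (final [surface_point_set()]), `offset`,
#'   and `report` (per-iteration thresholds, point counts, selected degree,
#'   residual spread).
#' @export
detect_surface <- function(pair, config = detection_config()) {
  stopifnot(inherits(pair, "scan_pair"), inherits(config, "detection_config"))
  d <- dim(pair)
  tiling <- compute_tiling(d[1], d[2])
  range <- full_depth_range()
  report <- list()
  sfit <- NULL; points <- NULL; stats <- NULL
  for (k in seq_len(config$n_outer_iterations)) {
    rec <- config$iterations[[k]]
    band_alpha <- function(vol) {
      if (!identical(rec$alpha, "adaptive")) return(rec$alpha)
      if (range$full) {
        warning("adaptive alpha requested on the full-depth range; ",
                "using alpha_max")
        return(config$alpha_max)
      }
      adaptive_alpha(vol, range, config$sensitivity,
                     config$alpha_min, config$alpha_max)$alpha_adpt
    }
    ths <- list(
      LF = local_thresholds(pair$lfr, tiling, range, band_alpha(pair$lfr),
                            rec$tau, config$sensitivity),
      HF = local_thresholds(pair$hfr, tiling, range, band_alpha(pair$hfr),
                            rec$tau, config$sensitivity))
    points <- find_surface_points(pair, ths, range, tiling)
    if (nrow(points) == 0L)
      stop("surface not found: no surface points at iteration ", k)
    inner_used <- 0L
    for (inner in seq_len(config$max_inner_iterations)) {
      inner_used <- inner
      seed <- config$random_seed + 97L * k + inner
      sfit <- fit_by_method(points, rec, config, seed)$sfit
      ex <- exclude_outliers(points, sfit, tiling,
                             rec$sigma_top, rec$sigma_bot,
                             rec$gamma_top, rec$gamma_bot, rec$h_abs)
      points <- ex$points; stats <- ex$stats
      if (stats$n_removed == 0L) break
      if (sum(points$included) < 3L)
        stop("surface not found: too few points after exclusion at iteration ",
             k)
    }
    report[[k]] <- list(
      iteration = k, fit_method = rec$fit_method,
      alpha = list(LF = ths$LF$alpha, HF = ths$HF$alpha),
      thresholds = list(LF = ths$LF$th, HF = ths$HF$th),
      n_points = nrow(points), n_included = sum(points$included),
      degree = sfit$degree, sigma = stats$sigma, gamma_t = stats$gamma_t,
      inner_iterations = inner_used)
    if (k < config$n_outer_iterations)
      range <- feasible_range(sfit, rec$theta_top, rec$theta_bot, d)
  }
  inc <- points$included
  final_resid <- sf_eval(sfit, points$x[inc], points$y[inc]) - points$z[inc]
  surface <- finalize_surface(sfit, final_resid)
  structure(list(surface = surface, points = points,
                 offset = surface$offset, report = report,
                 schedule_note = "non-canonical defaults"),
            class = "surface_detection")
}

#' @export
print.surface_detection <- function(x, ...) {
  cat(sprintf("<surface_detection> degree (%d,%d), offset %.3f, %d/%d points included\n",
              x$surface$degree[1], x$surface$degree[2], x$offset,
              sum(x$points$included), nrow(x$points)))
  invisible(x)
}
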