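test_that("degree penalty is 1.01^((m-1)^2 + (n-1)^2)", {
  expect_equal(penalty(1, 1), 1)
  expect_equal(penalty(3, 2), 1.01^5)
  expect_equal(penalty(4, 4), 1.01^18)
})

test_that("polynomial fit recovers an exact plane with minimal cost", {
  pts <- plane_points(120, 100, 2, -1)
  fit <- fit_polyfit(pts, seed = 3)
  expect_equal(fit$sfit$degree, c(1L, 1L))
  expect_equal(sf_eval(fit$sfit, c(1, 10, 33), c(1, 25, 7)),
               100 + 2 * c(1, 10, 33) - c(1, 25, 7), tolerance = 1e-8)
  costs <- fit$report[!fit$report$skipped, ]
  expect_equal(costs$cost[costs$n == 1 & costs$m == 1], 0, tolerance = 1e-12)
})

test_that("quadratic surfaces select a quadratic degree over the plane", {
  set.seed(8)
  x <- sample(1:60, 200, replace = TRUE); y <- sample(1:40, 200, replace = TRUE)
  pts <- surface_point_set(data.frame(
    x = x, y = y, z = 50 + 0.01 * x^2, band = "LF", included = TRUE))
  fit <- fit_polyfit(pts, seed = 5)
  expect_gte(fit$sfit$degree[1], 2L)
  rep <- fit$report
  cost_11 <- rep$cost[rep$n == 1 & rep$m == 1]
  expect_gt(cost_11, min(rep$cost, na.rm = TRUE))
  # closed-form LS oracle for the winning degree refit on all points
  pred <- sf_eval(fit$sfit, x, y)
  expect_equal(pred, 50 + 0.01 * x^2, tolerance = 1e-6)
})

test_that("a single candidate degree reduces to plain least squares", {
  set.seed(9)
  pts <- plane_points(80, 90, 1.5, 0.5)
  pts$z <- pts$z + rnorm(80, sd = 2)
  fit <- fit_polyfit(pts, candidate_degrees = list(c(1L, 1L)), seed = 1)
  ora <- lm(z ~ x + y, data = as.data.frame(pts))
  expect_equal(sf_eval(fit$sfit, pts$x, pts$y), unname(fitted(ora)),
               tolerance = 1e-8)
})

test_that("cost ties resolve to the earlier degree in enumeration order", {
  # an empty test split scores every candidate 0 -> exact tie -> first wins
  pts <- plane_points(50, 70, 1, 1)
  fit <- fit_polyfit(pts, train_fraction = 0.999, seed = 2)
  expect_equal(fit$sfit$degree, c(1L, 1L))
  expect_true(all(fit$report$cost[!fit$report$skipped] == 0))
})

test_that("RANSAC rejects gross outliers and is deterministic", {
  pts <- plane_points(90, 120, 1, 0, seed = 4)
  out <- plane_points(10, 20, 0, 0, seed = 5)
  all_pts <- surface_point_set(rbind(as.data.frame(pts), as.data.frame(out)))
  fit <- fit_ransac(all_pts, sample_size = 10, max_distance = 30, seed = 11)
  expect_false(fit$fallback)
  clean <- as.data.frame(pts)
  ora <- lm(z ~ x + y, data = clean)
  expect_equal(sf_eval(fit$sfit, clean$x, clean$y), unname(fitted(ora)),
               tolerance = 1e-6)
  resid_out <- abs(sf_eval(fit$sfit, out$x, out$y) - out$z)
  expect_true(all(resid_out > 30))
  expect_equal(fit$n_inliers, 90L)

  fit2 <- fit_ransac(all_pts, sample_size = 10, max_distance = 30, seed = 11)
  expect_identical(fit$sfit$coef, fit2$sfit$coef)

  planar <- fit_ransac(pts, seed = 3)
  expect_equal(planar$n_inliers, nrow(pts))
})

test_that("outlier exclusion applies the sigma/gamma band with absolute cap", {
  tl <- compute_tiling(50, 30)
  # all residuals zero: zero-width band retains exact-fit points
  pts <- plane_points(60, 100, 1, -1)
  sfit <- fit_polyfit(pts, candidate_degrees = list(c(1L, 1L)), seed = 1)$sfit
  ex <- exclude_outliers(pts, sfit, tl, 3, 3, 3, 3, 30)
  expect_true(all(ex$points$included))
  expect_equal(ex$stats$sigma, 0)

  # a hair 60 voxels above the plane is removed by the h_abs cap
  hair <- data.frame(x = 25, y = 15, z = 100 + 25 - 15 - 60,
                     band = "LF", included = TRUE)
  pts2 <- surface_point_set(rbind(as.data.frame(pts), hair))
  pts2$z <- pts2$z + rep(c(0.5, -0.5), length.out = nrow(pts2))  # small spread
  sfit2 <- fit_ransac(pts2, seed = 2)$sfit
  ex2 <- exclude_outliers(pts2, sfit2, tl, 3, 3, 3, 3, 30)
  r_hair <- sf_eval(sfit2, 25, 15) - hair$z
  expect_gt(r_hair, 30)                     # above the absolute cap
  expect_false(ex2$points$included[nrow(pts2)])

  # symmetric residuals +/-5 with multipliers 3 keep every point
  set.seed(3)
  pts3 <- plane_points(40, 80, 0.5, 0.2, seed = 6)
  pts3$z <- pts3$z + rep(c(5, -5), 20)
  sfit3 <- fit_polyfit(pts3, candidate_degrees = list(c(1L, 1L)),
                       seed = 1)$sfit
  ex3 <- exclude_outliers(pts3, sfit3, tl, 3, 3, 3, 3, 100)
  expect_equal(ex3$stats$sigma, sd(sf_eval(sfit3, pts3$x, pts3$y) - pts3$z))
  expect_true(all(ex3$points$included))
})

test_that("exclusion is sound: kept and removed points split exactly on the band", {
  ph <- small_phantom(seed = 20, n_hairs = 2L, noise_sd = 8)
  tl <- compute_tiling(60, 40)
  cfg <- detection_config()
  ths <- list(LF = local_thresholds(ph$pair$lfr, tl, alpha = 0.98),
              HF = local_thresholds(ph$pair$hfr, tl, alpha = 0.98))
  pts <- find_surface_points(ph$pair, ths, full_depth_range(), tl)
  sfit <- fit_ransac(pts, seed = 1)$sfit
  ex <- exclude_outliers(pts, sfit, tl, 3, 3, 2.5, 2.5, 80)
  r <- sf_eval(sfit, pts$x, pts$y) - pts$z
  g <- ex$stats$gamma_t[tile_of(tl, pts$x, pts$y)]
  h_top <- pmin(pmax(3 * ex$stats$sigma, 2.5 * g), 80)
  h_bot <- pmax(3 * ex$stats$sigma, 2.5 * g)
  expect_identical(ex$points$included, -h_bot < r & r < h_top)
})

test_that("feasible range follows the thetas and clamps to the lattice", {
  flat <- surface_function(c(1L, 1L), poly_terms(1, 1), c(150, 0, 0))
  rng <- feasible_range(flat, 30, 50, c(10, 8, 300))
  expect_equal(unique(as.vector(rng$shallow)), 120)
  expect_equal(unique(as.vector(rng$deep)), 200)
  expect_true(feasible_range(flat, Inf, Inf, c(10, 8, 300))$full)

  low <- surface_function(c(1L, 1L), poly_terms(1, 1), c(10, 0, 0))
  rng2 <- feasible_range(low, 30, 50, c(10, 8, 300))
  b <- emipr:::range_bounds(rng2, c(10, 8, 300))
  expect_true(all(b$lo == 1))
})

test_that("surface points are the first crossings inside the range", {
  ph <- generate_phantom(phantom_spec(
    n_x = 30, n_y = 20, n_z = 300, surface_coefficients = c(c00 = 150),
    n_vessels = 0L, n_hairs = 0L, noise_sd = 0, seed = 2))
  tl <- compute_tiling(30, 20)
  ths <- list(LF = local_thresholds(ph$pair$lfr, tl, alpha = 0.5, tau = 0.5),
              HF = local_thresholds(ph$pair$hfr, tl, alpha = 0.5, tau = 0.5))
  pts <- find_surface_points(ph$pair, ths, full_depth_range(), tl)
  expect_equal(nrow(pts), 2 * 30 * 20)   # one point per column and band
  expect_true(all(pts$z == 150))

  high <- ths
  high$LF$th[] <- 1e9; high$HF$th[] <- 1e9
  expect_equal(nrow(find_surface_points(ph$pair, high, full_depth_range(),
                                        tl)), 0L)
})

test_that("a hair above the surface is picked first and later excluded", {
  ph <- small_phantom(seed = 21, n_hairs = 2L)
  hair_cols <- which(apply(ph$truth$hair_mask, c(1, 2), any), arr.ind = TRUE)
  expect_gt(nrow(hair_cols), 3)
  tl <- compute_tiling(60, 40)
  ths <- list(LF = local_thresholds(ph$pair$lfr, tl, alpha = 0.9, tau = 0.5),
              HF = local_thresholds(ph$pair$hfr, tl, alpha = 0.9, tau = 0.5))
  pts <- find_surface_points(ph$pair, ths, full_depth_range(), tl)
  # first-crossing oracle on one hair column
  i <- hair_cols[1, 1]; j <- hair_cols[1, 2]
  col <- ph$pair$lfr$values[i, j, ]
  th_ij <- ths$LF$th[tile_of(tl, i, j)]
  z_ora <- which(col >= th_ij)[1]
  got <- pts$z[pts$x == i & pts$y == j & pts$band == "LF"]
  expect_equal(got, z_ora)
  expect_lt(got, evaluate_true_surface(ph$truth, i, j))

  det <- detect_surface(ph$pair, detection_config())
  hair_pts <- mapply(function(x, y) any(pts$x == x & pts$y == y),
                     hair_cols[, 1], hair_cols[, 2])
  inc <- det$points[det$points$included, ]
  # fraction of hair-column points still included at the end
  on_hair <- vapply(seq_len(nrow(inc)), function(r) {
    z_true <- evaluate_true_surface(ph$truth, inc$x[r], inc$y[r])
    inc$z[r] < z_true - 5
  }, TRUE)
  expect_lt(mean(on_hair), 0.05)
})

test_that("the safety offset follows q80 + sd/5 + 3", {
  sfit <- surface_function(c(1L, 1L), poly_terms(1, 1), c(0, 0, 0))
  expect_equal(finalize_surface(sfit, rep(0, 10))$offset, 3)
  r <- -2:7
  fin <- finalize_surface(sfit, r)
  expect_equal(fin$offset, 5.2 + sqrt(8.25) / 5 + 3, tolerance = 1e-12)
  expect_equal(fin$offset, 8.7744566, tolerance = 1e-7)
  expect_warning(finalize_surface(sfit, numeric(0)), "residuals")
})

test_that("detection recovers a noiseless tilted plane and is deterministic", {
  ph <- small_phantom(seed = 30, surface = c(c00 = 120, c10 = 0.3))
  det <- suppressWarnings(detect_surface(ph$pair, detection_config()))
  est <- sf_eval_grid(det$surface, 60, 40) - det$offset
  rmse <- sqrt(mean((est - ph$truth$true_surface)^2))
  expect_lt(rmse, 1)

  det2 <- suppressWarnings(detect_surface(ph$pair, detection_config()))
  expect_identical(det$surface$coef, det2$surface$coef)
  expect_identical(det$offset, det2$offset)
})

test_that("finalized surface covers at least 80% of included points", {
  ph <- small_phantom(seed = 31, n_hairs = 1L, noise_sd = 10)
  det <- detect_surface(ph$pair, detection_config())
  inc <- det$points[det$points$included, ]
  r_final <- sf_eval(det$surface, inc$x, inc$y) - inc$z
  expect_gte(mean(r_final >= 0), 0.80)
})

test_that("feasible-range width narrows over the default schedule", {
  widths <- vapply(default_iteration_schedule(), function(it)
    it$theta_top + it$theta_bot, 0)
  expect_true(all(diff(widths[-4]) <= 0))
  # and the per-column realized range narrows on an actual run
  ph <- small_phantom(seed = 32, noise_sd = 6)
  cfg <- detection_config()
  det <- detect_surface(ph$pair, cfg)
  expect_equal(length(det$report), 4L)
  counts <- vapply(det$report, function(r) r$n_included, 0)
  expect_true(all(counts >= 10))               # coarse first pass is sparse
  expect_gte(counts[4], 0.9 * 2 * 60 * 40)     # final pass covers the field
})

test_that("an impossible detection raises 'surface not found'", {
  set.seed(1)
  v <- array(abs(rnorm(20 * 20 * 150)), c(20, 20, 150))
  pair <- scan_pair(rsom_volume(v, "LF"), rsom_volume(v, "HF"))
  # a near-zero sensitivity raises every threshold above the volume maximum
  cfg <- detection_config(sensitivity = 1e-6)
  expect_error(suppressWarnings(detect_surface(pair, cfg)),
               "surface not found.*iteration 1")
})
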