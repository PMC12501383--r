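test_that("MOS averages repeats first, then raters", {
  rt <- rating_table(matrix(3L, 4, 8))
  expect_true(all(mos(rt) == 3))

  one <- rating_table(matrix(c(1L, 2L, 2L, 3L, 3L, 3L, 4L, 4L), 1, 8))
  expect_equal(unname(mos(one)), 2.75)

  reps <- matrix(NA_integer_, 1, 8); reps[1, 1] <- 3L
  two <- rating_table(matrix(c(2L, rep(3L, 7)), 1, 8), repeats = reps)
  expect_equal(unname(mos(two)), 2.9375)  # (2.5 + 7*3) / 8

  with_na <- rating_table(matrix(c(2L, 4L, NA, NA), 1, 4))
  expect_equal(unname(mos(with_na)), 3)
})

test_that("rating tables validate their entries", {
  expect_error(rating_table(matrix(5L, 2, 2)), "1..4")
  expect_error(rating_table(matrix(2L, 2, 2), repeats = matrix(2L, 3, 2)),
               "shape")
  r <- matrix(c(1L, NA, 2L, 3L), 2, 2)
  rep2 <- matrix(c(NA, 2L, NA, NA), 2, 2)
  expect_error(rating_table(r, repeats = rep2), "first rating")
})

test_that("MOS differences and substantial fractions are exact", {
  base <- matrix(rep(c(2L, 2L, 2L, 2L, 3L, 3L, 3L, 3L), each = 2), 2, 8)
  mipt <- rating_table(base, method = "MIP")
  emipt <- rating_table(mipt$ratings, method = "eMIP")
  d0 <- mos_differences(emipt, mipt)
  expect_true(all(d0$d == 0))
  expect_equal(d0$frac_substantial_positive, 0)
  expect_equal(d0$frac_substantial_negative, 0)

  # +0.5 on every scan: half the raters go one level up
  up <- mipt$ratings; up[, 1:4] <- up[, 1:4] + 1L
  emip2 <- rating_table(up, method = "eMIP")
  d1 <- mos_differences(emip2, mipt)
  expect_true(all(d1$d == 0.5))
  expect_equal(d1$mean_d, 0.5)
  expect_equal(d1$frac_substantial_positive, 1)

  rownames(up) <- c("a", "b")
  expect_error(mos_differences(rating_table(up), mipt), "scan sets differ")
})

test_that("a simulated +0.25 shift is recovered in the mean difference", {
  q <- with(list(), {set.seed(99); rnorm(1725, 2.4, 0.6)})
  m_mip <- simulate_ratings(1725, 8, rater_noise_sd = 0.4, seed = 1,
                            quality = q)
  m_emip <- simulate_ratings(1725, 8, rater_noise_sd = 0.4, seed = 2,
                             quality = q + 0.25)
  d <- mos_differences(rating_table(m_emip, method = "eMIP"),
                       rating_table(m_mip, method = "MIP"))
  tt <- mean_diff_test(mos(rating_table(m_emip)), mos(rating_table(m_mip)),
                       conf_level = 0.95)
  expect_gt(tt$ci[1] - 0.12, 0)          # clearly positive shift
  expect_lt(abs(d$mean_d - 0.25), 0.08)  # rounding to 1..4 attenuates a bit
})

test_that("histograms use left-open right-closed bins", {
  h <- histogram_mos(c(2.0, 2.01, 2.125, 3.999), width = 0.125)
  left_of_2 <- h[abs(h$bin_right - 2) < 1e-9, ]
  expect_equal(left_of_2$count, 1L)      # the exact 2.0 goes left
  bin_2_2125 <- h[abs(h$bin_right - 2.125) < 1e-9, ]
  expect_equal(bin_2_2125$count, 2L)

  same <- histogram_mos(rep(3.1, 7))
  expect_equal(sum(same$count > 0), 1L)
  expect_equal(max(same$percent), 100)

  hd <- histogram_diff(c(0, 1 / 6, 1 / 6 + 1e-9, 0.5))
  centre <- hd[abs(hd$bin_centre) < 1e-9, ]
  expect_equal(centre$count, 2L)         # 0 and the boundary 1/6 go centre

  # brute-force binning oracle on a grid
  vals <- seq(1, 4, by = 0.05)
  h2 <- histogram_mos(vals)
  ora <- table(ceiling(vals / 0.125 - 1e-9))
  expect_equal(sum(h2$count), length(vals))
  expect_equal(sort(h2$count[h2$count > 0], decreasing = TRUE),
               sort(as.integer(ora), decreasing = TRUE))
})

test_that("the t test matches the pooled closed form", {
  set.seed(4)
  x <- rnorm(40, 1); y <- rnorm(35)
  res <- mean_diff_test(x, y, conf_level = 0.9999)
  sp2 <- ((39 * var(x) + 34 * var(y)) / 73)
  t_ora <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 40 + 1 / 35))
  expect_equal(res$statistic, t_ora, tolerance = 1e-10)
  p_ora <- 2 * pt(-abs(t_ora), 73)
  expect_equal(res$p_value, p_ora, tolerance = 1e-10)

  same <- mean_diff_test(rep(2, 5), rep(2, 6))
  expect_true(same$degenerate)

  big <- mean_diff_test(rnorm(100, 1, 0.1), rnorm(100, 0, 0.1))
  expect_lt(big$p_value, 1e-4)
})

test_that("the signed-rank test and bootstrap CI behave", {
  set.seed(5)
  d_sym <- c(rnorm(30), -rnorm(30))
  res <- median_diff_test(d_sym, seed = 2)
  expect_gt(res$p_value, 0.05)

  d_const <- rep(0.3, 20)
  res2 <- median_diff_test(d_const, seed = 3)
  expect_equal(res2$ci, c(0.3, 0.3))
  expect_lt(res2$p_value, 0.01)

  res3 <- median_diff_test(rep(0, 10), seed = 1)
  expect_true(res3$degenerate)
})

test_that("bootstrap CI of the median covers a known median", {
  hits <- 0L
  for (s in 1:60) {
    d <- with_seed_d <- local({set.seed(s + 500); rnorm(80, 0.3, 0.5)})
    ci <- median_diff_test(d, n_boot = 1000, seed = s, conf_level = 0.95)$ci
    if (ci[1] <= 0.3 && 0.3 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 53L)   # ~ nominal 95% coverage at modest n
})

test_that("linear weights match |i-j|/range on native and expanded scales", {
  w <- linear_weights(1:4)
  expect_equal(w[1, 4], 1)
  expect_true(all(diag(w) == 0))
  expect_equal(w[2, 3], 1 / 3)
  expect_true(isSymmetric(unclass(w)))
  w10 <- linear_weights(seq(3, 12) / 3)
  expect_equal(w10[1, 2], (1 / 3) / 3)
  expect_error(linear_weights(2), "2 distinct")
})

test_that("weighted Fleiss' kappa matches the brute-force pairwise oracle", {
  w <- linear_weights(1:4)
  clones <- matrix(rep(c(1L, 3L, 4L, 2L, 2L), 8), 5, 8)
  expect_equal(weighted_fleiss_kappa(clones, w)$kappa, 1)

  toy <- matrix(c(1, 2, 2,
                  3, 3, 4,
                  1, 1, 2), 3, 3, byrow = TRUE)
  expect_equal(weighted_fleiss_kappa(toy, w)$kappa,
               brute_force_kappa(toy, w), tolerance = 1e-10)

  set.seed(12)
  for (rep in 1:5) {
    m <- matrix(sample(1:4, 8 * 5, replace = TRUE), 8, 5)
    expect_equal(weighted_fleiss_kappa(m, w)$kappa, brute_force_kappa(m, w),
                 tolerance = 1e-10)
  }

  # single-category table: De = 0 -> kappa defined as 1
  expect_equal(weighted_fleiss_kappa(matrix(2L, 4, 3), w)$kappa, 1)
})

test_that("kappa is invariant under scan and rater relabeling", {
  set.seed(13)
  m <- simulate_ratings(40, 6, rater_noise_sd = 0.6, seed = 3)
  w <- linear_weights(1:4)
  k0 <- weighted_fleiss_kappa(m, w)$kappa
  expect_equal(weighted_fleiss_kappa(m[sample(40), ], w)$kappa, k0)
  expect_equal(weighted_fleiss_kappa(m[, sample(6)], w)$kappa, k0)
})

test_that("independent uniform ratings give near-zero kappa", {
  m <- with_seed_m <- local({
    set.seed(77); matrix(sample(1:4, 500 * 8, replace = TRUE), 500, 8)
  })
  expect_lt(abs(weighted_fleiss_kappa(m)$kappa), 0.05)
})

test_that("missing ratings are handled per scan", {
  m <- matrix(c(1L, 1L, NA,
                2L, NA, NA,
                3L, 3L, 3L,
                4L, 4L, 3L), 4, 3, byrow = TRUE)
  expect_message(res <- weighted_fleiss_kappa(m), "dropping 1")
  expect_equal(res$n_scans, 3L)
})

test_that("jackknife rater variance matches direct enumeration", {
  w <- linear_weights(1:4)
  clones <- matrix(rep(c(1L, 3L, 4L, 2L), 4), 4, 4)
  expect_equal(jackknife_rater_variance(clones, w), 0)

  set.seed(14)
  m <- matrix(sample(1:4, 10 * 4, replace = TRUE), 10, 4)
  k_l <- vapply(1:4, function(l)
    weighted_fleiss_kappa(m[, -l], w)$kappa, 0)
  ora <- 3 / 4 * sum((k_l - mean(k_l))^2)
  expect_equal(jackknife_rater_variance(m, w), ora, tolerance = 1e-12)
  expect_gte(jackknife_rater_variance(m, w), 0)
  expect_error(jackknife_rater_variance(m[, 1:2], w), "3 raters")
})

test_that("intra-rater kappa averages per-rater session agreement", {
  set.seed(15)
  base <- matrix(sample(1:4, 30 * 8, replace = TRUE), 30, 8)
  perfect <- rating_table(base, repeats = base)
  res <- intra_kappa(perfect)
  expect_equal(res$kappa, 1)
  expect_equal(res$v_r, 0)

  # hand-computed variance of given per-rater kappas
  ks <- c(0.5, 0.5, 0.5, 0.5, 0.7, 0.7, 0.7, 0.7)
  expect_equal(var(ks) / 8, 0.0114285714 / 8, tolerance = 1e-8)

  set.seed(151)
  noisy <- base
  noisy[, 1] <- sample(1:4, 30, replace = TRUE)  # rater 1 re-rolls session 2
  res2 <- intra_kappa(rating_table(base, repeats = noisy))
  expect_equal(res2$per_rater[2:8], rep(1, 7))
  expect_lt(res2$per_rater[1], 0.5)
  expect_equal(res2$kappa, mean(res2$per_rater))
})

test_that("group-pair enumeration matches the combinatorial construction", {
  gp <- enumerate_group_pairs(8, 3)
  expect_equal(gp$P, 560L)
  gp2 <- enumerate_group_pairs(4, 1)
  expect_equal(gp2$P, 12L)
  for (p in gp2$pairs) {
    expect_length(p$a, 1L); expect_length(p$b, 1L)
    expect_length(intersect(p$a, p$b), 0L)
  }
  ok <- vapply(gp$pairs, function(p)
    length(p$a) == 3 && length(p$b) == 3 &&
      length(intersect(p$a, p$b)) == 0, TRUE)
  expect_true(all(ok))
  expect_error(enumerate_group_pairs(4, 3), "<=")
})

test_that("group-of-3 kappa matches a miniature brute-force enumeration", {
  set.seed(16)
  m <- simulate_ratings(25, 6, rater_noise_sd = 0.7, seed = 5)
  res <- group3_kappa(m, group_size = 2L)
  # brute force: all ordered pairs of disjoint 2-groups from 6 raters
  levels <- seq(2, 8) / 2
  w <- linear_weights(levels)
  gp <- enumerate_group_pairs(6, 2)
  ks <- vapply(gp$pairs, function(p) {
    ga <- rowMeans(m[, p$a]); gb <- rowMeans(m[, p$b])
    brute_force_kappa(cbind(ga, gb), w)
  }, 0)
  expect_equal(res$kappa, mean(ks), tolerance = 1e-10)

  clones <- matrix(rep(sample(1:4, 20, replace = TRUE), 6), 20, 6)
  resc <- group3_kappa(clones, group_size = 2L)
  expect_equal(resc$kappa, 1)
  expect_equal(resc$v_r, 0)   # all subset kappas equal -> zero jackknife sum
})

test_that("group averaging raises agreement for noisy-but-shared quality", {
  q <- local({set.seed(21); rnorm(120, 2.5, 0.9)})
  m <- simulate_ratings(120, 8, rater_noise_sd = 0.8, seed = 6, quality = q)
  k_inter <- inter_kappa(m)
  k_g3 <- group3_kappa(m)
  expect_gt(k_g3$kappa, k_inter$kappa)
})

test_that("agreement gains and their tests follow the normal approximation", {
  set.seed(17)
  m <- simulate_ratings(60, 8, rater_noise_sd = 0.6, seed = 7)
  same <- inter_kappa_gain(m, m)
  expect_equal(same$gain, 0)
  expect_equal(same$p_value, 0.5, tolerance = 1e-12)

  ka <- kappa_result_stub <- weighted_fleiss_kappa(m)
  res <- kappa_gain(structure(list(kappa = ka$kappa + 2 * sqrt(0.01),
                                   v_im = 0.005), class = "kappa_result"),
                    structure(list(kappa = ka$kappa, v_im = 0.005),
                              class = "kappa_result"),
                    v_r_gain = 0)
  expect_equal(res$p_value, 1 - pnorm(2), tolerance = 1e-12)

  # genuinely more concordant eMIP ratings are detected
  q <- local({set.seed(18); rnorm(150, 2.5, 0.9)})
  rej <- 0L
  for (s in 1:20) {
    mm <- simulate_ratings(150, 8, rater_noise_sd = 1.0, seed = 100 + s,
                           quality = q)
    me <- simulate_ratings(150, 8, rater_noise_sd = 0.45, seed = 200 + s,
                           quality = q)
    if (inter_kappa_gain(me, mm)$p_value < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / 20, 0.5)
})

test_that("intra and group gains use their paired variance schemes", {
  base <- local({set.seed(19)
    matrix(sample(1:4, 40 * 8, replace = TRUE), 40, 8)})
  t_mip <- rating_table(base, repeats = base, method = "MIP")
  t_emip <- rating_table(base, repeats = base, method = "eMIP")
  g <- intra_kappa_gain(t_emip, t_mip)
  expect_equal(g$gain, 0)
  expect_equal(g$p_value, 0.5)

  g3 <- group3_kappa_gain(base, base)
  expect_equal(g3$gain, 0)
  expect_equal(g3$p_value, 0.5)
})

test_that("kappa interpretation bands match the benchmark table", {
  expect_equal(interpret_kappa(0.5), "Moderate agreement")
  expect_equal(interpret_kappa(-0.2), "Poor agreement")
  expect_equal(interpret_kappa(0.15), "Slight agreement")
  expect_equal(interpret_kappa(0.35), "Fair agreement")
  expect_equal(interpret_kappa(0.75), "Substantial agreement")
  expect_equal(interpret_kappa(0.95), "Almost perfect agreement")
  expect_equal(interpret_kappa(1), "Almost perfect agreement")
})

test_that("ratings CSV round-trips into tables per method", {
  df <- expand.grid(scan_id = paste0("s", 1:4), rater_id = paste0("r", 1:3),
                    method = c("MIP", "eMIP"), stringsAsFactors = FALSE)
  df$session <- 1L
  df$rating <- rep(c(2L, 3L, 3L, 4L), 6)
  extra <- data.frame(scan_id = "s1", rater_id = "r1", method = "MIP",
                      session = 2L, rating = 3L)
  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(rbind(df, extra), csv, row.names = FALSE)
  tabs <- read_ratings_csv(csv)
  expect_named(tabs, c("MIP", "eMIP"), ignore.order = TRUE)
  expect_equal(dim(tabs$MIP$ratings), c(4L, 3L))
  expect_equal(tabs$MIP$repeats["s1", "r1"], 3L)
  expect_equal(unname(mos(tabs$eMIP)["s2"]), 3)

  bad <- df; bad$rating[1] <- 9L
  write.csv(bad, csv, row.names = FALSE)
  expect_error(read_ratings_csv(csv), "invalid rating")
  write.csv(df[, -3], csv, row.names = FALSE)
  expect_error(read_ratings_csv(csv), "missing columns")
})
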