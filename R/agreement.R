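#' Ordinal rating table
#'
#' Scans x raters matrix of perceptual quality ratings on the 4-level scale
#' (1 bad, 2 medium, 3 good, 4 perfect), with an optional second-session
#' matrix for the subset of scans each rater assessed twice.
#'
#' @param ratings integer matrix (scans x raters), values in 1..4 or `NA`.
#' @param repeats optional matrix of the same shape holding second-session
#'   ratings; entries are only allowed where a first rating exists.
#' @param method label of the rendering method being rated (`"MIP"` or
#'   `"eMIP"`).
#' @return object of class `rating_table`.
#' @export
rating_table <- function(ratings, repeats = NULL, method = "MIP") {
  ratings <- as.matrix(ratings)
  ok <- function(m) all(is.na(m) | (m %in% 1:4))
  if (!ok(ratings)) stop("ratings must be integers in 1..4 (or NA)")
  if (!is.null(repeats)) {
    repeats <- as.matrix(repeats)
    if (!identical(dim(repeats), dim(ratings)))
      stop("repeats must match the shape of ratings")
    if (!ok(repeats)) stop("repeat ratings must be integers in 1..4 (or NA)")
    if (any(!is.na(repeats) & is.na(ratings)))
      stop("repeat entries are only allowed where a first rating exists")
  }
  if (is.null(rownames(ratings)))
    rownames(ratings) <- paste0("scan", seq_len(nrow(ratings)))
  structure(list(ratings = ratings, repeats = repeats, method = method),
            class = "rating_table")
}

#' Read rating tables from a long-format CSV
#'
#' Expected columns: `scan_id`, `rater_id`, `method` (MIP or eMIP),
#' `session` (1 or 2), `rating` (1-4). Returns one [rating_table()] per
#' method present.
#'
#' @param path CSV file path.
#' @return named list of `rating_table` objects.
#' @export
read_ratings_csv <- function(path) {
  if (!file.exists(path)) stop("ratings file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("scan_id", "rater_id", "method", "session", "rating")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("ratings CSV is missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!(df$rating %in% 1:4) | !(df$session %in% 1:2))
  if (length(bad) > 0L)
    stop("invalid rating/session values at rows: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  scans <- sort(unique(df$scan_id)); raters <- sort(unique(df$rater_id))
  out <- list()
  for (meth in unique(df$method)) {
    sub <- df[df$method == meth, ]
    mk <- function(session) {
      m <- matrix(NA_integer_, length(scans), length(raters),
                  dimnames = list(scans, raters))
      s <- sub[sub$session == session, ]
      m[cbind(match(s$scan_id, scans), match(s$rater_id, raters))] <- s$rating
      m
    }
    rep2 <- mk(2L)
    out[[meth]] <- rating_table(mk(1L),
                                repeats = if (any(!is.na(rep2))) rep2,
                                method = meth)
  }
  out
}

# Per-rater score with repeat averaging: mean of first and second session
# where a repeat exists, the first rating otherwise.
effective_scores <- function(table) {
  stopifnot(inherits(table, "rating_table"))
  s <- table$ratings * 1.0
  if (!is.null(table$repeats)) {
    has <- !is.na(table$repeats)
    s[has] <- (table$ratings[has] + table$repeats[has]) / 2
  }
  s
}

#' Mean opinion score per scan
#'
#' Each rater's score is first averaged over sessions where a repeat
#' exists, then scores are averaged across raters with non-missing scores.
#' Scans without any rating are dropped (with a message).
#'
#' @param table [rating_table()].
#' @return named numeric vector of per-scan MOS values.
#' @export
mos <- function(table) {
  s <- effective_scores(table)
  n_ok <- rowSums(!is.na(s))
  if (any(n_ok == 0L)) {
    message("dropping ", sum(n_ok == 0L), " scan(s) without ratings")
    s <- s[n_ok > 0L, , drop = FALSE]
  }
  rowMeans(s, na.rm = TRUE)
}

#' Paired MOS differences between renderings
#'
#' `d_i = MOS(scan_i, eMIP) - MOS(scan_i, MIP)` over the common scan set,
#' plus the fractions of substantially better (`d >= 0.5`) and substantially
#' worse (`d <= -0.5`) scans.
#'
#' @param emip,mip [rating_table()] objects rating the same scans.
#' @return list with `d`, `mean_d`, `frac_substantial_positive`,
#'   `frac_substantial_negative`.
#' @export
mos_differences <- function(emip, mip) {
  me <- mos(emip); mm <- mos(mip)
  if (!identical(sort(names(me)), sort(names(mm))))
    stop("scan sets differ between methods: ",
         paste(utils::head(c(setdiff(names(me), names(mm)),
                             setdiff(names(mm), names(me))), 10L),
               collapse = ", "))
  d <- me - mm[names(me)]
  list(d = d, mean_d = mean(d),
       frac_substantial_positive = mean(d >= 0.5),
       frac_substantial_negative = mean(d <= -0.5))
}

bin_counts <- function(values, width, origin) {
  # left-open, right-closed bins anchored at `origin`: a value exactly on a
  # boundary counts toward the bin ending there (the bin to the left).
  idx <- ceiling((values - origin) / width - 1e-9)
  rng <- range(idx)
  bins <- rng[1]:rng[2]
  counts <- vapply(bins, function(b) sum(idx == b), 0L)
  data.frame(bin_left = origin + (bins - 1) * width,
             bin_right = origin + bins * width,
             count = counts,
             percent = 100 * counts / length(values))
}

#' Histogram of MOS values
#'
#' Bin width 0.125 with edges on multiples of the width; values that fall on
#' a boundary are included in the bin to the left.
#'
#' @param values finite numeric vector.
#' @param width bin width.
#' @return data frame with `bin_left`, `bin_right`, `count`, `percent`.
#' @export
histogram_mos <- function(values, width = 0.125) {
  stopifnot(all(is.finite(values)))
  bin_counts(values, width, origin = 0)
}

#' Histogram of MOS differences
#'
#' Bin width 1/3 with the central bin centred at zero, boundary values to
#' the left.
#'
#' @inheritParams histogram_mos
#' @return data frame as in [histogram_mos()]; adds `bin_centre`.
#' @export
histogram_diff <- function(values, width = 1 / 3) {
  stopifnot(all(is.finite(values)))
  h <- bin_counts(values, width, origin = -width / 2)
  h$bin_centre <- (h$bin_left + h$bin_right) / 2
  h
}

#' Two-sample t test of MOS means
#'
#' Classical pooled-variance two-sample t test between the two MOS samples
#' (Welch via `var_equal = FALSE`), with the confidence interval of the mean
#' difference at the chosen level. Sidedness is selectable; the default is
#' two-sided.
#'
#' @param x,y MOS samples (e.g. eMIP and MIP).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param conf_level confidence level of the interval; the default matches a
#'   0.01% significance level.
#' @param var_equal pool the variances (classical test) or not (Welch).
#' @return list with `statistic`, `p_value`, `ci`, `mean_difference`,
#'   `degenerate` flag.
#' @export
mean_diff_test <- function(x, y, alternative = "two.sided",
                           conf_level = 0.9999, var_equal = TRUE) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                ci = c(mean(x) - mean(y), mean(x) - mean(y)),
                mean_difference = mean(x) - mean(y), degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, alternative = alternative,
                      conf.level = conf_level, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       ci = unname(tt$conf.int), mean_difference = mean(x) - mean(y),
       degenerate = FALSE)
}

#' Wilcoxon signed-rank test and bootstrap CI of the median difference
#'
#' Paired signed-rank test on the difference vector plus a seeded percentile
#' bootstrap confidence interval for the median difference.
#'
#' @param d paired differences.
#' @param n_boot bootstrap replicates (>= 1000).
#' @param seed RNG seed for the bootstrap.
#' @param alternative test sidedness, default two-sided.
#' @param conf_level CI level; the default matches a 0.01% significance
#'   level.
#' @return list with `p_value`, `ci`, `median_difference`, `degenerate`.
#' @export
median_diff_test <- function(d, n_boot = 2000L, seed = 1L,
                             alternative = "two.sided",
                             conf_level = 0.9999) {
  stopifnot(length(d) >= 2L, n_boot >= 1000L)
  degenerate <- all(d == 0)
  p <- if (degenerate) NA_real_ else
    suppressWarnings(stats::wilcox.test(d, alternative = alternative)$p.value)
  meds <- with_seed(seed, vapply(seq_len(n_boot), function(b)
    stats::median(sample(d, replace = TRUE)), 0))
  alpha <- 1 - conf_level
  ci <- unname(intensity_quantile(meds, c(alpha / 2, 1 - alpha / 2)))
  list(p_value = p, ci = ci, median_difference = stats::median(d),
       degenerate = degenerate)
}

#' Linear disagreement weights
#'
#' `w_ij = |v_i - v_j| / (v_max - v_min)` over the ordered level values; on
#' the native 1..4 scale this is `|i - j| / 3`.
#'
#' @param levels ordered numeric level values (at least 2 distinct).
#' @return L x L weight matrix of class `weight_matrix` with attribute
#'   `"levels"`.
#' @export
linear_weights <- function(levels = 1:4) {
  levels <- sort(unique(as.numeric(levels)))
  if (length(levels) < 2L) stop("need at least 2 distinct levels")
  w <- abs(outer(levels, levels, "-")) / (max(levels) - min(levels))
  structure(w, levels = levels, class = c("weight_matrix", "matrix"))
}

match_levels <- function(values, levels, tol = 1e-8) {
  idx <- vapply(values, function(v) {
    if (is.na(v)) return(NA_integer_)
    j <- which(abs(levels - v) < tol)
    if (length(j) != 1L) stop("rating value ", v, " is not on the scale")
    j
  }, 0L)
  idx
}

kappa_result <- function(kappa, v_im, v_r = NA_real_, n_scans = NA_integer_,
                         extra = list()) {
  v <- v_im + if (is.na(v_r)) 0 else v_r
  se <- sqrt(v)
  structure(c(list(kappa = kappa, v_im = v_im, v_r = v_r, se = se,
                   ci = c(kappa - 1.96 * se, kappa + 1.96 * se),
                   n_scans = n_scans), extra),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("<kappa_result> kappa %.4f (SE %.4f, 95%% CI %.4f..%.4f) - %s\n",
              x$kappa, x$se, x$ci[1], x$ci[2], interpret_kappa(x$kappa)))
  invisible(x)
}

#' Generalized weighted Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement `kappa = 1 - Do/De`, where `Do` is the mean
#' observed pairwise disagreement weight within scans and `De` the expected
#' disagreement under the pooled marginal category distribution (equivalent
#' to the agreement-weight form with weights `1 - w`). The per-rater count of
#' raters may vary across scans; scans with fewer than 2 ratings are
#' dropped. If every rating falls in one category the expected disagreement
#' is zero and kappa is defined as 1.
#'
#' The image-sampling variance `v_im` is the closed-form linearized
#' subject-sampling variance of this estimator (the rater panel is treated
#' as fixed); rater-sampling variance is estimated separately by jackknife.
#'
#' @param ratings numeric matrix (scans x raters) of level values, `NA`
#'   allowed, or a [rating_table()] (its first-session ratings are used).
#' @param weights [linear_weights()]-style disagreement matrix whose
#'   `"levels"` attribute matches the rating values.
#' @return [kappa_result] with `v_r` unset.
#' @export
weighted_fleiss_kappa <- function(ratings, weights = linear_weights(1:4)) {
  if (inherits(ratings, "rating_table")) ratings <- ratings$ratings
  ratings <- as.matrix(ratings)
  levels <- attr(weights, "levels")
  u <- 1 - unclass(weights)          # agreement weights
  L <- length(levels)
  idx <- matrix(match_levels(as.vector(ratings), levels),
                nrow(ratings), ncol(ratings))
  R <- matrix(0, nrow(ratings), L)   # per-scan level counts
  for (q in seq_len(L)) R[, q] <- rowSums(idx == q, na.rm = TRUE)
  ri <- rowSums(R)
  keep <- ri >= 2
  if (!all(keep)) {
    message("dropping ", sum(!keep), " scan(s) with fewer than 2 ratings")
    R <- R[keep, , drop = FALSE]; ri <- ri[keep]
  }
  n <- nrow(R)
  if (n < 2L) stop("need at least 2 scans with >= 2 ratings")
  pa_i <- (rowSums((R %*% u) * R) - ri) / (ri * (ri - 1))
  pa <- mean(pa_i)
  pi_q <- colMeans(R / ri)
  pe <- drop(t(pi_q) %*% u %*% pi_q)
  if (1 - pe <= .Machine$double.eps) {
    return(kappa_result(1, v_im = 0, n_scans = n))
  }
  kappa <- (pa - pe) / (1 - pe)
  # linearized subject-sampling variance
  kappa_i <- (pa_i - pe) / (1 - pe)
  pe_i <- drop((R / ri) %*% (u %*% pi_q))
  kappa_star <- kappa_i - 2 * (1 - kappa) * (pe_i - pe) / (1 - pe)
  v_im <- sum((kappa_star - kappa)^2) / (n * (n - 1))
  kappa_result(kappa, v_im = v_im, n_scans = n)
}

#' Delete-one jackknife variance over raters
#'
#' @param ratings scans x raters matrix of level values.
#' @param weights disagreement weight matrix.
#' @param kappa_fn function mapping a ratings matrix to a kappa estimate;
#'   defaults to the weighted Fleiss' kappa point estimate.
#' @return rater-sampling variance `v_r`.
#' @export
jackknife_rater_variance <- function(ratings, weights = linear_weights(1:4),
                                     kappa_fn = NULL) {
  if (inherits(ratings, "rating_table")) ratings <- ratings$ratings
  R <- ncol(ratings)
  if (R < 3L) stop("need at least 3 raters for the jackknife")
  if (is.null(kappa_fn))
    kappa_fn <- function(m) weighted_fleiss_kappa(m, weights)$kappa
  k_l <- vapply(seq_len(R), function(l)
    kappa_fn(ratings[, -l, drop = FALSE]), 0)
  (R - 1) / R * sum((k_l - mean(k_l))^2)
}

#' Inter-rater agreement with full variance
#'
#' Weighted Fleiss' kappa across all raters, with the closed-form
#' image-sampling variance and the delete-one jackknife rater-sampling
#' variance combined into the unconditional standard error.
#'
#' @param table [rating_table()] or ratings matrix.
#' @param weights disagreement weight matrix.
#' @return [kappa_result] with both variance components set.
#' @export
inter_kappa <- function(table, weights = linear_weights(1:4)) {
  ratings <- if (inherits(table, "rating_table")) table$ratings else table
  res <- weighted_fleiss_kappa(ratings, weights)
  v_r <- jackknife_rater_variance(ratings, weights)
  kappa_result(res$kappa, v_im = res$v_im, v_r = v_r, n_scans = res$n_scans)
}

#' Intra-rater agreement from repeated sessions
#'
#' Per rater, the weighted kappa between the first and second session over
#' the repeated scans; the reported coefficient is the mean across raters.
#' Rater-sampling variance is the unbiased variance of the per-rater kappas
#' divided by the number of raters; image-sampling variance is the mean of
#' the per-rater closed-form variances divided by the number of raters.
#'
#' @param table [rating_table()] with repeats.
#' @param weights disagreement weight matrix.
#' @return [kappa_result]; field `per_rater` holds the individual kappas.
#' @export
intra_kappa <- function(table, weights = linear_weights(1:4)) {
  stopifnot(inherits(table, "rating_table"))
  if (is.null(table$repeats)) stop("table has no repeated sessions")
  R <- ncol(table$ratings)
  per <- lapply(seq_len(R), function(l) {
    has <- !is.na(table$repeats[, l]) & !is.na(table$ratings[, l])
    if (sum(has) < 2L)
      stop("rater ", l, " has fewer than 2 repeated scans")
    weighted_fleiss_kappa(cbind(table$ratings[has, l],
                                table$repeats[has, l]), weights)
  })
  k_l <- vapply(per, function(p) p$kappa, 0)
  v_im_l <- vapply(per, function(p) p$v_im, 0)
  kappa_result(mean(k_l),
               v_im = mean(v_im_l) / R,
               v_r = stats::var(k_l) / R,
               n_scans = per[[1L]]$n_scans,
               extra = list(per_rater = k_l))
}

#' Enumerate disjoint rater-group pairs
#'
#' The construction used for group agreement: choose the
#' `n_raters - 2 * group_size` raters to exclude, then split the remaining
#' `2 * group_size` raters into a first group of `group_size` and its
#' complement, giving `choose(n, n - 2g) * choose(2g, g)` ordered pairs
#' (560 for 8 raters in groups of 3).
#'
#' @param n_raters panel size.
#' @param group_size raters per group; `2 * group_size <= n_raters`.
#' @return list with `pairs` (each a list `a`, `b`, `excluded`) and the
#'   count `P`.
#' @export
enumerate_group_pairs <- function(n_raters, group_size) {
  stopifnot(group_size >= 1L, 2L * group_size <= n_raters)
  raters <- seq_len(n_raters)
  n_excl <- n_raters - 2L * group_size
  excl_sets <- if (n_excl == 0L) list(integer(0)) else
    asplit(utils::combn(raters, n_excl), 2L)
  pairs <- list()
  for (ex in excl_sets) {
    rest <- setdiff(raters, ex)
    firsts <- utils::combn(rest, group_size)
    for (c_i in seq_len(ncol(firsts))) {
      a <- firsts[, c_i]
      pairs[[length(pairs) + 1L]] <-
        list(a = a, b = setdiff(rest, a), excluded = as.integer(ex))
    }
  }
  list(pairs = pairs, P = length(pairs))
}

#' Agreement between averaged groups of raters
#'
#' Forms every pair of disjoint rater groups (see
#' [enumerate_group_pairs()]), averages each group's first-session ratings
#' per scan, treats the attainable averages as an ordinal scale with linear
#' weights, and computes the two-"rater" weighted kappa per pair. Reports
#' the mean kappa, the summed per-pair image-sampling variances (as in the
#' printed group-variance formula, which carries no normalizing factor),
#' and the delete-two jackknife rater-sampling variance
#' `v_r = (R-2)/(2R) * sum_l (kappa_l - kappa_g)^2` over the
#' `choose(R, 2)` six-rater subsets.
#'
#' @param table [rating_table()] or ratings matrix without missing entries.
#' @param group_size raters per group (default 3).
#' @return [kappa_result]; fields `per_pair` and `per_subset` hold the
#'   pairwise and subset-mean kappas.
#' @export
group3_kappa <- function(table, group_size = 3L) {
  ratings <- if (inherits(table, "rating_table")) table$ratings else
    as.matrix(table)
  if (any(is.na(ratings)))
    stop("group agreement needs complete ratings (no NA)")
  R <- ncol(ratings)
  gp <- enumerate_group_pairs(R, group_size)
  levels <- seq(group_size, 4L * group_size) / group_size
  w <- linear_weights(levels)
  per_pair <- lapply(gp$pairs, function(p) {
    ga <- rowMeans(ratings[, p$a, drop = FALSE])
    gb <- rowMeans(ratings[, p$b, drop = FALSE])
    weighted_fleiss_kappa(cbind(ga, gb), w)
  })
  k_pair <- vapply(per_pair, function(p) p$kappa, 0)
  v_pair <- vapply(per_pair, function(p) p$v_im, 0)
  kappa_g <- mean(k_pair)
  excl_key <- vapply(gp$pairs, function(p)
    paste(p$excluded, collapse = ","), "")
  k_subset <- tapply(k_pair, excl_key, mean)
  v_r <- (R - 2) / (2 * R) * sum((k_subset - kappa_g)^2)
  kappa_result(kappa_g, v_im = sum(v_pair), v_r = v_r,
               n_scans = per_pair[[1L]]$n_scans,
               extra = list(per_pair = k_pair,
                            per_subset = as.numeric(k_subset),
                            subset_key = names(k_subset)))
}

#' Agreement gain between renderings
#'
#' `gain = kappa_eMIP - kappa_MIP` with variance
#' `v = v_r_gain + v_im_MIP + v_im_eMIP` and the one-sided
#' normal-approximation p-value `p = 1 - Phi(gain / sqrt(v))`. The
#' rater-sampling variance of the gain, `v_r_gain`, must come from the
#' matching paired resampling scheme (see the convenience wrappers).
#'
#' @param result_emip,result_mip [kappa_result] objects on the same scans.
#' @param v_r_gain rater-sampling variance of the paired kappa difference.
#' @return list of class `gain_result`: `gain`, `variance`, `p_value`.
#' @export
kappa_gain <- function(result_emip, result_mip, v_r_gain) {
  stopifnot(v_r_gain >= 0)
  gain <- result_emip$kappa - result_mip$kappa
  variance <- v_r_gain + result_emip$v_im + result_mip$v_im
  p <- if (variance == 0) {
    if (gain == 0) {
      message("zero gain with zero variance; p = 0.5 by continuity")
      0.5
    } else if (gain > 0) 0 else 1
  } else 1 - stats::pnorm(gain / sqrt(variance))
  structure(list(gain = gain, variance = variance, p_value = p),
            class = "gain_result")
}

#' @rdname kappa_gain
#' @param emip,mip [rating_table()] objects (or matrices for the inter
#'   case); the wrappers compute both kappas and the matching paired
#'   rater-resampling variance (delete-one jackknife for inter, per-rater
#'   paired differences for intra, delete-two jackknife for groups).
#' @param weights disagreement weight matrix (inter/intra).
#' @export
inter_kappa_gain <- function(emip, mip, weights = linear_weights(1:4)) {
  re <- if (inherits(emip, "rating_table")) emip$ratings else emip
  rm_ <- if (inherits(mip, "rating_table")) mip$ratings else mip
  stopifnot(ncol(re) == ncol(rm_))
  res_e <- weighted_fleiss_kappa(re, weights)
  res_m <- weighted_fleiss_kappa(rm_, weights)
  R <- ncol(re)
  d_l <- vapply(seq_len(R), function(l)
    weighted_fleiss_kappa(re[, -l, drop = FALSE], weights)$kappa -
      weighted_fleiss_kappa(rm_[, -l, drop = FALSE], weights)$kappa, 0)
  v_r_gain <- (R - 1) / R * sum((d_l - mean(d_l))^2)
  kappa_gain(res_e, res_m, v_r_gain)
}

#' @rdname kappa_gain
#' @export
intra_kappa_gain <- function(emip, mip, weights = linear_weights(1:4)) {
  res_e <- intra_kappa(emip, weights)
  res_m <- intra_kappa(mip, weights)
  d_l <- res_e$per_rater - res_m$per_rater
  v_r_gain <- stats::var(d_l) / length(d_l)
  kappa_gain(res_e, res_m, v_r_gain)
}

#' @rdname kappa_gain
#' @param group_size raters per group for the group-agreement gain.
#' @export
group3_kappa_gain <- function(emip, mip, group_size = 3L) {
  res_e <- group3_kappa(emip, group_size)
  res_m <- group3_kappa(mip, group_size)
  stopifnot(identical(res_e$subset_key, res_m$subset_key))
  R <- if (inherits(emip, "rating_table")) ncol(emip$ratings) else ncol(emip)
  d_l <- res_e$per_subset - res_m$per_subset
  gain <- res_e$kappa - res_m$kappa
  v_r_gain <- (R - 2) / (2 * R) * sum((d_l - gain)^2)
  kappa_gain(res_e, res_m, v_r_gain)
}

#' Two-sample comparison of two agreement coefficients
#'
#' One-sided normal-approximation p-value that the first coefficient
#' exceeds the second: `p = 1 - Phi((k_a - k_b) / sqrt(v_a + v_b))`, with
#' each unconditional variance the sum of its components.
#'
#' @param result_a,result_b [kappa_result] objects.
#' @return list with `difference` and `p_value`.
#' @export
kappa_compare <- function(result_a, result_b) {
  va <- result_a$v_im + if (is.na(result_a$v_r)) 0 else result_a$v_r
  vb <- result_b$v_im + if (is.na(result_b$v_r)) 0 else result_b$v_r
  diff <- result_a$kappa - result_b$kappa
  p <- if (va + vb == 0) {
    if (diff == 0) 0.5 else if (diff > 0) 0 else 1
  } else 1 - stats::pnorm(diff / sqrt(va + vb))
  list(difference = diff, p_value = p)
}

#' Verbal interpretation band of a kappa value
#'
#' The conventional benchmark scale: below 0 poor; 0-0.20 slight; 0.21-0.40
#' fair; 0.41-0.60 moderate; 0.61-0.80 substantial; 0.81-1 almost perfect.
#'
#' @param kappa agreement coefficient in \[-1, 1\].
#' @return character label.
#' @export
interpret_kappa <- function(kappa) {
  stopifnot(kappa >= -1, kappa <= 1)
  if (kappa < 0) "Poor agreement"
  else if (kappa <= 0.20) "Slight agreement"
  else if (kappa <= 0.40) "Fair agreement"
  else if (kappa <= 0.60) "Moderate agreement"
  else if (kappa <= 0.80) "Substantial agreement"
  else "Almost perfect agreement"
}

#' Synthetic ordinal rating generator
#'
#' Latent-quality rater model for calibration studies: each scan carries a
#' latent quality `q_i ~ N(quality_mean, quality_sd)`, each rater adds
#' independent noise `N(0, rater_noise_sd)`, and the sum is rounded and
#' clamped onto the 1..4 scale. Passing a shared `quality` vector lets two
#' method tables rate the same scans.
#'
#' @param n_scans,n_raters table dimensions.
#' @param rater_noise_sd per-rating noise; smaller values give more
#'   concordant raters.
#' @param seed RNG seed.
#' @param quality optional latent quality vector (length `n_scans`).
#' @param quality_mean,quality_sd latent quality distribution when
#'   `quality` is NULL.
#' @return integer matrix (scans x raters) of ratings in 1..4.
#' @export
simulate_ratings <- function(n_scans, n_raters = 8L, rater_noise_sd = 0.5,
                             seed = 1L, quality = NULL,
                             quality_mean = 2.5, quality_sd = 0.8) {
  with_seed(seed, {
    if (is.null(quality))
      quality <- stats::rnorm(n_scans, quality_mean, quality_sd)
    stopifnot(length(quality) == n_scans)
    noise <- matrix(stats::rnorm(n_scans * n_raters, 0, rater_noise_sd),
                    n_scans, n_raters)
    m <- clamp(round_half_up(quality + noise), 1L, 4L)
    storage.mode(m) <- "integer"
    m
  })
}
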