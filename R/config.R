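#' Surface-detection configuration
#'
#' Bundles every tunable of the iterative surface detection: the global
#' sensitivity that scales all intensity thresholds, the per-iteration
#' schedule (fit method, quantile level, threshold multiplier, outlier-band
#' multipliers, absolute cap, feasible-range half-widths), the adaptive-alpha
#' bounds, the train split for penalized degree selection, RANSAC settings,
#' and the flattening zero level.
#'
#' The default four-iteration schedule is this package's own calibration
#' (non-canonical defaults, every value overridable): it starts with a robust
#' RANSAC plane over the full depth, then tightens to fixed-plane and
#' dynamic-degree polynomial fits on progressively narrower feasible ranges,
#' with the last iteration choosing its quantile adaptively from the noise
#' just above the current surface estimate.
#'
#' @param sensitivity positive; larger values lower all thresholds and so
#'   admit more candidate surface points.
#' @param iterations list of per-iteration records; see Details in the
#'   package vignette. Default: the built-in 4-iteration schedule.
#' @param alpha_min,alpha_max bounds (in (0,1)) for the adaptively determined
#'   quantile of the final iteration.
#' @param max_inner_iterations cap on fit/exclude cycles inside one iteration.
#' @param train_fraction fraction of included points used to train each
#'   candidate polynomial degree (the remainder scores the penalized cost).
#' @param max_degree largest polynomial degree per lateral direction.
#' @param ransac_sample_size,ransac_max_distance RANSAC minimal sample and
#'   inlier distance (voxels).
#' @param zero_level depth index to which the detected surface is shifted
#'   during flattening (100 voxels = 400 um at the default pitch).
#' @param random_seed seed for the train/test split and RANSAC sampling.
#' @return object of class `detection_config`; attribute `"defaulted"` lists
#'   the top-level fields that were not user-specified.
#' @export
detection_config <- function(sensitivity = 1,
                             iterations = default_iteration_schedule(),
                             alpha_min = 0.90, alpha_max = 0.999,
                             max_inner_iterations = 5L,
                             train_fraction = 0.95,
                             max_degree = 4L,
                             ransac_sample_size = 10L,
                             ransac_max_distance = 30,
                             zero_level = 100L,
                             random_seed = 1L) {
  supplied <- names(match.call())[-1L]
  fields <- c("sensitivity", "iterations", "alpha_min", "alpha_max",
              "max_inner_iterations", "train_fraction", "max_degree",
              "ransac_sample_size", "ransac_max_distance", "zero_level",
              "random_seed")
  cfg <- structure(
    list(sensitivity = sensitivity, iterations = iterations,
         n_outer_iterations = length(iterations),
         alpha_min = alpha_min, alpha_max = alpha_max,
         max_inner_iterations = as.integer(max_inner_iterations),
         train_fraction = train_fraction, max_degree = as.integer(max_degree),
         ransac_sample_size = as.integer(ransac_sample_size),
         ransac_max_distance = ransac_max_distance,
         zero_level = as.integer(zero_level),
         random_seed = as.integer(random_seed)),
    class = "detection_config",
    defaulted = setdiff(fields, supplied))
  validate_detection_config(cfg)
  cfg
}

#' @rdname detection_config
#' @export
default_iteration_schedule <- function() {
  it <- function(fit_method, alpha, tau, mult, h_abs, theta_top, theta_bot)
    list(fit_method = fit_method, alpha = alpha, tau = tau,
         sigma_top = mult, sigma_bot = mult,
         gamma_top = mult, gamma_bot = mult,
         h_abs = h_abs, theta_top = theta_top, theta_bot = theta_bot)
  list(it("RANSAC_linear",  0.99,       1.0, 4,   200, 150, 150),
       it("Polyfit_fixed",  0.98,       0.9, 3,    80,  80, 100),
       it("Polyfit_fixed",  0.97,       0.8, 2.5,  40,  40,  60),
       it("Polyfit_dynamic", "adaptive", 0.7, 2,    30,  40,  60))
}

validate_detection_config <- function(cfg) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid config: ", msg)
  chk(is.numeric(cfg$sensitivity) && cfg$sensitivity > 0,
      "sensitivity must be positive")
  chk(cfg$alpha_min > 0 && cfg$alpha_min < 1 &&
        cfg$alpha_max > 0 && cfg$alpha_max < 1,
      "alpha_min and alpha_max must lie in (0, 1)")
  chk(cfg$alpha_min < cfg$alpha_max, "alpha_min must be < alpha_max")
  chk(cfg$train_fraction > 0 && cfg$train_fraction < 1,
      "train_fraction must lie in (0, 1)")
  chk(cfg$max_inner_iterations >= 1L, "max_inner_iterations must be >= 1")
  chk(cfg$max_degree >= 1L, "max_degree must be >= 1")
  chk(cfg$ransac_sample_size >= 3L, "ransac_sample_size must be >= 3")
  chk(cfg$ransac_max_distance > 0, "ransac_max_distance must be positive")
  chk(cfg$zero_level >= 1L, "zero_level must be a positive depth index")
  chk(length(cfg$iterations) >= 1L, "need at least one iteration")
  methods <- c("RANSAC_linear", "Polyfit_fixed", "Polyfit_dynamic")
  for (i in seq_along(cfg$iterations)) {
    rec <- cfg$iterations[[i]]
    miss <- setdiff(c("fit_method", "alpha", "tau", "sigma_top", "sigma_bot",
                      "gamma_top", "gamma_bot", "h_abs", "theta_top",
                      "theta_bot"), names(rec))
    chk(length(miss) == 0L,
        sprintf("iteration %d is missing fields: %s", i,
                paste(miss, collapse = ", ")))
    chk(rec$fit_method %in% methods,
        sprintf("iteration %d: unknown fit_method '%s'", i, rec$fit_method))
    adaptive <- identical(rec$alpha, "adaptive")
    chk(adaptive || (is.numeric(rec$alpha) && rec$alpha > 0 && rec$alpha < 1),
        sprintf("iteration %d: alpha must be in (0, 1) or \"adaptive\"", i))
    chk(is.numeric(rec$tau) && rec$tau > 0,
        sprintf("iteration %d: tau must be positive", i))
    for (f in c("sigma_top", "sigma_bot", "gamma_top", "gamma_bot", "h_abs"))
      chk(is.numeric(rec[[f]]) && rec[[f]] > 0,
          sprintf("iteration %d: %s must be positive", i, f))
    for (f in c("theta_top", "theta_bot"))
      chk(is.numeric(rec[[f]]) && rec[[f]] > 0,  # Inf marks "unbounded"
          sprintf("iteration %d: %s must be positive (Inf for unbounded)", i, f))
  }
  invisible(cfg)
}

#' Load a detection configuration from a YAML file
#'
#' Unspecified keys take the documented defaults of [detection_config()];
#' unknown keys are rejected. Per-iteration overrides live under an
#' `iterations` list of records; a record may say `alpha: adaptive` and
#' `theta_top: unbounded` (mapped to `Inf`).
#'
#' @param path YAML file, or `NULL` for all defaults.
#' @return `detection_config`, with attribute `"defaulted"` naming the
#'   top-level fields that fell back to defaults.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(detection_config())
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("sensitivity", "iterations", "alpha_min", "alpha_max",
             "max_inner_iterations", "train_fraction", "max_degree",
             "ransac_sample_size", "ransac_max_distance", "zero_level",
             "random_seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(raw$iterations)) {
    base <- default_iteration_schedule()
    its <- vector("list", length(raw$iterations))
    for (i in seq_along(raw$iterations)) {
      rec <- raw$iterations[[i]]
      tmpl <- if (i <= length(base)) base[[i]] else base[[length(base)]]
      bad <- setdiff(names(rec), names(tmpl))
      if (length(bad) > 0L)
        stop("unknown iteration keys: ", paste(bad, collapse = ", "))
      for (f in c("theta_top", "theta_bot"))
        if (identical(rec[[f]], "unbounded")) rec[[f]] <- Inf
      tmpl[names(rec)] <- rec
      its[[i]] <- tmpl
    }
    raw$iterations <- its
  }
  cfg <- do.call(detection_config, raw)
  attr(cfg, "defaulted") <- setdiff(known, names(raw))
  cfg
}

#' @export
print.detection_config <- function(x, ...) {
  cat(sprintf("<detection_config> sensitivity %g, %d outer iterations, zero level %d\n",
              x$sensitivity, x$n_outer_iterations, x$zero_level))
  for (i in seq_along(x$iterations)) {
    r <- x$iterations[[i]]
    cat(sprintf("  k=%d %s alpha=%s tau=%g mult=%g/%g h_abs=%g theta=%g/%g\n",
                i, r$fit_method, paste(r$alpha), r$tau, r$sigma_top,
                r$gamma_top, r$h_abs, r$theta_top, r$theta_bot))
  }
  def <- attr(x, "defaulted")
  if (length(def) > 0L)
    cat("  defaulted:", paste(def, collapse = ", "), "\n")
  invisible(x)
}
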