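#' Maximum intensity projection along a lattice axis
#'
#' @param volume [rsom_volume()].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return object of class `projection2d`: `values` (2D matrix), `axis`,
#'   `band`. Projecting along x gives an (n_y x n_z) matrix, along y an
#'   (n_x x n_z) matrix, along z an (n_x x n_y) matrix.
#' @export
mip <- function(volume, axis = c("z", "x", "y")) {
  stopifnot(inherits(volume, "rsom_volume"))
  axis <- match.arg(axis)
  d <- dim(volume)
  vals <- switch(axis,
    z = {
      out <- volume$values[, , 1]
      for (k in seq_len(d[3])[-1]) out <- pmax(out, volume$values[, , k])
      out
    },
    x = {
      out <- volume$values[1, , ]
      for (i in seq_len(d[1])[-1]) out <- pmax(out, volume$values[i, , ])
      out
    },
    y = {
      out <- volume$values[, 1, ]
      for (j in seq_len(d[2])[-1]) out <- pmax(out, volume$values[, j, ])
      out
    })
  structure(list(values = as.matrix(vals), axis = axis, band = volume$band),
            class = "projection2d")
}

#' Least-squares band equalization factor
#'
#' The factor `alpha* = argmin_alpha || im_LF - alpha * im_HF ||` under the
#' Euclidean norm, i.e. the closed form
#' `<im_LF, im_HF> / <im_HF, im_HF>`. Used by the conventional rendering to
#' bring the weaker HF band onto the LF intensity scale.
#'
#' @param im_lf,im_hf projections (matrices or `projection2d`) of equal
#'   shape.
#' @return scalar `alpha*`; 0 with a warning when `im_hf` is identically
#'   zero.
#' @export
alpha_optimize <- function(im_lf, im_hf) {
  lf <- if (inherits(im_lf, "projection2d")) im_lf$values else im_lf
  hf <- if (inherits(im_hf, "projection2d")) im_hf$values else im_hf
  stopifnot(identical(dim(lf), dim(hf)))
  denom <- sum(hf * hf)
  if (denom == 0) {
    warning("HF projection is identically zero; alpha* = 0")
    return(0)
  }
  sum(lf * hf) / denom
}

#' Contrast parameters for band fusion
#'
#' @param mode `"alpha_joint"` (conventional rendering: joint linear scaling
#'   plus a saturation window) or `"dynamic"` (per-channel threshold
#'   normalization).
#' @param alpha_star equalization factor (alpha_joint mode; computed by
#'   [alpha_optimize()] when `NULL`).
#' @param th_lf_plus,th_hf_plus per-band upper thresholds (dynamic mode).
#' @param saturation saturation window `(low, high)` on the jointly scaled
#'   image, defaults `(0.06, 0.35)`.
#' @return object of class `contrast_params`.
#' @export
contrast_params <- function(mode = c("alpha_joint", "dynamic"),
                            alpha_star = NULL,
                            th_lf_plus = NULL, th_hf_plus = NULL,
                            saturation = c(0.06, 0.35)) {
  mode <- match.arg(mode)
  if (mode == "dynamic") {
    stopifnot(!is.null(th_lf_plus), !is.null(th_hf_plus))
    if (th_lf_plus < 0 || th_hf_plus < 0)
      stop("dynamic thresholds must be non-negative")
  }
  stopifnot(length(saturation) == 2L, saturation[1] >= 0,
            saturation[1] < saturation[2], saturation[2] <= 1)
  structure(list(mode = mode, alpha_star = alpha_star,
                 th_lf_plus = th_lf_plus, th_hf_plus = th_hf_plus,
                 saturation = saturation),
            class = "contrast_params")
}

saturation_window <- function(v, low, high) {
  out <- (v - low) / (high - low)
  clamp(out, 0, 1)
}

#' Conventional fused rendering (joint scaling + saturation window)
#'
#' Scales `alpha* * im_HF` and `im_LF` jointly to \[0, 1\] between their
#' combined minimum and maximum, then applies the saturation window: values
#' at or below `low` map to 0, at or above `high` to 1, linear in between.
#' LF fills the red channel, equalized HF the green channel.
#'
#' @param im_lf,im_hf per-band projections of equal shape.
#' @param params [contrast_params()] in `alpha_joint` mode.
#' @return [rgb_image()].
#' @export
fuse_alpha_joint <- function(im_lf, im_hf, params = contrast_params()) {
  stopifnot(params$mode == "alpha_joint")
  lf <- if (inherits(im_lf, "projection2d")) im_lf$values else im_lf
  hf <- if (inherits(im_hf, "projection2d")) im_hf$values else im_hf
  a <- if (is.null(params$alpha_star)) alpha_optimize(lf, hf) else
    params$alpha_star
  hf_star <- a * hf
  jmin <- min(hf_star, lf); jmax <- max(hf_star, lf)
  if (jmax == jmin) {
    warning("degenerate projections (joint max equals joint min); black image")
    z <- matrix(0, nrow(lf), ncol(lf))
    return(rgb_image(z, z))
  }
  low <- params$saturation[1]; high <- params$saturation[2]
  red <- saturation_window((lf - jmin) / (jmax - jmin), low, high)
  green <- saturation_window((hf_star - jmin) / (jmax - jmin), low, high)
  rgb_image(red, green)
}

#' Outlier-robust per-band contrast thresholds
#'
#' `th+ = 1.25 * q0.95(z-MIP)` per band, computed over all pixels of the
#' full-depth z-MIP. The 95th percentile (rather than the maximum) keeps
#' isolated strong absorbers and artifacts from setting the contrast
#' reference.
#'
#' @param pair [scan_pair()].
#' @return list with `th_lf_plus` and `th_hf_plus`.
#' @export
dynamic_thresholds <- function(pair) {
  stopifnot(inherits(pair, "scan_pair"))
  th <- function(vol) {
    t <- 1.25 * intensity_quantile(mip(vol, "z")$values, 0.95)
    if (t <= 0)
      warning(vol$band,
              " band threshold is non-positive; channel will render black")
    t
  }
  list(th_lf_plus = th(pair$lfr), th_hf_plus = th(pair$hfr))
}

#' Dynamic per-channel contrast fusion
#'
#' Each band is clipped below at zero, capped at its own upper threshold and
#' divided by it, mapping the channel linearly onto \[0, 1\] independently of
#' the other band. LF fills red, HF fills green.
#'
#' @param im_lf,im_hf per-band projections of equal shape.
#' @param params [contrast_params()] in `dynamic` mode.
#' @return [rgb_image()].
#' @export
fuse_dynamic <- function(im_lf, im_hf, params) {
  stopifnot(inherits(params, "contrast_params"), params$mode == "dynamic")
  lf <- if (inherits(im_lf, "projection2d")) im_lf$values else im_lf
  hf <- if (inherits(im_hf, "projection2d")) im_hf$values else im_hf
  channel <- function(im, th) {
    if (th <= 0) return(matrix(0, nrow(im), ncol(im)))
    clamp(im, 0, th) / th
  }
  rgb_image(channel(lf, params$th_lf_plus), channel(hf, params$th_hf_plus))
}

# Lateral projections are displayed with depth increasing downward: the
# (lateral x depth) MIP matrices are transposed so image rows run along z.
orient_for_display <- function(im, axis) {
  if (axis == "z") im else t(im)
}

#' Conventional MIP rendering of a scan
#'
#' Projects both bands along each requested axis, equalizes the HF band by
#' the per-axis least-squares factor, and fuses with joint scaling and the
#' saturation window.
#'
#' @param pair [scan_pair()].
#' @param axes subset of `c("x", "y", "z")`.
#' @param saturation saturation window, default `(0.06, 0.35)`.
#' @return named list of [rgb_image()] per axis; lateral views are oriented
#'   with depth increasing downward. Attribute `"alpha_star"` records the
#'   per-axis equalization factors.
#' @export
render_mip <- function(pair, axes = c("x", "y", "z"),
                       saturation = c(0.06, 0.35)) {
  stopifnot(inherits(pair, "scan_pair"), all(axes %in% c("x", "y", "z")))
  out <- list(); alphas <- list()
  for (ax in axes) {
    lf <- mip(pair$lfr, ax)$values
    hf <- mip(pair$hfr, ax)$values
    a <- alpha_optimize(lf, hf)
    img <- fuse_alpha_joint(lf, hf,
                            contrast_params("alpha_joint", alpha_star = a,
                                            saturation = saturation))
    out[[ax]] <- rgb_image(orient_for_display(img$red, ax),
                           orient_for_display(img$green, ax))
    alphas[[ax]] <- a
  }
  attr(out, "alpha_star") <- alphas
  out
}

#' Enhanced MIP rendering of a scan
#'
#' Flattens both bands with the detected surface (zero level from
#' `config`), computes the dynamic contrast thresholds on the corrected
#' volumes, projects along each requested axis and fuses per channel.
#'
#' @param pair [scan_pair()].
#' @param sfit finalized [surface_function()] (e.g. from
#'   [detect_surface()]).
#' @param config [detection_config()] supplying the zero level.
#' @param axes subset of `c("x", "y", "z")`.
#' @return named list of [rgb_image()] per axis, oriented as in
#'   [render_mip()]; attributes `"thresholds"` and `"shift_map"` carry the
#'   dynamic thresholds and the shift map used.
#' @export
render_emip <- function(pair, sfit, config = detection_config(),
                        axes = c("x", "y", "z")) {
  stopifnot(inherits(pair, "scan_pair"), inherits(sfit, "surface_function"))
  shift <- rasterize_surface(sfit, dim(pair), config$zero_level)
  flat <- flatten_pair(pair, shift)
  th <- dynamic_thresholds(flat)
  params <- contrast_params("dynamic", th_lf_plus = th$th_lf_plus,
                            th_hf_plus = th$th_hf_plus)
  out <- list()
  for (ax in axes) {
    img <- fuse_dynamic(mip(flat$lfr, ax), mip(flat$hfr, ax), params)
    out[[ax]] <- rgb_image(orient_for_display(img$red, ax),
                           orient_for_display(img$green, ax))
  }
  attr(out, "thresholds") <- th
  attr(out, "shift_map") <- shift
  out
}
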