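#' Read a reconstruction volume
#'
#' Reads a single-band volume from a multi-page float TIFF (pages = depth
#' slices, rows = slow axis x, columns = fast axis y) or a NIfTI-1 file with
#' axis order (x, y, z). Depth index `k = 1` is the slice nearest the
#' detector in both formats.
#'
#' @param path file path ending in `.tif`/`.tiff` or `.nii`/`.nii.gz`.
#' @param band frequency band of the stored reconstruction, `"LF"` or `"HF"`.
#' @param voxel_size_um voxel pitch in micrometres; default 20 x 20 x 4.
#' @return [rsom_volume()].
#' @export
read_volume <- function(path, band = c("LF", "HF"),
                        voxel_size_um = c(20, 20, 4)) {
  band <- match.arg(band)
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    read_float_tiff(path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    a <- as.array(RNifti::readNifti(path))
    if (length(dim(a)) == 4L && dim(a)[4] == 1L) dim(a) <- dim(a)[1:3]
    if (length(dim(a)) != 3L) stop("NIfTI payload is not 3D: ", path)
    array(as.vector(a), dim(a))  # drop image-header attributes
  } else stop("unsupported volume format (need TIFF or NIfTI): ", path)
  if (!all(is.finite(vals)))
    stop("volume contains non-finite voxels: ", path)
  rsom_volume(vals, band = band, voxel_size_um = voxel_size_um)
}

#' Write a reconstruction volume
#'
#' TIFF output stores IEEE-float samples (32-bit by default, 64-bit
#' optionally); NIfTI output always stores doubles, so NIfTI round trips are
#' bit-exact for any input and TIFF round trips are bit-exact whenever the
#' values are representable at the chosen bit depth.
#'
#' @param volume [rsom_volume()] or bare 3D array.
#' @param path output path; format chosen by extension as in [read_volume()].
#' @param bits TIFF sample width, 32 or 64; ignored for NIfTI.
#' @export
write_volume <- function(volume, path, bits = 32L) {
  vals <- if (inherits(volume, "rsom_volume")) volume$values else volume
  stopifnot(is.array(vals), length(dim(vals)) == 3L)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    write_float_tiff(vals, path, bits = as.integer(bits))
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    RNifti::writeNifti(RNifti::asNifti(vals, datatype = "double"), path)
  } else stop("unsupported volume format (need TIFF or NIfTI): ", path)
  invisible(path)
}

#' RGB rendering container
#'
#' Red and green channels carry the LF and HF bands of a fused projection;
#' the blue channel is identically zero by construction.
#'
#' @param red,green numeric matrices in \[0, 1\], same shape.
#' @return object of class `rgb_image` with fields `red`, `green`, `blue`.
#' @export
rgb_image <- function(red, green) {
  stopifnot(is.matrix(red), is.matrix(green), identical(dim(red), dim(green)))
  if (any(!is.finite(red)) || any(!is.finite(green)) ||
      any(red < 0 | red > 1) || any(green < 0 | green > 1))
    stop("channel values must be finite and within [0, 1]")
  structure(list(red = red, green = green,
                 blue = matrix(0, nrow(red), ncol(red))),
            class = "rgb_image")
}

#' @export
dim.rgb_image <- function(x) dim(x$red)

#' Write an RGB rendering as 8-bit PNG
#'
#' Quantization is round-half-up of `value * 255` (so 0.5 maps to byte 128),
#' applied in this function; the PNG encoder receives the already-quantized
#' bytes.
#'
#' @param image [rgb_image()].
#' @param path output file path.
#' @export
write_rgb_png <- function(image, path) {
  stopifnot(inherits(image, "rgb_image"))
  d <- dim(image)
  bytes <- round_half_up(c(image$red, image$green, image$blue) * 255)
  png::writePNG(array(bytes / 255, dim = c(d, 3L)), path)
  invisible(path)
}

#' Persist / restore a fitted surface function
#'
#' The sidecar is a JSON file storing everything needed to re-evaluate the
#' surface exactly: the selected degree, the monomial index set in its
#' documented enumeration order, the coefficients in the internally used
#' centred/scaled lateral coordinates, the affine coordinate transform, and
#' the final offset. `load_surface_sidecar` is the exact inverse.
#'
#' @param sfit [surface_function()].
#' @param path JSON file path.
#' @export
save_surface_sidecar <- function(sfit, path) {
  stopifnot(inherits(sfit, "surface_function"))
  # doubles are stored as full-precision decimal strings ("%.17g" survives a
  # double -> text -> double round trip exactly)
  num <- function(x) sprintf("%.17g", x)
  payload <- list(
    degree = as.integer(sfit$degree),
    terms = unname(apply(sfit$terms, 1L, as.integer, simplify = FALSE)),
    coefficients = num(sfit$coef),
    transform = lapply(sfit$transform, num),
    offset = num(sfit$offset))
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_surface_sidecar
#' @return `load_surface_sidecar` returns the stored [surface_function()].
#' @export
load_surface_sidecar <- function(path) {
  if (!file.exists(path)) stop("sidecar not found: ", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("degree", "terms", "coefficients", "transform", "offset"))
    if (is.null(p[[f]])) stop("malformed surface sidecar: missing field '", f, "'")
  for (f in c("xc", "xs", "yc", "ys"))
    if (is.null(p$transform[[f]]))
      stop("malformed surface sidecar: missing field 'transform.", f, "'")
  terms <- if (is.matrix(p$terms)) p$terms else do.call(rbind, p$terms)
  surface_function(degree = as.integer(p$degree),
                   terms = matrix(as.integer(terms), ncol = 2L,
                                  dimnames = list(NULL, c("i", "k"))),
                   coef = as.numeric(p$coefficients),
                   transform = lapply(p$transform[c("xc", "xs", "yc", "ys")],
                                      as.numeric),
                   offset = as.numeric(p$offset))
}
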