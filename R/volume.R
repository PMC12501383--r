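#' RSOM reconstruction volume
#'
#' A single frequency band's 3D reconstruction on the lattice
#' `{1..n_x} x {1..n_y} x {1..n_z}`. The first index `i` runs along the slow
#' scanning axis (x), the second `j` along the fast scanning axis (y), and the
#' third `k` along depth (z), with `k = 1` nearest the detector and `k`
#' increasing into the skin. All of the surface-detection arithmetic relies on
#' this orientation: "above the surface" always means smaller `k`.
#'
#' @param values 3D numeric array of voxel intensities, all finite.
#' @param band `"LF"` (10-40 MHz reconstruction) or `"HF"` (40-99 MHz).
#' @param voxel_size_um voxel pitch in micrometres along (x, y, z);
#'   the scanner default is 20 x 20 x 4 um.
#' @return An object of class `rsom_volume` with fields `values`, `band`,
#'   `voxel_size_um`.
#' @export
rsom_volume <- function(values, band = c("LF", "HF"),
                        voxel_size_um = c(20, 20, 4)) {
  band <- match.arg(band)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (!all(is.finite(values)))
    stop("volume contains non-finite voxel values")
  if (any(dim(values) < 1L)) stop("all lattice dimensions must be >= 1")
  if (length(voxel_size_um) != 3L || any(voxel_size_um <= 0))
    stop("`voxel_size_um` must be three positive numbers")
  structure(
    list(values = values, band = band,
         voxel_size_um = as.numeric(voxel_size_um)),
    class = "rsom_volume")
}

#' @export
dim.rsom_volume <- function(x) dim(x$values)

#' @export
print.rsom_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rsom_volume> band %s, %d x %d x %d voxels (%g x %g x %g um)\n",
              x$band, d[1], d[2], d[3],
              x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3]))
  invisible(x)
}

#' Co-registered dual-band scan
#'
#' Pairs the low-frequency (LF) and high-frequency (HF) reconstructions of one
#' scan. Both volumes must share the lattice and voxel geometry; the LF band
#' carries the larger vessels, the HF band the small vascular structures.
#'
#' @param lfr `rsom_volume` with band `"LF"`.
#' @param hfr `rsom_volume` with band `"HF"`.
#' @return An object of class `scan_pair` with fields `lfr` and `hfr`.
#' @export
scan_pair <- function(lfr, hfr) {
  stopifnot(inherits(lfr, "rsom_volume"), inherits(hfr, "rsom_volume"))
  if (lfr$band != "LF" || hfr$band != "HF")
    stop("`lfr` must have band LF and `hfr` band HF")
  if (!identical(dim(lfr), dim(hfr)))
    stop("LF and HF volumes must share lattice dimensions")
  if (!isTRUE(all.equal(lfr$voxel_size_um, hfr$voxel_size_um)))
    stop("LF and HF volumes must share voxel size")
  structure(list(lfr = lfr, hfr = hfr), class = "scan_pair")
}

#' @export
dim.scan_pair <- function(x) dim(x$lfr)

#' @export
print.scan_pair <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<scan_pair> LF + HF, %d x %d x %d voxels\n", d[1], d[2], d[3]))
  invisible(x)
}
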