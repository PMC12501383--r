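#' Rasterize a surface function to per-column shift levels
#'
#' Evaluates the finalized surface on the lateral lattice and projects each
#' value to the nearest depth index (exact halves resolve to the smaller
#' index; values outside the depth lattice clamp to its bounds).
#'
#' @param sfit finalized [surface_function()].
#' @param dims lattice dimensions `(n_x, n_y, n_z)`.
#' @param zero_level depth index at which the surface will be aligned.
#' @return object of class `shift_map` with integer matrix `s` and
#'   `zero_level`.
#' @export
rasterize_surface <- function(sfit, dims, zero_level = 100L) {
  stopifnot(inherits(sfit, "surface_function"), length(dims) == 3L,
            zero_level >= 1L, zero_level <= dims[3])
  s <- clamp(round_half_down(sf_eval_grid(sfit, dims[1], dims[2])),
             1L, dims[3])
  storage.mode(s) <- "integer"
  structure(list(s = s, zero_level = as.integer(zero_level),
                 n_z = as.integer(dims[3])),
            class = "shift_map")
}

#' Flatten a volume so the detected surface sits at the zero level
#'
#' Shifts every z-column so that the voxel at its surface level `s_ij` lands
#' at depth `zero_level`: the output satisfies
#' `V'[i, j, k] = V[i, j, k + (s_ij - zero_level)]` wherever the source
#' index lies inside the depth lattice, and 0 elsewhere (content shifted out
#' of the volume is cut off, missing content is zero-padded). The shape is
#' preserved.
#'
#' @param volume [rsom_volume()].
#' @param shift [rasterize_surface()] result on the same lateral lattice.
#' @return flattened [rsom_volume()].
#' @export
flatten_volume <- function(volume, shift) {
  stopifnot(inherits(volume, "rsom_volume"), inherits(shift, "shift_map"))
  d <- dim(volume)
  if (!identical(dim(shift$s), d[1:2]))
    stop("shift map does not match the volume's lateral lattice")
  nz <- d[3]
  m <- volume$values
  dim(m) <- c(d[1] * d[2], nz)
  out <- matrix(0, d[1] * d[2], nz)
  delta <- as.vector(shift$s) - shift$zero_level
  for (dlt in unique(delta)) {
    cols <- delta == dlt
    k_out <- seq_len(nz)
    k_src <- k_out + dlt
    ok <- k_src >= 1L & k_src <= nz
    out[cols, k_out[ok]] <- m[cols, k_src[ok]]
  }
  dim(out) <- d
  rsom_volume(out, band = volume$band, voxel_size_um = volume$voxel_size_um)
}

#' @rdname flatten_volume
#' @param pair [scan_pair()]; both bands are flattened with the one shared
#'   shift map (a single surface is fitted from the union of both bands'
#'   points).
#' @export
flatten_pair <- function(pair, shift) {
  scan_pair(flatten_volume(pair$lfr, shift), flatten_volume(pair$hfr, shift))
}
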