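#' Attenuation volume
#'
#' Container for a reconstructed 3D attenuation grid. Values are linear
#' attenuation coefficients in mm^-1; the first array axis is the bone's
#' axial (z) direction by convention, and voxels are isotropic.
#'
#' @param grid 3D numeric array of attenuation values (mm^-1).
#' @param voxel_size_mm isotropic voxel edge length in mm.
#' @param day acquisition day as days since baseline (day 0).
#' @param sample_id sample identifier.
#'
#' @return An object of class `ct_volume`: a list with elements `grid`,
#'   `voxel_size_mm`, `day` and `sample_id`.
#' @export
#' @examples
#' v <- ct_volume(array(0.1, c(4, 4, 4)), voxel_size_mm = 0.009)
#' voxel_volume_mm3(v)
ct_volume <- function(grid, voxel_size_mm, day = 0L, sample_id = "sample") {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("`grid` must be a 3D array", call. = FALSE)
  if (!is.numeric(grid))
    stop("`grid` must be numeric", call. = FALSE)
  if (any(dim(grid) < 1L))
    stop("all grid dimensions must be >= 1", call. = FALSE)
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L ||
      !is.finite(voxel_size_mm) || voxel_size_mm <= 0)
    stop("`voxel_size_mm` must be a single positive number", call. = FALSE)
  if (!is.numeric(day) || length(day) != 1L || day < 0)
    stop("`day` must be a single non-negative number", call. = FALSE)
  structure(
    list(grid = grid, voxel_size_mm = as.numeric(voxel_size_mm),
         day = as.numeric(day), sample_id = as.character(sample_id)),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf(
    "ct_volume '%s' | %d x %d x %d voxels @ %.4g mm | day %g | range [%.4g, %.4g] mm^-1\n",
    x$sample_id, d[1], d[2], d[3], x$voxel_size_mm, x$day,
    min(x$grid), max(x$grid)))
  invisible(x)
}

#' @rdname ct_volume
#' @param x object to test or measure.
#' @export
is_ct_volume <- function(x) inherits(x, "ct_volume")

#' @rdname ct_volume
#' @return `voxel_volume_mm3()`: the volume of one voxel in mm^3.
#' @export
voxel_volume_mm3 <- function(x) {
  stopifnot(is_ct_volume(x))
  x$voxel_size_mm^3
}
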