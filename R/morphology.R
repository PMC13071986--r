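## Binary 3D morphology with Euclidean (ball) structuring elements.
##
## All operations are exact-distance based: dilation/erosion threshold the
## squared Euclidean distance transform of the mask (or its complement), so
## the effective structuring element is the digital ball
## { o : |o|^2 <= r^2 }. Voxels outside the grid are treated as foreground
## for erosion (border-safe: a bone running through the full axial extent is
## not eaten from the ends) and as background for dilation.

.check_mask <- function(mask) {
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask))
    stop("mask must be a 3D logical array", call. = FALSE)
  invisible(mask)
}

.ball_r2 <- function(radius) radius^2 + 1e-9  # guard exact integer offsets

#' Ball-structured binary morphology in 3D
#'
#' Euclidean-metric dilation, erosion, opening and closing of a 3D logical
#' mask with a ball of the given radius (in voxels, need not be integer).
#' Erosion treats the outside of the grid as foreground, so structures
#' touching the volume border are not eroded from the border side.
#'
#' @param mask 3D logical array.
#' @param radius ball radius in voxels; `radius <= 0` returns the mask.
#' @return 3D logical array of the same dimensions.
#' @export
dilate_ball <- function(mask, radius) {
  .check_mask(mask)
  if (radius <= 0) return(mask)
  d2 <- cpp_edt_sq(mask, dim(mask))
  array(d2 <= .ball_r2(radius), dim(mask))
}

#' @rdname dilate_ball
#' @export
erode_ball <- function(mask, radius) {
  .check_mask(mask)
  if (radius <= 0) return(mask)
  d2 <- cpp_edt_sq(!mask, dim(mask))
  array(mask & (d2 > .ball_r2(radius)), dim(mask))
}

#' @rdname dilate_ball
#' @export
open_ball <- function(mask, radius) dilate_ball(erode_ball(mask, radius), radius)

#' @rdname dilate_ball
#' @export
close_ball <- function(mask, radius) erode_ball(dilate_ball(mask, radius), radius)

#' Fill enclosed cavities of a 3D mask
#'
#' Background voxels that cannot be reached from the volume border are added
#' to the mask. With `slicewise = TRUE` the fill is additionally applied
#' within every axial (first-axis) slice, which closes tubular cavities that
#' are open at the ends of the grid (e.g. the marrow canal of a bone scanned
#' over its full length).
#'
#' @param mask 3D logical array.
#' @param slicewise also fill 2D holes per axial slice.
#' @return 3D logical array.
#' @export
fill_holes <- function(mask, slicewise = TRUE) {
  .check_mask(mask)
  if (slicewise) {
    reached <- array(cpp_border_background(mask, dim(mask), TRUE), dim(mask))
    mask <- mask | !reached
  }
  reached <- array(cpp_border_background(mask, dim(mask), FALSE), dim(mask))
  mask | !reached
}

#' Label connected components of a 3D mask
#'
#' @param mask 3D logical array.
#' @param connectivity 26 (default, voxels sharing a face, edge or corner)
#'   or 6 (faces only).
#' @return Integer array of the same dimensions; background is 0, components
#'   are numbered from 1 in scan order.
#' @export
label_components <- function(mask, connectivity = 26L) {
  .check_mask(mask)
  if (!connectivity %in% c(6L, 26L))
    stop("connectivity must be 6 or 26", call. = FALSE)
  array(cpp_label_components(mask, dim(mask), as.integer(connectivity)),
        dim(mask))
}

# largest connected component (ties broken toward the first label)
.largest_component <- function(mask, connectivity = 26L) {
  lab <- label_components(mask, connectivity)
  if (max(lab) <= 1L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  array(lab == which.max(sizes), dim(mask))
}
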