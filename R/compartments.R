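## Cortical/trabecular separation and anatomical region delineation.

.as_mask_array <- function(mask) {
  if (inherits(mask, "bone_mask")) mask$mask else mask
}

#' Filled periosteal envelope
#'
#' Constructs the total-volume (TV) region of interest from a bone mask:
#' morphological closing with a ball, followed by interior hole filling per
#' axial slice and in 3D. The envelope contains the bone mask and the
#' enclosed marrow space; if closing leaves several connected components,
#' only the largest is kept (with a warning).
#'
#' @param mask a `bone_mask` or 3D logical array.
#' @param close_radius_vox closing ball radius in voxels (default 4); keep it smaller than anatomical concavities (e.g. the metaphyseal waist) so that TV follows the periosteal surface rather than bridging it.
#' @return 3D logical array (the envelope), with the radius stored in
#'   attribute `close_radius_vox`.
#' @export
build_envelope <- function(mask, close_radius_vox = 4) {
  m <- .as_mask_array(mask)
  .check_mask(m)
  if (!any(m)) stop("empty mask: no envelope to build", call. = FALSE)
  env <- close_ball(m, close_radius_vox)
  env <- fill_holes(env, slicewise = TRUE)
  lab <- label_components(env, 26L)
  if (max(lab) > 1L) {
    warning("envelope is not connected after closing; keeping the largest component")
    sizes <- tabulate(lab[lab > 0L])
    env <- array(lab == which.max(sizes), dim(env))
    env <- fill_holes(env, slicewise = TRUE)
  }
  attr(env, "close_radius_vox") <- close_radius_vox
  env
}

#' Separate cortical and trabecular compartments
#'
#' Morphological separation of the bone mask: the cortical shell is the
#' dominant connected component surviving a ball erosion of radius
#' `open_radius_vox` (which removes structures thinner than about twice that
#' radius, i.e. the trabeculae), re-dilated by the same radius and clipped to
#' the mask; every remaining bone voxel is trabecular. The two classes
#' partition the mask exactly.
#'
#' @param mask a `bone_mask` or 3D logical array.
#' @param envelope envelope built from the same mask (see
#'   [build_envelope()]).
#' @param open_radius_vox opening ball radius in voxels; choose about 1.5x
#'   the expected trabecular half-thickness, and less than half the cortical
#'   thickness.
#' @return An object of class `bone_label_map`: list with `labels` (integer
#'   array, 0 background / 1 cortical / 2 trabecular), `envelope`, and
#'   `params`.
#' @export
separate_compartments <- function(mask, envelope, open_radius_vox = 4) {
  m <- .as_mask_array(mask)
  .check_mask(m)
  stopifnot(identical(dim(m), dim(envelope)))
  core <- erode_ball(m, open_radius_vox)
  if (!any(core))
    stop(sprintf(paste0("opening removed the whole mask: open_radius_vox = %g ",
                        "exceeds half the thickest structure; reduce it"),
                 open_radius_vox), call. = FALSE)
  core <- .largest_component(core, 26L)
  cortical <- dilate_ball(core, open_radius_vox) & m
  labels <- array(0L, dim(m))
  labels[cortical] <- 1L
  labels[m & !cortical] <- 2L
  structure(list(labels = labels, envelope = envelope,
                 params = list(open_radius_vox = open_radius_vox)),
            class = "bone_label_map")
}

#' @export
print.bone_label_map <- function(x, ...) {
  cat(sprintf("bone_label_map | cortical %s | trabecular %s | envelope %s voxels\n",
              format(sum(x$labels == 1L), big.mark = ","),
              format(sum(x$labels == 2L), big.mark = ","),
              format(sum(x$envelope), big.mark = ",")))
  invisible(x)
}

#' Delineate proximal EM zone, diaphysis and distal EM zone
#'
#' Splits the axial extent of the envelope into the proximal
#' epiphysis/metaphysis (EM) zone, the diaphysis and the distal EM zone.
#'
#' The default `area-profile` method computes the envelope cross-sectional
#' area A(z) along the bone axis (array axis 1) and takes the diaphysis as
#' the maximal contiguous run of slices with
#' `A(z) <= A_min + beta * (A_end - A_min)`, where `A_min` is the minimal
#' mid-shaft area and `A_end` the mean of the two end maxima. The
#' `fixed-fraction` method cuts at fixed fractions of the axial extent and
#' is provided for exact reproducibility. A profile with no interior run
#' (e.g. a uniform cylinder) falls back to fixed fractions with a warning.
#'
#' @param envelope 3D logical array from [build_envelope()].
#' @param method `"area-profile"` (default) or `"fixed-fraction"`.
#' @param beta area-profile sensitivity in (0, 1); default 0.5.
#' @param fractions length-2 fractions of the axial extent at which the
#'   proximal/diaphysis and diaphysis/distal cuts fall for the
#'   fixed-fraction method (and the fallback).
#' @return An object of class `region_partition`: list with `cuts` (last
#'   axial slice of the proximal EM zone and of the diaphysis), `region`
#'   (factor of length `dim(envelope)[1]` with levels `proximal_EM`,
#'   `diaphysis`, `distal_EM`) and `method`.
#' @export
delineate_regions <- function(envelope,
                              method = c("area-profile", "fixed-fraction"),
                              beta = 0.5, fractions = c(0.40, 0.86)) {
  method <- match.arg(method)
  .check_mask(envelope)
  if (!any(envelope)) stop("empty envelope", call. = FALSE)
  nz <- dim(envelope)[1]
  area <- vapply(seq_len(nz), function(z) sum(envelope[z, , ]), numeric(1))

  make_partition <- function(z1, z2, method) {
    stopifnot(z1 >= 1, z1 < z2, z2 < nz)
    region <- factor(rep(c("proximal_EM", "diaphysis", "distal_EM"),
                         c(z1, z2 - z1, nz - z2)),
                     levels = c("proximal_EM", "diaphysis", "distal_EM"))
    structure(list(cuts = c(z1, z2), region = region, method = method),
              class = "region_partition")
  }

  fixed <- function(method) {
    z1 <- floor(fractions[1] * nz)
    z2 <- floor(fractions[2] * nz)
    make_partition(z1, z2, method)
  }
  if (method == "fixed-fraction") return(fixed("fixed-fraction"))

  ext <- range(which(area > 0))
  win <- seq(ext[1], ext[2])
  aw <- area[win]
  ne <- length(win)
  band <- seq(max(1L, floor(ne * 0.25)), min(ne, ceiling(ne * 0.75)))
  zmin <- band[which.min(aw[band])]
  a_min <- aw[zmin]
  a_end <- mean(c(max(aw[seq_len(zmin)]), max(aw[seq(zmin, ne)])))
  if (a_end <= a_min) {
    warning("flat area profile: falling back to fixed-fraction delineation")
    return(fixed("fixed-fraction (fallback)"))
  }
  thr <- a_min + beta * (a_end - a_min)
  lo <- zmin
  while (lo > 1L && aw[lo - 1L] <= thr) lo <- lo - 1L
  hi <- zmin
  while (hi < ne && aw[hi + 1L] <= thr) hi <- hi + 1L
  if (lo == 1L || hi == ne) {
    warning("area-profile run touches the bone ends: falling back to fixed-fraction delineation")
    return(fixed("fixed-fraction (fallback)"))
  }
  make_partition(win[lo] - 1L, win[hi], "area-profile")
}

#' @export
print.region_partition <- function(x, ...) {
  n <- table(x$region)
  cat(sprintf("region_partition (%s) | proximal_EM %d | diaphysis %d | distal_EM %d slices (cuts %d, %d)\n",
              x$method, n[1], n[2], n[3], x$cuts[1], x$cuts[2]))
  invisible(x)
}
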