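## Voxel-counting morphometry and median attenuation coefficients.

REGION_LEVELS <- c("whole", "proximal_EM", "diaphysis", "distal_EM")
MORPHO_PARAMS <- c("TV", "BV", "Ct.BV", "Tb.BV", "BV.TV",
                   "mu_B", "mu_Ct", "mu_Tb")

# shared worker: records for whole sample + the three regions given the
# logical class grids and the two axial cuts
.morphometry_table <- function(grid, cortical, trabecular, envelope, cuts,
                               voxel_size_mm, sample_id, day) {
  nz <- dim(grid)[1]
  vv <- voxel_size_mm^3
  slabs <- list(whole = seq_len(nz),
                proximal_EM = seq_len(cuts[1]),
                diaphysis = seq(cuts[1] + 1L, cuts[2]),
                distal_EM = seq(cuts[2] + 1L, nz))
  rows <- lapply(names(slabs), function(rg) {
    zi <- slabs[[rg]]
    g <- grid[zi, , , drop = FALSE]
    ct <- cortical[zi, , , drop = FALSE]
    tb <- trabecular[zi, , , drop = FALSE]
    env <- envelope[zi, , , drop = FALSE]
    n_env <- sum(env); n_ct <- sum(ct); n_tb <- sum(tb)
    tv <- n_env * vv
    bv <- (n_ct + n_tb) * vv
    data.frame(
      sample_id = sample_id, day = day, region = rg,
      TV = tv, BV = bv, Ct.BV = n_ct * vv, Tb.BV = n_tb * vv,
      BV.TV = if (n_env > 0) bone_volume_fraction(bv, tv) else NA_real_,
      mu_B = if (n_ct + n_tb > 0) median(g[ct | tb]) else NA_real_,
      mu_Ct = if (n_ct > 0) median(g[ct]) else NA_real_,
      mu_Tb = if (n_tb > 0) median(g[tb]) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$region <- factor(out$region, levels = REGION_LEVELS)
  rownames(out) <- NULL
  out
}

#' Compute morphometric parameters per region
#'
#' For the whole sample and each anatomical region: total volume TV
#' (envelope voxels x voxel volume, mm^3), bone volume BV (cortical +
#' trabecular), cortical and trabecular volumes Ct.BV / Tb.BV, bone volume
#' fraction BV/TV (%), and the linear attenuation coefficients mu_B, mu_Ct,
#' mu_Tb computed as the median attenuation over the voxels of the
#' respective class (mm^-1). A class with no voxels in a region has zero
#' volume and an absent (NA) median.
#'
#' @param volume a [ct_volume()].
#' @param labels a `bone_label_map` from [separate_compartments()].
#' @param partition a `region_partition` from [delineate_regions()].
#' @return A data frame of morphometry records (one row per region plus the
#'   whole sample) with columns `sample_id`, `day`, `region`, `TV`, `BV`,
#'   `Ct.BV`, `Tb.BV`, `BV.TV`, `mu_B`, `mu_Ct`, `mu_Tb`.
#' @seealso [apply_trabecular_exclusion()] for suppressing trabecular values
#'   in regions with negligible trabecular content.
#' @export
compute_morphometry <- function(volume, labels, partition) {
  stopifnot(is_ct_volume(volume), inherits(labels, "bone_label_map"),
            inherits(partition, "region_partition"))
  if (!identical(dim(volume$grid), dim(labels$labels)))
    stop("volume and label map have mismatched dimensions", call. = FALSE)
  if (length(partition$region) != dim(volume$grid)[1])
    stop("partition does not match the volume's axial extent", call. = FALSE)
  .morphometry_table(
    grid = volume$grid,
    cortical = labels$labels == 1L,
    trabecular = labels$labels == 2L,
    envelope = labels$envelope,
    cuts = partition$cuts,
    voxel_size_mm = volume$voxel_size_mm,
    sample_id = volume$sample_id, day = volume$day)
}

#' Bone volume fraction
#'
#' `100 * BV / TV`, in percent. Vectorized.
#'
#' @param BV bone volume (mm^3), with `0 <= BV <= TV`.
#' @param TV total volume (mm^3), strictly positive.
#' @return Bone volume fraction in percent.
#' @export
#' @examples
#' bone_volume_fraction(0.01076, 0.01365)  # 78.8% to one decimal
bone_volume_fraction <- function(BV, TV) {
  if (any(!is.finite(TV)) || any(TV <= 0))
    stop("TV must be positive", call. = FALSE)
  if (any(BV < 0) || any(BV > TV + 1e-12 * pmax(TV, 1)))
    stop("BV must satisfy 0 <= BV <= TV", call. = FALSE)
  100 * BV / TV
}

#' Suppress trabecular values in trabecula-poor regions
#'
#' Marks `Tb.BV` and `mu_Tb` as absent (NA) in every region whose trabecular
#' volume is below `threshold_fraction` of the whole-sample trabecular
#' volume — typically the diaphysis, where the few residual trabeculae
#' (about 1-2% of the total trabecular volume) do not support a meaningful
#' estimate. All other fields are untouched; `threshold_fraction = 0`
#' disables the rule.
#'
#' @param records morphometry record data frame (see
#'   [compute_morphometry()]), possibly spanning several samples and days.
#' @param threshold_fraction exclusion threshold as a fraction of the
#'   whole-sample trabecular volume (default 0.02).
#' @return The records with trabecular fields suppressed where applicable.
#' @export
apply_trabecular_exclusion <- function(records, threshold_fraction = 0.02) {
  stopifnot(is.data.frame(records))
  if (threshold_fraction <= 0) return(records)
  key <- interaction(records$sample_id, records$day, drop = TRUE)
  for (g in levels(key)) {
    rows <- which(key == g)
    whole <- rows[records$region[rows] == "whole"]
    if (length(whole) != 1L) next
    total_tb <- records$Tb.BV[whole]
    if (!is.finite(total_tb) || total_tb <= 0) next
    for (r in rows[records$region[rows] != "whole"]) {
      tb <- records$Tb.BV[r]
      if (is.finite(tb) && tb / total_tb < threshold_fraction) {
        records$Tb.BV[r] <- NA_real_
        records$mu_Tb[r] <- NA_real_
      }
    }
  }
  records
}
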