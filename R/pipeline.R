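#' Analyze a longitudinal scan series
#'
#' The full morphometry pipeline applied to a series of scans of one sample:
#' a common Otsu threshold is derived from the pooled histogram of all
#' scans, then every scan is independently binarized and cleaned, its
#' envelope built, compartments separated, regions delineated and
#' morphometry computed; finally the trabecular exclusion rule is applied.
#' Envelope and region cuts are re-derived per scan (total volume changes
#' over time, so the region of interest must be re-measured, not reused).
#'
#' @param volumes non-empty list of [ct_volume()] of one sample, ordered by
#'   day.
#' @param n_bins histogram bins for the threshold (default 256).
#' @param threshold_mode `"pooled"` (default) or `"first"`, see
#'   [common_threshold()].
#' @param min_component_vox speckle-removal size for
#'   [binarize_and_clean()].
#' @param close_radius_vox envelope closing radius, see [build_envelope()].
#' @param open_radius_vox compartment opening radius, see
#'   [separate_compartments()].
#' @param region_method,beta,fractions region delineation controls, see
#'   [delineate_regions()].
#' @param exclusion_fraction trabecular exclusion threshold, see
#'   [apply_trabecular_exclusion()].
#' @return Morphometry record data frame over all days and regions, with the
#'   common threshold in attribute `threshold`.
#' @export
#' @examples
#' \donttest{
#' sp <- phantom_spec(length_vox = 60, outer_radius_vox = 16,
#'                    cortical_thickness_vox = 10, trabecular_fill_fraction = 0.15,
#'                    rod_half_length_vox = c(4, 7), noise_sigma = 0)
#' sim <- simulate_fixation_series(sp, formalin_model(), days = c(0, 1565))
#' rec <- analyze_series(sim$volumes)
#' endpoint_differences(rec)
#' }
analyze_series <- function(volumes, n_bins = 256L,
                           threshold_mode = c("pooled", "first"),
                           min_component_vox = 27L,
                           close_radius_vox = 4,
                           open_radius_vox = 4,
                           region_method = c("area-profile", "fixed-fraction"),
                           beta = 0.5, fractions = c(0.40, 0.86),
                           exclusion_fraction = 0.02) {
  region_method <- match.arg(region_method)
  thr <- common_threshold(volumes, n_bins = n_bins,
                          mode = match.arg(threshold_mode))
  records <- do.call(rbind, lapply(volumes, function(v)
    analyze_volume(v, thr, min_component_vox = min_component_vox,
                   close_radius_vox = close_radius_vox,
                   open_radius_vox = open_radius_vox,
                   region_method = region_method, beta = beta,
                   fractions = fractions, provenance = "common")))
  records <- apply_trabecular_exclusion(records, exclusion_fraction)
  attr(records, "threshold") <- thr
  records
}

#' @rdname analyze_series
#' @param volume a single [ct_volume()].
#' @param threshold attenuation threshold in mm^-1 (for a series, derive it
#'   once with [common_threshold()]).
#' @param provenance threshold provenance recorded on the mask.
#' @export
analyze_volume <- function(volume, threshold, min_component_vox = 27L,
                           close_radius_vox = 4, open_radius_vox = 4,
                           region_method = c("area-profile", "fixed-fraction"),
                           beta = 0.5, fractions = c(0.40, 0.86),
                           provenance = "single") {
  region_method <- match.arg(region_method)
  mask <- binarize_and_clean(volume, threshold,
                             min_component_vox = min_component_vox,
                             provenance = provenance)
  env <- build_envelope(mask, close_radius_vox = close_radius_vox)
  labels <- separate_compartments(mask, env,
                                  open_radius_vox = open_radius_vox)
  partition <- delineate_regions(env, method = region_method, beta = beta,
                                 fractions = fractions)
  compute_morphometry(volume, labels, partition)
}
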