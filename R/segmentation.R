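#' Attenuation histogram
#'
#' Equal-width histogram of attenuation values, the input to Otsu
#' thresholding. The binning range defaults to the data range; when a series
#' of scans is to share one threshold, pass the series-wide range so that
#' per-scan histograms can be pooled bin by bin.
#'
#' @param x a [ct_volume()] or a numeric vector of attenuation values.
#' @param n_bins number of bins (default 256).
#' @param range length-2 numeric giving the binning range; defaults to
#'   `range(x)`.
#' @return An object of class `mu_histogram` with elements `bin_edges`
#'   (length `n_bins + 1`, mm^-1), `counts` and `n_bins`.
#' @export
attenuation_histogram <- function(x, n_bins = 256L, range = NULL) {
  vals <- if (is_ct_volume(x)) x$grid else x
  if (!is.numeric(vals) || length(vals) == 0L)
    stop("no values to histogram", call. = FALSE)
  if (is.null(range)) range <- base::range(vals)
  if (!(length(range) == 2L && range[2] > range[1]))
    stop("degenerate histogram: constant data have no Otsu threshold",
         call. = FALSE)
  edges <- seq(range[1], range[2], length.out = n_bins + 1L)
  idx <- findInterval(vals, edges, rightmost.closed = TRUE, all.inside = TRUE)
  structure(list(bin_edges = edges,
                 counts = tabulate(idx, nbins = n_bins),
                 n_bins = as.integer(n_bins)),
            class = "mu_histogram")
}

#' Pool histograms across a scan series
#'
#' Sums per-scan histograms computed on shared bin edges spanning the
#' series-wide value range; equivalent to histogramming the concatenated
#' voxel populations of all scans.
#'
#' @param series non-empty list of [ct_volume()].
#' @param n_bins number of bins.
#' @return A `mu_histogram`.
#' @export
pooled_histogram <- function(series, n_bins = 256L) {
  if (!is.list(series) || length(series) == 0L)
    stop("series must be a non-empty list of volumes", call. = FALSE)
  if (!all(vapply(series, is_ct_volume, logical(1))))
    stop("series must contain ct_volume objects", call. = FALSE)
  vs <- vapply(series, function(v) v$voxel_size_mm, numeric(1))
  if (max(vs) - min(vs) > 1e-12)
    stop("inconsistent metadata: scans in a series must share one voxel size",
         call. = FALSE)
  rng <- c(min(vapply(series, function(v) min(v$grid), numeric(1))),
           max(vapply(series, function(v) max(v$grid), numeric(1))))
  hists <- lapply(series, attenuation_histogram, n_bins = n_bins, range = rng)
  structure(list(bin_edges = hists[[1]]$bin_edges,
                 counts = Reduce(`+`, lapply(hists, `[[`, "counts")),
                 n_bins = as.integer(n_bins)),
            class = "mu_histogram")
}

#' Otsu threshold
#'
#' Threshold maximizing the between-class variance of the two classes the
#' threshold induces on the histogram. The returned value is the bin edge
#' separating the optimal background bins from the foreground bins; ties are
#' broken toward the lower threshold. Applied as `value >= threshold`.
#'
#' @param x a `mu_histogram`, a [ct_volume()] or a numeric vector (the
#'   latter two are histogrammed first).
#' @param ... passed to [attenuation_histogram()] for non-histogram input.
#' @return The threshold in mm^-1.
#' @export
#' @examples
#' h <- attenuation_histogram(c(rnorm(500, 0.1, 0.02), rnorm(500, 1.2, 0.05)))
#' otsu_threshold(h)
otsu_threshold <- function(x, ...) UseMethod("otsu_threshold")

#' @export
otsu_threshold.default <- function(x, ...) {
  otsu_threshold(attenuation_histogram(x, ...))
}

#' @export
otsu_threshold.ct_volume <- function(x, ...) {
  otsu_threshold(attenuation_histogram(x, ...))
}

#' @export
otsu_threshold.mu_histogram <- function(x, ...) {
  counts <- as.numeric(x$counts)
  if (sum(counts > 0) < 2L)
    stop("degenerate histogram: need at least two non-empty bins",
         call. = FALSE)
  centers <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  p <- counts / sum(counts)
  w0 <- cumsum(p)                 # class-0 mass for split after bin k
  m0 <- cumsum(p * centers)       # unnormalized class-0 mean
  mt <- m0[length(m0)]
  k <- seq_len(x$n_bins - 1L)
  valid <- w0[k] > 0 & w0[k] < 1
  # between-class variance: w0*w1*(mu0 - mu1)^2 = (mt*w0 - m0)^2 / (w0*w1)
  sb2 <- rep(-Inf, length(k))
  sb2[valid] <- (mt * w0[k][valid] - m0[k][valid])^2 /
    (w0[k][valid] * (1 - w0[k][valid]))
  k_opt <- which.max(sb2)         # which.max takes the first (lowest) tie
  x$bin_edges[k_opt + 1L]
}

#' Common threshold for a longitudinal series
#'
#' Otsu threshold of the pooled histogram over all scans of a series, so
#' that every time point is binarized identically and longitudinal volume
#' changes are interpretable. Alternatively (`mode = "first"`) the threshold
#' can be derived from the baseline scan only.
#'
#' @param series non-empty list of [ct_volume()] on a shared value scale.
#' @param n_bins number of histogram bins.
#' @param mode `"pooled"` (default) or `"first"`.
#' @return The common threshold in mm^-1.
#' @export
common_threshold <- function(series, n_bins = 256L,
                             mode = c("pooled", "first")) {
  mode <- match.arg(mode)
  if (!is.list(series) || length(series) == 0L)
    stop("series must be a non-empty list of volumes", call. = FALSE)
  if (mode == "first")
    return(otsu_threshold(attenuation_histogram(series[[1]], n_bins = n_bins)))
  otsu_threshold(pooled_histogram(series, n_bins = n_bins))
}

#' Binarize a volume and remove speckle
#'
#' Thresholds the volume at `value >= threshold` and removes 26-connected
#' components smaller than `min_component_vox` voxels. A threshold outside
#' the volume's value range yields an all-empty or all-full mask with a
#' warning (not an error).
#'
#' @param volume a [ct_volume()].
#' @param threshold attenuation threshold in mm^-1.
#' @param min_component_vox minimum component size kept (default 27, a 3x3x3
#'   speckle); 1 disables cleanup.
#' @param provenance how the threshold was obtained (`"single"` or
#'   `"common"`), stored for reporting.
#' @return An object of class `bone_mask`: list with `mask` (3D logical),
#'   `threshold` and `provenance`.
#' @export
binarize_and_clean <- function(volume, threshold, min_component_vox = 27L,
                               provenance = "single") {
  stopifnot(is_ct_volume(volume))
  rng <- range(volume$grid)
  if (threshold <= rng[1])
    warning("threshold at or below the volume minimum: mask is all-full")
  if (threshold > rng[2])
    warning("threshold above the volume maximum: mask is all-empty")
  mask <- array(volume$grid >= threshold, dim(volume$grid))
  if (min_component_vox > 1L && any(mask)) {
    lab <- label_components(mask, 26L)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_component_vox)
    mask <- array(lab %in% keep, dim(mask))
  }
  structure(list(mask = mask, threshold = threshold,
                 provenance = provenance),
            class = "bone_mask")
}

#' @export
print.bone_mask <- function(x, ...) {
  cat(sprintf("bone_mask | %s voxels in mask | threshold %.4g mm^-1 (%s)\n",
              format(sum(x$mask), big.mark = ","), x$threshold,
              x$provenance))
  invisible(x)
}
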