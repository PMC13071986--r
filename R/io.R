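## Volume, manifest and report I/O.
##
## Volumes travel as NIfTI files (lossless, double precision) or multi-page
## 32-bit float TIFF stacks; both carry a JSON sidecar recording the voxel
## size (mm), acquisition day, sample id and value units (mm^-1). TIFF
## samples are stored normalized to [0, 1] with the scale factor in the
## sidecar (the format's float path clamps values outside that range), so
## TIFF round trips are exact to single precision while NIfTI round trips
## are bitwise. The first array axis is the bone's axial direction; TIFF
## pages are axial slices.

.sidecar_path <- function(path) paste0(path, ".json")

.write_sidecar <- function(volume, path, extra = list()) {
  meta <- c(list(voxel_size_mm = volume$voxel_size_mm,
                 day = volume$day,
                 sample_id = volume$sample_id,
                 units = list(values = "mm^-1", voxel_size = "mm",
                              day = "days since baseline")),
            extra)
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
}

.read_sidecar <- function(path, sidecar = NULL) {
  sc <- if (is.null(sidecar)) .sidecar_path(path) else sidecar
  if (is.character(sc) && file.exists(sc))
    return(jsonlite::read_json(sc, simplifyVector = TRUE))
  if (is.list(sc)) return(sc)
  NULL
}

#' Write a volume to disk
#'
#' Writes the attenuation grid as either a NIfTI volume (`.nii` / `.nii.gz`,
#' double precision, voxel size in the header) or a multi-page 32-bit float
#' TIFF stack (`.tif` / `.tiff`, one page per axial slice), plus a JSON
#' sidecar `<path>.json` holding voxel size, day, sample id and units.
#'
#' @param volume a [ct_volume()].
#' @param path output path; the extension selects the format.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(volume, path) {
  stopifnot(is_ct_volume(volume))
  ext <- tolower(sub("^.*?((\\.nii)?\\.[a-z]+)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    grid <- volume$grid
    attr(grid, "pixdim") <- rep(volume$voxel_size_mm, 3)
    img <- RNifti::asNifti(grid, datatype = "double")
    RNifti::writeNifti(img, path)
    .write_sidecar(volume, path, list(format = "nifti"))
  } else if (ext %in% c(".tif", ".tiff")) {
    top <- max(volume$grid)
    scale <- if (top > 0) top else 1
    pages <- lapply(seq_len(dim(volume$grid)[1]),
                    function(z) volume$grid[z, , ] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    .write_sidecar(volume, path, list(format = "tiff", value_scale = scale))
  } else {
    stop(sprintf("unsupported volume format '%s' (use .nii, .nii.gz, .tif or .tiff)",
                 ext), call. = FALSE)
  }
  invisible(path)
}

#' Read a volume from disk
#'
#' Reads a NIfTI volume or a multi-page TIFF stack written by
#' [write_volume()] (or by other tools, given a sidecar with the voxel
#' size). The voxel size is taken from the sidecar when present, otherwise —
#' for NIfTI — from the header; anisotropic voxels are rejected. TIFF input
#' must be a stack of at least two grayscale pages.
#'
#' @param path input path.
#' @param sidecar optional sidecar: a path to a JSON file or a named list
#'   with at least `voxel_size_mm`; defaults to `<path>.json` when present.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  meta <- .read_sidecar(path, sidecar)
  ext <- tolower(sub("^.*?((\\.nii)?\\.[a-z]+)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::readNifti(path)
    grid <- as.array(img)
    if (length(dim(grid)) != 3L)
      stop("format error: expected a 3D volume", call. = FALSE)
    vs <- meta$voxel_size_mm
    if (is.null(vs)) {
      pd <- RNifti::pixdim(img)
      if (max(pd) - min(pd) > 1e-9)
        stop("anisotropic voxels are not supported", call. = FALSE)
      vs <- pd[1]
    }
    attributes(grid) <- list(dim = dim(grid))
  } else if (ext %in% c(".tif", ".tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2L)
      stop("format error: a single 2D image is not a volume (need a stack)",
           call. = FALSE)
    if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
      stop("format error: TIFF pages must be single-channel grayscale",
           call. = FALSE)
    grid <- aperm(simplify2array(pages), c(3, 1, 2))
    if (is.null(meta$voxel_size_mm))
      stop("metadata error: TIFF input needs a sidecar with voxel_size_mm",
           call. = FALSE)
    vs <- meta$voxel_size_mm
    if (!is.null(meta$value_scale)) grid <- grid * meta$value_scale
  } else {
    stop(sprintf("unsupported volume format '%s'", ext), call. = FALSE)
  }
  ct_volume(grid, voxel_size_mm = vs,
            day = if (is.null(meta$day)) 0 else meta$day,
            sample_id = if (is.null(meta$sample_id)) basename(path)
                        else meta$sample_id)
}

#' Series manifest
#'
#' A YAML manifest maps acquisition days to volume files for one sample:
#' fields `sample_id`, `fixative` (free text, e.g. "10% formalin") and
#' `scans`, a list of `{day, path}` entries with strictly increasing days
#' starting at the day-0 baseline.
#'
#' @param manifest list with `sample_id`, `fixative` and a data frame or
#'   list `scans` (columns/fields `day`, `path`).
#' @param path YAML file path.
#' @return `write_series_manifest()`: invisibly, `path`;
#'   `read_series_manifest()`: the validated manifest as a list with a
#'   data-frame `scans`.
#' @export
write_series_manifest <- function(manifest, path) {
  manifest <- .validate_manifest(manifest)
  scans <- lapply(seq_len(nrow(manifest$scans)), function(i)
    list(day = manifest$scans$day[i], path = manifest$scans$path[i]))
  yaml::write_yaml(list(sample_id = manifest$sample_id,
                        fixative = manifest$fixative, scans = scans), path)
  invisible(path)
}

#' @rdname write_series_manifest
#' @export
read_series_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  m <- yaml::read_yaml(path)
  m$scans <- data.frame(day = vapply(m$scans, function(s) as.numeric(s$day),
                                     numeric(1)),
                        path = vapply(m$scans, function(s) as.character(s$path),
                                      character(1)),
                        stringsAsFactors = FALSE)
  .validate_manifest(m)
}

.validate_manifest <- function(m) {
  if (is.null(m$sample_id) || is.null(m$scans))
    stop("manifest needs sample_id and scans", call. = FALSE)
  scans <- as.data.frame(m$scans)
  if (nrow(scans) == 0L) stop("manifest has no scans", call. = FALSE)
  if (scans$day[1] != 0)
    stop("first manifest entry must be the day-0 baseline", call. = FALSE)
  if (any(diff(scans$day) <= 0))
    stop("manifest days must be strictly increasing", call. = FALSE)
  m$scans <- scans
  if (is.null(m$fixative)) m$fixative <- ""
  m
}

#' @rdname write_series_manifest
#' @param base_dir directory against which relative scan paths are resolved;
#'   defaults to the manifest's directory when reading from file.
#' @return `read_series()`: list of [ct_volume()] in manifest order, with
#'   day and sample id taken from the manifest.
#' @export
read_series <- function(path, base_dir = dirname(path)) {
  m <- read_series_manifest(path)
  lapply(seq_len(nrow(m$scans)), function(i) {
    p <- m$scans$path[i]
    if (!file.exists(p)) p <- file.path(base_dir, p)
    v <- read_volume(p)
    v$day <- m$scans$day[i]
    v$sample_id <- m$sample_id
    v
  })
}

#' Write / read a morphometry report
#'
#' CSV with one row per (sample, day, region) and the columns `TV`, `BV`,
#' `Ct.BV`, `Tb.BV`, `BV/TV`, `mu_B`, `mu_Ct`, `mu_Tb`. Absent values
#' (excluded trabecular entries) are written as empty fields, not zeros. A
#' leading comment line states the units.
#'
#' @param records morphometry record data frame (see
#'   [compute_morphometry()]); must be non-empty.
#' @param path CSV file path.
#' @return `write_report()`: invisibly, `path`; `read_report()`: the record
#'   data frame.
#' @export
write_report <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("no records to write", call. = FALSE)
  out <- records
  names(out)[names(out) == "BV.TV"] <- "BV/TV"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# units: TV, BV, Ct.BV, Tb.BV in mm^3;",
                   "BV/TV in percent; mu_B, mu_Ct, mu_Tb in mm^-1;",
                   "day in days since baseline"), con)
  write.csv(out, con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- read.csv(path, comment.char = "#", check.names = FALSE,
                 stringsAsFactors = FALSE)
  names(df)[names(df) == "BV/TV"] <- "BV.TV"
  if ("region" %in% names(df))
    df$region <- factor(df$region, levels = REGION_LEVELS)
  df
}

#' @rdname write_report
#' @param tbl an `endpoint_table` from [endpoint_differences()].
#' @details `write_endpoint_table()` writes the formatted first/last/percent
#'   difference table with `"-"` for absent cells.
#' @export
write_endpoint_table <- function(tbl, path) {
  fmt <- format_endpoint_table(tbl)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# units: volumes in mm^3, attenuation in mm^-1,",
                   "difference in percent"), con)
  write.csv(fmt, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_volume
#' @param label_map integer label array (e.g. a phantom's ground-truth
#'   labels or a `bone_label_map$labels`), written as a NIfTI volume of
#'   integer codes next to which the same JSON sidecar conventions apply.
#' @param voxel_size_mm,day,sample_id metadata for the label volume.
#' @export
write_label_map <- function(label_map, path, voxel_size_mm, day = 0,
                            sample_id = "labels") {
  stopifnot(is.array(label_map), length(dim(label_map)) == 3L)
  vol <- ct_volume(array(as.numeric(label_map), dim(label_map)),
                   voxel_size_mm, day, sample_id)
  write_volume(vol, path)
}
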