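## Baseline-relative change curves and endpoint difference tables.

#' Percent change relative to a baseline value
#'
#' `100 * (value - baseline) / baseline`. The elementary operation behind
#' every change curve and difference column; vectorized. Absent values (NA)
#' propagate as absent.
#'
#' @param value current value(s).
#' @param baseline baseline value(s); must be nonzero.
#' @return Percent change.
#' @export
#' @examples
#' percent_change(50.75, 51.10)   # -0.68% to two decimals
percent_change <- function(value, baseline) {
  if (any(baseline == 0, na.rm = TRUE))
    stop("zero baseline: percent change is undefined", call. = FALSE)
  100 * (value - baseline) / baseline
}

#' Baseline-relative change curve of one parameter
#'
#' Computes, for one sample, region and morphometric parameter, the percent
#' difference of each acquisition day relative to day 0:
#' `delta(day) = 100 * (x(day) - x(0)) / x(0)`. The baseline point of the
#' curve is exactly 0. A parameter that is absent at baseline (e.g. excluded
#' trabecular values) yields an all-absent curve rather than zeros.
#'
#' @param records morphometry record data frame for one sample (several days).
#' @param region one of `"whole"`, `"proximal_EM"`, `"diaphysis"`,
#'   `"distal_EM"`.
#' @param parameter one of `TV`, `BV`, `Ct.BV`, `Tb.BV`, `BV.TV`, `mu_B`,
#'   `mu_Ct`, `mu_Tb`.
#' @return A data frame with columns `sample_id`, `region`, `parameter`,
#'   `day`, `value` and `delta_percent`, ordered by day.
#' @export
relative_change <- function(records, region, parameter) {
  stopifnot(is.data.frame(records), parameter %in% MORPHO_PARAMS)
  rows <- records[records$region == region, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop(sprintf("no records for region '%s'", region), call. = FALSE)
  if (length(unique(rows$sample_id)) > 1L)
    stop("relative_change expects records of a single sample", call. = FALSE)
  rows <- rows[order(rows$day), , drop = FALSE]
  if (rows$day[1] != 0)
    stop("missing baseline: first record must be day 0", call. = FALSE)
  x <- rows[[parameter]]
  x0 <- x[1]
  if (is.na(x0)) {
    delta <- rep(NA_real_, length(x))
  } else {
    if (x0 == 0)
      stop("zero baseline: relative change is undefined", call. = FALSE)
    delta <- percent_change(x, x0)
    delta[1] <- 0
  }
  data.frame(sample_id = rows$sample_id, region = region,
             parameter = parameter, day = rows$day, value = x,
             delta_percent = delta, stringsAsFactors = FALSE)
}

#' All change curves of a sample
#'
#' [relative_change()] applied to every region present in the records and
#' every requested parameter, stacked into one long data frame.
#'
#' @param records morphometry record data frame for one sample.
#' @param parameters parameters to include.
#' @return Long data frame of change curves.
#' @export
change_curves <- function(records,
                          parameters = c("TV", "BV", "Ct.BV", "Tb.BV",
                                         "mu_B", "mu_Ct", "mu_Tb")) {
  regions <- intersect(REGION_LEVELS, unique(as.character(records$region)))
  out <- do.call(rbind, lapply(regions, function(rg)
    do.call(rbind, lapply(parameters, function(p)
      relative_change(records, rg, p)))))
  rownames(out) <- NULL
  out
}

#' First/last endpoint difference table
#'
#' One row per region and parameter with the first-day value, the last-day
#' value and the percent difference `100 * (last - first) / first`. A
#' parameter absent at either endpoint has an absent difference.
#'
#' @param records morphometry record data frame for one sample with at least
#'   two acquisition days.
#' @param parameters parameters to include.
#' @return A data frame of class `endpoint_table` with columns `region`,
#'   `parameter`, `first`, `last`, `difference_percent`.
#' @export
endpoint_differences <- function(records,
                                 parameters = c("TV", "BV", "Ct.BV", "Tb.BV",
                                                "mu_B", "mu_Ct", "mu_Tb")) {
  stopifnot(is.data.frame(records))
  days <- sort(unique(records$day))
  if (length(days) < 2L)
    stop("endpoint differences need at least two time points", call. = FALSE)
  regions <- intersect(REGION_LEVELS, unique(as.character(records$region)))
  rows <- lapply(regions, function(rg) {
    first_row <- records[records$region == rg & records$day == days[1], ]
    last_row <- records[records$region == rg & records$day == days[length(days)], ]
    do.call(rbind, lapply(parameters, function(p) {
      f <- first_row[[p]][1]
      l <- last_row[[p]][1]
      d <- if (is.na(f) || is.na(l) || f == 0) NA_real_ else percent_change(l, f)
      data.frame(region = rg, parameter = p, first = f, last = l,
                 difference_percent = d, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("endpoint_table", class(out))
  out
}

#' Experimental spread of a control series
#'
#' The maximum absolute baseline-relative change over all curves of a series
#' — used as an empirical measurement-error band: a fixative effect is only
#' meaningful where it exceeds the spread of the stable (control) series.
#'
#' @param curves long curve data frame from [change_curves()].
#' @return Maximum absolute `delta_percent` (percentage points), ignoring
#'   absent values.
#' @export
experimental_spread <- function(curves) {
  stopifnot(is.data.frame(curves), "delta_percent" %in% names(curves))
  d <- curves$delta_percent[curves$day > 0]
  if (all(is.na(d))) return(NA_real_)
  max(abs(d), na.rm = TRUE)
}

#' Render an endpoint table at report precision
#'
#' Formats an [endpoint_differences()] table the way morphometry endpoint
#' tables are printed: volumes to 2 decimals (mm^3), attenuation
#' coefficients to 3 decimals (mm^-1), differences to 2 decimals (%), and
#' absent cells as `"-"`.
#'
#' @param tbl an `endpoint_table`.
#' @return Data frame of character columns.
#' @export
format_endpoint_table <- function(tbl) {
  stopifnot(inherits(tbl, "endpoint_table"))
  fmt_val <- function(p, v) {
    digits <- ifelse(grepl("^mu", p), 3L, 2L)
    ifelse(is.na(v), "-", sprintf("%.*f", digits, v))
  }
  data.frame(region = as.character(tbl$region), parameter = tbl$parameter,
             first = fmt_val(tbl$parameter, tbl$first),
             last = fmt_val(tbl$parameter, tbl$last),
             difference_percent = ifelse(is.na(tbl$difference_percent), "-",
                                         sprintf("%.2f", tbl$difference_percent)),
             stringsAsFactors = FALSE)
}

#' Plot change curves
#'
#' One panel per parameter, one line per region, percent change against day.
#' A convenience viewer for simulated or measured series.
#'
#' @param curves long curve data frame from [change_curves()].
#' @param parameters parameters to plot (default: all present).
#' @return Invisibly, `curves`.
#' @export
plot_change_curves <- function(curves, parameters = unique(curves$parameter)) {
  stopifnot(is.data.frame(curves))
  parameters <- intersect(parameters, unique(curves$parameter))
  old <- par(mfrow = c(ceiling(length(parameters) / 2), min(2, length(parameters))),
             mar = c(4, 4, 2, 1))
  on.exit(par(old))
  for (p in parameters) {
    sub <- curves[curves$parameter == p & !is.na(curves$delta_percent), ]
    if (nrow(sub) == 0L) next
    regions <- unique(sub$region)
    cols <- hcl.colors(max(3, length(regions)), "Dark 3")
    plot(NA, xlim = range(sub$day), ylim = range(sub$delta_percent),
         xlab = "day", ylab = "change from baseline (%)", main = p)
    abline(h = 0, col = "grey70")
    for (i in seq_along(regions)) {
      s <- sub[sub$region == regions[i], ]
      lines(s$day[order(s$day)], s$delta_percent[order(s$day)],
            type = "b", col = cols[i], pch = 16)
    }
    legend("topleft", legend = regions, col = cols[seq_along(regions)],
           lty = 1, pch = 16, bty = "n", cex = 0.8)
  }
  invisible(curves)
}
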