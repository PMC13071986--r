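# shared fixtures: scaled-down phantoms (fast) and the published endpoint
# values used as arithmetic fixtures

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# dumbbell phantom small enough for per-test use but with the same
# proportions (shell thickness vs opening radius, gentle flare) as the
# full-size default
small_phantom_spec <- function(seed = 1, noise_sigma = 0,
                               trabecular_fill_fraction = 0.2, ...) {
  phantom_spec(length_vox = 80, outer_radius_vox = 20,
               cortical_thickness_vox = 10, flare_factor = 1.3,
               transition_fraction = 0.14,
               trabecular_fill_fraction = trabecular_fill_fraction,
               rod_half_length_vox = c(4, 8), noise_sigma = noise_sigma,
               seed = seed, ...)
}

# plain cortical tube: uniform outer radius, no trabeculae
tube_spec <- function(seed = 1, outer_radius_vox = 20,
                      cortical_thickness_vox = 8, length_vox = 60, ...) {
  phantom_spec(length_vox = length_vox, outer_radius_vox = outer_radius_vox,
               cortical_thickness_vox = cortical_thickness_vox,
               flare_factor = 1, trabecular_fill_fraction = 0,
               diaphysis_trabecular_fraction = 0, noise_sigma = 0,
               seed = seed, ...)
}

# Published gerbil-humerus endpoint table (first day, last day, printed
# percent difference) for both fixatives; `u` columns give the printed
# precision (one unit in the last place) of the endpoint values.
table2_endpoints <- function(fixative = c("ethanol", "formalin")) {
  fixative <- match.arg(fixative)
  p <- c("TV", "BV", "Ct.BV", "Tb.BV", "mu_B", "mu_Ct", "mu_Tb")
  rg <- function(region, first, last, diff, u) {
    data.frame(region = region, parameter = p, first = first, last = last,
               printed_diff = diff, u = u, stringsAsFactors = FALSE)
  }
  u_v2 <- c(rep(0.01, 4), rep(0.001, 3))          # volumes 2 dp, mu 3 dp
  u_v3 <- c(0.001, 0.001, 0.01, 0.01, rep(0.001, 3))  # distal: TV/BV at 3 dp
  if (fixative == "ethanol") {
    rbind(
      rg("whole",
         c(51.10, 28.96, 25.91, 3.05, 1.162, 1.196, 0.873),
         c(50.75, 28.67, 25.66, 3.01, 1.155, 1.191, 0.870),
         c(-0.68, -1.01, -0.96, -1.42, -0.55, -0.46, -0.31), u_v2),
      rg("proximal_EM",
         c(20.42, 7.54, 4.96, 2.57, 0.957, 1.011, 0.860),
         c(20.24, 7.42, 4.88, 2.54, 0.951, 1.002, 0.858),
         c(-0.88, -1.59, -1.71, -1.35, -0.56, -0.88, -0.20), u_v2),
      rg("diaphysis",
         c(23.71, 16.17, 16.11, NA, 1.288, 1.288, NA),
         c(23.54, 16.00, 15.93, NA, 1.291, 1.292, NA),
         c(-0.71, -1.08, -1.08, NA, 0.30, 0.30, NA), u_v2),
      rg("distal_EM",
         c(6.973, 5.250, 4.84, 0.41, 1.096, 1.106, 0.956),
         c(6.974, 5.252, 4.85, 0.40, 1.092, 1.102, 0.946),
         c(0.02, 0.03, -0.20, -1.91, -0.34, -0.37, -0.98), u_v3))
  } else {
    rbind(
      rg("whole",
         c(50.98, 29.21, 26.09, 3.12, 1.149, 1.186, 0.863),
         c(52.88, 31.11, 27.80, 3.31, 1.101, 1.131, 0.838),
         c(3.72, 6.51, 6.53, 6.31, -4.20, -4.60, -2.89), u_v2),
      rg("proximal_EM",
         c(20.19, 7.57, 4.94, 2.63, 0.949, 1.004, 0.852),
         c(20.59, 8.05, 5.26, 2.79, 0.908, 0.956, 0.824),
         c(2.00, 6.29, 6.31, 6.25, -4.25, -4.70, -3.29), u_v2),
      rg("diaphysis",
         c(23.95, 16.56, 16.50, NA, 1.287, 1.288, NA),
         c(25.02, 17.55, 17.49, NA, 1.220, 1.220, NA),
         c(4.48, 5.98, 6.01, NA, -5.25, -5.26, NA), u_v2),
      rg("distal_EM",
         c(6.84, 5.08, 4.65, 0.43, 1.067, 1.079, 0.928),
         c(7.26, 5.52, 5.05, 0.47, 1.030, 1.037, 0.930),
         c(6.11, 8.56, 8.63, 7.80, -3.48, -3.83, 0.29), u_v2))
  }
}

# the same table reshaped as a two-day morphometry record frame
table2_records <- function(fixative = c("ethanol", "formalin")) {
  tbl <- table2_endpoints(fixative)
  one_day <- function(day, col) {
    wide <- lapply(split(tbl, tbl$region), function(s) {
      row <- as.list(stats::setNames(s[[col]], s$parameter))
      c(list(sample_id = paste0("gerbil-", fixative), day = day,
             region = s$region[1]), row, list(BV.TV = NA_real_))
    })
    do.call(rbind, lapply(wide, as.data.frame))
  }
  out <- rbind(one_day(0, "first"), one_day(1565, "last"))
  out$region <- factor(out$region,
                       levels = c("whole", "proximal_EM", "diaphysis",
                                  "distal_EM"))
  rownames(out) <- NULL
  out
}
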