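## Synthetic long-bone phantom.
##
## The phantom is a parametric long bone on an isotropic voxel grid: a
## cortical shell whose outer radius flares from the diaphyseal shaft to the
## two epiphysis/metaphysis (EM) ends, a marrow cavity, and a trabecular
## lattice of randomly oriented rods restricted to the endosteal space of
## the EM zones (plus an optional small residual in the diaphysis, to
## exercise the trabecular exclusion rule). Geometry is kept in continuous
## "reference" coordinates so that a fixative-induced swelling can be
## applied as an exact sub-voxel radial scaling of the labels before
## attenuation assignment: ground-truth morphometry stays computable in
## closed form (all compartment volumes scale with the square of the radial
## scale factor).

TRUTH_BACKGROUND <- 0L
TRUTH_MARROW     <- 1L
TRUTH_CORTICAL   <- 2L
TRUTH_TRABECULAR <- 3L

#' Phantom specification
#'
#' Parameters of the synthetic long-bone phantom. Defaults emulate a small
#' rodent humerus imaged at 9 um isotropic voxels with monochromatic 17.5 keV
#' attenuation values: cortical bone near 1.29 mm^-1, trabecular bone near
#' 0.86 mm^-1, marrow/soft tissue near 0.12 mm^-1.
#'
#' @param length_vox axial extent of the grid in voxels.
#' @param proximal_fraction,diaphysis_fraction fractions of the axial extent
#'   occupied by the proximal EM zone and the diaphysis (the distal EM zone
#'   takes the remainder). Both in (0, 1) with sum < 1.
#' @param outer_radius_vox outer cortical radius of the diaphyseal shaft, in
#'   voxels.
#' @param cortical_thickness_vox cortical shell thickness in voxels; must be
#'   strictly between 0 and `outer_radius_vox`.
#' @param flare_factor ratio of the EM-zone outer radius to the shaft radius
#'   (>= 1); the transition follows a cosine taper.
#' @param transition_fraction axial width of each flare transition as a
#'   fraction of `length_vox`.
#' @param trabecular_fill_fraction target fraction of the EM endosteal space
#'   occupied by trabecular rods, in [0, 1).
#' @param diaphysis_trabecular_fraction target fraction of the total
#'   trabecular volume placed inside the diaphysis (small residual; default
#'   1%).
#' @param rod_radius_vox trabecular rod radius in voxels.
#' @param rod_half_length_vox range (min, max) of rod half-lengths in voxels.
#' @param mu_cortical,mu_trabecular,mu_marrow,mu_background attenuation
#'   values in mm^-1 assigned to the respective classes; all non-negative.
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param noise_sigma default additive Gaussian noise level in mm^-1 used by
#'   [simulate_fixation_series()].
#' @param seed integer seed controlling rod placement (and, offset per time
#'   point, the simulated noise).
#' @param width_vox in-plane grid width in voxels; `NULL` (default) chooses
#'   the smallest width that fits the flared bone with a safety margin for
#'   swelling.
#'
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' sp <- phantom_spec(length_vox = 40, outer_radius_vox = 10,
#'                    cortical_thickness_vox = 4, trabecular_fill_fraction = 0)
#' ph <- generate_bone_phantom(sp)
#' ph$volume
phantom_spec <- function(length_vox = 160L,
                         proximal_fraction = 0.40,
                         diaphysis_fraction = 0.46,
                         outer_radius_vox = 45,
                         cortical_thickness_vox = 12,
                         flare_factor = 1.35,
                         transition_fraction = 0.12,
                         trabecular_fill_fraction = 0.20,
                         diaphysis_trabecular_fraction = 0.01,
                         rod_radius_vox = 2,
                         rod_half_length_vox = c(6, 12),
                         mu_cortical = 1.288,
                         mu_trabecular = 0.86,
                         mu_marrow = 0.12,
                         mu_background = 0.0,
                         voxel_size_mm = 0.009,
                         noise_sigma = 0.05,
                         seed = 1L,
                         width_vox = NULL) {
  stopifnot(length_vox >= 8)
  if (!(diaphysis_fraction > 0 && diaphysis_fraction < 1))
    stop("diaphysis_fraction must be in (0, 1)", call. = FALSE)
  if (!(proximal_fraction > 0 && proximal_fraction + diaphysis_fraction < 1))
    stop("proximal_fraction and diaphysis_fraction must leave room for the distal EM zone",
         call. = FALSE)
  if (!(cortical_thickness_vox > 0 && cortical_thickness_vox < outer_radius_vox))
    stop("cortical_thickness_vox must satisfy 0 < t < outer_radius_vox",
         call. = FALSE)
  if (!(trabecular_fill_fraction >= 0 && trabecular_fill_fraction < 1))
    stop("trabecular_fill_fraction must be in [0, 1)", call. = FALSE)
  if (flare_factor < 1) stop("flare_factor must be >= 1", call. = FALSE)
  mus <- c(mu_cortical, mu_trabecular, mu_marrow, mu_background)
  if (any(mus < 0)) stop("attenuation values must be non-negative", call. = FALSE)
  if (voxel_size_mm <= 0) stop("voxel_size_mm must be positive", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be non-negative", call. = FALSE)

  r_flare <- outer_radius_vox * flare_factor
  if (is.null(width_vox)) {
    margin <- ceiling(r_flare * 0.1) + 2
    width_vox <- 2L * as.integer(ceiling(r_flare + margin)) + 1L
  } else if (r_flare + 1 >= width_vox / 2) {
    stop("phantom does not fit: flared outer radius reaches the grid half-width",
         call. = FALSE)
  }

  structure(list(
    length_vox = as.integer(length_vox),
    proximal_fraction = proximal_fraction,
    diaphysis_fraction = diaphysis_fraction,
    outer_radius_vox = outer_radius_vox,
    cortical_thickness_vox = cortical_thickness_vox,
    flare_factor = flare_factor,
    transition_fraction = transition_fraction,
    trabecular_fill_fraction = trabecular_fill_fraction,
    diaphysis_trabecular_fraction = diaphysis_trabecular_fraction,
    rod_radius_vox = rod_radius_vox,
    rod_half_length_vox = rod_half_length_vox,
    mu_cortical = mu_cortical, mu_trabecular = mu_trabecular,
    mu_marrow = mu_marrow, mu_background = mu_background,
    voxel_size_mm = voxel_size_mm, noise_sigma = noise_sigma,
    seed = as.integer(seed), width_vox = as.integer(width_vox)
  ), class = "phantom_spec")
}

# continuous geometry derived from a spec: outer/inner radius per slice and
# the ground-truth region boundaries (last slice of proximal EM, last slice
# of diaphysis)
.phantom_geometry <- function(spec) {
  L <- spec$length_vox
  b1 <- round(L * spec$proximal_fraction)
  b2 <- round(L * (spec$proximal_fraction + spec$diaphysis_fraction))
  r_sh <- spec$outer_radius_vox
  r_fl <- spec$outer_radius_vox * spec$flare_factor
  w <- max(2, round(L * spec$transition_fraction))
  hw <- w / 2
  z <- seq_len(L)
  taper <- function(z, b) {
    # cosine taper from r_fl (EM side of b1 / far side of b2) to r_sh
    u <- (z - (b - hw)) / w
    r_sh + (r_fl - r_sh) * (1 + cos(pi * pmin(pmax(u, 0), 1))) / 2
  }
  # taper(z, b1): r_fl before b1-hw, falling to r_sh at b1+hw;
  # taper(-z, -b2) is its mirror rising back to r_fl around b2. Their
  # pointwise maximum is the dumbbell profile (transitions do not overlap).
  r_out <- pmax(taper(z, b1), taper(-z, -b2))
  list(L = L, W = spec$width_vox,
       c_yx = (spec$width_vox + 1) / 2,
       r_out = r_out,
       r_in = pmax(r_out - spec$cortical_thickness_vox, 0),
       b1 = b1, b2 = b2, trans_halfwidth = hw)
}

# base labels (no rods) at radial scale s, using reference-coordinate radii
.rasterize_base <- function(geom, s = 1) {
  W <- geom$W; L <- geom$L
  ax <- (seq_len(W) - geom$c_yx) / s
  rho <- sqrt(outer(ax^2, ax^2, "+"))
  labels <- array(TRUTH_BACKGROUND, c(L, W, W))
  for (z in seq_len(L)) {
    lab <- integer(W * W)
    lab[rho <= geom$r_out[z]] <- TRUTH_CORTICAL
    lab[rho <= geom$r_in[z]] <- TRUTH_MARROW
    labels[z, , ] <- lab
  }
  labels
}

# stamp one trabecular rod into a label array (marrow voxels only),
# honouring its zone restriction; rods live in reference coordinates, the
# grid is sampled at radial scale s. Returns the updated labels and the
# number of voxels converted to trabecular.
.stamp_rod <- function(labels, geom, rod, s = 1) {
  W <- geom$W; L <- geom$L; cc <- geom$c_yx
  zc <- rod[["zc"]]; uy <- rod[["uy"]]; ux <- rod[["ux"]]
  dz <- rod[["dz"]]; dy <- rod[["dy"]]; dx <- rod[["dx"]]
  hl <- rod[["hl"]]; rad <- rod[["rad"]]; zone <- rod[["zone"]]
  zi <- max(1L, floor(zc - hl * abs(dz) - rad)):min(L, ceiling(zc + hl * abs(dz) + rad))
  yr <- cc + s * (uy + c(-1, 1) * (hl * abs(dy) + rad))
  xr <- cc + s * (ux + c(-1, 1) * (hl * abs(dx) + rad))
  yi <- max(1L, floor(yr[1])):min(W, ceiling(yr[2]))
  xi <- max(1L, floor(xr[1])):min(W, ceiling(xr[2]))
  nz <- length(zi); ny <- length(yi); nx <- length(xi)
  # reference coordinates of the bbox voxels, relative to the rod's start
  p0z <- zc - hl * dz; p0y <- uy - hl * dy; p0x <- ux - hl * dx
  vz <- array(zi - p0z, c(nz, ny, nx))
  vy <- array(rep((yi - cc) / s - p0y, each = nz), c(nz, ny, nx))
  vx <- array(rep((xi - cc) / s - p0x, each = nz * ny), c(nz, ny, nx))
  tp <- pmin(pmax(vz * dz + vy * dy + vx * dx, 0), 2 * hl)
  dist2 <- vz^2 + vy^2 + vx^2 - tp^2
  inside <- dist2 <= rad^2
  # trabeculae taper off short of the zone boundary so that a one-slice
  # delineation shift cannot move a full trabecular slice between regions
  mg <- 2L
  zok <- if (zone == 1) zi <= geom$b1 - mg | zi > geom$b2 + mg
         else zi > geom$b1 + mg & zi <= geom$b2 - mg
  inside <- inside & array(zok, c(nz, ny, nx))
  sub <- labels[zi, yi, xi, drop = FALSE]
  hit <- inside & sub == TRUTH_MARROW
  sub[hit] <- TRUTH_TRABECULAR
  labels[zi, yi, xi] <- sub
  list(labels = labels, gained = sum(hit))
}

.stamp_rods <- function(labels, geom, rods, s = 1) {
  if (is.null(rods) || nrow(rods) == 0L) return(labels)
  for (r in seq_len(nrow(rods)))
    labels <- .stamp_rod(labels, geom, rods[r, ], s)$labels
  labels
}

.rasterize_labels <- function(geom, rods, s = 1) {
  .stamp_rods(.rasterize_base(geom, s), geom, rods, s)
}

.grid_from_labels <- function(labels, spec, mu_ct_scale = 1, mu_tb_scale = 1) {
  grid <- array(spec$mu_background, dim(labels))
  grid[labels == TRUTH_MARROW] <- spec$mu_marrow
  grid[labels == TRUTH_CORTICAL] <- spec$mu_cortical * mu_ct_scale
  grid[labels == TRUTH_TRABECULAR] <- spec$mu_trabecular * mu_tb_scale
  grid
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# sample rods until the target trabecular voxel count is reached
.sample_rods <- function(labels, geom, spec) {
  rods <- matrix(numeric(0), ncol = 9,
                 dimnames = list(NULL, c("zc", "uy", "ux", "dz", "dy", "dx",
                                         "hl", "rad", "zone")))
  L <- geom$L
  em_z <- c(seq_len(geom$b1), seq(geom$b2 + 1L, L))
  em_z <- em_z[geom$r_in[em_z] > spec$rod_radius_vox + 1]
  marrow_em <- sum(vapply(em_z, function(z)
    sum(labels[z, , ] != TRUTH_BACKGROUND & labels[z, , ] != TRUTH_CORTICAL),
    numeric(1)))
  target_em <- floor(spec$trabecular_fill_fraction * marrow_em)

  add_rods <- function(labels, rods, z_pool, target, hl_range, zone) {
    count <- 0L
    iter <- 0L
    while (count < target && iter < 6000L) {
      iter <- iter + 1L
      z <- if (length(z_pool) == 1L) z_pool else sample(z_pool, 1L)
      ri <- geom$r_in[z]
      if (ri <= 1) next
      repeat {
        uy <- runif(1, -ri, ri); ux <- runif(1, -ri, ri)
        if (uy^2 + ux^2 <= max(ri - 1, 0.5)^2) break
      }
      d <- rnorm(3)
      d <- d / sqrt(sum(d^2))
      hl <- runif(1, hl_range[1], hl_range[2])
      rod <- c(zc = z, uy = uy, ux = ux, dz = d[1], dy = d[2], dx = d[3],
               hl = hl, rad = spec$rod_radius_vox, zone = zone)
      st <- .stamp_rod(labels, geom, rod)
      if (st$gained > 0L) {
        if (count > 0L && count + st$gained > target * 1.3) break
        labels <- st$labels
        rods <- rbind(rods, rod)
        count <- count + st$gained
      }
    }
    list(labels = labels, rods = rods, count = count)
  }

  if (target_em > 0 && length(em_z) > 0) {
    res <- add_rods(labels, rods, em_z, target_em,
                    spec$rod_half_length_vox, zone = 1)
    labels <- res$labels; rods <- res$rods
    tb_em <- res$count
  } else tb_em <- 0L

  if (spec$diaphysis_trabecular_fraction > 0 && tb_em > 0) {
    f <- spec$diaphysis_trabecular_fraction
    target_d <- round(f / (1 - f) * tb_em)
    dia_z <- seq(geom$b1 + 1L, geom$b2)
    if (target_d > 0 && length(dia_z) > 0) {
      res <- add_rods(labels, rods, dia_z, target_d,
                      pmax(spec$rod_half_length_vox / 2, 2), zone = 2)
      labels <- res$labels; rods <- res$rods
    }
  }
  list(labels = labels, rods = rods)
}

#' Generate a synthetic long-bone phantom
#'
#' Builds a noiseless attenuation volume and its voxel-exact ground truth
#' from a [phantom_spec()]. The result is deterministic for a given spec
#' (including its `seed`). Noise is added separately with [add_noise()].
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` (a [ct_volume()]) and `truth`
#'   (class `bone_ground_truth`): `label_map` (integer array, 0 background /
#'   1 marrow / 2 cortical / 3 trabecular), `region_boundaries` (last axial
#'   slice of the proximal EM zone and of the diaphysis),
#'   `true_morphometry` (a morphometry record table computed from the
#'   labels) and the continuous `geometry` used for re-rasterization.
#' @seealso [apply_fixation_model()], [simulate_fixation_series()]
#' @export
generate_bone_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- .phantom_geometry(spec)
  labels <- .rasterize_base(geom)
  res <- .with_seed(spec$seed, .sample_rods(labels, geom, spec))
  labels <- res$labels
  grid <- .grid_from_labels(labels, spec)
  vol <- ct_volume(grid, spec$voxel_size_mm, day = 0,
                   sample_id = sprintf("phantom-seed%d", spec$seed))
  truth <- structure(list(
    label_map = labels,
    region_boundaries = c(geom$b1, geom$b2),
    true_morphometry = .truth_morphometry(vol, labels, geom),
    geometry = list(spec = spec, geom = geom, rods = res$rods)
  ), class = "bone_ground_truth")
  list(volume = vol, truth = truth)
}

.truth_morphometry <- function(vol, labels, geom) {
  .morphometry_table(
    grid = vol$grid,
    cortical = labels == TRUTH_CORTICAL,
    trabecular = labels == TRUTH_TRABECULAR,
    envelope = labels != TRUTH_BACKGROUND,
    cuts = c(geom$b1, geom$b2),
    voxel_size_mm = vol$voxel_size_mm,
    sample_id = vol$sample_id, day = vol$day)
}

#' Parametric fixative drift model
#'
#' Describes how a fixative changes a bone over storage time: a signed
#' percent change of bone volume and of the cortical/trabecular attenuation
#' coefficients, each following a saturating-exponential time course
#' `delta(t) = delta_max * (1 - exp(-t/tau)) / (1 - exp(-T/tau))` that is 0
#' at day 0 and reaches `delta_max` at the end of the experiment (day `T`).
#'
#' @param name identifier of the preset.
#' @param delta_volume_max signed percent change of bone volume at day
#'   `duration_days`.
#' @param delta_mu_ct_max,delta_mu_tb_max signed percent change of the
#'   cortical / trabecular attenuation at day `duration_days`.
#' @param tau_days time constant of the saturating curve (> 0).
#' @param duration_days total span of the experiment (> 0).
#' @return An object of class `fixation_model`.
#' @export
#' @examples
#' formalin_model()
#' ethanol_model()
fixation_model <- function(name, delta_volume_max = 0, delta_mu_ct_max = 0,
                           delta_mu_tb_max = 0, tau_days = 500,
                           duration_days = 1565) {
  if (duration_days <= 0) stop("duration_days must be > 0", call. = FALSE)
  if (tau_days <= 0) stop("tau_days must be > 0", call. = FALSE)
  if (delta_volume_max <= -100)
    stop("delta_volume_max must be > -100 percent", call. = FALSE)
  structure(list(name = name, delta_volume_max = delta_volume_max,
                 delta_mu_ct_max = delta_mu_ct_max,
                 delta_mu_tb_max = delta_mu_tb_max,
                 tau_days = tau_days, duration_days = duration_days),
            class = "fixation_model")
}

#' @rdname fixation_model
#' @details `formalin_model()` emulates formalin storage: progressive
#'   swelling of the mineralized compartments (+8.6% bone volume at the end
#'   of the experiment) with demineralization-like attenuation loss (-5.3%
#'   cortical, -2.9% trabecular). `ethanol_model()` is the stable control:
#'   all drifts are zero.
#' @export
formalin_model <- function(tau_days = 500, duration_days = 1565) {
  fixation_model("formalin", delta_volume_max = 8.6, delta_mu_ct_max = -5.3,
                 delta_mu_tb_max = -2.9, tau_days = tau_days,
                 duration_days = duration_days)
}

#' @rdname fixation_model
#' @export
ethanol_model <- function(tau_days = 500, duration_days = 1565) {
  fixation_model("ethanol", tau_days = tau_days,
                 duration_days = duration_days)
}

#' @rdname fixation_model
#' @param model a `fixation_model`.
#' @param day day since baseline.
#' @return `fixation_fraction()`: the saturating time-course value in
#'   [0, 1].
#' @export
fixation_fraction <- function(model, day) {
  stopifnot(inherits(model, "fixation_model"))
  (1 - exp(-day / model$tau_days)) /
    (1 - exp(-model$duration_days / model$tau_days))
}

#' Evolve a phantom under a fixation model
#'
#' Re-rasterizes the phantom's continuous geometry at a given storage day:
#' the labelled geometry is radially scaled by `s = sqrt(1 + dV/100)` (so
#' every compartment volume changes by the programmed percentage `dV`, up to
#' voxel discretization) and the cortical/trabecular attenuation values are
#' scaled by their programmed percentages. Day 0 returns the inputs
#' unchanged. The returned volume is noiseless.
#'
#' @param truth `bone_ground_truth` from [generate_bone_phantom()].
#' @param base the baseline [ct_volume()] from the same call.
#' @param model a [fixation_model()].
#' @param day day since baseline; must lie in `[0, duration_days]`.
#' @return A list with elements `volume` and `truth` as in
#'   [generate_bone_phantom()], with metadata set to `day`.
#' @export
apply_fixation_model <- function(truth, base, model, day) {
  stopifnot(inherits(truth, "bone_ground_truth"), is_ct_volume(base),
            inherits(model, "fixation_model"))
  if (day < 0 || day > model$duration_days)
    stop("day must lie within [0, duration_days]", call. = FALSE)
  f <- fixation_fraction(model, day)
  deltas <- c(model$delta_volume_max, model$delta_mu_ct_max,
              model$delta_mu_tb_max)
  if (f == 0 || all(deltas == 0)) {
    vol <- base
    vol$day <- day
    truth$true_morphometry$day <- day
    return(list(volume = vol, truth = truth))
  }
  spec <- truth$geometry$spec
  geom <- truth$geometry$geom
  s <- sqrt(1 + model$delta_volume_max * f / 100)
  ct_sc <- 1 + model$delta_mu_ct_max * f / 100
  tb_sc <- 1 + model$delta_mu_tb_max * f / 100
  labels <- .rasterize_labels(geom, truth$geometry$rods, s)
  grid <- .grid_from_labels(labels, spec, ct_sc, tb_sc)
  vol <- ct_volume(grid, spec$voxel_size_mm, day = day,
                   sample_id = base$sample_id)
  new_truth <- structure(list(
    label_map = labels,
    region_boundaries = truth$region_boundaries,
    true_morphometry = .truth_morphometry(vol, labels, geom),
    geometry = truth$geometry
  ), class = "bone_ground_truth")
  list(volume = vol, truth = new_truth)
}

#' Add reconstruction-like Gaussian noise to a volume
#'
#' Additive zero-mean Gaussian noise with standard deviation `sigma`
#' (mm^-1). `sigma = 0` returns the input unchanged; results are
#' deterministic for a given `seed` and do not disturb the caller's RNG
#' state.
#'
#' @param volume a [ct_volume()].
#' @param sigma noise standard deviation in mm^-1 (>= 0).
#' @param seed optional integer seed.
#' @return A [ct_volume()] with the same metadata.
#' @export
add_noise <- function(volume, sigma, seed = NULL) {
  stopifnot(is_ct_volume(volume))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("sigma must be a single non-negative number", call. = FALSE)
  if (sigma == 0) return(volume)
  noise_of <- function() rnorm(length(volume$grid), 0, sigma)
  eps <- if (is.null(seed)) noise_of() else .with_seed(seed, noise_of())
  volume$grid <- volume$grid + array(eps, dim(volume$grid))
  volume
}

#' Simulate a longitudinal fixation scan series
#'
#' Generates the baseline phantom and evolves it to each requested day under
#' a fixation model, adding Gaussian noise independently per time point
#' (seeded from the spec's seed, so the series is reproducible).
#'
#' @param spec a [phantom_spec()].
#' @param model a [fixation_model()].
#' @param days acquisition days; defaults to five points spanning the
#'   model's duration, starting at day 0.
#' @param noise_sigma noise level in mm^-1; defaults to `spec$noise_sigma`.
#' @return A list with `volumes` (list of noisy [ct_volume()]), `truths`
#'   (list of `bone_ground_truth`, noiseless) and `days`.
#' @export
simulate_fixation_series <- function(spec, model,
                                     days = round(seq(0, model$duration_days,
                                                      length.out = 5)),
                                     noise_sigma = spec$noise_sigma) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(model, "fixation_model"))
  base <- generate_bone_phantom(spec)
  volumes <- vector("list", length(days))
  truths <- vector("list", length(days))
  for (i in seq_along(days)) {
    st <- apply_fixation_model(base$truth, base$volume, model, days[i])
    truths[[i]] <- st$truth
    volumes[[i]] <- add_noise(st$volume, noise_sigma,
                              seed = spec$seed + 7919L * i)
  }
  list(volumes = volumes, truths = truths, days = days)
}
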