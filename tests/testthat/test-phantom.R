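# phantom generation, fixation drift model, noise

test_that("phantom generation is deterministic and labels partition the grid", {
  sp <- small_phantom_spec(seed = 7)
  a <- generate_bone_phantom(sp)
  b <- generate_bone_phantom(sp)
  expect_identical(a$volume$grid, b$volume$grid)
  expect_identical(a$truth$label_map, b$truth$label_map)

  counts <- tabulate(a$truth$label_map + 1L, nbins = 4L)
  expect_identical(sum(counts), length(a$truth$label_map))
  expect_true(all(counts > 0))  # all four classes present
  b12 <- a$truth$region_boundaries
  expect_true(b12[1] >= 1 && b12[1] < b12[2] && b12[2] < sp$length_vox)
})

test_that("zero fill fraction yields a trabecula-free phantom", {
  sp <- small_phantom_spec(trabecular_fill_fraction = 0,
                           diaphysis_trabecular_fraction = 0)
  ph <- generate_bone_phantom(sp)
  expect_identical(sum(ph$truth$label_map == 3L), 0L)
  expect_true(all(ph$truth$true_morphometry$Tb.BV == 0))
})

test_that("trabecular rods are confined to the EM zones (plus the programmed diaphyseal residual)", {
  ph <- generate_bone_phantom(small_phantom_spec(seed = 2))
  b <- ph$truth$region_boundaries
  tb_per_slice <- vapply(seq_len(dim(ph$truth$label_map)[1]),
                         function(z) sum(ph$truth$label_map[z, , ] == 3L),
                         numeric(1))
  dia <- sum(tb_per_slice[(b[1] + 1):b[2]])
  total <- sum(tb_per_slice)
  expect_lt(dia / total, 0.02)
  expect_gt(dia, 0)  # the residual used by the exclusion rule exists
})

test_that("ground-truth cortical volume of a plain tube matches the analytic annulus", {
  sp <- tube_spec()
  ph <- generate_bone_phantom(sp)
  ro <- sp$outer_radius_vox
  ri <- ro - sp$cortical_thickness_vox
  analytic <- pi * (ro^2 - ri^2) * sp$length_vox * sp$voxel_size_mm^3
  expect_equal(ph$truth$true_morphometry$Ct.BV[1], analytic,
               tolerance = 0.02)
  expect_identical(sum(ph$truth$label_map == 3L), 0L)
})

test_that("noiseless phantom medians equal the programmed class attenuations exactly", {
  sp <- small_phantom_spec(seed = 5)
  ph <- generate_bone_phantom(sp)
  g <- ph$volume$grid
  lm <- ph$truth$label_map
  expect_identical(median(g[lm == 2L]), sp$mu_cortical)
  expect_identical(median(g[lm == 3L]), sp$mu_trabecular)
  expect_identical(median(g[lm == 1L]), sp$mu_marrow)
  tm <- ph$truth$true_morphometry
  expect_true(all(tm$mu_Ct == sp$mu_cortical))
  expect_true(all(tm$mu_Tb[tm$Tb.BV > 0] == sp$mu_trabecular))
})

test_that("misfitting geometry is rejected", {
  expect_error(phantom_spec(outer_radius_vox = 40, cortical_thickness_vox = 5,
                            flare_factor = 1.3, width_vox = 80),
               "does not fit")
  expect_error(phantom_spec(cortical_thickness_vox = 50, outer_radius_vox = 45),
               "0 < t")
  expect_error(phantom_spec(trabecular_fill_fraction = 1), "\\[0, 1\\)")
  expect_error(phantom_spec(diaphysis_fraction = 1.2), "\\(0, 1\\)")
})

test_that("the fixation time course is a saturating, monotone schedule", {
  m <- formalin_model()
  days <- seq(0, m$duration_days, length.out = 25)
  f <- fixation_fraction(m, days)
  expect_identical(f[1], 0)
  expect_equal(f[length(f)], 1)
  expect_true(all(diff(f) > 0))
})

test_that("the ethanol preset is an exact identity at every day", {
  sp <- small_phantom_spec(seed = 3)
  ph <- generate_bone_phantom(sp)
  for (day in c(0, 700, 1565)) {
    st <- apply_fixation_model(ph$truth, ph$volume, ethanol_model(), day)
    expect_identical(st$volume$grid, ph$volume$grid)
    expect_identical(st$truth$label_map, ph$truth$label_map)
    expect_identical(st$volume$day, as.numeric(day))
    tm <- st$truth$true_morphometry
    tm$day <- 0
    expect_identical(tm, ph$truth$true_morphometry)
  }
})

test_that("the formalin preset swells volumes and dims attenuation as programmed", {
  sp <- small_phantom_spec(seed = 4)
  ph <- generate_bone_phantom(sp)
  m <- formalin_model()
  st0 <- apply_fixation_model(ph$truth, ph$volume, m, 0)
  expect_identical(st0$volume$grid, ph$volume$grid)  # day 0 unchanged

  st <- apply_fixation_model(ph$truth, ph$volume, m, m$duration_days)
  tm0 <- ph$truth$true_morphometry
  tm1 <- st$truth$true_morphometry
  w <- tm0$region == "whole"
  # radial scaling: every compartment volume changes by ~delta_volume_max
  expect_equal(percent_change(tm1$TV[w], tm0$TV[w]), m$delta_volume_max,
               tolerance = 0.1)
  expect_equal(percent_change(tm1$Ct.BV[w], tm0$Ct.BV[w]),
               m$delta_volume_max, tolerance = 0.1)
  # attenuation scales exactly
  expect_equal(percent_change(tm1$mu_Ct[w], tm0$mu_Ct[w]),
               m$delta_mu_ct_max, tolerance = 1e-9)
  expect_equal(percent_change(tm1$mu_Tb[w], tm0$mu_Tb[w]),
               m$delta_mu_tb_max, tolerance = 1e-9)
  # magnitude of the programmed change is monotone over days
  dts <- vapply(c(300, 800, 1565), function(d) {
    s <- apply_fixation_model(ph$truth, ph$volume, m, d)
    percent_change(s$truth$true_morphometry$TV[1], tm0$TV[1])
  }, numeric(1))
  expect_true(all(diff(dts) > 0))

  expect_error(apply_fixation_model(ph$truth, ph$volume, m, -1), "day")
  expect_error(apply_fixation_model(ph$truth, ph$volume, m,
                                    m$duration_days + 1), "day")
})

test_that("additive noise is zero-mean, seeded and optional", {
  v <- ct_volume(array(0.5, c(100, 100, 100)), 0.009)
  expect_identical(add_noise(v, 0), v)
  n1 <- add_noise(v, 0.05, seed = 11)
  n2 <- add_noise(v, 0.05, seed = 11)
  expect_identical(n1$grid, n2$grid)
  n3 <- add_noise(v, 0.05, seed = 12)
  expect_false(identical(n1$grid, n3$grid))
  # law of large numbers over 1e6 voxels
  resid <- n1$grid - v$grid
  n <- length(resid)
  expect_lt(abs(mean(resid)), 3 * 0.05 / sqrt(n))
  expect_error(add_noise(v, -0.1), "non-negative")
})

test_that("add_noise does not disturb the caller's RNG stream", {
  set.seed(42)
  x1 <- runif(1)
  set.seed(42)
  invisible(add_noise(ct_volume(array(0, c(2, 2, 2)), 1), 0.1, seed = 5))
  x2 <- runif(1)
  expect_identical(x1, x2)
})
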