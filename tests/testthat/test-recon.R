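# Scatter-window algebra, MLEM/OSEM reconstruction and calibration.

test_that("TEW and DEW follow the window formulas", {
  geom <- acquisition_geometry(n_views = 1, heads = 1, time_per_view_s = 1)
  mkp <- function(val) projection_set(array(val, c(2, 2, 1)), geom)
  w_lu <- default_windows("lu177")   # w_l 25.5, w_u 24, w_p 31.2 keV

  # zero counts -> zero estimate
  expect_equal(max(tew_scatter_estimate(mkp(0), mkp(0), w_lu)$views), 0)

  # hand evaluation with w_l = w_p = 31.2 keV, w_u = 24 keV
  w_hand <- energy_window_set(208, 0.15, data.frame(
    center_keV = c(208, 240), frac_width = c(0.15, 0.10),
    position = c("lower", "upper")))
  s <- tew_scatter_estimate(mkp(100), mkp(50), w_hand)
  expect_equal(s$views[1, 1, 1], (100 / 31.2 + 50 / 24) * 31.2 / 2,
               tolerance = 1e-12)
  expect_rel_equal(s$views[1, 1, 1], 82.5, 1e-3)

  # upper term only
  s_u <- tew_scatter_estimate(mkp(0), mkp(50), w_hand)
  expect_equal(s_u$views[1, 1, 1], 50 * 31.2 / (2 * 24))

  # DEW: C_l = 60, w_l = 44 keV, w_p = 88 keV -> S = 60
  w_ac <- default_windows("ac225")
  expect_equal(dew_scatter_estimate(mkp(60), w_ac)$views[1, 1, 1], 60)
  # halving the scatter-window width doubles the estimate
  w_half <- energy_window_set(440, 0.20, data.frame(
    center_keV = 440, frac_width = 0.05, position = "lower"))
  expect_equal(dew_scatter_estimate(mkp(60), w_half)$views[1, 1, 1], 120)

  # TEW with the upper window zeroed equals DEW exactly
  w_sym <- energy_window_set(440, 0.20, data.frame(
    center_keV = c(440, 500), frac_width = c(0.10, 0.10),
    position = c("lower", "upper")))
  expect_equal(tew_scatter_estimate(mkp(60), mkp(0), w_sym)$views,
               dew_scatter_estimate(mkp(60), w_sym)$views)
})

test_that("MLEM recovers a point source and is monotone in likelihood", {
  g <- small_grid()
  ai <- point_activity(g, 1e6, at = c(16, 16, 8))
  geom <- small_geom()
  p <- forward_project(ai, NULL, psf_delta(), geom, 22.7)
  prot <- recon_protocol("ac225", iterations = 60)
  r <- osem_reconstruct(p, NULL, NULL, psf_delta(), prot, grid = g,
                        track_likelihood = TRUE)
  conc <- calibrate_to_concentration(r, calibration_factor("ac225", 22.7))
  expect_rel_equal(conc$values[16, 16, 8], 1e6, 0.001)
  expect_true(all(r$values >= 0))

  ll <- attr(r, "loglik")
  expect_true(all(diff(ll) >= -1e-7 * abs(ll[-1])))

  # count conservation at convergence (no attenuation)
  sys <- tandemspect:::.build_system(g, geom, psf_delta(), NULL, 15)
  tot <- sum(tandemspect:::.sys_forward(r$values, sys, 10))
  expect_rel_equal(tot, sum(p$views), 0.005)
})

test_that("OSEM with one subset equals MLEM iterate-for-iterate", {
  g <- voxel_grid(c(24, 24, 12), 4.7952)
  ph <- build_cylinder_phantom(
    phantom_spec(body = geometry_spec("cylinder", c(0, 0, 0),
                                      radius = 40, height = 40),
                 inserts = list(hot = geometry_spec("sphere", c(15, 0, 0),
                                                    radius = 10)),
                 bg_rods = list()), g)
  geom <- small_geom()
  p <- forward_project(ph$activity, NULL, psf_delta(), geom, 22.7)
  prot_mlem <- recon_protocol("ac225", iterations = 5,
                              projections_per_subset = 0)
  prot_os1 <- recon_protocol("ac225", iterations = 5,
                             projections_per_subset = 16)  # 16 views = all
  r1 <- osem_reconstruct(p, NULL, NULL, psf_delta(), prot_mlem, grid = g)
  r2 <- osem_reconstruct(p, NULL, NULL, psf_delta(), prot_os1, grid = g)
  expect_equal(r1$values, r2$values, tolerance = 1e-10)

  # subset size must divide the view count
  bad <- recon_protocol("ac225", iterations = 1,
                        projections_per_subset = 5)
  expect_error(osem_reconstruct(p, NULL, NULL, psf_delta(), bad, grid = g),
               "divide")

  # OSEM with real subsets stays nonnegative and converges to a
  # similar image
  prot_os <- recon_protocol("lu177", iterations = 5,
                            projections_per_subset = 8)
  r3 <- osem_reconstruct(p, NULL, NULL, psf_delta(), prot_os, grid = g)
  expect_true(all(r3$values >= 0))
})

test_that("reconstruction with an exact scatter estimate quantifies
           like the scatter-free reconstruction", {
  # with the true scatter added to the EM denominator, the scattered
  # acquisition and the scatter-free acquisition reconstruct to the
  # same quantification: VOI means agree within 1 % (individual voxels
  # in poorly determined directions of the finite-view system may
  # differ more)
  g <- voxel_grid(c(32, 32, 16), 4.7952)
  ph <- build_cylinder_phantom(
    phantom_spec(body = geometry_spec("cylinder", c(0, 0, 0),
                                      radius = 60, height = 60),
                 inserts = list(hot = geometry_spec("sphere", c(20, 0, 0),
                                                    radius = 14)),
                 bg_rods = list()), g)
  geom <- acquisition_geometry(n_views = 16, heads = 2, radius_mm = 200,
                               time_per_view_s = 60)
  psf <- psf_delta()
  mu <- mu_map_from_density(ph$density, 440)
  primary <- forward_project(ph$activity, mu, psf, geom, 22.7)
  w_ac <- default_windows("ac225")
  wins <- emulate_scatter_windows(primary, w_ac, scatter_fraction = 0.4)
  est <- dew_scatter_estimate(wins$lower, w_ac)
  prot <- recon_protocol("ac225", iterations = 40)
  r_clean <- osem_reconstruct(primary, NULL, mu, psf, prot)
  r_corr <- osem_reconstruct(wins$peak, est, mu, psf, prot)
  ins <- ph$mask$labels == 1L
  bg <- ph$density$values > 0 & ph$mask$labels == 0L
  expect_rel_equal(mean(r_corr$values[ins]), mean(r_clean$values[ins]),
                   0.01)
  expect_rel_equal(mean(r_corr$values[bg]), mean(r_clean$values[bg]),
                   0.015)
  # without the correction the quantification is biased high
  r_none <- osem_reconstruct(wins$peak, NULL, mu, psf, prot)
  expect_gt(mean(r_none$values[ins]) / mean(r_clean$values[ins]), 1.05)
})

test_that("calibration closes the loop from sensitivity to concentration", {
  cal <- calibration_factor("ac225", 22.7)
  g <- small_grid(c(16, 16, 8))
  r <- volume_image(array(10, g$shape), g, "counts",
                    meta = list(nuclide = "ac225"))
  conc <- calibrate_to_concentration(r, cal)
  # inverting the conversion recovers the count rates
  back <- conc$values * cal$value_cps_per_MBq * voxel_volume_ml(g) / 1e6
  expect_equal(back, r$values, tolerance = 1e-12)
  cal2 <- calibration_factor("ac225", 45.4)
  expect_equal(calibrate_to_concentration(r, cal2)$values,
               conc$values / 2, tolerance = 1e-12)
  expect_error(calibrate_to_concentration(r, calibration_factor("lu177", 7)),
               "calibration factor")
})

test_that("the calibration factor is recovered from a cylinder run", {
  g <- voxel_grid(c(32, 32, 16), 4.7952)
  cyl <- geometry_spec("cylinder", c(0, 0, 0), radius = 55, height = 60)
  act <- array(0, g$shape)
  act[tandemspect:::.inside_geometry(cyl, g)] <- 5000
  ai <- volume_image(act, g, "activity_conc_Bq_per_ml",
                     meta = list(nuclide = "ac225"))
  a_MBq <- sum(act) * voxel_volume_ml(g) * 1e-6
  geom <- small_geom(120)
  mu <- mu_map_from_density(
    volume_image(1 * (act > 0), g, "density_g_per_ml"), 440)
  psf <- small_psf()
  primary <- forward_project(ai, mu, psf, geom, 22.7)

  # attenuation-corrected reconstruction route
  prot <- recon_protocol("ac225", iterations = 30)
  r <- osem_reconstruct(primary, NULL, mu, psf, prot)
  cal <- derive_calibration_factor(r, a_MBq, "ac225")
  expect_rel_equal(cal$value_cps_per_MBq, 22.7, 0.01)

  # intensive in the activity: doubling both leaves the factor alone
  ai2 <- ai; ai2$values <- ai$values * 2
  r2 <- osem_reconstruct(forward_project(ai2, mu, psf, geom, 22.7),
                         NULL, mu, psf, prot)
  cal2 <- derive_calibration_factor(r2, 2 * a_MBq, "ac225")
  expect_rel_equal(cal2$value_cps_per_MBq, cal$value_cps_per_MBq, 1e-6)

  # unattenuated projection route with Poisson noise: within 3 sigma
  p0 <- forward_project(ai, NULL, psf_delta(), geom, 22.7)
  noisy <- add_poisson_noise(p0, 7)
  caln <- derive_calibration_factor(noisy, a_MBq, "ac225")
  sigma <- 22.7 / sqrt(sum(p0$views))
  expect_lt(abs(caln$value_cps_per_MBq - 22.7), 3 * sigma)

  expect_error(derive_calibration_factor(r, 0), "> 0")
})

test_that("the full noiseless chain recovers a uniform concentration", {
  g <- voxel_grid(c(32, 32, 16), 4.7952)
  cyl <- geometry_spec("cylinder", c(0, 0, 0), radius = 55, height = 60)
  inside <- tandemspect:::.inside_geometry(cyl, g)
  act <- array(0, g$shape)
  act[inside] <- 4000
  ai <- volume_image(act, g, "activity_conc_Bq_per_ml",
                     meta = list(nuclide = "ac225"))
  dens <- volume_image(1 * (act > 0), g, "density_g_per_ml")
  mu <- mu_map_from_density(dens, 440)
  geom <- small_geom(120)
  psf <- analytic_psf_stack("gaussian", slope_mm_per_mm = 0.04)
  primary <- forward_project(ai, mu, psf, geom, 22.7)
  prot <- recon_protocol("ac225", iterations = 150)
  r <- osem_reconstruct(primary, NULL, mu, psf, prot)
  conc <- calibrate_to_concentration(r, calibration_factor("ac225", 22.7))
  # 80 %-eroded interior VOI
  core <- geometry_spec("cylinder", c(0, 0, 0), radius = 44, height = 48)
  m <- rasterize_geometry(core, g)
  expect_rel_equal(mask_stats(conc, m, 1)$mean, 4000, 0.02)
})
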