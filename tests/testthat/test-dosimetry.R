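# Kinetics fitting, half-life conversion, TIA, dose kernels, weighting
# and reports.

test_that("decay correction scales by powers of two", {
  expect_equal(decay_correct(10, 0, 45), 10)
  expect_equal(decay_correct(10, 45, 45), 20)
  expect_equal(decay_correct(10, -45, 45), 5)
  expect_error(decay_correct(10, 1, 0), "> 0")
})

test_that("two-point fits recover the half-life or flag exclusion", {
  f <- fit_two_point_half_life(100, 50, 24, 48)
  expect_equal(f$half_life_h, 24)
  expect_false(f$excluded)

  f2 <- fit_two_point_half_life(100, 100 / sqrt(2), 24, 48)
  expect_rel_equal(f2$half_life_h, 48, 1e-9)

  # rising uptake between the scans cannot be fit mono-exponentially
  f3 <- fit_two_point_half_life(80, 100, 24, 48)
  expect_true(f3$excluded)
  expect_true(is.na(f3$half_life_h))

  expect_error(fit_two_point_half_life(-1, 10), "> 0")
  expect_error(fit_two_point_half_life(10, 10, 48, 24), "after")
})

test_that("effective half-lives convert between nuclides and back", {
  lu <- builtin_nuclide("lu177")
  ac <- builtin_nuclide("ac225")
  # the printed kidney mean: 31 h for Lu-177 maps to 33 h for Ac-225
  t_ac <- convert_effective_half_life(31, lu, ac)
  expect_equal(round(t_ac), 33)
  # pure physical decay maps physical to physical
  expect_equal(convert_effective_half_life(lu$half_life_h, lu, ac),
               ac$half_life_h, tolerance = 1e-9)
  # algebraic inverse
  for (t in c(5, 31, 51, 120)) {
    rt <- convert_effective_half_life(
      convert_effective_half_life(t, lu, ac), ac, lu)
    expect_equal(rt, t, tolerance = 1e-10)
  }
  expect_error(convert_effective_half_life(200, lu, ac), "negative")
})

test_that("closed-form TIA matches numerical integration", {
  expect_rel_equal(tia_closed_form(1, 0, 33), 33 / log(2), 1e-12)
  # oracle: integrate A(t) = A(t*) 2^(-(t - t*)/T) from 0 to Inf
  for (t_star in c(0, 24, 48)) for (t12 in c(10, 33, 100)) {
    oracle <- stats::integrate(function(t) 2^(-(t - t_star) / t12),
                               0, Inf, rel.tol = 1e-10)$value
    expect_rel_equal(tia_closed_form(1, t_star, t12), oracle, 1e-6)
  }
  # reference example: 1 MBq at 24 h with T = 33 h -> ~78.8 MBq h
  expect_rel_equal(tia_closed_form(1, 24, 33), 78.8, 0.001)
  # strictly increasing in the half-life
  tias <- vapply(c(20, 33, 50, 80), tia_closed_form, numeric(1),
                 a_ref = 1, t_star_h = 24)
  expect_true(all(diff(tias) > 0))
})

test_that("voxel TIA uses each VOI's half-life and demands kinetics", {
  g <- voxel_grid(c(8, 8, 4), 4)
  labels <- array(0L, g$shape)
  labels[1:2, 1, 1] <- 1L
  m <- voi_mask(labels, g, c(kidney = 1L))
  act <- volume_image(array(100, g$shape), g, "activity_conc_Bq_per_ml")
  tia <- voxel_tia(act, m, c(kidney = 33, background = 25), 24)
  expect_equal(tia$values[1, 1, 1], tia_closed_form(100, 24, 33))
  expect_equal(tia$values[5, 5, 2], tia_closed_form(100, 24, 25))
  expect_error(voxel_tia(act, m, c(background = 25), 24), "kidney")
  expect_error(voxel_tia(act, m, c(kidney = 33), 24), "background")
})

test_that("voxel S-value kernels conserve the energy per decay", {
  g <- voxel_grid(c(16, 16, 16), 4.7952)
  ac <- builtin_nuclide("ac225")
  lu <- builtin_nuclide("lu177")

  # full-chain alpha energy deposited in one clinical voxel at 1 g/ml
  k_ac <- build_vsv_kernel(ac, g, rho_g_per_ml = 1.0)
  self_S <- 27.6 * 1.602176634e-13 / (prod(g$spacing) * 1e-6)
  expect_rel_equal(k_ac$kernel[1, 1, 1], self_S, 1e-9)
  expect_rel_equal(k_ac$kernel[1, 1, 1], 4.0e-8, 0.01)

  # energy conservation for both nuclides at the reference density
  for (k in list(k_ac, build_vsv_kernel(lu, g, rho_g_per_ml = 1.04))) {
    vox_kg <- prod(g$spacing) / 1000 * k$rho_g_per_ml * 1e-3
    expect_rel_equal(sum(k$kernel) * vox_kg, k$energy_per_decay_J, 1e-6)
  }

  # beta self-dose fraction grows with voxel size
  f2 <- vsv_self_fraction(build_vsv_kernel(lu, voxel_grid(c(8, 8, 8), 2)))
  f10 <- vsv_self_fraction(build_vsv_kernel(lu, voxel_grid(c(8, 8, 8), 10)))
  expect_lt(f2, f10)
  expect_lt(f10, 1 + 1e-12)

  expect_error(build_vsv_kernel(lu, voxel_grid(c(8, 8, 8), c(1, 1, 2))),
               "anisotropic")
})

test_that("VSV convolution turns TIA maps into dose maps", {
  g <- voxel_grid(c(12, 12, 12), 4.7952)
  ac <- builtin_nuclide("ac225")
  lu <- builtin_nuclide("lu177")
  k_ac <- build_vsv_kernel(ac, g)
  k_lu <- build_vsv_kernel(lu, g)

  zero <- volume_image(array(0, g$shape), g, "tia_Bq_h_per_ml")
  expect_equal(max(abs(apply_vsv(zero, k_ac)$values)), 0)

  # point TIA with the single-voxel kernel: dose only there
  pt <- array(0, g$shape)
  pt[6, 6, 6] <- 1e3
  tia_pt <- volume_image(pt, g, "tia_Bq_h_per_ml")
  d <- apply_vsv(tia_pt, k_ac)
  decays <- 1e3 * voxel_volume_ml(g) * 3600
  expect_equal(sum(d$values > 0), 1L)
  expect_rel_equal(d$values[6, 6, 6], decays * k_ac$kernel[1, 1, 1], 1e-12)

  # uniform TIA: interior dose equals TIA density x energy / mass
  u <- volume_image(array(500, g$shape), g, "tia_Bq_h_per_ml")
  du <- apply_vsv(u, k_lu)
  expected <- 500 * 3600 * k_lu$energy_per_decay_J /
    (k_lu$rho_g_per_ml * 1e-3)
  expect_rel_equal(du$values[6, 6, 6], expected, 1e-9)

  # linearity
  u2 <- u; u2$values <- u$values * 2
  expect_equal(apply_vsv(u2, k_lu)$values, 2 * du$values,
               tolerance = 1e-12)

  k_bad <- build_vsv_kernel(ac, voxel_grid(c(4, 4, 4), 3))
  expect_error(apply_vsv(u, k_bad), "spacing")
})

test_that("density weighting is inversely proportional to density", {
  g <- voxel_grid(c(6, 6, 6), 4)
  dose <- volume_image(array(2, g$shape), g, "dose_Gy")
  rho <- array(1.04, g$shape)
  dens <- volume_image(rho, g, "density_g_per_ml")
  expect_equal(density_weight(dose, dens)$values, dose$values)

  dens2 <- volume_image(rho * 2, g, "density_g_per_ml")
  expect_equal(density_weight(dose, dens2)$values, dose$values / 2)

  set.seed(10)
  mixed <- array(runif(prod(g$shape), 0.5, 2), g$shape)
  densm <- volume_image(mixed, g, "density_g_per_ml")
  expect_equal(density_weight(dose, densm)$values,
               dose$values * 1.04 / mixed, tolerance = 1e-12)

  zero <- volume_image(array(0, g$shape), g, "density_g_per_ml")
  expect_error(density_weight(dose, zero), "zero density")
})

test_that("RBE weighting multiplies by the nuclide RBE, linearly", {
  g <- voxel_grid(c(4, 4, 4), 4)
  lu <- builtin_nuclide("lu177")
  ac <- builtin_nuclide("ac225")
  d <- volume_image(array(0.1, g$shape), g, "dose_Gy")
  d_lu <- rbe_weight(d, lu)
  expect_equal(d_lu$values, d$values)
  expect_identical(d_lu$quantity, "dose_Sv_RBE")
  d_ac <- rbe_weight(d, ac)
  expect_equal(d_ac$values[1], 0.5)
  # linearity
  a <- volume_image(array(0.2, g$shape), g, "dose_Gy")
  s <- volume_image(d$values + a$values, g, "dose_Gy")
  expect_equal(rbe_weight(s, ac)$values,
               rbe_weight(d, ac)$values + rbe_weight(a, ac)$values)
})

test_that("dose reports normalize per administered activity", {
  g <- voxel_grid(c(10, 10, 4), 4)
  labels <- array(0L, g$shape)
  labels[1:3, 1:3, 1] <- 1L
  labels[6:8, 6:8, 2] <- 2L
  m <- voi_mask(labels, g, c(a = 1L, b = 2L))
  v <- array(0, g$shape)
  v[labels == 1L] <- 2
  v[labels == 2L] <- 4
  dose <- volume_image(v, g, "dose_Sv_RBE")
  ac <- builtin_nuclide("ac225")
  rep1 <- voi_dose_report(dose, m, 8, ac)
  expect_equal(rep1$dose_per_admin[rep1$voi == "a"], 0.25)
  expect_equal(rep1$per_admin_unit[1], "Sv_RBE5_per_MBq")

  # row content independent of VOI ordering
  rep2 <- voi_dose_report(dose, m, 8, ac, vois = c("b", "a"))
  expect_equal(rep2[rep2$voi == "a", ]$dose_per_admin,
               rep1[rep1$voi == "a", ]$dose_per_admin)

  lu <- builtin_nuclide("lu177")
  rep3 <- voi_dose_report(dose, m, 1000, lu)
  expect_equal(rep3$dose_per_admin[rep3$voi == "b"], 4)  # per GBq
  expect_equal(rep3$per_admin_unit[1], "Sv_RBE1_per_GBq")
  expect_error(voi_dose_report(dose, m, 0, ac), "> 0")
})
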