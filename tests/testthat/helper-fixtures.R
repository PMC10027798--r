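# Shared small fixtures, built in code at test time.

# A small grid at the clinical pixel pitch.
small_grid <- function(shape = c(32, 32, 16), spacing = 4.7952)
  voxel_grid(shape, spacing)

# A fast acquisition for unit tests (8 x 2 views, short dwell).
small_geom <- function(time_per_view_s = 10)
  acquisition_geometry(n_views = 8, heads = 2, radius_mm = 200,
                       time_per_view_s = time_per_view_s)

# A coarse high-energy PSF stack (few planes keeps construction fast).
small_psf <- function(penetration = 0.3)
  analytic_psf_stack("high_energy", intrinsic_fwhm_mm = 4.5,
                     slope_mm_per_mm = 0.07, penetration = penetration,
                     n_planes = 30, max_distance_mm = 400)

# Uniform-concentration single-voxel activity image.
point_activity <- function(grid, conc = 1e6,
                           at = ceiling(grid$shape / 2)) {
  v <- array(0, grid$shape)
  v[at[1], at[2], at[3]] <- conc
  volume_image(v, grid, "activity_conc_Bq_per_ml",
               meta = list(nuclide = "ac225"))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object / expected - 1), tol)
}
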