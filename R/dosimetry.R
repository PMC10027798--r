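# Single-time-point voxel dosimetry: two-point kinetics fitting,
# cross-nuclide effective-half-life conversion, closed-form
# time-integrated activity, voxel S-value kernel convolution, density
# and RBE weighting, and per-VOI dose reports.

#' Physical decay correction
#'
#' Multiplies by `2^(dt / half_life)`: positive `dt_h` corrects a value
#' measured `dt_h` later back to the reference time.
#'
#' @param value numeric value(s).
#' @param dt_h time difference in hours.
#' @param half_life_h physical half-life in hours.
#' @export
decay_correct <- function(value, dt_h, half_life_h) {
  if (half_life_h <= 0) stop("half-life must be > 0")
  value * 2^(dt_h / half_life_h)
}

#' Mono-exponential two-point effective half-life fit
#'
#' `T_eff = (t2 - t1) * ln 2 / ln(A1 / A2)` for decreasing uptake; if
#' the uptake does not decrease between the two time points the VOI is
#' flagged `excluded` (no half-life), mirroring the handling of lesions
#' whose maximum uptake occurs at the later scan.
#'
#' @param a1,a2 uptake (any consistent unit, > 0) at `t1_h`, `t2_h`.
#' @param t1_h,t2_h measurement times, `t2_h > t1_h`.
#' @param voi VOI name carried through to the result.
#' @return list with `voi`, `a_ref` (= `a1`), `t_ref_h`, `half_life_h`
#'   (NA if excluded), `excluded`, `points`.
#' @export
fit_two_point_half_life <- function(a1, a2, t1_h = 24, t2_h = 48,
                                    voi = NA_character_) {
  if (a1 <= 0 || a2 <= 0) stop("activities must be > 0")
  if (t2_h <= t1_h) stop("t2 must be after t1")
  excluded <- a2 >= a1
  half_life <- if (excluded) NA_real_ else
    (t2_h - t1_h) * log(2) / log(a1 / a2)
  list(voi = voi, a_ref = a1, t_ref_h = t1_h, half_life_h = half_life,
       excluded = excluded,
       points = data.frame(t_h = c(t1_h, t2_h), a = c(a1, a2)))
}

#' Convert an effective half-life between nuclides
#'
#' Assumes equal biological pharmacokinetics of the two labelled
#' compounds: the biological clearance `1/T_bio = 1/T_eff -
#' 1/T_phys(from)` is kept and recombined with the target nuclide's
#' physical half-life. `T_eff = T_phys(from)` (no biological
#' clearance) maps to `T_phys(to)`.
#'
#' @param t_eff_h effective half-life to convert.
#' @param from_nuclide,to_nuclide [nuclide_spec()]s.
#' @export
convert_effective_half_life <- function(t_eff_h, from_nuclide, to_nuclide) {
  if (t_eff_h <= 0) stop("effective half-life must be > 0")
  if (t_eff_h > from_nuclide$half_life_h)
    stop("effective half-life exceeds the physical half-life of ",
         from_nuclide$name, ": negative biological clearance")
  inv_bio <- 1 / t_eff_h - 1 / from_nuclide$half_life_h
  1 / (inv_bio + 1 / to_nuclide$half_life_h)
}

#' Closed-form time-integrated activity of a single voxel value
#'
#' `TIA = A(t*) * exp(ln 2 * t* / T_eff) * T_eff / ln 2`: the
#' mono-exponential curve through the reference uptake, integrated from
#' time zero to infinity.
#'
#' @param a_ref uptake at the reference time (any activity unit).
#' @param t_star_h reference time in hours.
#' @param half_life_h effective half-life in hours.
#' @return TIA in (unit of `a_ref`) x hours.
#' @export
tia_closed_form <- function(a_ref, t_star_h, half_life_h) {
  stopifnot(half_life_h > 0)
  a_ref * exp(log(2) * t_star_h / half_life_h) * half_life_h / log(2)
}

#' Voxel-wise time-integrated activity map
#'
#' Applies [tia_closed_form()] per voxel with the effective half-life
#' of the VOI the voxel belongs to; voxels outside every VOI use the
#' mandatory `"background"` entry of the kinetics table.
#'
#' @param activity [volume_image()] (Bq/ml) at the reference time.
#' @param mask a [voi_mask()] on the same grid.
#' @param half_life_h named vector of effective half-lives (h) per VOI
#'   name plus `"background"`.
#' @param t_star_h reference time (h).
#' @return A [volume_image()] of quantity `"tia_Bq_h_per_ml"`.
#' @export
voxel_tia <- function(activity, mask, half_life_h, t_star_h) {
  stop_if_grid_mismatch(activity$grid, mask$grid)
  if (!"background" %in% names(half_life_h))
    stop("missing kinetics for background")
  missing <- setdiff(names(mask$names), names(half_life_h))
  if (length(missing) > 0L)
    stop("missing kinetics for VOI: ", paste(missing, collapse = ", "))
  fac <- array(NA_real_, activity$grid$shape)
  fac[] <- exp(log(2) * t_star_h / half_life_h[["background"]]) *
    half_life_h[["background"]] / log(2)
  for (nmv in names(mask$names)) {
    t12 <- half_life_h[[nmv]]
    if (!is.finite(t12) || t12 <= 0)
      stop("invalid half-life for VOI ", nmv)
    fac[mask$labels == mask$names[[nmv]]] <-
      exp(log(2) * t_star_h / t12) * t12 / log(2)
  }
  volume_image(activity$values * fac, activity$grid, "tia_Bq_h_per_ml",
               meta = c(activity$meta, list(t_star_h = t_star_h)))
}

#' Build an energy-conserving voxel S-value kernel
#'
#' The kernel gives absorbed dose (Gy) to each neighbouring voxel per
#' decay in the source voxel, for soft tissue of reference density
#' `rho_g_per_ml`. For `ac225` the full decay chain's charged-particle
#' energy is deposited in the source voxel (alpha ranges are far below
#' the voxel size; full local deposition of all daughters). For
#' `lu177` the mean beta energy is spread over an isotropic
#' exponential point kernel of decay length `beta_decay_mm` and
#' integrated over the neighbouring voxels. In both cases the energy-
#' conservation identity sum(kernel x voxel mass) = energy per decay
#' holds by construction.
#'
#' @param nuclide a [nuclide_spec()].
#' @param grid a [voxel_grid()] (only the spacing is used; the max/min
#'   spacing ratio must be <= 1.5).
#' @param rho_g_per_ml soft-tissue reference density.
#' @param beta_decay_mm exponential decay length of the beta point
#'   kernel.
#' @param support_voxels half-width of the kernel support for spread
#'   kernels.
#' @return A `vsv_kernel` object: `kernel` (Gy per decay), `spacing`,
#'   `nuclide`, `rho_g_per_ml`.
#' @export
build_vsv_kernel <- function(nuclide, grid, rho_g_per_ml = 1.04,
                             beta_decay_mm = 0.2, support_voxels = 2L) {
  sp <- grid$spacing
  if (max(sp) / min(sp) > 1.5)
    stop("voxel spacing too anisotropic for an isotropic kernel")
  e_J <- nuclide$energy_per_decay_MeV * 1.602176634e-13
  vox_kg <- prod(sp) / 1000 * rho_g_per_ml * 1e-3
  if (nuclide$name == "ac225") {
    kern <- array(e_J / vox_kg, c(1, 1, 1))
  } else {
    h <- as.integer(support_voxels)
    n <- 2L * h + 1L
    w <- array(0, c(n, n, n))
    sub <- 4L  # subsamples per axis for the voxel integrals
    offs <- ((seq_len(sub) - 0.5) / sub - 0.5)
    lam <- beta_decay_mm
    for (ix in -h:h) for (iy in -h:h) for (iz in -h:h) {
      if (ix == 0 && iy == 0 && iz == 0) next
      pts <- expand.grid(x = (ix + offs) * sp[1], y = (iy + offs) * sp[2],
                         z = (iz + offs) * sp[3])
      r <- sqrt(pts$x^2 + pts$y^2 + pts$z^2)
      dens <- exp(-r / lam) / (8 * pi * lam^3)  # integrates to 1
      w[ix + h + 1, iy + h + 1, iz + h + 1] <-
        mean(dens) * prod(sp)
    }
    w[h + 1, h + 1, h + 1] <- max(1 - sum(w), 0)
    w <- w / sum(w)
    kern <- w * e_J / vox_kg
  }
  structure(list(kernel = kern, spacing = sp, nuclide = nuclide$name,
                 rho_g_per_ml = rho_g_per_ml,
                 energy_per_decay_J = e_J),
            class = "vsv_kernel")
}

#' Self-dose fraction of a voxel S-value kernel
#' @param vsv a `vsv_kernel`.
#' @export
vsv_self_fraction <- function(vsv) {
  h <- (dim(vsv$kernel) - 1) %/% 2
  vsv$kernel[h[1] + 1, h[2] + 1, h[3] + 1] / sum(vsv$kernel)
}

#' Convolve a TIA map with a voxel S-value kernel
#'
#' The TIA map (Bq h per ml) is converted to decays per voxel and
#' convolved with the kernel (Gy per decay), yielding the soft-tissue
#' absorbed dose map. Linear in the TIA.
#'
#' @param tia a [volume_image()] of quantity `"tia_Bq_h_per_ml"`.
#' @param vsv a `vsv_kernel` built on the same voxel spacing.
#' @export
apply_vsv <- function(tia, vsv) {
  stopifnot(tia$quantity == "tia_Bq_h_per_ml")
  if (any(abs(tia$grid$spacing - vsv$spacing) > 1e-6))
    stop("kernel and image voxel spacings do not match")
  decays <- tia$values * voxel_volume_ml(tia$grid) * 3600
  k <- vsv$kernel
  h <- (dim(k) - 1L) %/% 2L
  dose <- array(0, dim(decays))
  for (ix in seq_len(dim(k)[1])) for (iy in seq_len(dim(k)[2]))
    for (iz in seq_len(dim(k)[3])) {
      w <- k[ix, iy, iz]
      if (w == 0) next
      dose <- dose + w * .shift3d(decays, c(ix - 1L - h[1], iy - 1L - h[2],
                                            iz - 1L - h[3]))
    }
  volume_image(dose, tia$grid, "dose_Gy",
               meta = c(tia$meta, list(kernel_nuclide = vsv$nuclide)))
}

# Zero-padded integer shift of a 3-D array.
.shift3d <- function(a, by) {
  if (all(by == 0L)) return(a)
  dm <- dim(a)
  out <- array(0, dm)
  src <- dst <- vector("list", 3)
  for (k in 1:3) {
    b <- by[k]
    if (abs(b) >= dm[k]) return(out)
    if (b >= 0) { dst[[k]] <- (1 + b):dm[k]; src[[k]] <- 1:(dm[k] - b) }
    else { dst[[k]] <- 1:(dm[k] + b); src[[k]] <- (1 - b):dm[k] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Weight a soft-tissue dose map by local CT density
#'
#' Absorbed dose is inversely proportional to the local density:
#' `dose(x) * rho_soft / rho(x)`.
#'
#' @param dose a dose [volume_image()] (Gy).
#' @param density a density [volume_image()] (g/ml).
#' @param rho_soft_g_per_ml soft-tissue reference density.
#' @export
density_weight <- function(dose, density, rho_soft_g_per_ml = 1.04) {
  stop_if_grid_mismatch(dose$grid, density$grid)
  bad <- density$values <= 0 & dose$values > 0
  if (any(bad)) stop("zero density under nonzero dose")
  ratio <- ifelse(density$values > 0,
                  rho_soft_g_per_ml / density$values, 0)
  out <- dose
  out$values <- dose$values * ratio
  out$meta$density_weighted <- TRUE
  out
}

#' Apply the relative biological effectiveness
#'
#' Converts absorbed dose (Gy) into RBE-weighted dose (Sv_RBE):
#' RBE 5 for the alpha-emitting Ac-225 chain, RBE 1 for Lu-177.
#'
#' @param dose a [volume_image()] of quantity `"dose_Gy"`.
#' @param nuclide a [nuclide_spec()] carrying the RBE.
#' @export
rbe_weight <- function(dose, nuclide) {
  stopifnot(dose$quantity == "dose_Gy")
  meta <- dose$meta
  meta$rbe <- nuclide$rbe
  volume_image(dose$values * nuclide$rbe, dose$grid, "dose_Sv_RBE",
               meta = meta)
}

#' Per-VOI dose report
#'
#' Mean dose and dose per administered activity for every VOI in the
#' mask. Doses per administered activity are reported in the customary
#' units: Sv_RBE=5 per MBq for Ac-225 and Sv_RBE=1 per GBq for Lu-177.
#'
#' @param dose a dose [volume_image()] (`"dose_Gy"` or
#'   `"dose_Sv_RBE"`).
#' @param mask a [voi_mask()].
#' @param administered_MBq administered activity.
#' @param nuclide a [nuclide_spec()] (controls the per-activity unit).
#' @param vois optional character vector restricting the report.
#' @return data.frame with one row per VOI: `voi`, `mean_dose`,
#'   `dose_unit`, `dose_per_admin`, `per_admin_unit`, `volume_ml`.
#' @export
voi_dose_report <- function(dose, mask, administered_MBq, nuclide,
                            vois = names(mask$names)) {
  if (administered_MBq <= 0) stop("administered activity must be > 0")
  per_GBq <- nuclide$name == "lu177"
  denom <- if (per_GBq) administered_MBq / 1000 else administered_MBq
  rows <- lapply(vois, function(nmv) {
    st <- mask_stats(dose, mask, nmv)
    if (st$n_voxels == 0L) stop("empty VOI: ", nmv)
    data.frame(voi = nmv, mean_dose = st$mean,
               dose_unit = dose$quantity,
               dose_per_admin = st$mean / denom,
               per_admin_unit = if (per_GBq)
                 sprintf("Sv_RBE%d_per_GBq", nuclide$rbe)
               else sprintf("Sv_RBE%d_per_MBq", nuclide$rbe),
               volume_ml = st$volume_ml, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
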