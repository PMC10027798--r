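# Forward model: project activity volumes into energy-windowed, noisy
# SPECT projections with attenuation, distance-dependent collimator-
# detector response (including a star-shaped septal-penetration
# component for the 440 keV regime) and emulated scatter windows.
#
# The projector is rotation-based: for each view the volume is rotated
# so the camera looks along +y, attenuated cumulatively towards the
# detector, and each constant-distance plane is convolved with the PSF
# kernel for its source-to-collimator distance before summation.

#' Energy window set for a photopeak and its scatter windows
#'
#' @param peak_keV,peak_frac_width photopeak centre and fractional
#'   width.
#' @param scatter data.frame with columns `center_keV`, `frac_width`,
#'   `position` (`"lower"`/`"upper"`).
#' @export
energy_window_set <- function(peak_keV, peak_frac_width, scatter) {
  stopifnot(peak_frac_width > 0, peak_frac_width < 1,
            all(scatter$frac_width > 0 & scatter$frac_width < 1),
            all(scatter$position %in% c("lower", "upper")))
  ws <- structure(list(peak_keV = peak_keV,
                       peak_frac_width = peak_frac_width,
                       scatter = scatter),
                  class = "energy_window_set")
  ws
}

#' Width of a window in keV
#' @param ws an [energy_window_set()].
#' @param which `"peak"`, `"lower"` or `"upper"`.
#' @export
window_width_keV <- function(ws, which = c("peak", "lower", "upper")) {
  which <- match.arg(which)
  if (which == "peak") return(ws$peak_keV * ws$peak_frac_width)
  row <- ws$scatter[ws$scatter$position == which, , drop = FALSE]
  if (nrow(row) == 0L) stop("no ", which, " scatter window configured")
  row$center_keV[1] * row$frac_width[1]
}

#' Default energy windows per nuclide
#'
#' Lu-177: 208 keV photopeak (15% width) with a lower scatter window at
#' 170 keV (15%) and an upper at 240 keV (10%). Ac-225 (imaging the
#' 440 keV Bi-213 gamma): 440 keV photopeak of 20% total width with a
#' lower adjacent scatter window of 10% width.
#'
#' @param nuclide `"lu177"` or `"ac225"`.
#' @export
default_windows <- function(nuclide = c("lu177", "ac225")) {
  nuclide <- match.arg(nuclide)
  if (nuclide == "lu177")
    energy_window_set(208, 0.15, data.frame(
      center_keV = c(170, 240), frac_width = c(0.15, 0.10),
      position = c("lower", "upper")))
  else
    energy_window_set(440, 0.20, data.frame(
      center_keV = 440, frac_width = 0.10, position = "lower"))
}

#' Acquisition geometry of a rotating dual-head camera
#'
#' @param n_views projections per head.
#' @param heads number of detector heads (mounted at
#'   `span_deg / heads` offsets; 2 heads at 180 degrees by default).
#' @param span_deg total angular span covered by all heads.
#' @param radius_mm radius of rotation (circular orbit).
#' @param time_per_view_s acquisition time per view in seconds.
#' @param det_pitch_mm detector pixel pitch (defaults to the clinical
#'   4.7952 mm).
#' @export
acquisition_geometry <- function(n_views = 16, heads = 2, span_deg = 360,
                                 radius_mm = 250, time_per_view_s = 210,
                                 det_pitch_mm = 4.7952) {
  stopifnot(n_views >= 1, heads >= 1, time_per_view_s > 0, radius_mm > 0)
  structure(list(n_views = as.integer(n_views), heads = as.integer(heads),
                 span_deg = span_deg, radius_mm = radius_mm,
                 time_per_view_s = time_per_view_s,
                 det_pitch_mm = det_pitch_mm),
            class = "acquisition_geometry")
}

#' View angles (degrees) of an acquisition
#' @param geom an [acquisition_geometry()].
#' @export
view_angles_deg <- function(geom) {
  step <- geom$span_deg / (geom$n_views * geom$heads)
  head_offset <- geom$span_deg / geom$heads
  angs <- as.vector(outer(
    (seq_len(geom$n_views) - 1) * step,
    (seq_len(geom$heads) - 1) * head_offset, `+`))
  sort(angs %% 360)
}

#' Construct a projection set
#'
#' @param views array `nx x nz x n_views` of (expected or observed)
#'   counts per detector pixel.
#' @param geom an [acquisition_geometry()].
#' @param window energy-window label, e.g. `"peak"`, `"lower"`.
#' @param nuclide nuclide label.
#' @param noise whether counts are a Poisson realization.
#' @param seed seed used for the realization (NA if noiseless).
#' @export
projection_set <- function(views, geom, window = "peak", nuclide = NA,
                           noise = FALSE, seed = NA_integer_) {
  views <- as.array(views)
  if (length(dim(views)) == 2L) dim(views) <- c(dim(views), 1L)
  if (any(views < 0)) stop("projection counts must be >= 0")
  if (dim(views)[3] != geom$n_views * geom$heads)
    stop("number of views does not match geometry")
  structure(list(views = views, geom = geom,
                 angles_deg = view_angles_deg(geom),
                 window = window, nuclide = nuclide, noise = noise,
                 seed = seed),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf("<projection_set> %s %s, %d views, %.3g total counts%s\n",
              ifelse(is.na(x$nuclide), "", x$nuclide), x$window,
              dim(x$views)[3], sum(x$views),
              if (x$noise) " (noisy)" else ""))
  invisible(x)
}

# Mass attenuation coefficients of water, mu/rho in cm^2/g (NIST XCOM
# grid); linear attenuation is interpolated log-log in energy and
# scaled by local density.
.water_mu_rho <- data.frame(
  keV = c(50, 60, 80, 100, 150, 200, 300, 400, 500, 600, 800, 1000),
  mu_rho = c(0.2269, 0.2059, 0.1837, 0.1707, 0.1505, 0.1370, 0.1186,
             0.1061, 0.09687, 0.08956, 0.07865, 0.07072))

#' Attenuation map from a density volume
#'
#' mu[mm^-1] = density[g/ml] x (mu/rho of water at the photon energy),
#' i.e. tissue is treated as density-scaled water, the standard
#' CT-based attenuation-correction model.
#'
#' @param density a density [volume_image()] (g/ml).
#' @param energy_keV photon energy; must lie inside the built-in table
#'   (50-1000 keV).
#' @export
mu_map_from_density <- function(density, energy_keV) {
  stopifnot(density$quantity == "density_g_per_ml")
  tb <- .water_mu_rho
  if (energy_keV < min(tb$keV) || energy_keV > max(tb$keV))
    stop("energy ", energy_keV, " keV outside attenuation table range")
  mu_rho <- exp(stats::approx(log(tb$keV), log(tb$mu_rho),
                              xout = log(energy_keV))$y)
  mu <- density$values * mu_rho / 10  # cm^2/g * g/cm^3 -> cm^-1 -> mm^-1
  volume_image(mu, density$grid, "mu_per_mm",
               meta = list(energy_keV = energy_keV))
}

#' Analytic collimator-detector-response kernel stack
#'
#' Builds the stack of 2-D PSF kernels indexed by source-to-collimator
#' distance. The `"gaussian"` regime (Lu-177 at 208 keV) uses isotropic
#' Gaussians with FWHM(d) = sqrt(intrinsic^2 + (slope * d)^2). The
#' `"high_energy"` regime (440 keV) adds a star of `2 * arm_pairs`
#' exponential-decay arms carrying the septal-penetration fraction
#' `penetration`, at 60-degree spacing by default (hexagonal collimator
#' symmetry); the Gaussian core carries `1 - penetration`. Every kernel
#' is normalized to unit sum.
#'
#' @param regime `"gaussian"` or `"high_energy"`.
#' @param intrinsic_fwhm_mm system resolution at distance zero.
#' @param slope_mm_per_mm FWHM growth per mm of distance.
#' @param penetration septal-penetration count fraction in `[0, 1)`.
#' @param arm_pairs number of opposite arm pairs (3 = hexagonal star).
#' @param arm_decay_mm exponential decay length of the arms.
#' @param arm_phase_deg orientation of the first arm.
#' @param pitch_mm detector pixel pitch the kernels are sampled on.
#' @param n_planes,max_distance_mm distance sampling of the stack.
#' @return A `psf_stack` object: `distances`, `kernels` (one matrix per
#'   distance), and the model parameters.
#' @export
analytic_psf_stack <- function(regime = c("gaussian", "high_energy"),
                               intrinsic_fwhm_mm = 4.5,
                               slope_mm_per_mm = 0.055,
                               penetration = 0,
                               arm_pairs = 3,
                               arm_decay_mm = 15,
                               arm_phase_deg = 0,
                               pitch_mm = 4.7952,
                               n_planes = 150,
                               max_distance_mm = 600) {
  regime <- match.arg(regime)
  stopifnot(intrinsic_fwhm_mm > 0, slope_mm_per_mm >= 0,
            penetration >= 0, penetration < 1, arm_decay_mm > 0,
            arm_pairs >= 1, n_planes >= 2)
  if (regime == "gaussian") penetration <- 0
  distances <- seq(0, max_distance_mm, length.out = n_planes)
  kernels <- lapply(distances, function(d)
    .psf_kernel(d, intrinsic_fwhm_mm, slope_mm_per_mm, penetration,
                arm_pairs, arm_decay_mm, arm_phase_deg, pitch_mm))
  structure(list(distances = distances, kernels = kernels,
                 regime = regime,
                 params = list(intrinsic_fwhm_mm = intrinsic_fwhm_mm,
                               slope_mm_per_mm = slope_mm_per_mm,
                               penetration = penetration,
                               arm_pairs = arm_pairs,
                               arm_decay_mm = arm_decay_mm,
                               arm_phase_deg = arm_phase_deg,
                               pitch_mm = pitch_mm)),
            class = "psf_stack")
}

#' A delta (identity) PSF stack, useful for idealized runs
#' @param pitch_mm detector pixel pitch.
#' @export
psf_delta <- function(pitch_mm = 4.7952) {
  k <- matrix(1, 1, 1)
  structure(list(distances = c(0, 1e6), kernels = list(k, k),
                 regime = "delta",
                 params = list(pitch_mm = pitch_mm)),
            class = "psf_stack")
}

# Sparse star of 2 * arm_pairs exponential-decay arms, bilinearly
# deposited on the pixel lattice and normalized to unit sum. The star
# is distance-independent (fixed decay length), which lets the
# projector apply it once per view; it is exactly centrosymmetric by
# construction (opposite arm pairs with negated offsets).
.arm_star_points <- function(arm_pairs, arm_decay, arm_phase, pitch,
                             trunc_decays = 4) {
  step <- pitch / 2
  radii <- seq(step, trunc_decays * arm_decay, by = step)
  w_rad <- exp(-radii / arm_decay)
  angles <- (arm_phase + (0:(2 * arm_pairs - 1)) * 180 / arm_pairs) *
    pi / 180
  dx <- dz <- ww <- numeric(0)
  for (a in angles) {
    xs <- radii * cos(a) / pitch
    zs <- radii * sin(a) / pitch
    x0 <- floor(xs); z0 <- floor(zs)
    fx <- xs - x0; fz <- zs - z0
    for (q in 1:4) {
      qx <- (q - 1) %% 2
      qz <- (q - 1) %/% 2
      wq <- (if (qx == 1) fx else 1 - fx) *
        (if (qz == 1) fz else 1 - fz) * w_rad
      dx <- c(dx, x0 + qx); dz <- c(dz, z0 + qz); ww <- c(ww, wq)
    }
  }
  keep <- ww > 0
  key <- paste(dx[keep], dz[keep])
  acc <- rowsum(ww[keep], key)
  parts <- do.call(rbind, strsplit(rownames(acc), " "))
  cbind(dx = as.integer(parts[, 1]), dz = as.integer(parts[, 2]),
        w = acc[, 1] / sum(acc[, 1]))
}

# Pixel-integrated 1-D Gaussian taps (normalized, symmetric).
.gauss_taps <- function(sigma_mm, pitch) {
  h <- max(1L, ceiling(3 * sigma_mm / pitch))
  off <- (-h:h) * pitch
  g <- stats::pnorm(off + pitch / 2, 0, sigma_mm) -
    stats::pnorm(off - pitch / 2, 0, sigma_mm)
  g / sum(g)
}

.psf_sigma_mm <- function(d, intrinsic, slope)
  sqrt(intrinsic^2 + (slope * d)^2) / (2 * sqrt(2 * log(2)))

# One dense 2-D kernel K_d = (1 - p) G_d + p (G_d * star): the
# user-facing realization of the factorized model the projector
# applies.
.psf_kernel <- function(d, intrinsic, slope, penetration, arm_pairs,
                        arm_decay, arm_phase, pitch) {
  sigma <- .psf_sigma_mm(d, intrinsic, slope)
  r_gauss <- max(3 * sigma, pitch)
  r_arm <- if (penetration > 0) 4 * arm_decay else 0
  h <- ceiling(max(r_gauss, r_arm) / pitch)
  n <- 2L * h + 1L
  g1 <- .gauss_taps(sigma, pitch)
  gh <- (length(g1) - 1L) %/% 2L
  g1n <- numeric(n)
  src <- intersect(seq_len(n), (h + 1 - gh):(h + 1 + gh))
  g1n[src] <- g1[src - h + gh]
  core <- outer(g1n, g1n)
  core <- core / sum(core)
  if (penetration == 0) return(core)
  pts <- .arm_star_points(arm_pairs, arm_decay, arm_phase, pitch)
  arms <- matrix(0, n, n)
  inb <- abs(pts[, "dx"]) <= h & abs(pts[, "dz"]) <= h
  arms[cbind(pts[inb, "dx"] + h + 1, pts[inb, "dz"] + h + 1)] <-
    pts[inb, "w"]
  arms <- .conv2_full_trim(arms, core)
  arms <- arms / sum(arms)
  (1 - penetration) * core + penetration * arms
}

# Small same-size 2-D convolution used only at kernel-build time.
.conv2_full_trim <- function(a, k) {
  na <- nrow(a); ma <- ncol(a)
  nk <- nrow(k); mk <- ncol(k)
  hn <- (nk - 1) %/% 2; hm <- (mk - 1) %/% 2
  out <- matrix(0, na, ma)
  for (i in seq_len(nk)) for (j in seq_len(mk)) {
    w <- k[i, j]
    if (w == 0) next
    di <- i - 1 - hn; dj <- j - 1 - hm
    si <- max(1, 1 - di):min(na, na - di)
    sj <- max(1, 1 - dj):min(ma, ma - dj)
    out[si + di, sj + dj] <- out[si + di, sj + dj] + w * a[si, sj]
  }
  out
}

#' Measure the FWHM of a PSF kernel
#' @param kernel 2-D kernel matrix.
#' @param pitch_mm pixel pitch.
#' @export
kernel_fwhm_mm <- function(kernel, pitch_mm) {
  h <- (nrow(kernel) - 1) / 2
  prof <- kernel[, h + 1]
  x <- (-h:h) * pitch_mm
  hm <- max(prof) / 2
  above <- which(prof >= hm)
  if (length(above) < 1) return(0)
  lo <- min(above); hi <- max(above)
  interp <- function(i1, i2) {
    if (i2 < 1 || i2 > length(prof) || prof[i1] == prof[i2])
      return(x[i1])
    x[i2] + (hm - prof[i2]) / (prof[i1] - prof[i2]) * (x[i1] - x[i2])
  }
  interp(hi, hi + 1) - interp(lo, lo - 1)
}

# ---- internal projector system ------------------------------------------

# Precompute everything fixed across MLEM iterations for one (grid,
# geometry, psf, mu) combination: per-view attenuation volumes (rotated
# frame), the per-plane Gaussian-group mapping, the Gaussian taps per
# group and the shared septal-penetration star. Distances are quantized
# to bins of psf_bin_mm: the PSF varies slowly with distance, so planes
# within a bin share one blur.
.build_system <- function(grid, geom, psf, mu = NULL, psf_bin_mm = 15) {
  if (!is.null(mu)) stop_if_grid_mismatch(grid, mu$grid)
  shape <- grid$shape
  dy <- grid$spacing[2]
  y_world <- grid_axes(grid)[[2]]
  dist <- pmin(pmax(geom$radius_mm - y_world, 0), max(psf$distances))
  bin <- floor(dist / psf_bin_mm)
  ubin <- sort(unique(bin))
  group <- match(bin, ubin)
  pitch <- grid$spacing[1]
  pr <- psf$params
  if (psf$regime == "delta") {
    taps <- lapply(ubin, function(b) 1)
    star <- cbind(dx = 0, dz = 0, w = 1)
  } else {
    taps <- lapply(ubin, function(b) {
      d <- min((b + 0.5) * psf_bin_mm, max(psf$distances))
      .gauss_taps(.psf_sigma_mm(d, pr$intrinsic_fwhm_mm,
                                pr$slope_mm_per_mm), pitch)
    })
    p <- pr$penetration
    star <- if (p > 0) {
      pts <- .arm_star_points(pr$arm_pairs, pr$arm_decay_mm,
                              pr$arm_phase_deg, pitch)
      rbind(cbind(dx = 0, dz = 0, w = 1 - p),
            cbind(pts[, 1:2, drop = FALSE], w = p * pts[, 3]))
    } else cbind(dx = 0, dz = 0, w = 1)
  }
  angles <- view_angles_deg(geom) * pi / 180
  att <- vector("list", length(angles))
  if (!is.null(mu)) {
    for (v in seq_along(angles)) {
      mur <- array(.cpp_rotate_z(as.numeric(mu$values), shape,
                                 angles[v], TRUE), shape)
      # Path integral from each voxel towards the detector at +y:
      # half of the local voxel plus all planes beyond it.
      path <- apply(mur[, rev(seq_len(shape[2])), , drop = FALSE], c(1, 3),
                    cumsum)                       # y_rev x nx x nz
      path <- aperm(path, c(2, 1, 3))[, rev(seq_len(shape[2])), , drop = FALSE]
      att[[v]] <- exp(-dy * (path - mur / 2))
    }
  }
  list(grid = grid, geom = geom, shape = shape, angles = angles,
       group = group, taps = taps, star = star, att = att,
       n_views = length(angles))
}

# Forward projection of a raw voxel array through the system.
# scale_per_view multiplies each view (e.g. time per view).
.sys_forward <- function(x, sys, scale_per_view = 1,
                         views = seq_len(sys$n_views)) {
  if (length(scale_per_view) == 1L)
    scale_per_view <- rep(scale_per_view, sys$n_views)
  shape <- sys$shape
  out <- array(0, c(shape[1], shape[3], length(views)))
  for (i in seq_along(views)) {
    v <- views[i]
    xr <- array(.cpp_rotate_z(as.numeric(x), shape, sys$angles[v], TRUE),
                shape)
    if (!is.null(sys$att[[v]])) xr <- xr * sys$att[[v]]
    out[, , i] <- .cpp_project_view(as.numeric(xr), shape, sys$group,
                                    sys$taps, sys$star) * scale_per_view[v]
  }
  out
}

# Exact adjoint of .sys_forward.
.sys_back <- function(p, sys, scale_per_view = 1,
                      views = seq_len(sys$n_views)) {
  if (length(scale_per_view) == 1L)
    scale_per_view <- rep(scale_per_view, sys$n_views)
  shape <- sys$shape
  out <- array(0, shape)
  for (i in seq_along(views)) {
    v <- views[i]
    bp <- .cpp_backproject_view(p[, , i] * scale_per_view[v], shape,
                                sys$taps, sys$star)
    tmp <- aperm(bp[, , sys$group, drop = FALSE], c(1, 3, 2))
    if (!is.null(sys$att[[v]])) tmp <- tmp * sys$att[[v]]
    out <- out + array(.cpp_rotate_z(as.numeric(tmp), shape,
                                     sys$angles[v], FALSE), shape)
  }
  out
}

#' Forward-project an activity volume into SPECT projections
#'
#' Noiseless expected counts per view: time-per-view x sensitivity x
#' attenuated, PSF-blurred line integrals of the activity. Linear in
#' the activity.
#'
#' @param activity [volume_image()] in Bq/ml.
#' @param mu attenuation [volume_image()] in mm^-1, or `NULL` for none.
#' @param psf a PSF stack from [analytic_psf_stack()] or [psf_delta()].
#' @param geom an [acquisition_geometry()].
#' @param sensitivity_cps_per_MBq system sensitivity (counts/s per MBq
#'   in the photopeak window).
#' @param psf_bin_mm distance-quantization width for kernel reuse.
#' @return A [projection_set()] of expected counts.
#' @export
forward_project <- function(activity, mu, psf, geom,
                            sensitivity_cps_per_MBq = 22.7,
                            psf_bin_mm = 15) {
  stopifnot(activity$quantity == "activity_conc_Bq_per_ml")
  sys <- .build_system(activity$grid, geom, psf, mu, psf_bin_mm)
  x_MBq <- activity$values * voxel_volume_ml(activity$grid) * 1e-6
  views <- .sys_forward(x_MBq, sys,
                        sensitivity_cps_per_MBq * geom$time_per_view_s)
  projection_set(views, geom, window = "peak",
                 nuclide = activity$meta$nuclide, noise = FALSE)
}

#' Emulate photopeak and scatter energy windows
#'
#' A parametric stand-in for photon scatter: the photopeak window
#' receives the primary counts plus `scatter_fraction` times a
#' broad-Gaussian-blurred copy of them; each scatter window receives a
#' configured fraction of the same blurred component. The default
#' window fractions are chosen so that the TEW/DEW estimate of the
#' injected scatter is exact for noiseless data (closed-form inversion
#' of the window formulas).
#'
#' @param primary noiseless peak [projection_set()].
#' @param windows an [energy_window_set()].
#' @param scatter_fraction scatter-to-primary ratio in the photopeak.
#' @param scatter_fwhm_mm FWHM of the scatter blur.
#' @param window_fractions optional named fractions (`lower`, `upper`)
#'   of the blurred component per scatter window; defaults invert the
#'   TEW/DEW formula exactly.
#' @return Named list of projection sets: `peak` plus one per scatter
#'   window (`lower`, `upper`).
#' @export
emulate_scatter_windows <- function(primary, windows,
                                    scatter_fraction = 0.3,
                                    scatter_fwhm_mm = 60,
                                    window_fractions = NULL) {
  if (scatter_fraction < 0) stop("scatter fraction must be >= 0")
  stopifnot(!primary$noise)
  w_p <- window_width_keV(windows, "peak")
  tags <- windows$scatter$position
  if (is.null(window_fractions)) {
    denom <- length(tags)  # split the inversion evenly over windows
    window_fractions <- stats::setNames(vapply(tags, function(tg) {
      w_s <- window_width_keV(windows, tg)
      scatter_fraction * 2 * w_s / (w_p * denom)
    }, numeric(1)), tags)
  }
  if (any(window_fractions < 0)) stop("window fractions must be >= 0")
  blurred <- primary$views
  if (scatter_fraction > 0) {
    sig_px <- scatter_fwhm_mm / (2 * sqrt(2 * log(2))) /
      primary$geom$det_pitch_mm
    for (v in seq_len(dim(blurred)[3]))
      blurred[, , v] <- .gauss_blur_2d(primary$views[, , v], sig_px)
  } else blurred[] <- 0
  out <- list(peak = projection_set(
    primary$views + scatter_fraction * blurred, primary$geom,
    window = "peak", nuclide = primary$nuclide))
  for (tg in tags)
    out[[tg]] <- projection_set(window_fractions[[tg]] * blurred,
                                primary$geom, window = tg,
                                nuclide = primary$nuclide)
  out
}

# Separable 2-D Gaussian blur with symmetric (half-sample) padding.
.gauss_blur_2d <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  h <- max(1L, ceiling(4 * sigma_px))
  k <- stats::dnorm(-h:h, 0, sigma_px)
  k <- k / sum(k)
  m <- .conv1_sym(m, k, 1L)
  .conv1_sym(m, k, 2L)
}

# 1-D convolution along a matrix margin with symmetric padding;
# conserves the total for symmetric kernels.
.conv1_sym <- function(m, k, margin) {
  h <- (length(k) - 1L) %/% 2L
  n <- dim(m)[margin]
  idx <- .mirror_index((1L - h):(n + h), n)
  pad <- if (margin == 1L) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
  out <- m * 0
  for (i in seq_along(k)) {
    sl <- (i - 1L) + seq_len(n)
    out <- out + k[i] * (if (margin == 1L) pad[sl, , drop = FALSE]
                         else pad[, sl, drop = FALSE])
  }
  out
}

#' Add Poisson counting noise to expected projections
#'
#' Low-count (LC) mode emulates a reduced acquisition: the expected
#' counts (and the recorded time per view) are divided by
#' `lc_time_factor` before drawing.
#'
#' @param p a noiseless [projection_set()] of expected counts.
#' @param seed integer seed; a fixed seed reproduces the realization.
#' @param lc_time_factor time-reduction factor (default 1 = as
#'   acquired; 30 = the clinical low-count emulation).
#' @export
add_poisson_noise <- function(p, seed, lc_time_factor = 1) {
  stopifnot(lc_time_factor > 0)
  lam <- p$views / lc_time_factor
  set.seed(as.integer(seed))
  draws <- array(stats::rpois(length(lam), lam), dim(lam))
  geom <- p$geom
  geom$time_per_view_s <- geom$time_per_view_s / lc_time_factor
  projection_set(draws, geom, window = p$window, nuclide = p$nuclide,
                 noise = TRUE, seed = as.integer(seed))
}
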