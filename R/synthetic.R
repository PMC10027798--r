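# Synthetic-data generators: the digital twin of the cylinder phantom
# used for the figure-of-merit study, and synthetic tandem-therapy
# patients with a fully known ground truth against which parameter
# recovery is tested.

#' Draw from a normal truncated to positive values
#' @noRd
.rtnorm_pos <- function(n, mean, sd, lower = 0) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (k in 1:1000) {
      x <- stats::rnorm(1, mean, sd)
      if (x > lower) break
    }
    if (x <= lower) x <- lower + abs(mean - lower)
    out[i] <- x
  }
  out
}

#' Draw from a log-normal moment-matched to a printed mean +/- sd
#' @noRd
.rlnorm_matched <- function(n, mean, sd, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  sdlog2 <- log(1 + (sd / mean)^2)
  meanlog <- log(mean) - sdlog2 / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- stats::rlnorm(1, meanlog, sqrt(sdlog2))
    for (k in 1:1000) {
      if (x < upper) break
      x <- stats::rlnorm(1, meanlog, sqrt(sdlog2))
    }
    out[i] <- min(x, upper * 0.999)
  }
  out
}

#' Specification of the cylinder quality-control phantom
#'
#' Digitizes a plastic QC phantom: a 3.5 l cylindrical body holding
#' three fillable inserts of roughly 200, 45 and 20 ml (kidney,
#' salivary-gland and typical-lesion sized) at a foreground-to-
#' background concentration ratio of 6.4:1. The high-count (HC) filling
#' corresponds to a total activity of about 4.5 MBq; the low-count (LC)
#' variant emulates the clinical signal by dividing the acquisition
#' time per view by `lc_time_factor`.
#'
#' @param background_Bq_per_ml background activity concentration.
#' @param fg_bg_ratio insert-to-background concentration ratio.
#' @param count_mode `"HC"` or `"LC"`.
#' @param lc_time_factor time-reduction factor applied in LC mode.
#' @param body geometry of the phantom body (defaults to a 3.53 l
#'   cylinder, radius 101 mm, height 110 mm).
#' @param inserts named list of insert geometries; defaults are three
#'   spheres of 200/45/20 ml placed around the cylinder axis.
#' @param bg_rods named list of background-VOI geometries; defaults to
#'   five ~100 ml rods placed between and around the default inserts.
#'   Pass `list()` for custom layouts without background VOIs.
#' @export
phantom_spec <- function(background_Bq_per_ml = 900,
                         fg_bg_ratio = 6.4,
                         count_mode = c("HC", "LC"),
                         lc_time_factor = 30,
                         body = NULL, inserts = NULL, bg_rods = NULL) {
  count_mode <- match.arg(count_mode)
  stopifnot(background_Bq_per_ml >= 0, fg_bg_ratio > 0, lc_time_factor > 0)
  if (is.null(body))
    body <- geometry_spec("cylinder", c(0, 0, 0), radius = 101, height = 110)
  if (is.null(inserts)) {
    r_for_ml <- function(ml) (3 * ml * 1000 / (4 * pi))^(1 / 3)
    pos <- function(r, a) c(r * cos(a * pi / 180), r * sin(a * pi / 180), 0)
    inserts <- list(
      insert_200ml = geometry_spec("sphere", pos(62, 0), radius = r_for_ml(200)),
      insert_45ml = geometry_spec("sphere", pos(58, 120), radius = r_for_ml(45)),
      insert_20ml = geometry_spec("sphere", pos(58, 240), radius = r_for_ml(20)))
  }
  if (is.null(bg_rods)) bg_rods <- .default_bg_rods()
  structure(list(background_Bq_per_ml = background_Bq_per_ml,
                 fg_bg_ratio = fg_bg_ratio, count_mode = count_mode,
                 lc_time_factor = lc_time_factor,
                 body = body, inserts = inserts, bg_rods = bg_rods),
            class = "phantom_spec")
}

#' Default five 100-ml rod-shaped background VOIs
#'
#' Rods (radius 17.85 mm, height 100 mm, about 100 ml each) placed
#' between and around the inserts of the default phantom layout.
#' @noRd
.default_bg_rods <- function() {
  pos <- function(r, a) c(r * cos(a * pi / 180), r * sin(a * pi / 180), 0)
  rod <- function(center) geometry_spec("cylinder", center,
                                        radius = 17.85, height = 100)
  list(bg_rod_1 = rod(c(0, 0, 0)),
       bg_rod_2 = rod(pos(70, 60)),
       bg_rod_3 = rod(pos(70, 170)),
       bg_rod_4 = rod(pos(70, 200)),
       bg_rod_5 = rod(pos(70, 290)))
}

#' Build the digital cylinder phantom
#'
#' Returns the activity and density volumes, a VOI mask holding the
#' inserts plus five 100-ml rod-shaped background VOIs, and a ground
#' truth record.
#'
#' @param spec a [phantom_spec()].
#' @param grid a [voxel_grid()]; the default 64 x 64 x 32 grid at the
#'   clinical 4.7952 mm pixel pitch comfortably contains the phantom.
#' @return list with `activity` (Bq/ml), `density` (g/ml; 1.0 water
#'   inside the body, 0 air outside), `mask`, `truth`.
#' @export
build_cylinder_phantom <- function(spec = phantom_spec(),
                                   grid = voxel_grid(c(64, 64, 32), 4.7952)) {
  body_in <- .inside_geometry(spec$body, grid)
  insert_in <- lapply(spec$inserts, .inside_geometry, grid = grid)
  for (i in seq_along(insert_in)) {
    if (!all(body_in[insert_in[[i]]]))
      stop("insert ", names(spec$inserts)[i], " extends outside the body")
    if (i > 1L) for (j in seq_len(i - 1L))
      if (any(insert_in[[i]] & insert_in[[j]]))
        stop("overlapping inserts: ", names(spec$inserts)[i], " and ",
             names(spec$inserts)[j])
  }
  fg <- spec$background_Bq_per_ml * spec$fg_bg_ratio
  act <- array(0, grid$shape)
  act[body_in] <- spec$background_Bq_per_ml
  for (m in insert_in) act[m] <- fg
  dens <- array(0, grid$shape)
  dens[body_in] <- 1.0

  labels <- array(0L, grid$shape)
  nm <- integer(0)
  lab <- 0L
  for (i in seq_along(insert_in)) {
    lab <- lab + 1L
    labels[insert_in[[i]]] <- lab
    nm[names(spec$inserts)[i]] <- lab
  }
  for (rn in names(spec$bg_rods)) {
    rod_in <- .inside_geometry(spec$bg_rods[[rn]], grid)
    if (any(labels[rod_in] != 0L))
      stop("background rod ", rn, " overlaps an insert")
    lab <- lab + 1L
    labels[rod_in] <- lab
    nm[rn] <- lab
  }
  mask <- voi_mask(labels, grid, nm)

  vol_ml <- voxel_volume_ml(grid)
  insert_vox <- vapply(insert_in, sum, integer(1))
  total_MBq <- sum(act) * vol_ml * 1e-6
  truth <- list(
    kind = "phantom",
    background_Bq_per_ml = spec$background_Bq_per_ml,
    insert_Bq_per_ml = stats::setNames(rep(fg, length(insert_in)),
                                       names(spec$inserts)),
    fg_bg_ratio = spec$fg_bg_ratio,
    insert_volume_ml = insert_vox * vol_ml,
    total_activity_MBq = total_MBq,
    count_mode = spec$count_mode,
    lc_time_factor = spec$lc_time_factor)

  list(activity = volume_image(act, grid, "activity_conc_Bq_per_ml",
                               meta = list(nuclide = "ac225", time_h = 0)),
       density = volume_image(dens, grid, "density_g_per_ml"),
       mask = mask, truth = truth)
}

#' Specification of a synthetic tandem-therapy patient
#'
#' Emulates the printed cohort statistics of a tandem Lu-177/Ac-225
#' PSMA therapy: kidney and lesion SUV distributions per nuclide,
#' Lu-177 effective half-life distributions, lesion volumes around
#' 21 +/- 13 ml, and injected activities of 1000 MBq Lu-177 and 8 MBq
#' Ac-225.
#'
#' The Ac-225 SUV of each VOI is generated as the Lu-177 SUV times a
#' paired ratio whose mean is the ratio of the per-nuclide SUV means
#' (so zero-sd cohorts reproduce both printed means exactly) and whose
#' sd reflects the printed paired spread.
#'
#' @param n_lesions number of lesions.
#' @param kidney_suv_lu,kidney_suv_ac,lesion_suv_lu,lesion_suv_ac
#'   `(mean, sd)` of truncated-normal SUV distributions at 24 h.
#' @param kidney_teff_lu,lesion_teff_lu `(mean h, sd h)` of log-normal
#'   (moment-matched) Lu-177 effective half-life distributions.
#' @param paired_ratio_sd sd of the paired Ac/Lu SUV ratio, kidneys and
#'   lesions.
#' @param lesion_volume_ml `(mean, sd)` of truncated-normal lesion
#'   volumes.
#' @param injected_MBq named injected activities.
#' @param weight_kg body weight.
#' @param background_suv,background_teff_h uptake of body tissue
#'   outside any VOI and its effective half-life.
#' @param seed integer seed driving every random draw.
#' @export
synthetic_patient_spec <- function(n_lesions = 3,
                                   kidney_suv_lu = c(2.1, 0.9),
                                   kidney_suv_ac = c(2.5, 0.8),
                                   lesion_suv_lu = c(2.1, 1.5),
                                   lesion_suv_ac = c(1.8, 1.1),
                                   kidney_teff_lu = c(31, 17),
                                   lesion_teff_lu = c(51, 39),
                                   paired_ratio_sd = c(kidney = 0.23,
                                                       lesion = 0.32),
                                   lesion_volume_ml = c(21, 13),
                                   injected_MBq = c(lu177 = 1000, ac225 = 8),
                                   weight_kg = 80,
                                   background_suv = 0.3,
                                   background_teff_h = 25,
                                   seed = 1L) {
  chk2 <- function(x) stopifnot(length(x) == 2L, x[1] > 0, x[2] >= 0)
  chk2(kidney_suv_lu); chk2(kidney_suv_ac)
  chk2(lesion_suv_lu); chk2(lesion_suv_ac)
  chk2(kidney_teff_lu); chk2(lesion_teff_lu); chk2(lesion_volume_ml)
  stopifnot(n_lesions >= 0, all(injected_MBq > 0), weight_kg > 0,
            background_suv >= 0, background_teff_h > 0,
            all(paired_ratio_sd >= 0))
  structure(list(n_lesions = as.integer(n_lesions),
                 kidney_suv_lu = kidney_suv_lu,
                 kidney_suv_ac = kidney_suv_ac,
                 lesion_suv_lu = lesion_suv_lu,
                 lesion_suv_ac = lesion_suv_ac,
                 kidney_teff_lu = kidney_teff_lu,
                 lesion_teff_lu = lesion_teff_lu,
                 paired_ratio_sd = paired_ratio_sd,
                 lesion_volume_ml = lesion_volume_ml,
                 injected_MBq = injected_MBq, weight_kg = weight_kg,
                 background_suv = background_suv,
                 background_teff_h = background_teff_h,
                 seed = as.integer(seed)),
            class = "synthetic_patient_spec")
}

# SUV -> activity concentration at the reference time, standard SUV
# convention: conc[Bq/ml] = SUV * (decayed injected activity [Bq] /
# body mass [g]) * rho, with rho = 1 g/ml for the conversion.
.suv_to_conc <- function(suv, injected_MBq, weight_kg, t_h, t_phys_h) {
  suv * injected_MBq * 1e6 * 2^(-t_h / t_phys_h) / (weight_kg * 1000)
}

# Local-deposition analytic absorbed dose (Gy) for a VOI with uniform
# concentration conc at the reference time and mono-exponential decay:
# TIA density integrated 0 -> Inf times energy per decay over mass.
.analytic_local_dose_Gy <- function(conc_Bq_per_ml, teff_h, t_star_h,
                                    energy_MeV, rho_g_per_ml = 1.04) {
  tia <- conc_Bq_per_ml * exp(log(2) * t_star_h / teff_h) * teff_h / log(2)
  decays_per_ml <- tia * 3600
  decays_per_ml * energy_MeV * 1.602176634e-13 / (rho_g_per_ml * 1e-3)
}

#' Build a synthetic tandem-therapy patient
#'
#' Places two kidney ellipsoids, `n_lesions` spherical lesions and one
#' rod-shaped background-reference VOI inside a torso-like soft-tissue
#' cylinder, draws per-VOI SUVs and effective half-lives from the
#' cohort distributions of `spec`, and returns activity maps for
#' Lu-177 at 24 h and 48 h and for Ac-225 (imaged via Bi-213) at 24 h,
#' together with the density map, the VOI mask and a ground-truth
#' record from which every downstream quantity can be recomputed.
#'
#' @param spec a [synthetic_patient_spec()].
#' @param grid a [voxel_grid()]; the default is 96 x 96 x 64 voxels at
#'   the clinical 4.7952 mm pitch.
#' @param rho_soft_g_per_ml soft-tissue density assigned to the body.
#' @return list with `activity` (named list `lu177_24h`, `lu177_48h`,
#'   `ac225_24h`), `density`, `mask`, `truth`.
#' @export
build_synthetic_patient <- function(spec = synthetic_patient_spec(),
                                    grid = voxel_grid(c(96, 96, 64), 4.7952),
                                    rho_soft_g_per_ml = 1.04) {
  set.seed(spec$seed)
  lu <- builtin_nuclide("lu177")
  ac <- builtin_nuclide("ac225")
  t_star <- 24

  body_r <- 140
  body_h <- min(280, (grid$shape[3] - 2) * grid$spacing[3])
  body <- geometry_spec("cylinder", c(0, 0, 0), radius = body_r,
                        height = body_h)
  kidneys <- list(
    kidney_left = geometry_spec("ellipsoid", c(-55, 30, 0),
                                semi_axes = c(28, 18, 50)),
    kidney_right = geometry_spec("ellipsoid", c(55, 30, 0),
                                 semi_axes = c(28, 18, 50)))
  bg_rod <- geometry_spec("cylinder", c(0, -80, 0), radius = 20, height = 120)

  # Lesions: draw volumes, then place without overlap (bounded retries).
  vols <- .rtnorm_pos(spec$n_lesions, spec$lesion_volume_ml[1],
                      spec$lesion_volume_ml[2], lower = 1)
  lesions <- list()
  for (i in seq_len(spec$n_lesions)) {
    r_les <- (3 * vols[i] * 1000 / (4 * pi))^(1 / 3)
    placed <- FALSE
    for (try in 1:200) {
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1)) * (body_r - r_les - 8)
      zmax <- body_h / 2 - r_les - 5
      ctr <- c(rad * cos(ang), rad * sin(ang), stats::runif(1, -zmax, zmax))
      ok <- TRUE
      for (k in kidneys)
        if (sqrt(sum((ctr - k$center)^2)) < max(k$semi_axes) + r_les + 3)
          ok <- FALSE
      if (sqrt(sum((ctr[1:2] - bg_rod$center[1:2])^2)) <
            bg_rod$radius + r_les + 3 &&
          abs(ctr[3]) < bg_rod$height / 2 + r_les + 3) ok <- FALSE
      for (l in lesions)
        if (sqrt(sum((ctr - l$center)^2)) < l$radius + r_les + 3) ok <- FALSE
      if (ok) {
        lesions[[sprintf("lesion_%02d", i)]] <-
          geometry_spec("sphere", ctr, radius = r_les)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place lesion ", i, " without overlap")
  }

  # Per-VOI draws: Lu SUV, paired Ac/Lu ratio, Lu effective half-life.
  n_k <- length(kidneys); n_l <- length(lesions)
  suv_lu_k <- .rtnorm_pos(n_k, spec$kidney_suv_lu[1], spec$kidney_suv_lu[2])
  ratio_k <- .rtnorm_pos(n_k, spec$kidney_suv_ac[1] / spec$kidney_suv_lu[1],
                         spec$paired_ratio_sd[["kidney"]], lower = 0.05)
  suv_lu_l <- .rtnorm_pos(n_l, spec$lesion_suv_lu[1], spec$lesion_suv_lu[2])
  ratio_l <- .rtnorm_pos(n_l, spec$lesion_suv_ac[1] / spec$lesion_suv_lu[1],
                         spec$paired_ratio_sd[["lesion"]], lower = 0.05)
  teff_k <- .rlnorm_matched(n_k, spec$kidney_teff_lu[1],
                            spec$kidney_teff_lu[2],
                            upper = 0.95 * lu$half_life_h)
  teff_l <- .rlnorm_matched(n_l, spec$lesion_teff_lu[1],
                            spec$lesion_teff_lu[2],
                            upper = 0.95 * lu$half_life_h)

  vois <- data.frame(
    name = c(names(kidneys), names(lesions)),
    type = c(rep("kidney", n_k), rep("lesion", n_l)),
    suv_lu = c(suv_lu_k, suv_lu_l),
    suv_ac = c(suv_lu_k * ratio_k, suv_lu_l * ratio_l),
    teff_lu_h = c(teff_k, teff_l),
    stringsAsFactors = FALSE)
  vois$teff_ac_h <- vapply(vois$teff_lu_h, convert_effective_half_life,
                           numeric(1), from_nuclide = lu, to_nuclide = ac)

  # Rasterize.
  body_in <- .inside_geometry(body, grid)
  geoms <- c(kidneys, lesions)
  labels <- array(0L, grid$shape)
  nm <- integer(0)
  voi_in <- list()
  for (i in seq_along(geoms)) {
    m <- .inside_geometry(geoms[[i]], grid)
    if (any(labels[m] != 0L)) stop("overlapping VOIs in patient layout")
    labels[m] <- i
    nm[names(geoms)[i]] <- i
    voi_in[[i]] <- m
  }
  rod_in <- .inside_geometry(bg_rod, grid) & labels == 0L
  labels[rod_in] <- length(geoms) + 1L
  nm[["background_rod"]] <- length(geoms) + 1L
  mask <- voi_mask(labels, grid, nm)

  a_lu <- spec$injected_MBq[["lu177"]]
  a_ac <- spec$injected_MBq[["ac225"]]
  conc <- function(suv, nuc, a0, t_h)
    .suv_to_conc(suv, a0, spec$weight_kg, t_h, nuc$half_life_h)

  vois$conc_lu24 <- conc(vois$suv_lu, lu, a_lu, t_star)
  vois$conc_lu48 <- vois$conc_lu24 * 2^(-24 / vois$teff_lu_h)
  vois$conc_ac24 <- conc(vois$suv_ac, ac, a_ac, t_star)

  bg24_lu <- conc(spec$background_suv, lu, a_lu, t_star)
  bg48_lu <- bg24_lu * 2^(-24 / spec$background_teff_h)
  bg24_ac <- conc(spec$background_suv, ac, a_ac, t_star)
  bg_teff_ac <- convert_effective_half_life(spec$background_teff_h, lu, ac)

  mk_map <- function(bg_val, voi_vals, nuclide, t_h) {
    v <- array(0, grid$shape)
    v[body_in] <- bg_val
    for (i in seq_along(voi_in)) v[voi_in[[i]]] <- voi_vals[i]
    volume_image(v, grid, "activity_conc_Bq_per_ml",
                 meta = list(nuclide = nuclide, time_h = t_h))
  }
  activity <- list(
    lu177_24h = mk_map(bg24_lu, vois$conc_lu24, "lu177", 24),
    lu177_48h = mk_map(bg48_lu, vois$conc_lu48, "lu177", 48),
    ac225_24h = mk_map(bg24_ac, vois$conc_ac24, "ac225", 24))

  dens <- array(0, grid$shape)
  dens[body_in] <- rho_soft_g_per_ml
  density <- volume_image(dens, grid, "density_g_per_ml")

  # Analytic ground-truth doses (local deposition, full chain for Ac).
  vois$dose_lu_Gy <- .analytic_local_dose_Gy(
    vois$conc_lu24, vois$teff_lu_h, t_star, lu$energy_per_decay_MeV,
    rho_soft_g_per_ml)
  vois$dose_ac_Gy <- .analytic_local_dose_Gy(
    vois$conc_ac24, vois$teff_ac_h, t_star, ac$energy_per_decay_MeV,
    rho_soft_g_per_ml)
  vois$dose_lu_Sv_per_GBq <- vois$dose_lu_Gy * lu$rbe / (a_lu / 1000)
  vois$dose_ac_Sv_per_MBq <- vois$dose_ac_Gy * ac$rbe / a_ac
  vois$volume_ml <- vapply(seq_along(voi_in),
                           function(i) sum(voi_in[[i]]) *
                             voxel_volume_ml(grid), numeric(1))

  truth <- list(kind = "tandem_patient", vois = vois,
                background = list(suv = spec$background_suv,
                                  teff_lu_h = spec$background_teff_h,
                                  teff_ac_h = bg_teff_ac,
                                  conc_lu24 = bg24_lu, conc_lu48 = bg48_lu,
                                  conc_ac24 = bg24_ac),
                injected_MBq = spec$injected_MBq,
                weight_kg = spec$weight_kg, t_star_h = t_star,
                rho_soft_g_per_ml = rho_soft_g_per_ml,
                seed = spec$seed)

  list(activity = activity, density = density, mask = mask, truth = truth)
}

#' Evolve an activity map by mono-exponential per-VOI decay
#'
#' Scales each voxel by `2^(-dt / T_eff)` using the effective half-life
#' of the VOI it belongs to; voxels outside any VOI use the mandatory
#' `"background"` entry.
#'
#' @param image activity [volume_image()].
#' @param mask a [voi_mask()] on the same grid.
#' @param half_life_h named numeric vector of effective half-lives (h):
#'   one entry per VOI name plus `"background"`.
#' @param dt_h time step in hours.
#' @export
decay_evolve <- function(image, mask, half_life_h, dt_h) {
  stop_if_grid_mismatch(image$grid, mask$grid)
  if (!"background" %in% names(half_life_h))
    stop("missing half-life for background")
  missing <- setdiff(names(mask$names), names(half_life_h))
  if (length(missing) > 0L)
    stop("missing half-life for VOI: ", paste(missing, collapse = ", "))
  if (any(half_life_h <= 0)) stop("half-lives must be > 0")
  fac <- array(2^(-dt_h / half_life_h[["background"]]), image$grid$shape)
  for (nmv in names(mask$names)) {
    lab <- mask$names[[nmv]]
    fac[mask$labels == lab] <- 2^(-dt_h / half_life_h[[nmv]])
  }
  out <- image
  out$values <- image$values * fac
  out$meta$time_h <- (if (is.null(image$meta$time_h)) 0 else
                        image$meta$time_h) + dt_h
  out
}
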