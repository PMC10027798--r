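# Quantitative MLEM/OSEM reconstruction with window-based scatter
# correction, collimator-detector-response modelling and calibration to
# absolute activity concentration.
#
# The scatter estimate enters the EM denominator (expected data) rather
# than being subtracted from the measured counts: this preserves the
# Poisson statistics and the nonnegativity of every iterate.

#' Reconstruction protocol
#'
#' Defaults follow the clinical schedules: Lu-177 uses 16 projections
#' per subset and 20 iterations; Ac-225 uses all views per update
#' (no subsets) and 60 iterations because of the low count level.
#'
#' @param nuclide `"lu177"` or `"ac225"` (or any label).
#' @param iterations number of full iterations.
#' @param projections_per_subset views per OSEM subset; 0 means all
#'   views (plain MLEM).
#' @param scatter_method `"TEW"`, `"DEW"` or `"none"`.
#' @param windows an [energy_window_set()].
#' @param psf_bin_mm distance-quantization width of the CDR model.
#' @export
recon_protocol <- function(nuclide = c("ac225", "lu177"),
                           iterations = NULL,
                           projections_per_subset = NULL,
                           scatter_method = NULL,
                           windows = NULL,
                           psf_bin_mm = 15) {
  nuclide <- match.arg(nuclide)
  if (is.null(iterations))
    iterations <- if (nuclide == "ac225") 60L else 20L
  if (is.null(projections_per_subset))
    projections_per_subset <- if (nuclide == "ac225") 0L else 16L
  if (is.null(scatter_method))
    scatter_method <- if (nuclide == "ac225") "DEW" else "TEW"
  scatter_method <- match.arg(scatter_method, c("TEW", "DEW", "none"))
  if (is.null(windows)) windows <- default_windows(nuclide)
  stopifnot(iterations >= 1, projections_per_subset >= 0)
  structure(list(nuclide = nuclide, iterations = as.integer(iterations),
                 projections_per_subset = as.integer(projections_per_subset),
                 scatter_method = scatter_method, windows = windows,
                 psf_bin_mm = psf_bin_mm),
            class = "recon_protocol")
}

.check_proj_geom <- function(a, b) {
  if (!identical(dim(a$views), dim(b$views)) ||
      abs(a$geom$span_deg - b$geom$span_deg) > 1e-9 ||
      a$geom$n_views != b$geom$n_views || a$geom$heads != b$geom$heads)
    stop("projection geometries do not match")
  invisible(TRUE)
}

#' Triple-energy-window scatter estimate
#'
#' Per pixel: `S = (C_l / w_l + C_u / w_u) * w_p / 2`, with the window
#' widths `w` in keV; negative estimates are clamped to zero.
#'
#' @param lower,upper scatter-window [projection_set()]s.
#' @param windows an [energy_window_set()] defining the widths.
#' @export
tew_scatter_estimate <- function(lower, upper, windows) {
  .check_proj_geom(lower, upper)
  w_l <- window_width_keV(windows, "lower")
  w_u <- window_width_keV(windows, "upper")
  w_p <- window_width_keV(windows, "peak")
  s <- pmax((lower$views / w_l + upper$views / w_u) * w_p / 2, 0)
  projection_set(s, lower$geom, window = "scatter_estimate",
                 nuclide = lower$nuclide)
}

#' Dual-energy-window scatter estimate
#'
#' One-sided variant of the triple-energy-window formula, used for the
#' 440 keV photopeak where only a lower scatter window is available:
#' `S = (C_l / w_l) * w_p / 2`.
#'
#' @param lower lower scatter-window [projection_set()].
#' @param windows an [energy_window_set()].
#' @export
dew_scatter_estimate <- function(lower, windows) {
  w_l <- window_width_keV(windows, "lower")
  w_p <- window_width_keV(windows, "peak")
  s <- pmax(lower$views / w_l * w_p / 2, 0)
  projection_set(s, lower$geom, window = "scatter_estimate",
                 nuclide = lower$nuclide)
}

#' MLEM/OSEM reconstruction
#'
#' Multiplicative EM updates with the rotation-based forward model of
#' [forward_project()] (attenuation, distance-dependent CDR). The
#' scatter estimate is added to the expected projections in the update
#' denominator. Voxels whose sensitivity falls below `1e-6` of the
#' maximum are frozen at zero. The returned image is in count-rate
#' units (cps per voxel) and must be calibrated to concentration with
#' [calibrate_to_concentration()].
#'
#' @param peak measured photopeak [projection_set()].
#' @param scatter scatter-estimate [projection_set()] or `NULL`.
#' @param mu attenuation [volume_image()] (mm^-1) or `NULL`.
#' @param psf a PSF stack.
#' @param protocol a [recon_protocol()].
#' @param grid reconstruction [voxel_grid()]; defaults to the grid of
#'   `mu`.
#' @param checkpoint_every if > 0, snapshot the image every this many
#'   iterations (returned in the `"checkpoints"` attribute).
#' @param track_likelihood record the Poisson log-likelihood after each
#'   full iteration (attribute `"loglik"`; no-subset protocols only).
#' @return A [volume_image()] of quantity `"counts"` (cps per voxel).
#' @export
osem_reconstruct <- function(peak, scatter = NULL, mu = NULL, psf,
                             protocol, grid = NULL,
                             checkpoint_every = 0,
                             track_likelihood = FALSE) {
  if (is.null(grid)) {
    if (is.null(mu)) stop("either grid or mu must be given")
    grid <- mu$grid
  }
  if (!is.null(scatter)) {
    .check_proj_geom(peak, scatter)
    if (any(scatter$views < 0)) stop("scatter estimate must be >= 0")
  }
  geom <- peak$geom
  sys <- .build_system(grid, geom, psf, mu, protocol$psf_bin_mm)
  nv <- sys$n_views
  t_view <- geom$time_per_view_s
  m <- peak$views
  b <- if (is.null(scatter)) array(0, dim(m)) else scatter$views

  pps <- protocol$projections_per_subset
  n_sub <- if (pps == 0L) 1L else nv %/% pps
  if (pps != 0L && nv %% pps != 0L)
    stop("projections per subset must divide the view count")
  # Interleaved subset assignment (standard OSEM ordering).
  subsets <- lapply(seq_len(n_sub), function(s) seq(s, nv, by = n_sub))

  eps <- 1e-12
  sens <- lapply(subsets, function(vs)
    .sys_back(array(1, c(sys$shape[1], sys$shape[3], length(vs))),
              sys, t_view, views = vs))
  live <- lapply(sens, function(s) s > 1e-6 * max(s))

  x <- array(0, sys$shape)
  live_any <- Reduce(`|`, live)
  x[live_any] <- 1
  loglik <- numeric(0)
  checkpoints <- list()

  for (it in seq_len(protocol$iterations)) {
    for (s in seq_len(n_sub)) {
      vs <- subsets[[s]]
      yhat <- .sys_forward(x, sys, t_view, views = vs) +
        b[, , vs, drop = FALSE]
      ratio <- m[, , vs, drop = FALSE] / pmax(yhat, eps)
      upd <- .sys_back(ratio, sys, t_view, views = vs)
      xn <- x
      xn[live[[s]]] <- x[live[[s]]] * upd[live[[s]]] / sens[[s]][live[[s]]]
      xn[!live[[s]]] <- 0
      x <- xn
    }
    if (track_likelihood && n_sub == 1L) {
      yhat <- .sys_forward(x, sys, t_view) + b
      loglik <- c(loglik, sum(m * log(pmax(yhat, eps)) - yhat))
    }
    if (checkpoint_every > 0 && it %% checkpoint_every == 0L &&
        it < protocol$iterations)
      checkpoints[[sprintf("iter_%03d", it)]] <-
        volume_image(x, grid, "counts",
                     meta = list(nuclide = peak$nuclide, iterations = it))
  }
  out <- volume_image(x, grid, "counts",
                      meta = list(nuclide = peak$nuclide,
                                  iterations = protocol$iterations,
                                  scatter_method = protocol$scatter_method))
  if (length(checkpoints) > 0) attr(out, "checkpoints") <- checkpoints
  if (track_likelihood) attr(out, "loglik") <- loglik
  out
}

#' Calibration factor of the camera
#'
#' @param nuclide nuclide label.
#' @param value_cps_per_MBq sensitivity in counts/s per MBq.
#' @param provenance free-form record (phantom activity, date).
#' @export
calibration_factor <- function(nuclide, value_cps_per_MBq,
                               provenance = list()) {
  stopifnot(value_cps_per_MBq > 0)
  structure(list(nuclide = nuclide, value_cps_per_MBq = value_cps_per_MBq,
                 provenance = provenance),
            class = "calibration_factor")
}

#' Convert a reconstructed count-rate image to activity concentration
#'
#' @param recon reconstruction in count-rate units (quantity
#'   `"counts"`, cps per voxel) from [osem_reconstruct()].
#' @param cal a [calibration_factor()] for the same nuclide.
#' @param nuclide nuclide of the acquisition (checked against `cal`).
#' @return A [volume_image()] in Bq/ml.
#' @export
calibrate_to_concentration <- function(recon, cal, nuclide = NULL) {
  if (is.null(nuclide)) nuclide <- recon$meta$nuclide
  if (!is.null(nuclide) && !is.na(nuclide) && nuclide != cal$nuclide)
    stop("calibration factor is for ", cal$nuclide, ", image is ", nuclide)
  bq_ml <- recon$values * 1e6 /
    (cal$value_cps_per_MBq * voxel_volume_ml(recon$grid))
  meta <- recon$meta
  meta$calibration_cps_per_MBq <- cal$value_cps_per_MBq
  volume_image(pmax(bq_ml, 0), recon$grid, "activity_conc_Bq_per_ml",
               meta = meta)
}

#' Derive a calibration factor from a homogeneous phantom acquisition
#'
#' Given the attenuation-corrected reconstruction (count-rate units) of
#' a large homogeneously filled cylinder of known activity, the factor
#' is total reconstructed count rate divided by the activity. A
#' [projection_set()] of an unattenuated acquisition may be passed
#' instead, in which case the total measured count rate is used
#' directly.
#'
#' @param recon_or_proj count-rate [volume_image()] or
#'   [projection_set()].
#' @param known_activity_MBq phantom activity.
#' @param nuclide nuclide label.
#' @export
derive_calibration_factor <- function(recon_or_proj, known_activity_MBq,
                                      nuclide = NA) {
  if (known_activity_MBq <= 0) stop("known activity must be > 0")
  cps <- if (inherits(recon_or_proj, "volume_image")) {
    stopifnot(recon_or_proj$quantity == "counts")
    sum(recon_or_proj$values)
  } else if (inherits(recon_or_proj, "projection_set")) {
    p <- recon_or_proj
    sum(p$views) / (p$geom$time_per_view_s * dim(p$views)[3])
  } else stop("expected a volume_image or projection_set")
  calibration_factor(nuclide, cps / known_activity_MBq,
                     provenance = list(activity_MBq = known_activity_MBq))
}
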