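# Post-filtering, phantom figures of merit (recovery coefficient,
# signal-to-noise ratio), cross-isotope SNR harmonization, isocontour
# segmentation and SUV conversion.

#' Gaussian post-reconstruction filter
#'
#' Separable Gaussian convolution with sigma = FWHM / 2.3548 per axis
#' (in mm, so anisotropic grids are handled correctly); symmetric
#' boundary padding conserves the image total.
#'
#' @param image a [volume_image()].
#' @param fwhm_mm filter FWHM in mm; 0 returns the image unchanged.
#' @export
gaussian_post_filter <- function(image, fwhm_mm) {
  if (fwhm_mm < 0) stop("filter FWHM must be >= 0")
  if (fwhm_mm == 0) return(image)
  sig_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  v <- image$values
  for (ax in 1:3) {
    sig_px <- sig_mm / image$grid$spacing[ax]
    h <- max(1L, ceiling(4 * sig_px))
    k <- stats::dnorm(-h:h, 0, sig_px)
    k <- k / sum(k)
    v <- .conv1_axis3d(v, k, ax)
  }
  out <- image
  out$values <- v
  out$meta$post_filter_fwhm_mm <- fwhm_mm
  out
}

# Index map for symmetric (half-sample mirror) padding of length n,
# valid for arbitrarily long overhangs; conserves mass for symmetric
# kernels because reflection tiling is measure preserving.
.mirror_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  j <- ((i - 1L) %% period) + 1L
  ifelse(j > n, period - j + 1L, j)
}

# 1-D convolution along one axis of a 3-D array, symmetric padding.
.conv1_axis3d <- function(a, k, axis) {
  h <- (length(k) - 1L) %/% 2L
  n <- dim(a)[axis]
  idx <- .mirror_index((1L - h):(n + h), n)
  pad <- switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
                a[, , idx, drop = FALSE])
  out <- a * 0
  for (i in seq_along(k)) {
    sl <- (i - 1L) + seq_len(n)
    out <- out + k[i] * switch(axis, pad[sl, , , drop = FALSE],
                               pad[, sl, , drop = FALSE],
                               pad[, , sl, drop = FALSE])
  }
  out
}

#' Recovery coefficient of an object
#'
#' RC = mean measured concentration inside the true-geometry VOI
#' divided by the true concentration; quantifies partial-volume loss.
#'
#' @param image measured concentration [volume_image()] (Bq/ml).
#' @param mask true-geometry [voi_mask()].
#' @param label VOI label or name.
#' @param truth_Bq_per_ml true concentration.
#' @export
recovery_coefficient <- function(image, mask, label, truth_Bq_per_ml) {
  if (truth_Bq_per_ml <= 0) stop("true concentration must be > 0")
  mask_stats(image, mask, label)$mean / truth_Bq_per_ml
}

#' Signal-to-noise ratio of an object
#'
#' SNR = mean over the object voxels divided by the sample sd of the
#' pooled background-VOI voxels (the five 100-ml rods in the phantom
#' study).
#'
#' @param image a [volume_image()].
#' @param mask a [voi_mask()].
#' @param label object VOI label or name.
#' @param background_labels labels or names of the background VOIs.
#' @export
snr <- function(image, mask, label, background_labels) {
  if (length(background_labels) == 0L) stop("background labels required")
  stop_if_grid_mismatch(image$grid, mask$grid)
  label <- mask_label(mask, label)
  bg_labs <- vapply(background_labels, mask_label, integer(1), mask = mask)
  bg <- image$values[mask$labels %in% bg_labs]
  s <- stats::sd(bg)
  if (!is.finite(s) || s == 0)
    stop("undefined SNR: background sd is zero")
  mean(image$values[mask$labels == label]) / s
}

#' Match image SNR by searching over Gaussian post-filter widths
#'
#' Filters `image_a` with every candidate FWHM and returns the one
#' whose VOI SNR is closest to the SNR of `image_b` (taken as given,
#' i.e. already filtered to its fixed width). Ties break toward the
#' smaller FWHM.
#'
#' @param image_a image whose filter is searched.
#' @param image_b reference image.
#' @param mask,label,background_labels VOI definition for [snr()].
#' @param candidates_mm candidate FWHM grid (default 20-50 mm in 5 mm
#'   steps).
#' @return list with `chosen_fwhm_mm`, `snr_target`, and a
#'   per-candidate `table` (fwhm, snr, gap).
#' @export
match_snr_fwhm <- function(image_a, image_b, mask, label,
                           background_labels,
                           candidates_mm = seq(20, 50, by = 5)) {
  if (length(candidates_mm) == 0L) stop("candidate list must be non-empty")
  snr_b <- snr(image_b, mask, label, background_labels)
  tab <- data.frame(fwhm_mm = candidates_mm, snr = NA_real_)
  for (i in seq_along(candidates_mm)) {
    fi <- gaussian_post_filter(image_a, candidates_mm[i])
    tab$snr[i] <- snr(fi, mask, label, background_labels)
  }
  tab$gap <- abs(tab$snr - snr_b)
  ord <- order(tab$gap, tab$fwhm_mm)
  list(chosen_fwhm_mm = tab$fwhm_mm[ord[1]], snr_target = snr_b,
       table = tab, voi = label)
}

#' Isocontour segmentation at a fraction of the local maximum
#'
#' Hill-climbs (26-neighbourhood) from the seed voxel to a local
#' maximum, then grows the connected component of voxels above
#' `fraction` times that maximum (26-connectivity).
#'
#' @param image a [volume_image()].
#' @param seed_voxel integer triple (1-based voxel index).
#' @param fraction threshold fraction of the maximum, in (0, 1).
#' @export
isocontour_voi <- function(image, seed_voxel, fraction = 0.8) {
  stopifnot(fraction > 0, fraction < 1)
  v <- image$values
  dm <- dim(v)
  if (max(v) == min(v)) stop("flat image: isocontour undefined")
  p <- as.integer(seed_voxel)
  if (any(p < 1L) || any(p > dm)) stop("seed outside image")
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  # hill climb
  repeat {
    cand <- sweep(nb, 2, p, `+`)
    ok <- cand[, 1] >= 1 & cand[, 1] <= dm[1] &
      cand[, 2] >= 1 & cand[, 2] <= dm[2] &
      cand[, 3] >= 1 & cand[, 3] <= dm[3]
    cand <- cand[ok, , drop = FALSE]
    vals <- v[cand]
    if (all(vals <= v[p[1], p[2], p[3]])) break
    p <- cand[which.max(vals), ]
  }
  vmax <- v[p[1], p[2], p[3]]
  thr <- fraction * vmax
  lab <- array(FALSE, dm)
  lin <- function(q) q[, 1] + dm[1] * (q[, 2] - 1L + dm[2] * (q[, 3] - 1L))
  queue <- matrix(p, 1)
  lab[lin(queue)] <- TRUE
  while (nrow(queue) > 0) {
    nxt <- NULL
    for (i in seq_len(nrow(queue))) {
      cand <- sweep(nb, 2, queue[i, ], `+`)
      ok <- cand[, 1] >= 1 & cand[, 1] <= dm[1] &
        cand[, 2] >= 1 & cand[, 2] <= dm[2] &
        cand[, 3] >= 1 & cand[, 3] <= dm[3]
      cand <- cand[ok, , drop = FALSE]
      li <- lin(cand)
      take <- !lab[li] & v[li] >= thr
      if (any(take)) {
        lab[li[take]] <- TRUE
        nxt <- rbind(nxt, cand[take, , drop = FALSE])
      }
    }
    queue <- if (is.null(nxt)) matrix(numeric(0), 0, 3) else nxt
  }
  labels <- array(0L, dm)
  labels[lab] <- 1L
  voi_mask(labels, image$grid, c(isocontour = 1L))
}

#' Standardized uptake value map
#'
#' SUV = concentration / (decay-corrected injected activity / body
#' mass), with the injected activity decayed to the scan time using the
#' nuclide's physical half-life and body density 1 g/ml.
#'
#' @param conc concentration [volume_image()] (Bq/ml).
#' @param injected_MBq injected activity.
#' @param weight_kg body weight.
#' @param time_h scan time after injection.
#' @param nuclide a [nuclide_spec()] (for the physical half-life).
#' @export
suv_map <- function(conc, injected_MBq, weight_kg, time_h, nuclide) {
  stopifnot(conc$quantity == "activity_conc_Bq_per_ml")
  if (injected_MBq <= 0 || weight_kg <= 0)
    stop("injected activity and weight must be > 0")
  a_t <- injected_MBq * 1e6 * 2^(-time_h / nuclide$half_life_h)
  suv <- conc$values / (a_t / (weight_kg * 1000))
  meta <- conc$meta
  meta$injected_MBq <- injected_MBq
  meta$weight_kg <- weight_kg
  volume_image(suv, conc$grid, "suv", meta = meta)
}
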