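# Nuclear data used across the package. Values are standard reference
# data (ICRP-107-style); every number is a configurable default, not a
# fitted quantity.

#' Describe a radionuclide
#'
#' @param name nuclide identifier, e.g. `"lu177"`.
#' @param half_life_h physical half-life in hours.
#' @param photons data.frame with columns `energy_keV`, `probability`
#'   (emissions used for imaging).
#' @param energy_per_decay_MeV charged-particle energy deposited per
#'   decay (for the full chain where applicable), used by the dose
#'   kernel.
#' @param rbe relative biological effectiveness applied when converting
#'   absorbed dose (Gy) to RBE-weighted dose (Sv_RBE).
#' @export
nuclide_spec <- function(name, half_life_h, photons,
                         energy_per_decay_MeV, rbe = 1) {
  stopifnot(half_life_h > 0, energy_per_decay_MeV > 0, rbe >= 1)
  stopifnot(all(photons$probability >= 0 & photons$probability <= 1))
  structure(list(name = name, half_life_h = half_life_h,
                 photons = photons,
                 energy_per_decay_MeV = energy_per_decay_MeV,
                 rbe = rbe),
            class = "nuclide_spec")
}

#' Built-in nuclides
#'
#' `lu177`: physical half-life 6.647 d; the 208 keV line (10.4%) is the
#' imaging photopeak; mean beta energy 0.147 MeV per decay; RBE 1.
#'
#' `ac225`: physical half-life 9.920 d; imaging uses the progeny gammas
#' (218 keV from Fr-221 at 11.4%, 440 keV from Bi-213 at 25.9%); the
#' full decay chain deposits 27.6 MeV of charged-particle (alpha)
#' energy under the full-local-deposition assumption; RBE 5 for alpha
#' dosimetry.
#'
#' `bi213`: the 45.6-min progeny whose 440 keV gamma is what the Ac-225
#' acquisition actually images.
#'
#' @param name one of `"lu177"`, `"ac225"`, `"bi213"`.
#' @return A [nuclide_spec()].
#' @export
builtin_nuclide <- function(name = c("lu177", "ac225", "bi213")) {
  name <- match.arg(name)
  switch(name,
    lu177 = nuclide_spec(
      "lu177", half_life_h = 6.647 * 24,
      photons = data.frame(energy_keV = c(112.9, 208.4),
                           probability = c(0.062, 0.104)),
      energy_per_decay_MeV = 0.147, rbe = 1),
    ac225 = nuclide_spec(
      "ac225", half_life_h = 9.920 * 24,
      photons = data.frame(energy_keV = c(218.0, 440.4),
                           probability = c(0.114, 0.259)),
      energy_per_decay_MeV = 27.6, rbe = 5),
    bi213 = nuclide_spec(
      "bi213", half_life_h = 45.6 / 60,
      photons = data.frame(energy_keV = 440.4, probability = 0.259),
      energy_per_decay_MeV = 8.4, rbe = 5))
}

#' Crosstalk of the Fr-221 218 keV line into the 208 keV window
#'
#' During simultaneous Lu-177/Ac-225 imaging the 218 keV gamma of the
#' first Ac-225 daughter Fr-221 falls close to (and partly inside) the
#' 208 keV photopeak window of Lu-177. This computes the expected
#' fractional contamination of the 208 keV window, modelling the
#' detector energy response as a Gaussian whose fractional FWHM scales
#' as 1/sqrt(E) from a reference resolution.
#'
#' @param activity_ratio Ac-225 : Lu-177 activity ratio (default the
#'   clinical 8 MBq : 1000 MBq).
#' @param window_center_keV,window_frac_width the Lu-177 photopeak
#'   window (default 208 keV, 15%).
#' @param p_lu,p_fr emission probabilities of the 208 keV (Lu-177) and
#'   218 keV (Fr-221, in equilibrium with Ac-225) lines.
#' @param resolution_fwhm_frac,resolution_ref_keV fractional energy
#'   resolution (FWHM/E) at the reference energy.
#' @return Fraction (not percent) of window counts contributed by the
#'   218 keV line.
#' @export
crosstalk_fraction <- function(activity_ratio = 8 / 1000,
                               window_center_keV = 208.4,
                               window_frac_width = 0.15,
                               p_lu = 0.104, p_fr = 0.114,
                               resolution_fwhm_frac = 0.099,
                               resolution_ref_keV = 140) {
  stopifnot(activity_ratio > 0, window_frac_width > 0)
  lo <- window_center_keV * (1 - window_frac_width / 2)
  hi <- window_center_keV * (1 + window_frac_width / 2)
  acc <- function(e_keV) {
    fwhm <- resolution_fwhm_frac * sqrt(resolution_ref_keV / e_keV) * e_keV
    s <- fwhm / (2 * sqrt(2 * log(2)))
    stats::pnorm(hi, e_keV, s) - stats::pnorm(lo, e_keV, s)
  }
  (activity_ratio * p_fr * acc(218.0)) / (p_lu * acc(208.4))
}
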