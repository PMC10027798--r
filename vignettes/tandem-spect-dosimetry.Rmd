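---
title: "Multi-isotope quantitative SPECT and single-time-point dosimetry: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-isotope quantitative SPECT and single-time-point dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemspect)
```

## The problem

Tandem radioligand therapy of metastasized prostate cancer combines a
beta emitter (Lu-177, ~1000 MBq) with an alpha emitter (Ac-225, ~8 MBq)
on the same PSMA-targeting ligand. Post-therapy quantitative SPECT of
the Lu-177 208 keV photopeak is routine; imaging the Ac-225 chain is
not, because the administered activity is two to three orders of
magnitude lower and the usable gamma line — 440 keV from the progeny
Bi-213 — lies above the conventional SPECT energy range, where septal
penetration through the collimator dominates the detector response.

`tandemspect` implements the full computational chain needed to study
this problem on synthetic data with known ground truth: a digital twin
of a cylinder quality-control phantom and of tandem-therapy patients,
a rotation-based SPECT forward model with energy windows, a
quantitative MLEM/OSEM reconstruction, image-quality harmonization
between the two isotopes, and single-time-point voxel dosimetry with
RBE weighting.

## Forward model and reconstruction

The projector is rotation-based: for every view the volume is rotated
into the camera frame (bilinear, in scatter form, which conserves
counts exactly for interior voxels), attenuated cumulatively toward the
detector using a CT-density-derived mu map (`mu_map_from_density()`;
water mass-attenuation coefficients scaled by density), and each
constant-distance plane is blurred with the collimator-detector
response (CDR) for its source-to-collimator distance.

The CDR is a stack of 150 two-dimensional kernels for distances up to
60 cm (`analytic_psf_stack()`):

* **Gaussian regime** (Lu-177 at 208 keV): isotropic Gaussians with
  `FWHM(d) = sqrt(intrinsic^2 + (slope * d)^2)`; defaults
  `intrinsic = 4.5` mm, `slope = 0.055` (high-energy collimator).
* **High-energy regime** (440 keV): the same Gaussian core carrying
  `1 - p` of the counts plus a star of three opposite arm pairs at
  60 degree spacing (hexagonal collimator symmetry) with exponential
  radial decay, carrying the septal-penetration fraction `p`.
  Defaults: `p = 0.3`, arm decay length 15 mm, slope 0.07. The star is
  distance independent in this parameterization, so the projector
  factorizes every kernel as `K_d = G_d * M` and applies the sparse
  star `M` once per view — this is exact, not an approximation, and is
  what makes 60-iteration MLEM runs take seconds.

Distances are quantized in 15 mm bins before kernel lookup; the PSF
width changes by well under a millimetre across a bin.

Energy windows follow the clinical settings: 208 keV with 15% width
plus 170 keV (15%) and 240 keV (10%) scatter windows for Lu-177; for
the 440 keV peak a 20% total width with a lower adjacent scatter
window of 10% width. Scatter itself is emulated parametrically
(`emulate_scatter_windows()`): the photopeak receives the primary
counts plus a fraction (default 0.3) of a broad-Gaussian-blurred copy,
and the scatter windows receive fractions of the same blurred
component chosen so that the triple-/dual-energy-window estimates
(`tew_scatter_estimate()`, `dew_scatter_estimate()`) invert the
injected scatter exactly on noiseless data. This tests the correction
algebra; it does not model the physics of Compton scatter, and
energy-resolution effects and photon transport are deliberately out of
scope.

Reconstruction (`osem_reconstruct()`) is multiplicative (OS-)MLEM with
the same system model; the scatter estimate is added to the expected
projections in the update denominator, which preserves Poisson
statistics and nonnegativity (pre-subtraction is the common
alternative; the denominator form was chosen because it cannot create
negative data). Protocol defaults follow clinical practice: 16
projections per subset and 20 iterations for Lu-177; all views and 60
iterations for Ac-225, where subsets are counter-indicated by the very
low counts. Voxels with sensitivity below 1e-6 of the maximum are
frozen at zero. Absolute quantification divides by a calibration
factor in cps/MBq (`calibrate_to_concentration()`); the calibration
procedure itself (homogeneous cylinder of known activity) is
implemented in `derive_calibration_factor()`. Default sensitivities
are 22.7 cps/MBq (440 keV) and 7.0 cps/MBq (208 keV).

## The phantom study

`build_cylinder_phantom()` digitizes a 3.5 l cylinder (radius 101 mm,
height 110 mm) with three spherical inserts of 200, 45 and 20 ml at a
foreground-to-background ratio of 6.4:1 and a background of
900 Bq/ml, for a total of about 4.5 MBq — the high-count (HC)
condition. The low-count (LC) condition divides the acquisition time
per view by 30, emulating the clinical count level. Since the physical
phantom's insert positions are not dimensioned anywhere, the layout
(inserts at 58–62 mm off axis, five ~100 ml background rods between
and around them) was fixed once as package defaults.

`run_phantom_study()` simulates both conditions (16 views/head, 2
heads, 3.5 min/view, 440 keV windows, Poisson noise), reconstructs
with 60 all-view MLEM iterations (checkpoints every 10), and tabulates
two figures of merit per insert, iteration and Gaussian post-filter
FWHM in {0, 10, 20, 30} mm:

* **Recovery coefficient** RC = mean reconstructed concentration in
  the CT-truth VOI / true concentration;
* **SNR** = insert mean / sample sd of the pooled background-rod
  voxels. The field has no single SNR definition; background-voxel sd
  was chosen (over insert-internal sd) because it uses structures the
  phantom defines and is stable under filtering.

At the default seed the HC chain reaches SNR well above 10 for all
inserts at the best filter, the LC chain shows the characteristic
collapse of unfiltered SNR and the RC-versus-SNR trade-off as the
filter widens, and RC orders by insert size at every filter. These are
exactly the checks in `tests/testthat/test-acceptance.R` and what
`scripts/acceptance.R` recomputes.

Because the reconstruction uses the same CDR model that generated the
data (an "inverse crime" in the simulation-study sense), unfiltered
recovery coefficients here are higher than a physical measurement
would give; the qualitative orderings and trade-offs are the
transferable content, not the absolute RC level.

## Synthetic patients

`build_synthetic_patient()` places two kidney ellipsoids (~105 ml),
`n_lesions` spherical lesions (volumes drawn around 21 ± 13 ml) and a
background-reference rod in a torso-like soft-tissue cylinder, then
draws per-VOI parameters from the printed cohort statistics:

* Lu-177 SUV: kidneys 2.1 ± 0.9, lesions 2.1 ± 1.5 (truncated
  normal);
* Ac-225 SUV: generated as the Lu-177 SUV times a paired ratio. The
  ratio's mean is the ratio of the per-nuclide means (2.5/2.1 for
  kidneys, 1.8/2.1 for lesions) and its sd the printed paired spread
  (0.23, 0.32). Tying the mean to the per-nuclide means rather than to
  the printed mean excess (21% for kidneys) keeps zero-variance
  cohorts exactly on both printed means — the two parameterizations
  are within ~2% of each other and cannot both hold simultaneously;
* Lu-177 effective half-lives: kidneys 31 ± 17 h, lesions 51 ± 39 h,
  log-normal moment-matched (half-lives are positive and
  right-skewed; the printed sd is of the order of the mean), truncated
  below the Lu-177 physical half-life;
* Ac-225 effective half-lives: converted from the Lu-177 draws via the
  shared biological clearance, `1/T_bio = 1/T_eff - 1/T_phys`
  (`convert_effective_half_life()`), mirroring the assumption of equal
  ligand pharmacokinetics; 31 h maps to 33 h;
* body uptake outside any VOI: SUV 0.3 with a 25 h effective
  half-life — nothing is printed for non-target tissue; a nonzero
  background exercises scatter and segmentation realistically;
* injected activities 1000 MBq / 8 MBq, body weight 80 kg; SUV to
  concentration uses the standard convention
  `conc = SUV * (decay-corrected injected activity / body mass)` with
  1 g/ml for the conversion.

One integer seed drives every draw; builds are bit-identical under a
fixed seed. The Bi-213-imaged uptake is taken equal to the Ac-225
uptake (the imaging chain sees the progeny gamma); redistribution of
free daughters is exposed only as this documented assumption, not
modelled.

The ground-truth record stores, per VOI, the drawn SUVs, half-lives,
concentrations at both time points and an analytic local-deposition
dose (time-integrated activity density times energy per decay over
mass), so every downstream quantity can be recomputed independently —
the self-consistency test does exactly that to 1e-10.

## Single-time-point dosimetry

The kinetics model is a per-VOI mono-exponential: a two-point fit of
the 24 h and 48 h Lu-177 VOI means gives the effective half-life
(`fit_two_point_half_life()`); VOIs whose uptake does not decrease
between the scans are flagged and excluded, mirroring the clinical
handling of late-peaking lesions. The voxel time-integrated activity
uses the closed form

TIA(x) = A(x, t*) · exp(ln 2 · t*/T½) · T½ / ln 2,

i.e. the fitted curve integrated from time zero to infinity
(`voxel_tia()`). Extrapolating the mono-exponential back to t = 0
ignores the uptake phase; that is a property of the closed form as
used clinically, and the package implements it as written rather than
substituting an uptake model.

Dose maps come from convolving the TIA map (converted to decays per
voxel) with a voxel S-value kernel (`build_vsv_kernel()`,
`apply_vsv()`). The kernels are analytic and energy conserving by
construction (`sum(kernel x voxel mass) = energy per decay` to 1e-6):

* **Ac-225**: the full decay chain's charged-particle energy,
  27.6 MeV (the four alpha energies of the chain), deposited in the
  source voxel — alpha ranges (< 0.1 mm) are negligible against the
  4.8 mm voxel, and full local deposition of all daughters is the
  stated modelling assumption;
* **Lu-177**: the mean electron energy per decay, 0.147 MeV, spread
  over an isotropic exponential point kernel with a 0.2 mm decay
  length (mean radial displacement 0.6 mm, matching the sub-millimetre
  beta range) and integrated over neighbouring voxels; at clinical
  voxel sizes the self-dose fraction is effectively 1.

Both energies, the half-lives (Lu-177 6.647 d, Ac-225 9.920 d) and the
kernel reference density are configurable constants of
`builtin_nuclide()` / `build_vsv_kernel()`, not fitted values. Dose
maps are weighted voxel-wise by `rho_soft / rho(x)` with
`rho_soft = 1.04 g/ml` (`density_weight()`), and converted to
RBE-weighted dose with RBE 5 for the alpha chain and 1 for Lu-177
(`rbe_weight()`). Reports normalize per administered activity in the
customary units, Sv_RBE=5/MBq for Ac-225 and Sv_RBE=1/GBq for Lu-177.

A deliberate consistency choice: the kernel reference density, the
density-weighting reference and the generator's body density are all
1.04 g/ml, so on soft tissue the chain reduces to energy per unit
tissue mass and the pipeline dose matches the analytic truth exactly.

## The tandem patient study

`run_tandem_patient_study()` chains everything per patient: generate;
image the three acquisitions (Lu-177 at 24 h and 48 h, Ac-225 at
24 h); harmonize image quality (Ac-225 fixed at a 30 mm post-filter,
the Lu-177 filter searched over 20–50 mm in 5 mm steps for the closest
kidney SNR match, `match_snr_fwhm()`, ties toward the smaller width);
segment lesions at an 80% isocontour of the local maximum
(`isocontour_voi()`, 26-connectivity with a hill-climb from the seed,
which makes the operation robust to imprecise seeds); compute SUVs;
fit and convert half-lives; and produce per-VOI dose reports together
with recovery errors against the ground truth.

Two imaging modes exist. `"simulated"` runs the full forward +
reconstruction chain. `"ideal"` uses the generated concentration maps
directly, skipping projection, noise, filtering and harmonization
(SNR is undefined on noiseless uniform backgrounds); this isolates the
dosimetry chain and is the mode in which the parameter-recovery
contract is exact: zero-variance cohorts recover kidney SUVs 2.1/2.5,
the generator half-lives and the analytic per-VOI doses to well within
2%.

## Problem sizes and numerical choices

The package's default study conditions are desk scale: the phantom
study runs on a 64 x 64 x 32 grid and the patient study on
96 x 96 x 64, both at the clinical 4.7952 mm pixel pitch (the phantom
fits a 64-pixel transaxial field of view with margin; the clinical
128-pixel matrix is available by configuration). The orbit is circular
with a 250 mm radius and two heads at 180 degrees — neither is stated
in the source protocol; circular is the reproducible default.

Numerical conventions worth knowing:

* world coordinates in mm, voxel-centre convention, axis order
  (x, y, z), shared by every module; masks use centre inclusion with
  no partial-volume weighting;
* the projector pair is an exact linear adjoint (tested to 1e-6,
  measured at machine precision), which is what MLEM's convergence
  proof requires;
* TEW estimates are clamped at zero per pixel (the formula goes
  negative under noise);
* Gaussian post-filters use symmetric boundary padding, which
  conserves the image total exactly for symmetric kernels;
* on-disk volumes are NIfTI-1, 32-bit float, RAS affine, with a JSON
  sidecar of identical basename for quantity/nuclide/time metadata;
  write-read-write is byte idempotent.

## Limitations

The scatter emulator is parametric, not photon transport; it validates
the correction algebra, not scatter physics. The CDR star model shares
its parameters between simulation and reconstruction, so absolute
recovery coefficients are optimistic relative to a physical
measurement. Anatomy is geometric (cylinders, ellipsoids, spheres);
there is no organ motion, no bladder/intestinal activity, no
registration step (all synthetic volumes share one grid), and no
recovery correction of SUVs or doses (deliberately, matching clinical
practice for these data). Kinetics are mono-exponential with two time
points; multi-compartment models, biologically effective dose and
per-progeny transport are out of scope.
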