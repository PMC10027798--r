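# tandemspect

Quantitative multi-isotope SPECT simulation and single-time-point
dosimetry for tandem Lu-177 / Ac-225 radioligand therapy, in R.

Tandem PSMA therapy injects ~1000 MBq of the beta emitter Lu-177 and
~8 MBq of the alpha emitter Ac-225 on the same ligand. Imaging the
Ac-225 chain means reconstructing the 440 keV gamma of the progeny
Bi-213 from extremely low counts, through a collimator whose septa the
photons partly penetrate (star-shaped detector response). This package
is for physicists and method developers who want to study that chain
quantitatively on synthetic data with known ground truth:

* **Digital phantoms and patients** — a 3.5 l cylinder phantom with
  200/45/20 ml inserts at 6.4:1 contrast (~4.5 MBq high-count, 30-fold
  reduced low-count), and synthetic tandem patients drawn from cohort
  statistics (kidney SUV 2.1 ± 0.9 Lu / 2.5 ± 0.8 Ac, lesion SUV
  2.1 ± 1.5 / 1.8 ± 1.1, effective half-lives 31 ± 17 h and
  51 ± 39 h), with an analytic ground-truth record.
* **Forward model** — rotation-based projector with CT-based
  attenuation, a 150-plane distance-dependent detector-response stack
  (Gaussian for 208 keV; Gaussian core + exponential star arms
  carrying the septal-penetration fraction for 440 keV), emulated
  scatter energy windows, Poisson noise.
* **Reconstruction** — quantitative MLEM/OSEM with the scatter
  estimate in the EM denominator, triple-energy-window (Lu-177) and
  dual-energy-window (Ac-225) scatter correction, calibration to
  Bq/ml (22.7 cps/MBq at 440 keV, 7.0 cps/MBq at 208 keV defaults).
* **Image metrics** — recovery coefficients, background-rod SNR,
  Gaussian post-filters, cross-isotope SNR harmonization (Ac fixed at
  30 mm, Lu searched over 20–50 mm), 80 % isocontour segmentation,
  SUV maps.
* **Dosimetry** — two-point mono-exponential half-life fits with
  exclusion of non-decreasing uptake, cross-nuclide half-life
  conversion via shared biological clearance, closed-form voxel
  time-integrated activity, energy-conserving voxel S-value kernels
  (27.6 MeV full-chain alpha energy for Ac-225, 0.147 MeV mean beta
  for Lu-177), CT-density weighting, RBE weighting (5 for the alpha
  chain), per-VOI dose-per-administered-activity reports.

The core model, in the field's notation: per-VOI kinetics are
mono-exponential, `A(t) = A(t*) 2^{-(t-t*)/T_eff}` with
`1/T_eff = 1/T_phys + 1/T_bio`, fitted from the 24 h/48 h Lu-177
scans and transferred to Ac-225 by keeping `T_bio`. The voxel
time-integrated activity is

```
TIA(x) = A(x, t*) · exp(ln2 · t* / T_eff) · T_eff / ln2
```

and the absorbed dose map is `D = (TIA as decays/voxel) ⊛ S_voxel`,
density-weighted by `rho_soft / rho(x)` and RBE-weighted to Sv_RBE.

## Worked example

Simulate the high-count phantom experiment and read off the figures of
merit (about 15 s on one CPU at the default 64×64×32 grid):

```r
library(tandemspect)
cfg <- default_run_config("phantom")
cfg$count_modes <- "HC"
res <- run_phantom_study(cfg)
m <- subset(res$metrics, iterations == 60 & insert != "background")
aggregate(cbind(rc, snr) ~ insert + fwhm_mm, m, identity)
```

At the default seed this prints, for the final iteration (selected
rows):

```
        insert fwhm_mm    rc  snr
  insert_200ml       0 0.891 16.9
  insert_200ml      20 0.759 32.4
  insert_45ml       20 0.597 25.5
  insert_20ml       20 0.508 21.7
  insert_20ml       30 0.369 14.8
```

Reading: the 200 ml insert is recovered at 89 % of its true
concentration unfiltered; a 20 mm post-filter trades recovery
(0.89 → 0.76) for noise suppression (SNR 17 → 32). Every insert
clears SNR 10 at its best filter in the high-count condition, while
the low-count condition (`cfg$count_modes <- "LC"`) drops unfiltered
SNRs to ~3 and needs the 30 mm filter to approach 10 — the
feasibility boundary of clinical Ac-225 imaging.

The synthetic-patient chain with idealized imaging recovers the
generator truth exactly:

```r
cfg <- default_run_config("tandem_patient")
cfg$patient$sd_zero <- TRUE
res <- run_tandem_patient_study(cfg)
res$cohort[, c("voi", "suv_lu", "suv_ac", "teff_lu_h", "teff_ac_h",
               "dose_ac_Sv_per_MBq")]
#>           voi suv_lu suv_ac teff_lu_h teff_ac_h dose_ac_Sv_per_MBq
#> 1 kidney_left     2.1    2.5        31     33.12             0.1761
#> ...
```

— kidney SUVs 2.1 (Lu) / 2.5 (Ac), the 31 h effective half-life
converting to 33 h, and an RBE-weighted kidney dose of
~0.18 Sv_RBE=5 per MBq administered.

A thin command-line wrapper lives in `inst/cli/tandemspect.R`
(`Rscript tandemspect.R phantom --config run.yaml --out DIR`).

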