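# perispect

Serial MR-spectroscopy quantification and lesion volumetry for
perihematomal tissue after intracerebral hemorrhage (ICH).

After an ICH, the hematoma is surrounded by a rim of perihematomal edema
(PHE) and, beyond it, by perilesional tissue without visible edema (ATNE).
Whether tissue that has been through edema recovers metabolically is a
question that serial, non-invasive proton MR spectroscopy can answer: the
concentrations of N-acetylaspartate (NAA, neuronal integrity), creatine
(Cr, energy metabolism) and choline (Cho, membrane turnover) in the PHE,
ATNE and contralesional voxels, tracked over days, separate reversible
from persistent injury. perispect implements the full analysis chain of
such a study as tested, reusable R code, together with a synthetic-data
module that generates every input with known ground truth — so the whole
pipeline is verifiable by parameter recovery without any raw scanner data.

The core computation is water-referenced absolute quantification with
relaxation correction,

    Cm = (Am / Aw) * [ Nw (1 - exp(-TR/T1w)) exp(-TE/T2w) ]
                   / [ Nm (1 - exp(-TR/T1m)) exp(-TE/T2m) ] * Cw   [mM]

where `Am`/`Aw` are the metabolite and unsuppressed-water peak areas,
`Nm`/`Nw` proton counts, `T1*`/`T2*` relaxation times and `Cw` the tissue
water concentration. Around it the package provides:

* **synthesis** — `simulate_spectrum()` / `simulate_csi_grid()` render
  complex Lorentzian CSI spectra whose areas invert the equation above
  (TR/TE = 2000/144 ms, 9 x 9 grid, 2000 Hz, 15 mm voxels by default);
  `simulate_flair_phantom()` builds FLAIR-like concentric-ellipsoid lesion
  phantoms with exact label volumes; `simulate_cohort()` draws longitudinal
  region-by-day cohorts with animal-level random effects.
* **spectral processing** — `phase_correct()` (automated zero/first-order
  phasing by a phase-constrained line-model fit), `integrate_peak()`
  (windowed trapezoidal integration with an edge-anchored linear
  baseline), `measure_water()`, `water_ratio_qc()`.
* **quantification** — `relaxation_factor()`, `quantify()`,
  `quantify_spectra()`, `quantify_grid()`, and `recovery_study()` for
  Monte-Carlo recovery experiments.
* **volumetry** — `region_grow()` seed-growing segmentation (running-mean
  tolerance, 6/26-connectivity), `segment_icv()`, `compute_volumes()`,
  `percent_change()`.
* **inference** — `fit_lmm()` (REML mixed model, region x categorical day,
  random intercepts for animal and animal-by-region, Satterthwaite df),
  `region_time_contrasts()`, `fit_volume_model()`, `correlate_volumes()`.
* **orchestration** — `run_pipeline()` ties simulate / process / quantify /
  segment / model into one seeded, manifest-writing run;
  `inst/cli/perispect` is a thin command-line wrapper.

## Worked example

Quantify one noisy synthetic voxel whose ground truth is the day-1 PHE
profile, then check recovery statistically:

```r
library(perispect)
pri <- load_priors()                 # shipped 3 T priors (stand-in values)
acq <- acquisition_params()          # TR/TE = 2000/144 ms, 2000 Hz, 2048 pts

truth <- ground_truth_voxel("PHE", c(NAA = 9.70, Cr = 3.62, Cho = 1.60),
                            phase0 = 21, snr = 20)
v <- simulate_spectrum(truth, pri$metabolites, pri$water, acq, seed = 42)
quantify_spectra(v$suppressed, v$unsuppressed, pri$metabolites, pri$water, acq)
#>   metabolite     am    aw correction cm_mM
#> 1        NAA 0.6784 649.5    0.21537 8.867
#> 2         Cr 0.2467 649.5    0.30906 4.628
#> 3        Cho 0.3398 649.5    0.07133 1.471

rs <- recovery_study(13.7, "NAA", n_reps = 100, snr = 20, seed = 1)
mean(rs$cm_hat)
#> [1] 13.87744
```

A single SNR-20 realisation scatters around the truth (here NAA 8.87 vs
9.70 mM); the mean over 100 realisations recovers a 13.7 mM ground truth
to about 1%. `correction` is the dimensionless relaxation/proton factor of
the equation above. Lesion volumetry on a noiseless 0.5 mm phantom sized
to 1.00 ml hematoma / 2.38 ml edema returns the targets exactly:

```r
ph <- simulate_flair_phantom(phantom_spec())
seg <- segment_phantom(ph$image, ph$seeds)
compute_volumes(seg, ph$voxel_mm)
#>   icv_ml hematoma_ml edema_ml
#> 1   70.3           1     2.38
```

An end-to-end demo (CSI grids, phantoms and a 12-animal cohort for days 1,
7, 14, with summary tables, figures and a manifest):

```r
run_pipeline(load_run_config(), seed = 1, out_dir = "demo_run")
```

or, from a shell, `inst/cli/perispect run --seed 1 --out demo_run`.

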