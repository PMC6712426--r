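---
title: "Methods: simulation, quantification, volumetry and longitudinal inference in perispect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, quantification, volumetry and longitudinal inference in perispect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perispect)
```

perispect re-creates, as tested and reusable code, the analysis chain of a
serial proton-MRS study of perihematomal tissue after intracerebral
hemorrhage (ICH): multivoxel chemical shift imaging (CSI) spectra are
quantified against the unsuppressed tissue-water signal with relaxation
correction, lesion volumes are measured by seed-growing segmentation of
FLAIR-like volumes, and region-by-time trajectories are analysed with
linear mixed models. Because no raw animal data are publicly available,
the package ships a synthetic-data module that generates every input with
known ground truth; all validation is parameter recovery against those
truths.

## The quantification model

Absolute metabolite concentrations use the water-referenced relation with
T1/T2 correction,

$$
C_m \;=\; \frac{A_m\, N_w\, \bigl(1-e^{-TR/T_{1w}}\bigr)\, e^{-TE/T_{2w}}}
               {A_w\, N_m\, \bigl(1-e^{-TR/T_{1m}}\bigr)\, e^{-TE/T_{2m}}}\; C_w ,
$$

where $A_m$ and $A_w$ are the metabolite and water peak areas, $N_m$ and
$N_w$ the proton counts, $T_{1m}, T_{2m}, T_{1w}, T_{2w}$ the relaxation
times, and $C_w$ the reference tissue water concentration.
`relaxation_factor()` implements the bracketed correction;
`quantify()` applies it to measured areas. In the fully relaxed, zero-echo
limit the correction collapses to $N_w/N_m$, which the test suite checks to
1e-12.

**Relaxation priors and $C_w$.** No measured relaxation values accompany
the study design this package emulates, so the package ships a versioned
YAML table (`inst/extdata/priors-3t.yaml`) of literature-informed stand-ins
(NAA 2.01 ppm, $N_m=3$, $T_1/T_2$ 1470/247 ms; Cr 3.03 ppm, 3, 1460/152 ms;
Cho 3.19 ppm, 9, 1200/217 ms; water 4.7 ppm, 2, 1200/80 ms). They are
explicitly replaceable per site and must not be read as the original
study's values. $C_w$ defaults to pure-water molarity times a configurable
tissue water fraction, $55{,}510\ \mathrm{mM} \times 0.71 = 39{,}412\
\mathrm{mM}$.

## The forward simulator

`simulate_spectrum()` renders each resonance as a *complex* Lorentzian
(absorption in the real channel, dispersion in the imaginary channel), as
produced by Fourier transforming an exponentially damped FID. Peak areas
are obtained by inverting the quantification relation above, so in the
noiseless, perfectly phased limit the analysis chain recovers the ground
truth exactly; this round trip is the package's central correctness
argument. Defaults mirror the acquisition protocol of the study design:
TR/TE = 2000/144 ms, 9 x 9 CSI matrix, 2000 Hz bandwidth, 15 mm isotropic
voxels, with 2048 spectral points and 5 Hz linewidths.

Three numerical choices matter:

* **Matched linewidths.** Water is rendered at the same FWHM as the
  metabolites. A finite integration window captures only part of a
  Lorentzian (about 85% of the absorption integral at the default +-0.08
  ppm window for 5 Hz lines, and less after baseline subtraction); with
  matched lineshapes and identical windows that attenuation is identical
  for numerator and denominator and cancels in $A_m/A_w$. Quantification
  accuracy therefore degrades if real data carry a much broader water line
  than the metabolites; that sensitivity is a documented limitation, not a
  hidden assumption.
* **SNR definition.** `snr` is defined per channel: the dominant peak
  height of that channel (water in the unsuppressed companion, the tallest
  metabolite line in the suppressed spectrum) divided by the noise SD of
  the real part. A single water-referenced noise level would make the
  metabolite lines, which are three orders of magnitude smaller than
  unsuppressed water at physiological $C_w$, unrecoverable at any usable
  SNR; the per-channel definition reflects that water suppression and
  metabolite acquisition operate at different effective signal scales.
* **ppm axis.** Stored ascending and centred on water at 4.7 ppm; display
  conventions (reversed axis) are left to plotting.

The simulator deliberately omits pulse-sequence physics, macromolecular
baselines and lactate; it emulates the inputs the analysis chain needs,
not a scanner.

## Phase correction

The study performed phasing manually; perispect replaces it with a
documented automated operator. We first implemented the classical
negative-lobe penalty (minimise the integrated magnitude of negative
real-part excursions over the metabolite region). On sparse Lorentzian
spectra that objective turns out to be *exactly degenerate*: entire
(phi0, phi1) families keep the real part non-negative everywhere on the
sampled axis, so the penalty cannot locate the true phase to the accuracy
this pipeline needs (1 degree zero-order, 0.5 degree/ppm first-order).

`phase_correct()` therefore fits a phase-constrained line model: the
observed spectrum is modelled as
$e^{i(\phi_0+\phi_1 (p - p_\mathrm{pivot}))}\sum_k a_k L_k(p)$ with known
complex Lorentzian lineshapes $L_k$ at the NAA/Cr/Cho positions and real
amplitudes $a_k$. For fixed phases the amplitudes solve a linear
least-squares problem, so the fit reduces to maximising a two-parameter
profile criterion (coarse grid, then Nelder-Mead). The estimator is exact
for noiseless Lorentzian data, accounts for line overlap and for the phase
gradient across each line, and the 180-degree amplitude-sign ambiguity is
resolved toward positive absorption. The line model is used *only* for
phasing; quantification never fits peaks (see below). A residual
negative-lobe integral is still reported as a QC metric, and spectra whose
lines do not rise above the noise floor are flagged `low_confidence`
rather than silently phased. The unsuppressed water spectrum is corrected
zero-order only (a lone line cannot identify phi1); the voxel's
first-order estimate from the metabolite channel is applied to the water
channel before integration, since both channels share the acquisition's
phase error.

## Peak integration

`integrate_peak()` mirrors the study's "spectral integration": a
trapezoidal integral of the real part over a +-0.08 ppm window after
subtracting a linear baseline anchored at the window edges (each anchor is
the mean of five samples at fixed offsets inside the edge). Window
endpoints and anchors are evaluated by interpolation at exact ppm
positions, so the integral geometry is identical for every peak however
its centre falls on the discrete axis — without this, sub-sample grid
offsets between the 2.01 ppm and 4.7 ppm windows leave percent-level,
position-dependent biases in the area ratio. The 0.08 ppm half-width is
our declared default (there is no canonical value): it is the widest window
that keeps Cr (3.03) and Cho (3.19) disjoint. Cross-contamination of
adjacent windows by Lorentzian tails remains and biases Cr/Cho by a few
percent when both lines are strong; the two-peak test quantifies it
(within 5% of the isolated areas). No Voigt/basis-set fitting is offered:
the package reproduces an integration-based analysis, and a fitting
quantifier would change the method, not implement it.

## Lesion phantoms and volumetry

`simulate_flair_phantom()` builds concentric-ellipsoid FLAIR-like volumes:
a bright edema shell (intensity 180) around a dark hematoma core (40)
inside a brain ellipsoid (100) on a dark background (10), with optional
Gaussian noise. Ellipsoid scales are calibrated so the *discrete* voxel
count matches the target volume to the nearest voxel (via the order
statistics of the normalised quadratic form); an uncalibrated analytic
mode demonstrates convergence of the voxelised volume as the voxel size
shrinks. Default targets follow the published day-1 group means
(ICV 70.3 ml, hematoma 1.00 ml, edema 2.38 ml).

`region_grow()` implements seed-growing segmentation: a frontier expands
from the seed, and a candidate voxel joins when its intensity lies within
a tolerance of the *running region mean*, updated after each sweep rather
than per voxel so the result is order-independent and deterministic.
Connectivity is 6 or 26 (default 26); masks touching the image border are
flagged as possible leaks instead of being manually edited (the study's
manual mask editing is out of scope). The intracranial volume is obtained
by thresholding plus hole filling, since the original ICV method is not
described; the threshold sits halfway between background and the darkest
intracranial class. Volumes are voxel count times voxel volume (ml), and
`percent_change()` reports reductions relative to a baseline day.

## The longitudinal cohort and mixed models

`simulate_cohort()` draws, per metabolite,
$y_{ird} = \mu_{rd} + a_i + b_{ir} + \varepsilon_{ird}$ with animal
intercepts $a_i$, animal-by-region intercepts $b_{ir}$ and residual noise —
the nested covariance structure the analysis model assumes. Cell means
default to the published day-1/day-14 group means for NAA and Cr in the
PHE (perihematomal edema), ATNE (adjacent tissue, no edema) and
contralesional regions; day-7 values and all Cho values are unpublished
and are stand-ins chosen to preserve the qualitative trajectory (early
bilateral-perilesional loss, day-14 restoration in PHE only).

Variance components are calibrated to the published test statistics rather
than guessed: the reported day-14 vs day-1 p-values in ATNE (0.51 for a
0.54 mM difference) and contralesional tissue (0.36 for 0.8 mM) imply a
within-animal contrast SE near 0.82 mM at n = 12, i.e. a residual SD near
2.0 mM; the animal (1.0 mM) and animal-by-region (0.8 mM) SDs then bring
the total per-cell SD to about 2.4 mM, matching the printed 2.1-3.1 mM
spread. With these inputs the same contrasts that the design treats as
real effects come out significant in simulation, and the null ones do not.
The variance components are calibrated at the NAA/Cr concentration scale
and are applied to all metabolites; simulated Cho values (means below
3 mM) can therefore occasionally dip below zero — a generator artifact
that leaves the Gaussian mixed model unaffected and is irrelevant to the
recovery experiments, which use NAA and Cr.

`fit_lmm()` fits the REML model `response ~ region * day + (1 | animal) +
(1 | animal:region)` with categorical (polychotomous) day, reference
region CONTRA, and Satterthwaite degrees of freedom (our documented
choice, well calibrated at this design size — the suite verifies a 4-6%
type-I rate at alpha = 0.05 over 1000 null cohorts). Random effects are
intercept-only, the structure the design implies. Singular fits are
flagged, and an outright lmer failure (e.g. an exactly zero-residual
cohort) falls back to OLS for the fixed effects, flagged `fallback_ols`,
never silently. `region_time_contrasts()` emits the design's comparison
set — each region versus CONTRA at each day, and day-14 versus day-1
within each region — with two-sided p-values and no multiplicity
correction by default (Holm available), matching the original reporting.
Volumes are modelled per outcome with day as fixed effect and an animal
intercept (`fit_volume_model()`). Volume/metabolite correlations are
provided only as a descriptive Pearson table.

## Problem sizes and determinism

Validation runs at desk scale by design: recovery studies use 100 noise
realisations per ground truth at SNR 20; mixed-model calibration uses 1000
null cohorts of 12 animals; phantom volumetry uses 0.5 mm voxels in a
128-cube; the demo pipeline uses 1 mm voxels and one 9 x 9 grid per day.
Every stochastic routine takes an explicit seed, derives per-item streams
from it, and restores the caller's RNG state, so identical seeds give
bit-identical outputs (the pipeline writes byte-identical summary CSVs
under a fixed seed).

## What passing tests do and do not show

The synthetic generator shares its lineshape model, its noise model and
its priors with the analysis chain. Recovery therefore demonstrates
internal consistency, numerical correctness and statistical calibration —
not robustness to real-scanner effects: eddy-current lineshape distortion,
frequency drift, macromolecular baselines, chemical-shift displacement,
partial-volume mixing at lesion boundaries and water-content changes in
edematous tissue are all absent. The water-ratio QC (`water_ratio_qc()`),
which checks that regional water signals stay stable
over time, is the only guard against reference-water confounds and is
reported, not acted on, by the pipeline.

## Container formats

CSI grids are serialised to a single JSON container (`write_csi()` /
`read_csi()`) holding the suppressed/unsuppressed datasets as
real/imaginary arrays, the ppm axis, region labels, acquisition parameters
and the ground truth; phantoms and masks use NIfTI (`write_phantom()`,
RNifti); cohorts, concentration records, volumes and contrast tables are
plain CSV.
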