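---
title: "Models and methods behind alidose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind alidose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alidose)
```

`alidose` covers the statistics of a flow-through air–liquid-interface (ALI)
nanoparticle exposure experiment end to end: viability normalisation,
multi-plate Bayesian consensus, aerosol mass dosimetry, ICP-MS dose
bookkeeping, assay QC, and ToF-SIMS spectral discrimination. This vignette
explains each model, its assumptions and tunable parameters, the synthetic
data the test suite runs on, and the design decisions that were genuinely
open.

## Viability normalisation

A WST-1 well's 450 nm absorbance is proportional to the metabolically active
cell number plus an assay background. Percentage viability is the
blank-corrected signal relative to the blank-corrected incubator negative
control,

$$V = 100\,\% \cdot \frac{A_\text{test} - A_\text{blank}}
                        {A_\text{control} - A_\text{blank}},$$

computed strictly within a plate: each plate's blank and control levels come
from that plate's own wells, because WST-1 lots, incubation times and reader
drift shift whole plates together. Technical replicates (three 50 µL
aliquots of one insert's supernatant) estimate a single underlying quantity
and are averaged *before* the ratio; with linear noise-free data the order
would not matter, and averaging first keeps one record per insert, which is
the unit the hierarchical model treats as an observation.

Two deliberate choices:

* **No clipping.** Test wells below blank give negative viability. They are
  flagged, not clipped to zero, because the consensus model assumes Gaussian
  observations and clipping would bias low-viability conditions upward.
* **Interference flag.** The 562 nm channel lies outside the formazan
  spectrum; an insert is flagged when its 562 nm mean exceeds twice the
  plate-blank 562 nm level. The factor of 2 is a package default (the
  control's purpose, not a cutoff, is what the assay protocol specifies);
  it is exposed as `interference_factor`.

## Hierarchical consensus across plates

Plates run on different days disagree by more than their within-plate
scatter suggests. Per condition the model is

$$y_{ij} \sim N(\theta_j, \sigma_j^2), \qquad
  \theta_j \sim N(\mu, \tau^2), \qquad
  \mu \sim N(100, 1000^2),$$

with independent Half-Cauchy(25) priors on every $\sigma_j$ and on $\tau$
(all in percentage-viability units). The prior on $\mu$ is effectively flat;
scale 25 for the Half-Cauchy priors is weakly informative for data living on
a 0–100 scale — it keeps mass near plausible single-digit-to-tens sds
without forbidding large ones.

**Sampler.** The Half-Cauchy priors admit an inverse-gamma auxiliary-variable
representation ($\sigma^2 \mid a \sim \mathrm{IG}(1/2, 1/a)$,
$a \sim \mathrm{IG}(1/2, 1/A^2)$), which makes every full conditional
conjugate. The resulting Gibbs sampler needs no step-size tuning and mixes
quickly at these dimensions. Defaults: 4 chains, 4000 iterations, 50%
burn-in, thin 1, all seeded. `sigma_fixed`/`tau_fixed` collapse the model to
single-level reductions; the test suite uses them to compare against the
closed-form conjugate posterior.

**Diagnostics and fallback.** Split-R̂ (each chain halved, so slow drift also
registers) and an autocorrelation-based effective sample size are computed
per parameter. The convergence threshold is R̂ < 1.05 — stricter than the
common 1.1 — so the fallback triggers conservatively. The fallback,
`fallback_consensus()`, is a frequentist random-effects combination of
per-plate means and standard uncertainties: DerSimonian–Laird moment
estimate of $\tau^2$ (floored at zero), inverse-variance weights
$1/(u_j^2+\hat\tau^2)$, normal 95% bounds. When all $u_j = 0$ the
estimator's limit is used ($\hat\tau^2$ = sample variance of the plate
means, equal weights).

**Decision rules.** "Below control" means
$\Pr(\mu < 100\,\%) > 0.95$ under the posterior — the consensus is less than
the control with at least 95% likelihood. "Statistically equal" for a pair
of conditions means the central 95% credible interval of the difference of
their consensus means contains zero; the null hypothesis of equality is
stated by the assay design, and interval inclusion is the operational rule
adopted here. Conditions are fitted independently, so the difference draws
treat the two posteriors as independent — correct when conditions share no
wells, which is the design here.

**What the calibration tests show.** On synthetic three-plate,
three-insert-per-plate datasets with 12% well COV and a 5-point plate
effect, the 95% credible interval covers the true consensus in well over
88 of 100 replicates, and a true viability of 39% is flagged below control
in essentially all replicates. The calibration loop runs 100 datasets at
1500 iterations × 4 chains — enough for ±2-point Monte-Carlo error on an
interval endpoint, and a deliberate problem size the whole loop completes in
about a minute.

## Aerosol mass and modality

The SMPS reports number concentration per mobility-diameter bin. Under the
spherical-particle assumption with bulk density $\rho$ (7.3 g/cm³ for
CeO₂),

$$C_\text{mass} = \sum_i N_i \,\rho\, \frac{\pi}{6} d_i^3,$$

with the reported bin midpoint as representative diameter (no within-bin
integration — bin widths are narrow on the SMPS's log grid, and the error
is far below scan-to-scan variability). Readers accept both per-bin counts
and dN/dlogD$_p$ exports; the latter are multiplied by each bin's log₁₀
width at ingest.

The sub-50 nm region of a nebulised-suspension aerosol is dominated by a
residual mode (dried solutes in the carrier water) whose day-to-day
variability makes blank subtraction unreliable; the implemented policy is
therefore *exclusion*: `apply_size_cutoff()` drops bins below the cutoff.
Because mass scales with $d^3$, excluding the sub-50 nm bins of a
20 nm + 90 nm bimodal aerosol removes only a few percent of total mass.
Mode detection is a 3-bin moving average followed by strict interior local
maxima — enough to reproduce "two maxima near 20 and 90 nm" without
pretending to be a peak-fitting method.

## ICP-MS dose bookkeeping

Elemental Ce masses arrive per compartment: digested cells, the PBS wash,
and the basolateral medium. All values are corrected by subtracting the mean
of six blank digests; LOD and LOQ are 3× and 10× the blank sd (sample sd,
n−1 — the estimator is not specified by the convention itself, and the
unbiased-variance form is the package's choice). Below-LOD and negative
corrected values are flagged but retained, keeping compartment sums
unbiased. Recovery against a certified reference is screened on an
inclusive 86–120% band.

Rates divide by insert area and exposure duration:
deposition = (cells + wash + basal)/(A·t), uptake = cells/(A·t), and the
intracellular fraction is their ratio. All masses are carried in ng, areas
in cm², times in h; concentration × volume conversion happens once, at
ingest.

## Dosimetry

With the aerosol concentration $C$ in mg/m³ (numerically equal to ng/mL)
and the per-insert flow $F$ in mL/min, the theoretical maximum deposition
rate is $C \cdot F \cdot 60 / A$ in ng·cm⁻²·h⁻¹ — the dose that would
deposit if every particle carried to the insert stuck. Deposition
efficiency is the measured rate as a percentage of this maximum; ~3% is
typical of flow-through ALI exposure systems. The in-vivo reference rate
converts a whole-lung burden (µg) to the same areal units via the alveolar
surface area and cumulative exposure time, and the in-vitro/in-vivo
comparison reports their ratio with a configurable comparability band,
default a factor of two either way — wide enough to absorb the biological
and dosimetric uncertainties on both sides, and a reporting aid rather than
a test.

The surface-coverage fraction uses a projected-area monolayer model: an
areal mass $m$ of $d$-spheres is $m/(\rho \frac{\pi}{6} d^3)$ particles per
unit area, each shadowing $\frac{\pi}{4} d^2$, so the covered fraction is
$1.5\, m /(\rho d)$. No published formula accompanies the ~8 × 10⁻⁴ figure
such studies quote; this reconstruction reproduces it with the 90 nm
principal mode as the default diameter, and the diameter is an explicit
parameter because agglomerates would cover less area per unit mass.

## Assay QC

Control charting is Shewhart-style on per-date means of the control's
insert absorbances: centre line at the grand mean, limits at ±3 sd of the
per-date means. No run/trend rules are applied — with tens of dates the
simple limit-breach rule is what the chart can support. The COV series
(100 · sd/mean per date, across inserts within a day) isolates pipetting
variability; under the default generator it averages ~12% for the incubator
control, and the medium blank sits at ~3% of the control signal. Whether
COV should be taken across wells within a day or across technical
replicates is ambiguous in common practice; across wells within a day is
implemented, since technical replicates share an insert and underestimate
handling variability.

The positive control (detergent-killed cells) demonstrates the assay's
dynamic range when it is statistically indistinguishable from the medium
blank; `dynamic_range_check()` reuses the consensus machinery's
pairwise-equality rule for this.

## ToF-SIMS statistics

Spectra are summed into nearest-integer mass-unit bins (ties at .5 round
up — a fixed convention, since "binned to 1 u" underdetermines the rule),
restricted to 200–1200 u (below 200 u salts and medium components dominate;
the metal-oxide ions of interest for imaging lie below the range and are
excluded from the discriminant statistics), and normalised so the retained
peak sum is 100%. Preprocessing is idempotent, and every output sums to
100% within 10⁻⁹.

PCA is centred and unscaled over all bins. The Fisher discriminant
maximises between- over within-group scatter; with ~1000 bins and six
spectra per group the within-group scatter is singular, so it is shrunk
toward its diagonal, $(1-\lambda)W + \lambda\,\mathrm{diag}(W)$ with a small
fixed $\lambda = 0.1$, plus a tiny ridge for bins with zero within-group
variance. Classification is nearest group centroid in the discriminant
space; performance is leave-one-out cross-validation. Under label
permutation LOOCV accuracy is known to centre *below* nominal chance for
balanced two-group designs, so the test suite's null band is the central
99% range of Binomial(n_folds, 1/2)/n_folds rather than a normal interval
around 0.5.

Per-ion comparisons report the exposed group's mean normalised intensity as
a percentage of the control mean with a Welch test per target ion at
p ≤ 0.05, uncorrected by default — mirroring per-ion asterisk reporting —
with Benjamini–Hochberg available via `p_adjust = "BH"`.

## The synthetic-data generators

The generators emulate *statistical structure*, not physics or biology:

* **Plates.** Noise is Gaussian on absorbance (the measurement level), not
  on viability; viability noise then arises through the normalisation
  ratio. Defaults: 12% well-to-well COV for cell-bearing wells, 7.5% for
  blanks, 2% technical-replicate noise, blank at 3% of the control mean,
  and a plate random effect of sd 5 viability points. The plate effect
  shifts exposure conditions only — the incubator control defines 100% on
  its own plate by construction, so shifting it would merely renormalise
  away. The 5-point plate sd is a package default exposed in the config;
  between-plate magnitude is rarely reported and this value produces the
  visible but not dominant day-to-day scatter typical of such assays.
* **Aerosol.** Two lognormal modes on a fixed 64-bin log grid from 10 to
  1000 nm (a typical SMPS export density): a residual mode at 20 nm
  (GSD 1.4) and a particle mode at 90 nm (GSD 1.6), with number totals
  7.4 × 10⁵ and 1.37 × 10⁵ cm⁻³ chosen so the analytic mass concentration
  is ~1.07 mg/m³ whole and ~1.03 mg/m³ above 50 nm — i.e. the bimodal
  number shape and the few-percent sub-50 nm mass share hold
  simultaneously. Scan-to-scan variability is a single lognormal factor
  per scan (GSD 1.1).
* **ICP-MS.** Six Gaussian blanks; per insert and timepoint the true
  compartment masses follow the configured uptake rate and intracellular
  fraction (default 4.85 ng·cm⁻²·h⁻¹ and 0.56, the remainder split evenly
  between wash and basal), observed through a 30% multiplicative
  measurement error plus blank-level background.
* **Spectra.** Six replicate spectra per group with Gaussian peak
  intensities at fractional m/z positions; the exposed group's
  phospholipid/ceramide ions (nominal 625, 777, 791, 813 u) are depressed
  to roughly half the control level.

What the generators do **not** emulate — and what passing tests therefore do
not show about real data: aerosol transport physics (impaction, diffusion,
evaporation), particle agglomeration kinetics, WST-1 reaction kinetics and
saturation, spatially correlated plate artefacts (edge effects), ICP-MS
drift and isobaric interferences, and real lipidomic covariance structure
between ions. Tests against the generators validate the *statistics*; they
cannot validate instrument models the package does not contain.

## Numerical choices and degenerate inputs

* Variance parameters are initialised from data moments, floored at 10⁻⁶ to
  survive zero-variance inputs (identical observations).
* The DerSimonian–Laird $\hat\tau^2$ is floored at 0; mixed zero/non-zero
  uncertainties are rejected rather than silently reweighted.
* Split-R̂ of constant, equal chains is defined as 1; constant, disjoint
  chains give ∞. Sampling noise can leave R̂ marginally below 1.
* `mass_concentration()` requires strictly increasing diameters and
  non-negative counts; an all-zero scan after a cutoff contributes 0 mass.
* PCA on identical spectra reports zero explained variance (not NaN).
* Ion comparisons where both groups are constants use the exact limit of
  the Welch test (p = 1 if equal, p = 0 if not) instead of failing.

## Known limitations

* The consensus model treats inserts as exchangeable within a plate;
  position effects within a plate are not modelled.
* The Gibbs sampler is exact for this conjugate hierarchy but is not a
  general-purpose engine; adding covariates would require restructuring.
* The Fisher discriminant's fixed shrinkage is not cross-validated; with
  six spectra per group there is no data to tune it on, which is the point
  of fixing it.
* Mode detection reports grid-resolution maxima, not fitted mode
  parameters.
* The in-vitro/in-vivo comparison is a rate ratio, not a dosimetric
  extrapolation model.
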