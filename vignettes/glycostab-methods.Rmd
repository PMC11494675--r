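---
title: "Models and design choices in glycostab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in glycostab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`glycostab` analyses the analytical precision and temporal stability of IgG
N-glycome profiles. This vignette records the statistical models the package
implements, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the design choices
made where more than one reasonable convention exists.

## Data model

Measurements are relative peak areas: each sample's electropherogram
(27 CGE-LIF peaks) or chromatogram (24 UPLC peaks) is integrated and each
peak expressed as % of the total integrated area. The data are therefore
*compositional*: values are non-negative, each measurement sums to 100, and
closure induces mild negative correlations between peaks. The container is a
`GlycanExperiment` (a `SummarizedExperiment`: features × measurements, with
sample metadata in `colData`) carrying a processing-state flag
(`raw → normalized → log → batch_corrected → traits → rank_normal`) that the
pipeline functions check, so stages cannot be run out of order.

Derived traits aggregate peaks sharing a structural feature. The groupings
are shipped as editable YAML panel data, not hard-coded. For the 27-peak
CGE-LIF panel the defaults were reconstructed exactly from the published
per-standard grand means (the groupings reproduce all three printed trait
blocks to 1e-5): S = GP1–GP13 (the sialylated peaks), G0 = {GP14, GP15,
GP18}, G2 = {GP25, GP26, GP27}, G1 = {GP16, GP17, GP19, GP20×2,
GP21–GP24}, and unique 12- and 14-peak sets for B and F. GP20 carries
weight 2 in G1 — the unique solution consistent with all three standards,
interpretable as a peak co-eluting two monogalactosylated structures; trait
definitions therefore support per-peak weights. The 24-peak UPLC groupings
follow the common structure-assignment convention and are labelled as
convention-based defaults in the panel file: no published values constrain
them.

## Intermediate precision

For a standards design (pools × plates × replicates, one plate per analysis
day) the package reports, per peak and per derived trait:

* grand mean $\bar{\bar{x}}$ — the mean of all measurements;
* between-run SD $S_b$ — by default the sample SD (denominator
  $n_\mathrm{runs}-1$) of per-plate means, matching the convention that
  tetraplicates are averaged before assessing run-to-run variability.
  Alternatives behind the `s_b` flag: `"pooled"` (SD of all individual
  measurements) and `"anova"` (the one-way ANOVA between-run variance
  component, truncated at zero), because published reports are not always
  explicit about which estimator they print;
* $CV = 100\,S_b/\bar{\bar{x}}$, with $CV = 0$ when $S_b = 0$;
* within-run repeatability (root mean within-plate variance), reported as an
  extra column even where published tables omit it.

Precision is computed on total-area-normalized values *without* batch
correction: correcting by plate would remove the between-run signal being
measured. Grading uses relative-abundance tiers (RA > 3% → CV < 5%;
0.5–3% → < 10%; < 0.5% → < 15%), configurable as a tier table that must
cover $(0, \infty)$ without overlap.

## Preprocessing chain

1. **Total-area normalization** — closure to 100; idempotent and
   scale-invariant. All-zero measurements are data errors.
2. **Log transform** — zeros are substituted before the log according to a
   policy: `"half-min"` (default; half the smallest positive value observed
   for that peak), `"offset"` (a fixed constant), or `"error"`. Zeros occur
   only in low-abundance peaks, where half-minimum substitution perturbs the
   composition negligibly.
3. **Empirical-Bayes batch correction** — the parametric location/scale
   model: per feature, a mean model with batch indicators (plus optional
   protected covariates) is fitted by OLS; residuals are standardized by the
   pooled SD; per (batch, feature) the standardized mean γ̂ and variance δ̂²
   are shrunk toward a normal prior (moment-matched mean and variance across
   features) and an inverse-gamma prior respectively, by iterating the
   posterior fixed-point equations to absolute change < 1e-6 (max 500
   iterations); the standardized data are adjusted by (z − γ*)/δ* and the
   grand mean, covariate fit and pooled scale restored. A single batch is
   the identity transform (with a warning); features constant within a batch
   pass through unadjusted. The fitted `BatchModel` (including the prior
   hyperparameters and iteration counts) is returned and serializable to
   JSON for audit. The implementation is validated in the test suite against
   the reference implementation in Bioconductor's `sva` package to 1e-6.
4. **Back-transform** — exponentiation followed by re-normalization, the
   exact inverse of the log step on normalized tables.
5. **Derived traits** — computed from back-transformed (original-scale)
   percentages, per measurement.
6. **Inverse rank-normal transform** — $z_i = \Phi^{-1}((r_i - c)/(n - 2c +
   1))$ with average ranks for ties and the Blom offset $c = 3/8$
   (configurable), applied per trait *within each analysis stratum* (e.g.
   within sex) so that stratified tests see mean-0/SD-1 inputs without
   cross-group leakage. With the plotting-position population the sample SD
   of the scores is slightly below 1 (about 0.998 at n = 795), which is why
   the contract is "SD within 2% of 1", not exact unity.

Two conventions deliberately differ between outputs: hypothesis tests on
cohorts run on rank-normal values, while trajectory displays and
extreme-value flags use baseline-relative values (each subject's series
divided by its first measurement) — the two representations serve different
purposes and are both kept.

## Time-effect models

**Cohorts** (≥2 subjects): per trait and stratum, the repeated-measures
model $y = \beta_0 + \beta_1 t + b_\mathrm{subject} + \varepsilon$ with a
random intercept per subject, fitted by REML, $t$ in days. The slope is
tested with a Wald-type t statistic using Satterthwaite degrees of freedom
(via `lmerTest`), which is well calibrated at the study's sample sizes
(10–70 subjects, 4–12 visits); a normal-based Wald test would be mildly
anticonservative at the male-stratum size. A singular fit (between-subject
variance estimated at zero) falls back to OLS with a recorded warning; for
balanced designs the slope estimate is identical either way. No random
slope is fitted: the smallest model consistent with repeated measures, and
the short observation windows give little information to identify one.
P-values are BH-adjusted (Bonferroni optional) across the family of six
traits within one stratum; a trait is labelled `increase`/`decrease` only
if its adjusted p-value is below α (default 0.05), otherwise `stable`.

**Single subjects** (≥3 time points): OLS of the baseline-normalized trait
on days since baseline. The slope unit — normalized abundance per day — is
the package's convention for "time effect"; multiplied by the span in days
it gives the total fractional change.

**Extreme values**: on baseline-relative trajectories, four rules: global
top/bottom decile (default 10%), |v − 1| ≥ threshold (default 0.09, i.e.
9% of the initial measurement), transient spikes (a threshold-exceeding
point whose two neighbours are in-band), and swap candidates (≥4 of the 6
traits beyond threshold at one visit with G0 and G2 deviating in opposite
directions — no plausible biological change moves a glycome against its own
galactosylation axis in one visit, but exchanging two subjects' samples
does). The ≥4-of-6/opposition operationalization is this package's
formalization of a phenomenon the source study describes narratively.
Because the F trait is ~95% of total area, closure pins its
baseline-relative value near 1 for any sample, so effectively five traits
carry the swap signature; sensitivity to *subtle* swaps (pairs differing by
barely more than the 9% threshold) is accordingly limited (~70% per swap in
simulation, and the two mirrored rows of one swap rarely both qualify),
while swaps of the conspicuousness actually reported in such screens
(trait deviations of several tens of percent) are detected nearly always
with a false-positive rate near zero.

## Synthetic-data generator

All effects are multiplicative on the peak scale followed by
renormalization, so generated data are compositional like the real thing.
Noise magnitudes that the source study does not state are one-time choices
documented here, not quantities tuned to any test:

* **Analytical noise** is calibrated from the shipped published per-peak
  between-run CVs (log-SD = CV/100; plate effect 0.9× and replicate noise
  1.0× that scale, so plate-mean variance ≈ the printed between-run
  variance). Closure attenuates the realized CV of high-abundance peaks
  (a peak correlates with its own row total), so simulated CVs for the
  largest peaks sit toward the lower end of the printed range — the
  calibration reproduces the printed CV *ranges*, not each peak exactly.
* **Between-subject variation** uses a latent ageing/galactosylation axis
  (log-SD 0.35; loadings +1 on G0 peaks, −0.9 on G2, −0.7 on S), an
  independent bisection axis (0.15 on bisected peaks), a sialylation axis
  (0.08), plus per-group (0.10) and per-peak (0.05) idiosyncrasies.
  Magnitudes are order-of-magnitude choices consistent with
  between-individual trait CVs reported for adult IgG glycomes (G0 roughly
  25–35%, B 15–20%, G1 ~10%) and the 19–48-year age span of the weekly
  cohort.
* **Menstrual-cycle modulation** (female subjects): a sinusoid with
  subject-specific cycle length ~ U[27, 31] days and random phase,
  amplitude 0.015 on the G0 (+) and G2/S (−) groups — the "minimal"
  fluctuation scale such cycles produce.
* **Plate assignment** is balanced round-robin (every visit spread across
  all plates). An earlier subject-major assignment confounded plate with
  visit number and made null cohorts anticonservative even after batch
  correction — perfect confounding is uncorrectable — so the generator
  emulates the randomized plate loading of actual practice.
* **Long-term series** parameterize trends directly on the
  baseline-normalized trait scale: the G0/G2/S peak groups are scaled by
  their target trait multipliers $1 + \beta_g t$ (times any intervention
  factor) and the neutral (G1) remainder group absorbs the closure balance,
  so with zero noise the realized G0/G2/S trajectories equal their targets
  *exactly* and trend recovery is exact to machine precision. Intervention
  episodes apply per-group counter-trend multipliers during a window, with
  exponential relaxation (configurable half-life) afterwards. The default
  5-year and 10-year designs use the published per-day time effects.
* Sample swaps exchange two subjects' peak vectors at one visit, leaving
  metadata untouched; the truth record accumulates in object metadata for
  downstream sensitivity evaluation.

What the generator does **not** emulate: real peak-integration errors,
hormone-mediated covariance between traits beyond the latent axes,
age-dependent nonlinearity (menopause makes female long-term trajectories
sigmoidal rather than linear — the linear-trend machinery here should not
be extrapolated to such data), vaccination or infection episodes, and
instrument drift within a plate. Passing tests therefore demonstrate the
statistical machinery under a faithful but idealized covariance structure,
not performance on raw instrument exports.

## Numerical choices and problem sizes

* EB iteration tolerance 1e-6 (absolute, on both γ* and δ*²), max 500
  iterations; non-convergence is an error naming the batch.
* Closure is asserted at 1e-9 relative; log/back round trips at 1e-9;
  trend recovery on noise-free data at 1e-12.
* Ties in the rank-normal transform use average ranks; a constant vector is
  an error rather than a silent zero vector.
* Precision tiers are half-open intervals $(\mathrm{ra\_min},
  \mathrm{ra\_max}]$, graded strictly (`cv < limit`).
* The test suite exercises the designs at their study scale — 312-
  measurement precision runs, 38-subject and 70-subject cohorts (the latter
  ~795 measurements after 5.4% missingness), 21- and 174-point single-
  subject series — with 50-seed Monte-Carlo loops for the calibration and
  detection properties and 60–100-fit loops for mixed-model calibration;
  the full suite runs in about two minutes on one core.

## Known limitations

* The UPLC-24 trait groupings are conventions, not reconstructed from
  printed data; users with a different integration scheme should supply
  their own panel YAML.
* The mixed model assumes exchangeable residuals within subject;
  menstrual-cycle periodicity aliased against a 30-day sampling grid acts
  like extra between-visit noise and is not explicitly modelled.
* Swap detection requires ≥4 simultaneously deviating traits; with F
  compositionally pinned, swaps between glycomically similar subjects are
  (correctly) hard to distinguish from biology.
* Batch correction removes batch *location and scale* only; it cannot
  rescue a design in which batch is confounded with time.
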