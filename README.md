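# glycostab

Analytical precision and time-dependent stability analysis for IgG
N-glycome profiles.

The IgG N-glycome — quantified as relative areas of 27 CGE-LIF
electropherogram peaks (GP1–GP27) or 24 HILIC-UPLC chromatogram peaks, each
expressed as % of total integrated area — is one of the best-validated
molecular readouts of biological ageing: agalactosylated (G0) and bisected
(B) structures rise with age while digalactosylated (G2) and sialylated (S)
structures fall. Before such a "glycan clock" can be trusted as a biomarker,
two questions must be answered quantitatively: how precise is the assay
across runs, and how stable is an individual's glycome over weeks, months
and years? `glycostab` implements the statistical machinery for both, plus a
synthetic-data generator that emulates the relevant study designs so the
whole pipeline is testable without access to raw cohort data.

## What the package computes

**Intermediate (between-run) precision.** For plasma-pool standards analysed
in replicate across many plates (one plate per analysis day), each peak or
derived trait is summarized by the grand mean x̄̄, the between-run SD S_b
(the SD of per-plate means, denominator n_runs − 1), and

    CV = 100 · S_b / x̄̄  (%)

Results are graded against relative-abundance-tiered acceptance criteria:
RA > 3% requires CV < 5%; 0.5–3% requires CV < 10%; RA < 0.5% requires
CV < 15%.

**Preprocessing chain.** Total-area normalization (closure to 100%) → natural
log → parametric empirical-Bayes location/scale batch correction over plates
(the ComBat model: per-feature standardization, per-(batch, feature) moment
estimates shrunk toward moment-matched normal / inverse-gamma priors, then
adjustment and back-standardization) → back-transform → derived traits
(G0, G1, G2, S, B, F as weighted sums of peak groups) → inverse rank-normal
transform z_i = Φ⁻¹((r_i − 3/8)/(n + 1/4)) per analysis stratum.

**Time effects.** Cohorts: a linear mixed model per trait and stratum,
`value ~ time + (1 | subject)` (REML), time in days, Satterthwaite t test on
the slope, Benjamini–Hochberg adjustment across the six traits of a stratum.
Single subjects: OLS of the baseline-normalized trait (every value divided
by that subject's first measurement) on days since baseline.

**Extreme-value screening.** On baseline-normalized trajectories: global
top/bottom decile flags, a ±9%-of-baseline threshold rule, transient-spike
detection, and a sample-swap heuristic (≥4 of 6 traits beyond threshold at
one visit with G0 and G2 deviating in opposite directions).

## Worked example

```r
library(glycostab)

# three plasma pools x 26 plates x 4 replicates (312 measurements),
# noise calibrated from the published between-run CVs
sim <- simulatePrecisionExperiment(precisionDesign(seed = 1))
res <- gradePrecision(precisionTable(sim))
subset(res, standard == "pool1" & trait %in% c("GP15", "GP20", "G0"))
#>    standard trait grand_mean    s_b      cv cv_limit grade
#> 15    pool1  GP15    17.6651 0.2060  1.1661        5  pass
#> 20    pool1  GP20     0.4135 0.1249 30.2096       15  fail
#> 28    pool1    G0    20.5443 0.2431  1.1833        5  pass
attr(res, "summary")
#> pass fail
#>   91    8
```

GP15 (a high-abundance agalactosylated peak) passes its 5% limit with CV
≈ 1.2%; GP20, a low-abundance (≈0.4%) bisected peak, exceeds even the
permissive 15% limit — the same peak the published precision assessment
singles out as the clearest criteria violation. The derived trait G0 is
measured with CV ≈ 1.2%, precise enough to track ageing effects of a few
percent per year.

```r
# a 5-year quarterly single-subject series with the published ageing drift
# (G0 +0.000051/day, S -0.000073/day) and 1.5% analytical noise
lt  <- simulateLongitudinalSubject(fiveYearDesign(seed = 1))
rel <- baselineNormalize(computeDerivedTraits(lt))
fitSubjectTrend(rel)[, c("trait", "time_effect", "p_adjusted", "direction")]
#>   trait time_effect p_adjusted direction
#> 1    G0    5.71e-05   1.03e-11  increase
#> 2    G1    3.81e-05   2.27e-12  increase
#> 3    G2   -4.86e-05   9.04e-08  decrease
#> 4     S   -7.59e-05   1.67e-15  decrease
#> 5     B   -2.72e-06   3.93e-01    stable
#> 6     F    1.04e-06   3.44e-06  increase
```

The OLS trend recovers the generating slopes (G0 within 12%, S within 4%
here) and labels the directions of change after multiple-testing
adjustment.

A command-line wrapper for the three experiment types lives at
`inst/scripts/glycostab.R` (subcommands `simulate`, `precision`,
`stability`; exit codes 0/2/3 for success/config error/data error).

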