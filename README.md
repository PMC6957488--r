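# thermosat

Complexity and coupling analysis of skin oxygen-saturation and
speed-resolved blood-perfusion recordings under local thermal stimulation.

## What it is for

Combined diffuse-reflectance / laser-Doppler probes (EPOS-style systems)
record, at 3 Hz, tissue oxygen saturation together with microvascular
perfusion resolved into three blood-speed components — V1 (< 1 mm/s),
V2 (1–10 mm/s), V3 (> 10 mm/s) — under a protocol of 30 min baseline,
30 min local heating (blank control, or 38/40/42/44 °C), and 30 min
post-stimulation recording. `thermosat` is for researchers analysing such
recordings who want to quantify

* how thermal stimulation changes the **complexity** of the
  oxygen-saturation signal, and
* how it changes the **coupling** between oxygen saturation and each
  perfusion speed component,

with reproducible, seeded statistics — plus a synthetic cohort generator
with known ground truth so every stage of the analysis can be validated
without access to human data.

## Methods at the core

* **Sample entropy** SampEn(m, r) = −ln(A/B), where B counts pairs of
  length-m templates within Chebyshev tolerance r·SD (self-matches
  excluded) and A counts those still matching at length m+1; and **fuzzy
  entropy**, which replaces the hard threshold by the membership function
  exp(−(d/r)^n) on mean-removed templates. Defaults m = 2, r = 0.15,
  fuzzy power n = 2.
* **Multiscale curves (MSE / MFE)**: the entropy of the coarse-grained
  series (disjoint block means of length τ) for scales τ = 1..20, and the
  **complexity area index (CAI)** — the trapezoidal integral of the
  entropy-versus-scale curve.
* **Spearman correlations** (mid-ranks; large-sample t p-values, exact
  permutation p for small n): per subject between perfusion and oxygen
  saturation in the time domain, and across subjects between the CAIs of
  the two signals.
* **Group comparisons**: one-way independent-design F across the five
  condition groups (with the study-sized cohort this carries df (4,141)),
  and seeded two-sided permutation posttests on all 10 pairwise contrasts,
  p = (1 + #{|perm| ≥ |obs|}) / (1 + n_perm), exhaustive for pooled
  n ≤ 10.

The entropy kernels are implemented in C++ and validated against plain-R
brute-force oracles, the analytic iid-Gaussian SampEn limit, and the
classic multiscale contrast (1/f noise has a larger CAI than white noise;
white-noise MSE decreases with scale).

## Worked example

```r
library(thermosat)

# generate a small synthetic cohort: 8 stimulated + 8 control subjects,
# 5-minute epochs
cfg <- synthetic_config(epoch_minutes = c(5, 5, 5), seed = 42)
cohort <- generate_cohort(study_design(8, 8, seed = 42), cfg)
cohort
#> signal_dataset: 200 records, 16 subjects, conditions: 38, 40, 42, 44, BC

# multiscale entropy of one oxygen-saturation recording (stimulation epoch)
rec <- get_record(cohort, "TS01", "40", "oxy_sat")
seg <- extract_epoch(rec, config_epochs(cfg), "stimulation")
mse_curve(seg$values, entropy_params(max_scale = 10))
#> MSE curve over scales 1..10  (m = 2, r = 0.15)
#>   CAI: 17.91264

# per-subject correlation of V1 perfusion with oxygen saturation
tab <- timecourse_correlations(cohort, config_epochs(cfg), "stimulation",
                               pairs = "V1")
round(tapply(tab$rho, tab$condition, mean), 3)
#>     38     40     42     44     BC
#>  0.490  0.240 -0.016 -0.083  0.187

# group comparison of those correlations across the five conditions
groups <- split(tab$rho, factor(tab$condition,
                                levels = c("BC", "38", "40", "42", "44")))
cmp <- compare_conditions(groups, n_perm = 999, seed = 42)
cmp$anova
#> one-way ANOVA: F(4,35) = 22.08, p = 3.626e-09  (n = 8/8/8/8/8)
```

The mean correlations recover the generator's configured couplings
(0.5 at 38 °C, 0.3 at 40 °C, 0 at 42 °C, −0.2 at 44 °C, 0.2 for blank
control): mild heating strengthens the rank coupling between low-speed
perfusion and oxygen saturation, strong heating abolishes or reverses it,
and the omnibus F detects the condition effect. `run_all()` composes the
full pipeline (time courses, CAIs with group comparisons, time-domain and
CAI correlations) into a results bundle of TSVs plus a JSON manifest;
`inst/scripts/thermosat.R` exposes the same stages as shell subcommands
(`simulate`, `timecourse`, `entropy`, `correlate`, `compare`, `all`).

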