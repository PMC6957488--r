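---
title: "Complexity and coupling of thermally stimulated skin oxygen saturation: methods"
author: "thermosat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complexity and coupling of thermally stimulated skin oxygen saturation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermosat)
```

## The problem

Local heating of the skin triggers thermal hyperaemia: microvascular
perfusion and tissue oxygen saturation both rise, with a magnitude and time
course that depend on the stimulus temperature. Combined diffuse-reflectance
/ laser-Doppler probes (EPOS-style systems) record, at 3 Hz, tissue oxygen
saturation (%) together with perfusion resolved into three blood-speed
components — V1 (< 1 mm/s), V2 (1–10 mm/s) and V3 (> 10 mm/s) — under a
protocol of 30 min baseline, 30 min stimulation (blank control, or heating
at 38/40/42/44 °C), and 30 min post-stimulation recording.

`thermosat` implements the downstream analysis of such recordings:

1. **Signal handling** — long-format CSV IO, protocol epoching, and
   minute-averaged time courses (each mean over the half-open window
   $[t-30\,\mathrm{s}, t+30\,\mathrm{s})$, i.e. exactly 180 samples at 3 Hz).
2. **Complexity** — multiscale entropy (MSE), multiscale fuzzy entropy
   (MFE), and the complexity area index (CAI) of the oxygen-saturation
   signal.
3. **Association** — Spearman correlations between each perfusion component
   and oxygen saturation, per subject in the time domain and across
   subjects at the level of CAIs.
4. **Group statistics** — one-way independent-design F across the five
   condition groups plus seeded permutation posttests for all pairwise
   contrasts.
5. **Synthetic cohorts** — a generator with known ground truth (response
   shapes, noise complexity, rank couplings) so that every stage can be
   validated by simulation without access to human data.

## Entropy estimators

**Sample entropy.** For a series of length $N$, embedding dimension $m$ and
absolute tolerance $r_{\mathrm{abs}}$, let $B$ count pairs $i<j$ of
length-$m$ templates (over the $N-m$ templates whose extension exists) with
Chebyshev distance strictly below $r_{\mathrm{abs}}$, and $A$ the subset
still matching at length $m+1$. Then
$\mathrm{SampEn} = -\ln(A/B)$. Self-matches are excluded. $A=0$ makes the
statistic undefined: the value is reported as `NA`, never substituted by a
ceiling, because substitution would silently bias group means. $B=0$ means
the tolerance is degenerate for that signal and is an error.

**Fuzzy entropy.** The hard threshold is replaced by the membership
function $\exp(-(d/r_{\mathrm{abs}})^n)$ ($n$ = fuzzy power) applied to
templates with their own mean removed; $\phi^m$ is the mean similarity over
ordered template pairs $i \ne j$ (equal to the unordered mean by symmetry,
which is what the brute-force oracle in the test suite evaluates), and
$\mathrm{FuzzyEn} = \ln\phi^m - \ln\phi^{m+1}$. Both $\phi$'s use the same
$N-m$ templates.

**Multiscale curves and CAI.** Coarse-graining at scale $\tau$ replaces the
series by means of disjoint blocks of length $\tau$ (tail discarded,
$\lfloor N/\tau \rfloor$ samples). The MSE/MFE curve evaluates the plain
entropy of each coarse-grained series for $\tau = 1..\tau_{\max}$, and the
CAI is the composite-trapezoid integral of the curve over the scale axis
(unit spacing). An undefined entropy at any scale invalidates the CAI
(reported missing) rather than being interpolated.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `m` | 2 | embedding dimension (template length) |
| `r` | 0.15 | tolerance as a fraction of the signal SD |
| `fuzzy_power` | 2 | exponent of the fuzzy membership function |
| `max_scale` | 20 | largest coarse-graining scale |
| `r_mode` | `fixed_original_sd` | tolerance fixed from the scale-1 series |

`m = 2`, `r = 0.15`, fuzzy power 2 are the standard settings for skin
blood-flux and oxygen-saturation complexity analysis. Numerical choices
made once and kept fixed:

* The SD entering $r_{\mathrm{abs}} = r \cdot \mathrm{SD}$ is the
  **population** SD (divisor $N$); the difference from the sample SD is
  immaterial at epoch lengths of thousands of samples but fixing it makes
  the tolerance bit-reproducible.
* By default the tolerance is computed from the original series and reused
  at every scale (the classical multiscale convention). `per_scale_sd`
  recomputes it per coarse-grained series and is available as an option.
* `max_scale` is not a universally agreed value; the default 20 is guarded
  by auto-reduction so that $\lfloor N/\tau\rfloor \ge m+2$ at every scale,
  with a warning and a structured log entry when the guard engages.

The estimators are implemented in C++ ($O(N^2)$ template loops with early
exit); the test suite checks them against plain-R brute-force oracles to
1e-10 and against the analytic iid-Gaussian limit
$-\ln\!\big(2\Phi(r/\sqrt2) - 1\big)$.

## Association analyses

Spearman's $\rho$ is the Pearson correlation of mid-ranks (ties averaged).
p-values use the large-sample $t$ approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df; an exact permutation p
(enumeration of all $n!$ orderings, mid-ranks preserved) is available for
$n \le 10$ and is the automatic choice for $n \le 8$. Two design choices:

* **Time-domain correlations use the raw 3 Hz epoch samples**, not minute
  means; which samples constitute "after stimulation" is configurable
  (`after_window`): the stimulation epoch (default — the response is
  maximal there), the post epoch, or both concatenated.
* **CAI correlations drop missing CAIs pairwise**, reporting the remaining
  n, mirroring how a study retains the subjects whose data import
  succeeded. p-values are two-sided with no multiplicity correction (the
  per-panel reporting convention); a Holm option exists for the group
  posttests.

## Group statistics

Printed F statistics in this literature carry independent-design degrees of
freedom — with 30 controls and 29 stimulated subjects per temperature,
$146$ condition cells give $F_{(4,141)}$ — so the omnibus test is the
classical one-way between/within F (via `stats::oneway.test`,
`var.equal = TRUE`). Repeated-measures covariance modelling is deliberately
out of scope. Posttests are two-sided label-shuffling permutation tests on
the difference of group means: `p = (1 + #{|perm| >= |obs|}) / (1 + n_perm)`
with a mandatory seed; for pooled samples of at most 10 observations the
test switches to exhaustive enumeration over all label splits. The test
suite verifies the F = t² identity for two groups, the df pattern, the
exhaustive toy case against full enumeration, and a 1000-replicate type-I
error calibration at α = 0.05.

## The synthetic cohort generator

The generator emulates the *structure* of EPOS-style thermal-stimulation
recordings — not the instrument physics, and not any numeric level read
off published figures (none are available as data).

**Protocol.** 3 Hz sampling; 30/30/30-minute baseline/stimulation/post
epochs (16,200 samples, 5,400 per epoch); a thermal-stimulation group whose
subjects each receive all four temperatures in a seeded random order, and a
blank-control group recorded unheated.

**Mean response.** Flat baseline; during stimulation a saturating
exponential rise of height $A(T)$ with time constant
$t_{\mathrm{peak}}(T)/3$ (so the rise is ~95% complete at the nominal time
to peak); after stimulation an exponential return towards baseline at rate
$k(T)$, with $k = 0$ freezing the post epoch at the stimulation-end level
(the high-temperature "no decay" regime). Defaults: baseline 50%,
amplitudes 4/7/9/10% and times-to-peak 30/15/5/5 min for 38/40/42/44 °C,
decay rates 1/300, 1/600, 1/900 and 0 s⁻¹. These levels are arbitrary
(stated as such): no published numeric oxygen-saturation levels exist for
this protocol, so they are free parameters chosen once to be physiologically
plausible — slower, smaller responses at milder temperatures; faster,
larger, more persistent responses at higher ones. The biphasic
axon-reflex/plateau shape of thermal hyperaemia is deliberately not
modelled: a single saturating rise is sufficient for the analyses validated
here, which never separate the two stages.

**Noise and complexity control.** Oxygen-saturation noise is
$w\cdot\text{white} + (1-w)\cdot 1/f$, both Gaussian, the $1/f$ component
synthesised by spectral shaping (FFT of white noise with a $1/\sqrt f$
amplitude envelope, DC zeroed) — chosen over AR cascades for exact seeding
and transparency. `white_fraction` $w$ tunes complexity: white noise has
the higher scale-1 entropy, $1/f$ noise the higher CAI over scales 1–20
(the classic multiscale contrast, verified by simulation in the acceptance
tests). A per-subject jitter of $w$ (optionally shared across channels)
gives subjects individual complexity, which is what makes cross-subject
CAI correlations recoverable.

**Coupling.** Each perfusion channel mixes a latent stream shared with the
oxygen channel with private noise. The shared stream is the
**normal-scores transform of the realised oxygen signal** (thermal response
included), and the mixing weight is $\lambda = 2\sin(\pi\rho_s/6)$ — the
bivariate-Gaussian identity between Pearson correlation and Spearman's
$\rho_s$. Two consequences drove this design: the configured rank coupling
holds (in population, exactly) even when the deterministic thermal trend
dominates the ranks; and negative couplings can coexist with a rising
response, which is exactly the high-temperature regime in which perfusion
and oxygen saturation decouple. The alternative — adding an independent
response template to each perfusion channel and sharing only the raw noise
— makes the common trend swamp the within-epoch ranks and caps the
achievable coupling range, so it was rejected. A corollary worth knowing:
the perfusion channels inherit their thermal response *through* the
coupling, so a channel configured with coupling 0 shows no mean response.
Oxygen saturation is clipped to [0, 100] after noise addition and clip
events are logged, because clipping creates ties and distorts entropy.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: instrument noise spectra and drift, movement
artefacts, the biphasic hyperaemia shape, physiological oscillation bands
(endothelial/neurogenic/myogenic), inter-channel couplings beyond the
single shared latent stream, and any absolute signal level. Ground-truth
recovery on this generator validates the *estimators*, not the physiology.

## Pipeline and reproducibility

`run_all()` composes the stages into a results bundle of tidy TSVs
(time courses; CAIs before/after with omnibus + pairwise comparisons;
per-subject time-domain correlations with group comparisons; per-condition
CAI correlations) plus a JSON manifest carrying the configuration, an MD5
configuration hash (also embedded in every TSV header), the package
version, and the structured event log (clipped samples, skipped subjects,
auto-reduced scales, undefined entropies). Identical configuration and
seed give byte-identical outputs; a failing stage aborts with its name and
removes partial output.

All randomness is routed through explicit seeds: a master seed plus a
deterministic stream-derivation scheme (multiplicative hashing modulo
$2^{31}-1$) gives every subject/condition/channel its own reproducible
stream without clobbering the caller's RNG state.

### Problem sizes used in the tests

The validation suite chooses sizes that exercise the estimators at full
recording length where the claim depends on it, and reduced cohorts where
it does not: entropy oracles on series of length ≤ 60 (where $O(N^2)$
brute force in R is exact and fast); the analytic SampEn limit at
N = 5,000 over 20 seeds; the white-vs-1/f CAI contrast at the full
N = 16,200 over 20 replicates; coupling-ordering recovery on
10-subject-per-group cohorts with 5-minute epochs (rank correlations at
n = 900 samples already estimate the configured couplings to ±0.05);
and permutation calibration over 1,000 null replicates at n_perm = 999.

## Known limitations

* The one-way F treats the four temperature cells of a stimulated subject
  as independent groups (matching the printed-df convention of the field);
  within-subject correlation is not modelled.
* Minute averaging assumes an aligned, gap-free grid; the reader rejects
  gaps > 1.5× the median step rather than imputing.
* The exact Spearman permutation p is enumerative and limited to n ≤ 10.
* MATLAB-format instrument exports are not read; the canonical interchange
  format is the long CSV.
* Refined/composite multiscale variants and other entropies (permutation,
  dispersion) are out of scope, as are frequency-domain (wavelet)
  analyses.
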