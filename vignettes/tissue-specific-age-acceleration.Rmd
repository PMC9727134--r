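---
title: "Tissue-specific epigenetic age acceleration: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-specific epigenetic age acceleration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsage)
```

## The scientific question and the analysis model

A disease confined to one tissue — here oligozoospermia, a clinically low
sperm concentration — may accelerate the epigenetic aging of that tissue
without touching the rest of the body. The design that answers this is
paired: each man contributes a semen and a blood sample, a germ-line
methylation clock scores the sperm and a somatic clock scores the blood,
and two-group comparisons are run per tissue.

A linear methylation clock predicts age from CpG beta values,
$m = b_0 + \sum_i c_i \beta_i$, optionally through the piecewise
"log-adult" transform that makes somatic clocks linear in
$\log\!\big((\text{age}+1)/(\text{adult}+1)\big)$ below the adult
breakpoint and in $(\text{age}-\text{adult})/(\text{adult}+1)$ above it.
Clocks carry cohort-level offsets (array batch, tissue, training-set
shift), so predicted ages are first **mean-matched** within tissue:
all predictions are shifted by $d = \overline{\text{chron}} -
\overline{\text{pred}}$, which forces the adjusted mean onto the
chronological mean while preserving every within-cohort contrast. The
per-sample **germ-line age differential** is then

$$\mathrm{GLAD}_i = \frac{\text{adjusted}_i - \text{chron}_i}{\text{chron}_i},$$

the *relative* age acceleration. The ratio form is deliberate: raw
year-differences grow with age (heteroskedasticity), while the ratio is
invariant to rescaling both ages. Applied to a somatic tissue the same
quantity is a "GLAD-equivalent" score.

One wording issue deserves a note. Descriptions of this statistic
sometimes read as "the normalized epigenetic age divided by the
chronological age", which would center the values near 1, yet the group
means discussed for such data (≈ 0.08, −0.02) center near 0. We therefore
define GLAD as the centered ratio above (`form = "centered"`), which is
the quotient minus one, and expose the literal quotient behind
`form = "ratio"`.

## The comparison battery

* Welch (unequal-variance) two-sample t-tests with Satterthwaite degrees
  of freedom compare GLAD between groups within each tissue. Group sizes
  are unequal (10 vs 24 by default) and the groups contain different
  individuals, so **between-group tests are unpaired**; the paired design
  is used only to form per-individual sperm − blood predicted-age
  differences, which are themselves compared between groups with a Welch
  test. All p-values are two-sided, unadjusted for multiplicity (a
  Bonferroni option exists on `run_comparisons()` and reports adjusted
  values alongside, never replacing, the raw ones).
* OLS regressions of predicted on chronological age per tissue report the
  slope p (t with $n-2$ df), $r^2$, and adjusted
  $r^2 = 1-(1-r^2)\frac{n-1}{n-2}$ — the accuracy diagnostic for the
  clocks themselves.
* Degenerate inputs (zero variance) return flagged non-finite statistics
  rather than raising, so Monte-Carlo batches never abort: equal constant
  samples give $t=0, p=1$; unequal constant samples give infinite $t$
  with `degenerate = TRUE` and `p = NA`.

## Sample-level quality control

* **Bimodality.** A clean methylome's beta density has peaks in
  $[0, 0.2]$ and $[0.8, 1]$ with a flat valley between. Visual density
  inspection is operationalized as interval masses: pass iff
  $P(\beta \le 0.2) \ge 0.25$, $P(\beta \ge 0.8) \ge 0.25$ and
  $P(0.2 < \beta < 0.8) \le 0.35$. The thresholds are deliberately
  permissive surrogates for "prominent peaks / flat valley" and are
  configurable; at least 1000 beta values are required.
* **DLK1 contamination sentinel.** The DLK1 region is nearly
  unmethylated in pure sperm and highly methylated in leukocytes, so the
  mean beta over DLK1-region CpGs rises affinely with the somatic mixing
  fraction (slope = blood mean − sperm mean). Pass iff the mean is
  ≤ 0.25, boundary inclusive. The direction (≤, not a two-sided band) is
  our reading of "within the accepted threshold": contamination can only
  raise the statistic from the clean state; both direction and threshold
  are configurable. CpG identities come from an annotation file, keeping
  the check array-agnostic. The check applies to sperm only by default.
* **Median intensity.** "Below the standard" is scanner-dependent; we
  default to 10.5 on the log2 scale, a conventional cutoff, and record
  the check as *not evaluated* (rather than silently passed) when no
  intensity table is supplied.
* **Age confound.** A Welch t-test on chronological age between groups,
  over unique individuals, guards against interpreting an age imbalance
  as a disease effect.

Renormalization of the retained samples (e.g. SWAN) operates on raw array
data and is out of scope: input betas are assumed pre-normalized.

## What the synthetic generator emulates

`generate_cohort()` states a world and the defaults are that world — they
are not tuning knobs:

* **Cohort structure.** 10 oligozoospermic vs 24 normozoospermic
  individuals, ages 32.73 ± 1.9 and 31.64 ± 1.3 (mean ± SE) years. The SE
  is converted to an individual-level SD by $SD = SE\sqrt{n}$, preserving
  the printed summaries in expectation; ages are truncated to [18, 60],
  which also keeps GLAD's denominator bounded away from 0. One sperm and
  one blood sample per individual (configurable only through the sheet).
* **Acceleration model.** Effective age = chronological × (1 + accel),
  applied to the case group per tissue. Multiplicative acceleration is a
  modeling choice (no generative model is stated for such data): it makes
  GLAD, a ratio, target `accel` directly, so "recover 0.095" is a
  well-posed parameter-recovery task. 0.095 mirrors the scale of the
  sperm GLAD group gap reported for cohorts of this design
  (0.078 − (−0.017)).
* **Clock CpGs.** $\beta_{ij} = \mathrm{clip}(b_{0i} + s_i \cdot
  \text{eff\_age}_j + \varepsilon_{ij},\ 0,\ 1)$ with slopes drawn
  uniformly from ±[0.002, 0.008]/year and baselines from [0.15, 0.35]
  (gaining CpGs) or [0.65, 0.85] (losing CpGs). These ranges keep
  noise-free trajectories inside [0,1] over the whole age span; a config
  whose ranges would clip > 1% of noise-free values at the extreme ages
  is rejected outright as an unusable generative regime. In the *other*
  tissue a clock's CpGs sit age-flat at their mid-trajectory level, so
  somatic contamination attenuates the sperm clock's signal toward a
  constant — the failure mode the DLK1 check catches.
* **Noise.** $\varepsilon \sim N(0, 0.13)$ per clock CpG per sample.
  No per-CpG noise magnitude is published for such arrays; 0.13 was
  chosen once so that the default 50-CpG clock has a prediction-error SD
  of ≈ 3.5 years (measured: 3.4), the accuracy scale real methylation
  clocks report, which puts adjusted r² in the 0.64–0.88 range and the
  sperm test's power near 0.6 at the default design — the regime in
  which a p ≈ 0.02–0.03 detection is plausible. It aggregates technical
  and inter-individual biological variance, hence is larger than pure
  array noise; background and DLK1 CpGs get a separate 0.03 technical SD.
* **True clocks.** Each generated clock ships its analytic least-squares
  inverse: minimizing $\sum_i (\beta_i - b_{0i} - s_i a)^2$ over $a$
  gives coefficients $s_i / \sum s^2$ and intercept
  $-\sum s_i b_{0i} / \sum s^2$. On noise-free data the inversion is
  exact (the basis of the zero-GLAD acceptance identity); under i.i.d.
  noise the error SD shrinks as $1/\sqrt{k}$.
* **Background CpGs.** Per-CpG archetype levels from a bimodal mixture
  (45% Beta(2,28), 45% Beta(28,2), 10% Beta(2,2)), shared across tissues,
  plus technical noise — giving valley mass well under the QC bound.
* **Determinism.** Same config + seed ⇒ byte-identical output; the
  generator saves and restores the caller's RNG state. The pipeline
  derives per-stage and per-replicate substreams from one global seed.

**What a green test does *not* establish.** The generator has no probe
cross-reactivity, SNP-affected probes, batch effects, cell-composition
gradients, or raw two-channel intensities (the intensity table is a
log-normal summary only), and clock CpGs are conditionally independent
given age, which real CpGs are not. Green acceptance means the *pipeline*
is correct and well-calibrated on data satisfying its assumptions — not
that any particular biological cohort satisfies them.

## Numerical choices and degenerate inputs

* Beta values violating [0,1] by ≤ 1e-6 are clamped (float dust from
  upstream normalizers); larger violations abort.
* Missing clock CpGs abort by default (`missing = "fail"`); mean and
  reference imputation are opt-in because silent imputation biases age
  acceleration. Mean imputation uses the sample's own mean over the
  clock CpGs present.
* Mean-matching pools both groups within a tissue. Per-group matching
  (`scope = "per_group"`) would force every group's mean GLAD to ~0 and
  erase the contrast of interest; it is kept as a diagnostic mode since
  the pooling scope is genuinely an open choice in this analysis style.
* The adjusted-r² guard `rss = max(rss, 0)` absorbs catastrophic
  cancellation on near-perfect fits; a perfect fit reports slope p = 0.
* QC filtering is idempotent and invariant to row/column order; if every
  sample fails, the run aborts with the per-sample reasons rather than
  proceeding on an empty matrix.

## Known limitations

* Real public clock coefficient sets are not bundled (licensing and
  versioning); any `cpg_id,coefficient` CSV loads, and the synthetic
  true clocks are the tested fixtures.
* The power simulation varies only sperm acceleration and sample sizes;
  it does not model covariates (smoking, BMI, ethnicity) that affect
  sperm methylation in real cohorts.
* The bimodality thresholds were chosen for 450K/EPIC-like beta
  distributions; arrays or WGBS data with different probe-type mixtures
  may need different `p_peak`/`p_valley`.

## A minimal run

```{r, eval = FALSE}
cfg <- sim_config(sperm_accel_oligo = 0.095, seed = 7)
res <- analyze_cohort(generate_cohort(cfg), qc = TRUE)
res$report

# power across the acceleration grid used by the acceptance battery
power_analysis(sim_config(n_background_cpgs = 1, n_dlk1_cpgs = 1, seed = 1),
               accel_grid = c(0, 0.05, 0.095, 0.15), n_replicates = 200)
```
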