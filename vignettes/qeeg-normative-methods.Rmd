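---
title: "Building and validating an age-stratified qEEG normative database"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and validating an age-stratified qEEG normative database}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qeegnorm)
```

## The problem

Quantitative EEG compares an individual's resting-state spectral features
with a reference ("normative") population. The core object is a table of
means and standard deviations of absolute band power — per age group, per
electrode, per frequency band — built from a screened healthy cohort.
Any subject can then be expressed as a z-score,

$$z = \frac{x - \mu_{g,e,b}}{\sigma_{g,e,b}},$$

where $x$ is the subject's absolute power at electrode $e$ and band $b$
and $(\mu, \sigma)$ come from the cell of the subject's own age group
$g$. Under a Gaussian reference, 68.26% / 95.44% / 99.74% of healthy
individuals fall within $\pm1$, $\pm2$, $\pm3$ SD; cohort-level mean z
or mean $|z|$ beyond $\pm 1$ is the conventional abnormality flag. The
$|z|$ companion table matters because bidirectional deviations cancel in
a signed mean but not in the absolute mean.

`qeegnorm` implements the full pipeline: recording IO and screening,
windowed artifact rejection, Welch band power, norm construction and
z/|z| reporting, the cohort statistics used to characterise such
databases, and the reliability/validity machinery (internal consistency,
leave-one-out, independent cross-database correlation, coverage audits).
A synthetic-data module generates cohorts and raw signals with known
ground truth so every stage can be exercised end to end.

## Recording model and preprocessing

Recordings are 19-channel 10--20 montages (Fp1 ... O2), linked-ear
referenced, eyes closed, sampled at 256 Hz (any rate above twice the
30 Hz analysis ceiling is accepted). Artifact screening tiles the
recording into consecutive 20-s windows — the width used when resting
EEG is deartifacted by visual inspection — and drops any window in which
a channel exceeds an absolute amplitude limit (default $\pm100\,\mu V$)
or jumps more than a gradient limit between consecutive samples
(default $50\,\mu V$/sample). These two thresholds are an automated,
reproducible surrogate for manual deartifacting; both are exposed as
arguments. The gradient is evaluated within windows only, which makes
rejection idempotent on the concatenation of retained windows. A
trailing partial window is discarded rather than padded, matching
fixed-window screening semantics. At least 60 s of clean data
(boundary inclusive) must survive, otherwise the subject is excluded
with reason `"artifact"` and feeds the cohort exclusion ledger.

Cohort screening is deliberately literal: healthy controls require
BDI-II < 14 *and* BAI < 8; patients require BDI-II > 14 *and* BAI > 8
with a primary MDD diagnosis; both require age 20--70 inclusive. Scores
exactly at 14/8 therefore fail both screens — the cutoff convention is
ambiguous in common practice, and we keep the strict reading while
exposing the thresholds in `screening_thresholds()`.

## Spectral estimation

Band power uses Welch's method: 2-s Hann-tapered epochs with 50%
overlap, drawn from clean segments only (epochs never cross a segment
boundary), one-sided PSD with density scaling in $\mu V^2$/Hz. Two-second
epochs give 0.5 Hz resolution, sufficient for the integer band edges.
Absolute band power is the trapezoidal integral of the PSD over each
band of the five-band scheme (delta 1--4, theta 4--8, alpha 8--12, beta
12--25, high-beta 25--30 Hz). Under trapezoidal weighting an interior
shared edge (4, 8, 12, 25 Hz) carries half weight in each adjacent band,
so each edge is counted exactly once overall and the five bands sum
exactly to the 1--30 Hz integral. Frequencies below 1 Hz and above
30 Hz never enter any band. No log transform is applied by default —
scoring operates on absolute power — but `log10_power = TRUE` is
available for workflows that prefer the log scale.

A useful calibration: a pure sinusoid of amplitude $A$ carries total
power $A^2/2$, so a 20 µV, 10 Hz tone yields $\approx 200\,\mu V^2$ in
alpha (the suite asserts this within 1% spectral-leakage tolerance).

## The normative database

`build_norms()` stratifies by the default ten-year scheme 20--30,
31--40, 41--50, 51--60, 61--70 (integer ages, inclusive bounds on both
ends, so 30 belongs to the first group). Cell means are arithmetic
means; cell SDs use the sample ($n-1$) denominator. That choice makes
the self-scoring invariant exact: scoring the construction cohort
against its own database yields mean z = 0 and sample SD of z = 1 in
every cell, up to floating round-off, because the same estimator is
used on both sides. Norms are age-stratified only; recruitment balances
sex, but the reference cells do not condition on it.

`zscore_subject()` offers two modes. `own_group` is the clinically
meaningful one. `all_groups` scores every subject against every age
group; its only purpose is bookkeeping — a cohort of $n$ subjects
produces exactly $n \times 19 \times 5 \times 5$ z-values (123,500 at
$n = 260$; 104,975 at $n = 221$) — and the cohort report is always
built from `own_group` scores. Cells with $\sigma = 0$ are stored but
poison scoring with an explicit error instead of returning $\pm\infty$.
The printed report drops the prefrontal pair Fp1/Fp2 (the conventional
17-row layout) while scoring retains all 19 electrodes.

## Statistics

The cohort statistics are thin, well-tested wrappers where base R
already provides the machinery (chi-square with adjusted standardized
residuals via `chisq.test`, LOWESS via `lowess`, Pearson via
`cor.test`) and direct formulas where it does not: t tests from
published group summaries (pooled df $n_1+n_2-2$, or Welch--Satterthwaite
fractional df), one-way ANOVA from sums of squares, Bonferroni post hoc
as all pairwise pooled t tests with p multiplied by the number of
comparisons (capped at 1), and Cronbach's
$\alpha = \frac{k}{k-1}\bigl(1 - \sum_i s_i^2 / s_T^2\bigr)$ with
sample variances. Cell-wise contingency comparisons use adjusted
standardized residuals with a $|1.96|$ cutoff, the standard post hoc
for r x c tables. The 2x2 chi-square is uncorrected by default (a
Yates flag exists); correlation matrices report raw two-sided p-values
without multiplicity adjustment. For internal consistency, the three
central electrodes C3/Cz/C4 act as items and participants as cases,
computed on absolute power per band. Sphericity corrections are not
implemented anywhere: they belong to repeated-measures designs, not to
the between-subjects one-way ANOVA used on age groups.

## Validation machinery

*Leave-one-out*: each subject is scored against norms rebuilt from their
age group minus themselves. As group size grows, the LOO z converges to
the own-group z at rate $O(1/n)$, and the LOO distribution per cell has
mean ≈ 0 and SD ≈ 1.

*Independent cross-database validation*: a benchmark cohort is scored
against two databases and the paired z-scores are correlated per
(electrode, band) across subjects. Within a single age group, z is an
affine map of x, so the correlation is driven entirely by mean/SD
estimation differences across groups; two databases built from
independent halves (n = 130 each) of one population keep every cell
above r = 0.9. The second database is always synthesized (an
independent half-cohort or perturbed norms): the commercial reference
database's parameters are not redistributable, so its *role*, not its
content, is reproduced.

*Coverage audits*: fractions of values within mean $\pm k$ SD for
$k = 1, 2, 3$, with closed intervals (boundary values count as inside,
matching "within the range of"). Self-scored z-values from a large
healthy cohort reproduce 68.26% / 95.44% within Monte-Carlo tolerance.

## The synthetic generator

The generator is first-class, tested code, and its defaults encode the
study conditions the package is exercised under:

* **Cohort structure.** The healthy preset has n = 260 over the five
  age groups (84/47/55/49/25) with the recruited sex splits (130 F /
  130 M overall); the patient preset has n = 221 (65/39/55/37/25,
  163 F / 58 M).
* **Baseline band powers.** Per-band means 20/12/18/9/4 $\mu V^2$
  (delta/theta/alpha/beta/high-beta) with SDs at 35% of the mean —
  magnitudes typical of eyes-closed adult absolute power. No published
  per-cell table exists to copy, so these are fixed presets, not
  claims.
* **Age trends.** Slow bands decline 2% per decade group; fast bands
  rise 5--8% after the 51--60 group, emulating the qualitative slowing
  pattern. The quantitative slopes are unpublished; the presets exist
  for trend-recovery tests only.
* **Patient effect.** The MDD preset shifts cell means by a per-cell
  $\delta$ (in SD units): slow bands essentially unshifted (delta
  ≈ −0.1), beta raised frontally/centrally (≈ +1.0 to +1.2) and
  high-beta raised over the whole scalp with a frontal maximum of
  +1.73 SD — the pattern recovery tests target.
* **Electrode correlation.** Within one (subject, band), electrodes
  share a common factor with loading $\sqrt{\rho}$, $\rho = 0.9$ by
  default. The value is derived from the published internal-consistency
  range for three central electrodes ($\alpha = k\bar\rho/(1+(k-1)\bar\rho)$
  with $k = 3$ puts $\alpha \approx 0.96$ at $\rho = 0.9$, inside the
  observed 0.917--0.986). Coverage audits use $\rho = 0$ because they
  concern the marginal Gaussian law and their Monte-Carlo tolerance
  presumes effectively independent draws.
* **Questionnaires.** Scores are integers from a truncated normal
  constrained to the screening region (HC: BDI ≤ 13, BAI ≤ 7; MDD:
  BDI ≥ 15, BAI ≥ 9). Truncating a normal moves its mean, so the
  underlying location is solved by root-finding on the closed-form
  truncated-normal mean: the *realised* distribution hits the target
  mean (4.23/1.95 healthy, 31.93/22.28 clinical). The pre-truncation SD
  is kept, so the realised SD is slightly smaller than nominal.
* **Truncation at 0.** Band powers are redrawn, not clipped, when a
  draw lands at or below zero, avoiding a point mass at zero; with the
  default means this touches ≈ 0.2% of draws in the worst cell.

Raw signals are sums of band-limited Gaussian noise scaled so each
band's variance equals its target power. The generator leaves a guard
margin of about one analysis bin (0.5 Hz) inside each band edge so that
the estimator's edge smearing stays inside the band; realised band
power then tracks the target within 5% on 60-s signals. Blink
artifacts are 300--500 µV Gaussian lobes (SD 0.15 s) on the frontal
channels; movement artifacts are half-second broadband bursts on all
channels. Everything is deterministic under a seed.

What the generator does *not* emulate: 1/f spectral background,
alpha-peak individuality, volume-conduction geometry (correlation is
uniform across electrode pairs, with no distance decay), non-Gaussian
power distributions (real absolute power is right-skewed; many
databases log-transform for exactly that reason), sex effects, and
eyes-open protocols. Passing tests therefore certify the pipeline's
arithmetic and statistical structure on data with the study's declared
moments — not distributional realism of raw EEG.

## Problem sizes and numerical choices

The suite runs on deliberately desk-scale problems: cohorts of 20--60
subjects per group for structural checks, 211 per group (≈ 100,000
z-values) for the coverage audit, 130-subject halves with a 200-subject
benchmark for cross-database validation, and 60--300 s of synthetic
signal for the spectral path. The patient-shift recovery check averages
three replicate 221-subject cohorts because a single cohort's frontal
mean z carries sampling noise of SD ≈ 0.11 (norm-estimation error,
$\hat\sigma$ bias and subject noise combined), and the check is about
estimator bias, not one draw's luck.

Other conventions: intervals over samples are 0-based half-open
`[start, end)`; age groups and coverage intervals are closed; the 60-s
gate is inclusive; band names are compared as strings with the
hyphenated `"high-beta"` spelling; norm JSON stores floats at full
precision. EDF support is a minimal hand-written 16-bit reader/writer
(no R EDF parser is available in the package's dependency set), and
quantisation error from the 16-bit physical mapping is below 0.01 µV at
typical amplitudes.

## Known limitations

* The artifact criteria are surrogates; tuned manual deartifacting will
  disagree with any fixed threshold pair.
* Norms are age-stratified only; a sex-stratified flag would require
  larger per-cell samples than the emulated design provides.
* The printed correlation matrix of a real cross-database comparison is
  not reproducible without the original recordings; the package
  validates the *property* (high r between independently built
  databases) rather than the printed values.
* Scores exactly at the questionnaire cutoffs are rejected from both
  cohorts by design; real intake procedures may adjudicate them
  differently.
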