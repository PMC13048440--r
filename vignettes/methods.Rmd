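---
title: "Methods: agreement, non-inferiority and error auditing for automated qualitative coding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: agreement, non-inferiority and error auditing for automated qualitative coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codagree)
```

## The evaluation design

`codagree` compares automated coders (e.g. large language models) with
blinded human analysts against an adjudicated reference standard, on three
axes:

1. **Deductive coding**: every participant segment of a transcript is
   labelled true/false against each code of a fixed codebook, giving a
   complete binary rectangle per coder (the motivating study: 124 segments
   × 10 codes = 1240 cells). Agreement with the reference is quantified
   per coder and per group mean.
2. **Inductive coding**: a qualitative reviewer scores each coder's
   inductive analysis against a reference theme set on a 1–5 Likert scale
   per reference code (14 codes in the study), and models are tested for
   non-inferiority against the human mean.
3. **Quote verification**: every evidence quote a model emits is audited
   against the transcript and classified, yielding hallucination and error
   rates.

The reference standard is a panel consensus, not objective ground truth;
all statements about "truth" below mean agreement with that consensus.

## Agreement metrics

For a coder versus the reference over n cells, with reference positive
rate $p_1$ and coder positive rate $p_2$:

- observed agreement $p_o = (tp + tn)/n$;
- Cohen's kappa $\kappa = (p_o - p_e)/(1 - p_e)$ with
  $p_e = p_1 p_2 + (1-p_1)(1-p_2)$;
- Gwet's AC1 $= (p_o - \gamma_e)/(1 - \gamma_e)$ with
  $\gamma_e = 2\hat\pi(1-\hat\pi)$, $\hat\pi = (p_1+p_2)/2$;
- Jaccard $tp/(tp+fp+fn)$, F1 $2tp/(2tp+fp+fn)$, sensitivity
  $tp/(tp+fn)$, specificity $tn/(tn+fp)$.

At low prevalence $p_e \to 1$ and $\kappa$ is attenuated even at high raw
agreement, while $\gamma_e \le 0.5$ keeps AC1 informative. The closed-form
population values (`population_metrics()`) at the study's model operating
point — sensitivity 0.30, specificity 0.98, prevalence 0.078 — are
$p_o = 0.927$, $\kappa = 0.355$, AC1 $= 0.918$: both facts (high AC1, low
kappa) are structural, not accidents of one dataset. Whenever both
positive rates are at most one half, $\gamma_e \le p_e$ and hence
AC1 $\ge \kappa$; the test suite asserts this on simulated batches.

**Pooled versus per-code.** An "overall" metric can pool all
segment-by-code cells into one binary vector or average per-code values.
The two constructions differ in general and published overall tables do
not always say which was used, so both are exposed: `agreement_metrics()`
/ `confusion_counts(code = "ALL")` pool; `per_code_kappa()` is per code.
Neither is asserted against any published overall kappa.

**Undefined values.** Kappa is undefined when both raters are constant and
equal ($p_e = 1$); ratio metrics are undefined at zero denominators. These
return a tagged `NA` rather than raising, because degenerate resamples are
expected at 7.8% prevalence and the bootstrap must be able to skip them
(dropped replicates are counted; more than 50% undefined aborts with a
diagnostic).

## Bootstrap confidence intervals

CIs are percentile bootstrap over **segments**: a replicate draws whole
segments with replacement and all codes of a drawn segment move together,
preserving within-segment dependence across codes. Defaults: B = 1000,
level 0.95, one integer seed per run, replicates consumed in a fixed
sequence so results are exactly reproducible. The percentile interval was
chosen as the minimal-assumption default; bias-corrected variants were
deliberately not layered on top, since the downstream non-inferiority test
consumes the raw replicate distribution, not the interval. Group-mean rows
("human mean", "model mean") average the per-coder point estimates and
bootstrap that mean over resamples shared by all group members.

Empirical coverage of the nominal-95% interval for kappa at the study
geometry (124 × 10, fixed prevalence 0.078, coder at 0.34/0.97) is
measured by simulation in the acceptance suite (500 studies, B = 500) and
falls near 0.94.

## Non-inferiority and superiority testing

**Deductive (AC1 difference).** For model $m$,
$\Delta_m = \mathrm{AC1}_m - \frac{1}{H}\sum_h \mathrm{AC1}_h$ on the
pooled vector. Each bootstrap replicate applies *one shared segment
resample* to the model and every human, recomputing $\Delta^*_m$ on paired
data. The one-sided p-value for $H_0: \Delta \le -\delta$ (margin
$\delta = 0.03$ AC1 units, chosen in the motivating study to reflect
inter-human variation) uses the add-one rule
$p = (1 + \#\{\Delta^* \le -\delta\})/(B+1)$, so a reported p is never
exactly zero at finite B; with B = 1000 the resolution is about $10^{-3}$.
Superiority reuses the machinery with margin 0. Holm's step-down
adjustment is applied across the models of one task, separately for the
non-inferiority and superiority families.

Simulation at the margin boundary checks calibration: the boundary coder
keeps the model-mean sensitivity (0.30) and has its **specificity**
calibrated (`calibrate_specificity_to_ac1()`) so its population AC1 sits
exactly 0.03 below the human operating point. Sensitivity cannot be used
for this at 7.8% prevalence: AC1 is specificity-dominated there, and even
a zero-sensitivity coder with specificity 0.98 stays within 0.03 of the
human value. Measured type-I error (500 replicates, B = 200) is ~0.05.

**Inductive (Likert differences).** Scores are treated as approximately
interval data. For model $m$ the per-code difference against the human
mean is $d_i$, and $H_0: \bar d \le -\delta_L$ (margin
$\delta_L = 0.5$ points) is tested with
$t = (\bar d + \delta_L)/(s_d/\sqrt n)$ on $n-1$ df, upper tail. A
zero-variance $d$ is flagged degenerate with p set to 0 or 1 by the side
of the margin. On the study's published 14 × 5 table this yields Holm
p = 0.043 for ChatGPT-5 and >0.05 for the other two models — exactly one
non-inferior model.

## Quote-verification audit

Each record (claimed segment id, verbatim quote, assigned code) receives
exactly one of four classes, checked in this order:

1. `researcher_segment` — the claimed (or best-matching) segment is
   facilitator speech. Precedence matters: a verbatim facilitator quote is
   an instruction violation, not an exact match, which keeps the four
   classes disjoint and summing to the total.
2. `exact` — the normalized quote is a substring of the segment text
   (of the best-matching segment when no id is claimed).
3. `partial` — normalized longest-common-substring ratio, relative to the
   shorter string, at or above the policy threshold (default 0.5).
4. `no_match` — everything else, including claimed segment ids absent
   from the transcript (logged, not raised).

Normalization: case-fold, map typographic quotes/dashes to ASCII, collapse
whitespace, strip enclosing quotation marks and terminal punctuation. The
published audit was human judgement, including whether a quote *supports*
the assigned code; that semantic judgement is not computable here and is
carried solely by the `match_override` field, which replays a manual
verdict verbatim and always wins. The LCS-ratio default makes the taxonomy
reproducible; its threshold (0.5) sits far from the similarity levels the
synthetic generator produces (~0.8 for partials, <0.2 for fabrications),
so closed-loop classification is exact by construction away from the
boundary.

Rates per model: strict = no-match/total; expanded adds
researcher-segments-coded; comprehensive adds partials. Across models:
unweighted mean and sample (n−1) SD of the per-model percentages (and of
raw counts for the count block). Percentages are kept at full precision
and rounded to one decimal only at report time.

## Synthetic data: what it emulates and what it does not

- `generate_reference()`: independent Bernoulli cells; per-code
  prevalences are drawn once from a clipped normal (mean 0.078, SD 0.032,
  clipped to (0.005, 0.5) — the study's reported prevalence distribution)
  and frozen into the spec for reproducibility.
- `simulate_coder()`: conditional flips by (sensitivity, specificity),
  independent across cells; defaults are the study's human mean
  (0.34, 0.97) and model mean (0.30, 0.98).
- `generate_likert()`: per-code base means drawn once (uniform 3–4.5, the
  observed range of adjudicated agreement scores), analyst score =
  round(base + shift + normal noise) clamped to 1..5; noise SD defaults to
  0.8, which reproduces Likert-table dispersion comparable to the study's.
- `generate_transcript_with_quotes()`: template-vocabulary segments with a
  facilitator fraction (default 0.2, two facilitators among a small focus
  group being typical) and quote records realizing each audit class;
  `enumerate = TRUE` realizes exact class counts for reproducing count
  tables.

Deliberately **not** modelled: co-occurrence structure among codes (cells
are independent; real codes plausibly co-occur, but no dependence
structure is identifiable from marginal prevalences alone — simulations
state independence explicitly), semantic content of text, and
analyst-specific bias profiles. Passing tests therefore demonstrate the
statistical machinery under the reported marginal conditions, not
robustness to dependence among codes or to semantic drift in real
transcripts. Segment-level bootstrap resampling remains valid under
within-segment dependence, which is precisely why segments, not cells, are
the resampling unit.

## Numerical choices and problem sizes

- Bootstrap: percentile, B = 1000 in analyses; acceptance simulations use
  B = 500 (coverage, 500 studies) and B = 200 (boundary type-I error, 500
  replicates), sizes at which the Monte-Carlo error of a coverage or
  rejection proportion (~0.01) is well inside the bands being checked.
- Population-consistency checks use 200 seeded 124 × 10 studies;
  large-sample checks use 50,000 segments.
- p-value conventions: add-one bootstrap rule (never exactly 0); Holm via
  `stats::p.adjust`. With B = 1000 the smallest reportable bootstrap p is
  ~0.001; published values below that from comparable frameworks imply a
  different convention and are not reproduced here.
- Ties/degeneracy: undefined metrics are tagged `NA` and skipped in
  resamples; zero-variance Likert differences short-circuit to p ∈ {0, 1}.
- All generators and resamplers take one integer seed; identical seeds
  give byte-identical results.

## Known limitations

- Two-rater metrics only (coder vs reference, or coder vs coder); no
  multi-rater kappa/AC1 generalizations, no weighted kappa (labels are
  binary), no ordinal models for the Likert scale beyond the
  interval-scale approximation.
- The partial-match criterion is a transparent proxy for human judgement;
  audited datasets should be replayed through `match_override`.
- Non-inferiority margins (0.03 AC1, 0.5 Likert points) are study-specific
  conventions, configurable but not derived from data here.
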