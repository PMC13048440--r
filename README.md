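# codagree

Blinded evaluation of automated coders (such as large language models)
against human analysts in qualitative thematic coding.

## The problem

When an LLM codes a focus-group transcript against a codebook, how do we
decide whether it performs as well as a blinded human analyst? Raw percent
agreement is misleading: qualitative codes are sparse (typical per-code
prevalence well under 10%), so a coder that labels almost nothing still
"agrees" with the reference standard on most cells. `codagree` implements
the statistical core of a blinded human-vs-model comparison framework for
researchers running such evaluations:

- **Chance-corrected agreement** between a coder and an adjudicated
  reference over a segment-by-code binary matrix. Cohen's kappa,

  κ = (p_o − p_e) / (1 − p_e),  p_e = p₁p₂ + (1−p₁)(1−p₂),

  uses marginal-product expected agreement and collapses at low prevalence
  (the prevalence paradox). Gwet's AC1,

  AC1 = (p_o − γ_e) / (1 − γ_e),  γ_e = 2π̂(1−π̂),  π̂ = (p₁+p₂)/2,

  bounds its chance term at 0.5 and stays informative. Both are reported,
  alongside Jaccard, sensitivity, specificity and F1, with **segment-level
  percentile bootstrap CIs** (whole segments are resampled so all codes of
  a segment move together).
- **Non-inferiority and superiority testing** of each model against the
  mean of the blinded human analysts: a one-sided bootstrap test of the
  AC1 difference (deductive task, margin 0.03) and a one-sided one-sample
  t-test on per-code Likert differences (inductive task, margin 0.5 points
  on a 5-point scale), each Holm-adjusted across the models compared.
- **Quote-verification error audit**: every evidence quote a model emits is
  classified as exact / partial / no-match / researcher-segment-coded
  (facilitator speech takes precedence — coding it is an instruction
  violation, not a hallucination), giving strict, expanded and
  comprehensive error rates per model.
- **Seeded simulators** for every input: reference standards with
  controlled prevalence, coders defined by (sensitivity, specificity),
  Likert tables with analyst shifts, and transcripts with quote records of
  known audit class, so the whole pipeline is testable end to end.

## Worked example

The inductive comparison on the study's published 14-code × 5-analyst
Likert table (shipped in `inst/extdata/`):

```r
library(codagree)
lt <- read_likert_table(system.file("extdata", "inductive_likert_scores.csv",
                                    package = "codagree"))
likert_mean_ci(lt$scores[, "chatgpt_5"])
#>     mean   ci_low  ci_high
#> 4.071429 3.592927 4.549930

res <- inductive_noninferiority(
  lt, c("chatgpt_5", "claude_4_sonnet", "qualigpt"),
  c("human_analyst_1", "human_analyst_2"), margin = 0.5)
res[, c("model_id", "effect", "p_holm_noninferior", "verdict_noninferior")]
#>                        model_id      effect p_holm_noninferior verdict_noninferior
#> chatgpt_5             chatgpt_5  0.21428571         0.04308719                TRUE
#> claude_4_sonnet claude_4_sonnet -0.21428571         0.19844135               FALSE
#> qualigpt               qualigpt  0.07142857         0.17538501               FALSE
```

ChatGPT-5 scores on average 0.21 Likert points above the human mean; its
Holm-adjusted one-sided p-value against the −0.5 margin is 0.043, so it is
the only model that demonstrates non-inferiority at α = 0.05.

The deductive machinery on simulated coders at the study's operating
points (prevalence ≈ 7.8%, model sensitivity 0.30 / specificity 0.98):

```r
spec <- deductive_sim_spec(seed = 7)        # 124 segments x 10 codes
ref  <- generate_reference(spec)
m1   <- simulate_coder(ref, 0.30, 0.98, seed = 201)
round(agreement_metrics(ref, m1), 2)
#>   agreement       kappa         ac1     jaccard sensitivity specificity          f1
#>        0.93        0.31        0.92        0.21        0.28        0.98        0.35
```

93% raw agreement and AC1 = 0.92 coexist with κ = 0.31 — the prevalence
attenuation the framework is built to expose.

The `analysis/` directory contains numbered drivers that run the full
workflow (simulate → deductive agreement → deductive non-inferiority →
inductive comparison → error audit) and write their tables under
`results/`:

```sh
Rscript analysis/01_simulate_study.R
Rscript analysis/02_deductive_agreement.R
# ... through 05_error_audit.R
```

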