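#!/usr/bin/env Rscript
# Generate a complete synthetic study: an adjudicated reference standard
# (124 participant segments x 10 codes, per-code prevalence ~ 7.8%), two
# blinded human coders (sensitivity 0.34, specificity 0.97), three
# model coders (0.30, 0.98), a 14-code x 5-analyst Likert table, and a
# transcript with quote records of known audit classes.
# Everything downstream (02-05) runs off these fixtures.

library(codagree)

seed <- 20260926
out <- "results"
run_pipeline(list(task = "simulate", seed = seed, out_dir = out))

fix <- file.path(out, "fixtures")
cat("Fixtures written to", fix, ":\n")
for (f in list.files(fix)) cat(" -", f, "\n")

spec <- deductive_sim_spec(seed = seed)
cat(sprintf("\nReference design: %d segments x %d codes, prevalence %.3f (SD %.3f)\n",
            spec$n_segments, spec$n_codes, mean(spec$prevalence),
            sd(spec$prevalence)))
cat(sprintf("Coder operating points: humans (%.2f, %.2f), models (%.2f, %.2f)\n",
            spec$human_profile[["sensitivity"]],
            spec$human_profile[["specificity"]],
            spec$model_profile[["sensitivity"]],
            spec$model_profile[["specificity"]]))
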