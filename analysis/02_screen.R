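#!/usr/bin/env Rscript
# Stage 2 — ADME screening of herb ingredients.
#
# Applies the joint OB >= 30% and DL >= 0.18 cutoffs with the literature
# whitelist override, then reports the per-herb candidate accounting and the
# compounds shared by several herbs.

suppressPackageStartupMessages({
  library(netpharm)
  library(jsonlite)
})

compounds <- read_compound_table("results/synthetic/compounds.tsv")
scr <- screen_compounds(compounds, screen_config())
summary <- screen_summary(compounds, scr)

dir.create("results", showWarnings = FALSE)
write_compound_table(scr$candidates, "results/candidates.tsv")
write_json(summary, "results/screen_summary.json", auto_unbox = TRUE,
           pretty = TRUE, digits = NA)

cat(sprintf("screened %d compounds: %d candidates (%d pass the cutoffs, %d whitelisted rescues)\n",
            summary$n_input, summary$n_candidates, summary$n_pass_filter,
            summary$n_whitelisted_rescues))
cat("candidates per herb:",
    paste(sprintf("%s=%d", names(summary$per_herb_counts),
                  unlist(summary$per_herb_counts)), collapse = ", "), "\n")
cat(sprintf("%d candidates belong to more than one herb\n", summary$n_shared))
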