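#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study bundle.
#
# Emulates the database extractions the downstream stages consume: a
# five-herb ingredient table straddling the OB/DL cutoffs, a heavy-tailed
# compound-target map, a 300-protein PPI graph with a planted 20-node dense
# module (the ground-truth hubs), a 60-protein disease target set with a
# planted 15-gene overlap, and 25 annotation terms including one planted
# enriched term. All files land under results/synthetic/.

suppressPackageStartupMessages(library(netpharm))

spec <- synthetic_spec(seed = 1)
manifest <- gen_all(spec, "results/synthetic")

cat(sprintf("wrote synthetic bundle (seed %d) to results/synthetic\n",
            spec$seed))
cat(sprintf("  PPI: %d nodes, %d edges; planted module of %d proteins\n",
            manifest$n_ppi_nodes, manifest$n_ppi_edges,
            length(manifest$planted_hubs)))
cat(sprintf("  compounds: %d candidates expected after screening (%d pass + %d whitelisted)\n",
            manifest$screen$n_candidates, manifest$screen$n_pass,
            manifest$screen$n_whitelisted_rescues))
cat(sprintf("  drug targets: %d; disease targets: %d (planted overlap %d)\n",
            manifest$n_drug_targets, manifest$n_disease_targets,
            length(manifest$planted_disease_overlap)))
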