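#!/usr/bin/env Rscript
# Stage 3 — compound-target bipartite network and disease overlap.
#
# Links candidate compounds to their predicted targets, reports the
# highly connected ingredients (degree >= 20), the distinct-target counts
# per herb, and the overlap of the potential targets with the
# disease-associated target list.

suppressPackageStartupMessages({
  library(netpharm)
  library(jsonlite)
})

candidates <- read_compound_table("results/candidates.tsv")
ctmap <- read.delim("results/synthetic/compound_targets.tsv",
                    stringsAsFactors = FALSE)
disease <- read_gene_list("results/synthetic/disease_targets.txt")

net <- build_bipartite(candidates, ctmap)
deg <- compound_degrees(net)
high <- high_degree_compounds(net, min_degree = 20)
herb_counts <- herb_target_counts(candidates, ctmap)
overlap <- disease_overlap(net$targets, disease)

write.table(data.frame(compound_id = names(deg), degree = unname(deg)),
            "results/compound_degrees.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_gene_list(overlap, "results/overlap_targets.txt")
write_json(list(n_nodes = length(net$compounds) + length(net$targets),
                n_edges = nrow(net$edges),
                n_high_degree_compounds = length(high),
                herb_target_counts = as.list(herb_counts),
                n_overlap_disease = length(overlap)),
           "results/bipartite_summary.json", auto_unbox = TRUE,
           pretty = TRUE, digits = NA)

cat(sprintf("bipartite network: %d nodes (%d compounds + %d targets), %d edges\n",
            length(net$compounds) + length(net$targets),
            length(net$compounds), length(net$targets), nrow(net$edges)))
cat(sprintf("%d compounds act on >= 20 targets", length(high)))
if (length(high)) {
  top <- utils::head(high, 3)
  cat("; top:", paste(sprintf("%s (%d)", names(top), top), collapse = ", "))
}
cat("\n")
cat("distinct targets per herb:",
    paste(sprintf("%s=%d", names(herb_counts), herb_counts),
          collapse = ", "), "\n")
cat(sprintf("%d potential targets are also disease-associated targets\n",
            length(overlap)))
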