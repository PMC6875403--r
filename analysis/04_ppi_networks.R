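#!/usr/bin/env Rscript
# Stage 4 — seed PPI networks and the core (CPPI) merge.
#
# Builds the interaction network around the potential drug targets and the
# one around the disease targets (seeds plus interactors bridging at least
# two seeds), then merges them by node intersection into the core PPI
# network on which hubs are screened.

suppressPackageStartupMessages({
  library(netpharm)
  library(jsonlite)
})

ppi <- read_network("results/synthetic/ppi.sif", "sif")
candidates <- read_compound_table("results/candidates.tsv")
ctmap <- read.delim("results/synthetic/compound_targets.tsv",
                    stringsAsFactors = FALSE)
potential <- build_bipartite(candidates, ctmap)$targets
disease <- read_gene_list("results/synthetic/disease_targets.txt")

drug_net <- seed_network(ppi, potential, "induced_plus_bridges")
disease_net <- seed_network(ppi, disease, "induced_plus_bridges")
cppi <- merge_networks(drug_net, disease_net, "node_intersection")

write_network(drug_net, "results/drug_net.sif", "sif")
write_network(disease_net, "results/disease_net.sif", "sif")
write_network(cppi, "results/cppi.sif", "sif")
write_json(list(mode = "induced_plus_bridges",
                drug_net = list(n_seeds_found = attr(drug_net, "n_seeds_found"),
                                n_nodes = n_nodes(drug_net),
                                n_edges = n_edges(drug_net)),
                disease_net = list(n_seeds_found = attr(disease_net, "n_seeds_found"),
                                   n_nodes = n_nodes(disease_net),
                                   n_edges = n_edges(disease_net)),
                merge_mode = "node_intersection",
                cppi = list(n_nodes = n_nodes(cppi), n_edges = n_edges(cppi))),
           "results/ppi_summary.json", auto_unbox = TRUE, pretty = TRUE,
           digits = NA)

cat(sprintf("drug-target network: %d nodes, %d edges (%d seeds found)\n",
            n_nodes(drug_net), n_edges(drug_net),
            attr(drug_net, "n_seeds_found")))
cat(sprintf("disease-target network: %d nodes, %d edges (%d seeds found)\n",
            n_nodes(disease_net), n_edges(disease_net),
            attr(disease_net, "n_seeds_found")))
cat(sprintf("core PPI network (node intersection): %d nodes, %d edges\n",
            n_nodes(cppi), n_edges(cppi)))
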