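#' Run the full network-pharmacology workflow
#'
#' Executes, in order: ADME screening -> compound-target bipartite network
#' and disease overlap -> seed PPI networks for drug and disease targets ->
#' merge into the core PPI (CPPI) network -> six-centrality table, median
#' thresholds and hub selection -> hypergeometric enrichment of the hubs
#' with kappa grouping. Inputs may be in-memory objects or file paths
#' (strings), so any stage's input can be substituted by an external table.
#' The run is deterministic: identical inputs and configuration give
#' bit-identical outputs.
#'
#' @param compounds Compound records data frame, or path to a compound TSV.
#' @param ctmap Compound-target data frame (`compound_id`, `target_id`), or
#'   path to a two-column TSV.
#' @param disease_targets Character vector, or path to a one-id-per-line
#'   file.
#' @param ppi A [ppi_graph()], or path to a SIF file.
#' @param annotations A [gene_sets()] collection, or path to a GMT file.
#' @param universe Optional explicit background gene set (vector or path);
#'   when supplied the enrichment universe mode switches to explicit.
#' @param screen A [screen_config()].
#' @param seed_mode Seed-network expansion mode (see [seed_network()]).
#' @param merge_mode CPPI merge mode (see [merge_networks()]).
#' @param enrich_cfg An [enrichment_config()].
#' @param high_degree_threshold Bipartite degree cut for the "highly
#'   connected compound" report (default 20).
#' @param out_dir Optional directory; when given, all intermediate artifacts
#'   (candidate TSV, networks, centrality table, thresholds JSON, hub list,
#'   enrichment TSV, summary JSON) are written there.
#' @return A `pipeline_result` list: `summary` (the run summary),
#'   `candidates`, `bipartite`, `overlap`, `drug_net`, `disease_net`,
#'   `cppi`, `centrality`, `thresholds`, `hubs`, `enrichment`.
#' @export
run_pipeline <- function(compounds, ctmap, disease_targets, ppi, annotations,
                         universe = NULL,
                         screen = screen_config(),
                         seed_mode = "induced_plus_bridges",
                         merge_mode = "node_intersection",
                         enrich_cfg = enrichment_config(),
                         high_degree_threshold = 20L,
                         out_dir = NULL) {
  is_path <- function(x) is.character(x) && length(x) == 1L && file.exists(x)
  if (is.character(compounds)) compounds <- read_compound_table(compounds)
  if (is.character(ctmap)) {
    ctmap <- utils::read.delim(ctmap, stringsAsFactors = FALSE)
  }
  if (is_path(disease_targets)) disease_targets <- read_gene_list(disease_targets)
  if (is.character(ppi)) ppi <- read_network(ppi, "sif")
  if (is.character(annotations)) annotations <- read_gmt(annotations)
  if (is_path(universe)) universe <- read_gene_list(universe)
  if (!is.null(universe) && enrich_cfg$universe_mode != "explicit") {
    enrich_cfg$universe_mode <- "explicit"
  }

  scr <- screen_compounds(compounds, screen)
  candidates <- scr$candidates
  ctmap <- ctmap[ctmap$compound_id %in% candidates$compound_id, , drop = FALSE]
  bip <- build_bipartite(candidates, ctmap)
  potential_targets <- bip$targets
  overlap <- disease_overlap(potential_targets, disease_targets)

  drug_net <- seed_network(ppi, potential_targets, seed_mode)
  disease_net <- seed_network(ppi, disease_targets, seed_mode)
  cppi <- merge_networks(drug_net, disease_net, merge_mode)

  if (n_nodes(cppi)) {
    cent <- centrality_table(cppi)
    thr <- median_thresholds(cent)
    hubs <- select_hubs(cent, thr)
  } else {
    cent <- centrality_table(cppi)
    thr <- NULL
    hubs <- character()
  }

  if (length(hubs)) {
    enr <- suppressWarnings(enrich(hubs, annotations, enrich_cfg, universe))
    enr <- group_terms(enr, annotations, enrich_cfg)
  } else {
    warning("no hubs selected; enrichment stage produced an empty result")
    enr <- empty_enrichment()
  }

  summary <- list(
    n_input_compounds = nrow(compounds),
    n_candidates = nrow(candidates),
    n_pass_filter = scr$n_pass_filter,
    n_whitelisted_rescues = scr$n_whitelisted_rescues,
    per_herb_counts = as.list(per_herb_counts(
      candidates, herbs = sort_c(unique(unlist(compounds$herbs))))),
    n_shared_compounds = nrow(shared_compounds(candidates)),
    bipartite = list(n_nodes = length(bip$compounds) + length(bip$targets),
                     n_edges = nrow(bip$edges),
                     n_high_degree_compounds =
                       length(high_degree_compounds(bip, high_degree_threshold))),
    n_potential_targets = length(potential_targets),
    n_disease_targets = length(unique(disease_targets)),
    n_overlap = length(overlap),
    seed_mode = seed_mode,
    merge_mode = merge_mode,
    drug_net = list(n_nodes = n_nodes(drug_net), n_edges = n_edges(drug_net),
                    n_seeds_found = attr(drug_net, "n_seeds_found")),
    disease_net = list(n_nodes = n_nodes(disease_net),
                       n_edges = n_edges(disease_net),
                       n_seeds_found = attr(disease_net, "n_seeds_found")),
    cppi = list(n_nodes = n_nodes(cppi), n_edges = n_edges(cppi)),
    medians = if (is.null(thr)) NULL else thr[c("dc_med", "bc_med", "cc_med",
                                                "ec_med", "nc_med", "lac_med")],
    n_hubs = length(hubs),
    n_significant_terms = sum(enr$significant),
    n_groups = length(unique(stats::na.omit(enr$group_id))),
    config = list(ob_min = screen$ob_min, dl_min = screen$dl_min,
                  inclusive = screen$inclusive,
                  p_cutoff = enrich_cfg$p_cutoff,
                  kappa_threshold = enrich_cfg$kappa_threshold,
                  universe_mode = enrich_cfg$universe_mode),
    package_version = as.character(utils::packageVersion("netpharm")))
  check_summary_consistency(summary)

  result <- structure(list(summary = summary, candidates = candidates,
                           bipartite = bip, overlap = overlap,
                           drug_net = drug_net, disease_net = disease_net,
                           cppi = cppi, centrality = cent, thresholds = thr,
                           hubs = hubs, enrichment = enr),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir)
  result
}

# internal sanity constraints every successful run must satisfy
check_summary_consistency <- function(s) {
  stopifnot(
    s$n_candidates + 0 >= 0,
    s$n_candidates <= s$n_input_compounds,
    s$n_pass_filter + s$n_whitelisted_rescues == s$n_candidates,
    s$n_overlap <= min(s$n_potential_targets, s$n_disease_targets),
    s$cppi$n_nodes <= min(s$drug_net$n_nodes, s$disease_net$n_nodes) ||
      s$merge_mode == "union",
    s$n_hubs <= s$cppi$n_nodes,
    s$n_groups <= s$n_significant_terms)
  invisible(TRUE)
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_compound_table(result$candidates, file.path(out_dir, "candidates.tsv"))
  utils::write.table(result$bipartite$edges,
                     file.path(out_dir, "compound_target_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_network(result$drug_net, file.path(out_dir, "drug_net.sif"), "sif")
  write_network(result$disease_net, file.path(out_dir, "disease_net.sif"),
                "sif")
  write_network(result$cppi, file.path(out_dir, "cppi.sif"), "sif")
  write_centrality_table(result$centrality,
                         file.path(out_dir, "centrality.tsv"))
  if (!is.null(result$thresholds)) {
    jsonlite::write_json(result$thresholds[c("dc_med", "bc_med", "cc_med",
                                             "ec_med", "nc_med", "lac_med",
                                             "strict")],
                         file.path(out_dir, "thresholds.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  writeLines(result$hubs, file.path(out_dir, "hubs.txt"))
  write_enrichment_table(result$enrichment,
                         file.path(out_dir, "enrichment.tsv"))
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Reproduce reported study quantities from supplementary table exports
#'
#' Given TSV/SIF exports of a study's supplementary tables — the candidate
#' compound table and the core PPI network — recomputes the screening
#' counts, CPPI size, six centrality medians and the hub count with this
#' package's machinery, for side-by-side comparison with printed values.
#'
#' @param compounds_tsv Path to the compound table export.
#' @param cppi_sif Path to the core-network SIF export.
#' @param screen A [screen_config()].
#' @return List with `screen` (the [screen_summary()]), `cppi`
#'   (node/edge counts), `medians` and `n_hubs`.
#' @export
reproduce_reported <- function(compounds_tsv, cppi_sif,
                               screen = screen_config()) {
  compounds <- read_compound_table(compounds_tsv)
  scr <- screen_compounds(compounds, screen)
  cppi <- read_network(cppi_sif, "sif")
  cent <- centrality_table(cppi)
  thr <- median_thresholds(cent)
  hubs <- select_hubs(cent, thr)
  list(screen = screen_summary(compounds, scr,
                               herbs = sort_c(unique(unlist(compounds$herbs)))),
       cppi = list(n_nodes = n_nodes(cppi), n_edges = n_edges(cppi)),
       medians = thr[c("dc_med", "bc_med", "cc_med", "ec_med", "nc_med",
                       "lac_med")],
       n_hubs = length(hubs),
       hubs = hubs)
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "network-pharmacology run\n",
    "  candidates: %d of %d compounds (%d pass filter + %d whitelisted)\n",
    "  potential targets: %d; disease targets: %d; overlap: %d\n",
    "  drug net %d/%d, disease net %d/%d, CPPI %d/%d (%s)\n",
    "  hubs: %d; significant terms: %d in %d groups\n"),
    s$n_candidates, s$n_input_compounds, s$n_pass_filter,
    s$n_whitelisted_rescues, s$n_potential_targets, s$n_disease_targets,
    s$n_overlap, s$drug_net$n_nodes, s$drug_net$n_edges,
    s$disease_net$n_nodes, s$disease_net$n_edges, s$cppi$n_nodes,
    s$cppi$n_edges, s$merge_mode, s$n_hubs, s$n_significant_terms,
    s$n_groups))
  invisible(x)
}

#' Planted-hub recovery experiment
#'
#' Generates a synthetic bundle, runs the full pipeline on it, and scores
#' the selected hubs against the generator's ground-truth module.
#'
#' @param spec A [synthetic_spec()].
#' @param ... Passed to [run_pipeline()].
#' @return List with `recall`, `precision`, `hubs`, `planted`, and the
#'   full `result`.
#' @export
hub_recovery_experiment <- function(spec, ...) {
  compounds <- gen_compound_table(spec)
  ppi <- gen_ppi(spec)
  ctmap <- gen_compound_target_map(spec)
  disease <- gen_disease_targets(spec)
  annot <- gen_annotations(spec)
  res <- run_pipeline(compounds, ctmap, disease, ppi$graph, annot,
                      universe = ppi$proteins, ...)
  planted <- ppi$planted_hubs
  hit <- intersect(res$hubs, planted)
  list(recall = length(hit) / length(planted),
       precision = if (length(res$hubs)) length(hit) / length(res$hubs) else NA,
       hubs = res$hubs, planted = planted, result = res)
}
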