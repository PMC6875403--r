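#' Specification of a synthetic study dataset
#'
#' Parameterises a complete synthetic input bundle with the statistical
#' structure each pipeline stage assumes: a five-herb compound table whose
#' OB/DL values straddle the screening cutoffs, a heavy-tailed
#' compound-target map, a background Erdős–Rényi PPI graph with a planted
#' densely wired module (the ground-truth hubs), a disease target set with
#' an exact planted overlap, and term annotations with one planted enriched
#' term. Everything is a pure function of the spec, including its seed.
#'
#' Structural guarantees wired into the generators (so the planted signal
#' can propagate through the pipeline): every planted hub is a target of at
#' least one candidate compound, and the disease/drug-target overlap
#' preferentially contains planted hubs.
#'
#' @param seed Integer seed; all generator randomness flows from it.
#' @param n_compounds_per_herb Named integer vector of ingredient counts for
#'   the five herb codes.
#' @param ob_pass_fraction Probability that a compound passes both ADME
#'   cutoffs jointly.
#' @param whitelist_fraction Probability that a failing compound is
#'   whitelisted on literature evidence.
#' @param multi_herb_fraction Fraction of compounds belonging to more than
#'   one herb.
#' @param n_targets Size of the drug-target pool (drawn from the PPI nodes,
#'   always containing the planted hubs).
#' @param target_degree_exponent Exponent (> 1) of the truncated power law
#'   of compound degrees in the compound-target map.
#' @param ppi_n_background Number of PPI proteins.
#' @param ppi_edge_prob Background edge probability.
#' @param planted_hub_count Size of the planted dense module.
#' @param planted_density Within-module edge probability (must exceed
#'   `ppi_edge_prob`; 0.9 by default so hub recovery is statistical, not
#'   definitional).
#' @param n_disease_targets Size of the disease-associated target set.
#' @param disease_overlap_count Exact size of the disease/drug-target
#'   overlap.
#' @param n_terms Number of annotation terms (one of them planted).
#' @param planted_term_size Gene count of the planted term.
#' @param planted_term_hub_overlap How many planted hubs the planted term
#'   contains.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_compounds_per_herb = c(BGZ = 25L, BZ = 60L,
                                                    FJ = 20L, WM = 25L,
                                                    GC = 120L),
                           ob_pass_fraction = 0.3,
                           whitelist_fraction = 0.1,
                           multi_herb_fraction = 0.08,
                           n_targets = 120L,
                           target_degree_exponent = 2,
                           ppi_n_background = 300L,
                           ppi_edge_prob = 0.02,
                           planted_hub_count = 20L,
                           planted_density = 0.9,
                           n_disease_targets = 60L,
                           disease_overlap_count = 15L,
                           n_terms = 25L,
                           planted_term_size = 40L,
                           planted_term_hub_overlap = 16L) {
  spec <- list(seed = as.integer(seed),
               n_compounds_per_herb = n_compounds_per_herb,
               ob_pass_fraction = ob_pass_fraction,
               whitelist_fraction = whitelist_fraction,
               multi_herb_fraction = multi_herb_fraction,
               n_targets = as.integer(n_targets),
               target_degree_exponent = target_degree_exponent,
               ppi_n_background = as.integer(ppi_n_background),
               ppi_edge_prob = ppi_edge_prob,
               planted_hub_count = as.integer(planted_hub_count),
               planted_density = planted_density,
               n_disease_targets = as.integer(n_disease_targets),
               disease_overlap_count = as.integer(disease_overlap_count),
               n_terms = as.integer(n_terms),
               planted_term_size = as.integer(planted_term_size),
               planted_term_hub_overlap = as.integer(planted_term_hub_overlap))
  probs <- c(spec$ob_pass_fraction, spec$whitelist_fraction,
             spec$multi_herb_fraction, spec$ppi_edge_prob,
             spec$planted_density)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (spec$planted_density <= spec$ppi_edge_prob) {
    stop("planted_density must exceed ppi_edge_prob")
  }
  if (spec$planted_hub_count >= spec$ppi_n_background) {
    stop("planted_hub_count must be smaller than ppi_n_background")
  }
  if (spec$target_degree_exponent <= 1) {
    stop("target_degree_exponent must exceed 1")
  }
  if (spec$n_targets > spec$ppi_n_background ||
      spec$n_targets < spec$planted_hub_count) {
    stop("n_targets must lie between planted_hub_count and ppi_n_background")
  }
  if (spec$planted_term_hub_overlap > min(spec$planted_term_size,
                                          spec$planted_hub_count)) {
    stop("planted_term_hub_overlap exceeds the term or hub size")
  }
  if (is.null(names(spec$n_compounds_per_herb)) ||
      any(spec$n_compounds_per_herb < 0)) {
    stop("n_compounds_per_herb must be a named vector of non-negative counts")
  }
  structure(spec, class = "synthetic_spec")
}

# each generator draws from its own derived stream, so outputs are invariant
# to the order in which generators are called
sub_seed <- function(spec, offset) {
  as.integer((abs(spec$seed) * 131L + offset) %% .Machine$integer.max)
}

#' Generate a synthetic herb-ingredient compound table
#'
#' OB is drawn above/below 30 and DL above/below 0.18 according to the
#' configured joint pass fraction; a random subset of failing compounds is
#' whitelisted; a configurable fraction of compounds belongs to several
#' herbs. Ground-truth bookkeeping (pass / rescue / candidate counts) is
#' attached as attribute `"ground_truth"`.
#'
#' @param spec A [synthetic_spec()].
#' @return Compound record data frame (see [read_compound_table()]).
#' @export
gen_compound_table <- function(spec) {
  withr::with_seed(sub_seed(spec, 1L), {
    herbs <- names(spec$n_compounds_per_herb)
    total <- sum(spec$n_compounds_per_herb)
    id <- sprintf("C%04d", seq_len(total))
    primary <- rep(herbs, spec$n_compounds_per_herb)
    herb_sets <- as.list(primary)
    n_multi <- floor(spec$multi_herb_fraction * total)
    if (n_multi > 0 && length(herbs) > 1L) {
      for (i in sample.int(total, n_multi)) {
        extra <- sample(setdiff(herbs, herb_sets[[i]]),
                        sample(1:2, 1L))
        herb_sets[[i]] <- sort_c(c(herb_sets[[i]], extra))
      }
    }
    pass <- stats::runif(total) < spec$ob_pass_fraction
    ob <- numeric(total)
    dl <- numeric(total)
    ob[pass] <- stats::runif(sum(pass), 30, 100)
    dl[pass] <- stats::runif(sum(pass), 0.18, 1)
    # failing compounds miss at least one cutoff
    fail_mode <- sample(c("ob", "dl", "both"), sum(!pass), replace = TRUE)
    nf <- sum(!pass)
    ob[!pass] <- ifelse(fail_mode == "dl", stats::runif(nf, 30, 100),
                        stats::runif(nf, 0, 29.9))
    dl[!pass] <- ifelse(fail_mode == "ob", stats::runif(nf, 0.18, 1),
                        stats::runif(nf, 0, 0.179))
    whitelisted <- !pass & stats::runif(total) < spec$whitelist_fraction
    rec <- compound_records(id, paste0("compound_", id), herb_sets, ob, dl,
                            whitelisted)
    scr <- screen_compounds(rec)
    attr(rec, "ground_truth") <- list(
      n_pass = sum(pass),
      n_whitelisted_rescues = sum(whitelisted),
      n_candidates = sum(pass | whitelisted),
      per_herb_counts = as.list(per_herb_counts(scr$candidates, herbs)),
      n_shared = nrow(shared_compounds(scr$candidates)))
    rec
  })
}

#' Generate a synthetic PPI graph with a planted dense module
#'
#' Background: Erdős–Rényi graph over `ppi_n_background` proteins at
#' `ppi_edge_prob`. A random subset of `planted_hub_count` proteins is
#' additionally wired at `planted_density` (a near-clique), giving the
#' ground-truth hub module.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `graph` (a [ppi_graph()]), `planted_hubs` (sorted ids)
#'   and `proteins` (the full protein id pool, including any isolates the
#'   graph dropped).
#' @export
gen_ppi <- function(spec) {
  withr::with_seed(sub_seed(spec, 2L), {
    n <- spec$ppi_n_background
    proteins <- sprintf("P%04d", seq_len(n))
    hubs <- sort_c(sample(proteins, spec$planted_hub_count))
    ut <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
    take <- stats::runif(nrow(ut)) < spec$ppi_edge_prob
    in_module <- proteins[ut[, 1L]] %in% hubs & proteins[ut[, 2L]] %in% hubs
    take[in_module] <- take[in_module] |
      stats::runif(sum(in_module)) < spec$planted_density
    pairs <- cbind(proteins[ut[take, 1L]], proteins[ut[take, 2L]])
    list(graph = build_graph(pairs), planted_hubs = hubs,
         proteins = proteins)
  })
}

#' Generate a synthetic compound-target map
#'
#' Candidate compounds (from [gen_compound_table()] + [screen_compounds()])
#' are linked to a pool of `n_targets` proteins drawn from the PPI node pool
#' and always containing the planted hubs. Compound degrees follow a
#' truncated power law with the configured exponent; every planted hub is
#' guaranteed at least one incident edge.
#'
#' @param spec A [synthetic_spec()].
#' @return Data frame with columns `compound_id`, `target_id` (deduplicated
#'   pairs), with attribute `"target_pool"`.
#' @export
gen_compound_target_map <- function(spec) {
  compounds <- gen_compound_table(spec)
  candidates <- screen_compounds(compounds)$candidates
  ppi <- gen_ppi(spec)
  withr::with_seed(sub_seed(spec, 3L), {
    pool <- c(ppi$planted_hubs,
              sample(setdiff(ppi$proteins, ppi$planted_hubs),
                     spec$n_targets - spec$planted_hub_count))
    pool <- sort_c(pool)
    dmax <- max(2L, floor(spec$n_targets / 2))
    pdeg <- (seq_len(dmax))^(-spec$target_degree_exponent)
    deg <- sample.int(dmax, nrow(candidates), replace = TRUE,
                      prob = pdeg / sum(pdeg))
    edges <- do.call(rbind, lapply(seq_len(nrow(candidates)), function(i) {
      data.frame(compound_id = candidates$compound_id[i],
                 target_id = sample(pool, deg[i]),
                 stringsAsFactors = FALSE)
    }))
    uncovered <- setdiff(ppi$planted_hubs, edges$target_id)
    if (length(uncovered) && nrow(candidates)) {
      edges <- rbind(edges, data.frame(
        compound_id = sample(candidates$compound_id, length(uncovered),
                             replace = TRUE),
        target_id = uncovered, stringsAsFactors = FALSE))
    }
    edges <- edges[!duplicated(paste(edges$compound_id, edges$target_id,
                                     sep = "\r")), , drop = FALSE]
    edges <- edges[order(rank_c(edges$compound_id), rank_c(edges$target_id)), ,
                   drop = FALSE]
    rownames(edges) <- NULL
    attr(edges, "target_pool") <- pool
    edges
  })
}

#' Generate a synthetic disease-associated target set
#'
#' Overlaps the drug-target set in exactly `disease_overlap_count` genes;
#' the overlap preferentially contains planted hubs (about 80% of it, so the
#' planted module lies in both seed networks), and the remainder of the
#' disease set is drawn from proteins that are not drug targets.
#'
#' @param spec A [synthetic_spec()].
#' @return Sorted character vector with attribute `"overlap"` (the exact
#'   planted intersection with the drug-target set).
#' @export
gen_disease_targets <- function(spec) {
  ctmap <- gen_compound_target_map(spec)
  ppi <- gen_ppi(spec)
  drug_targets <- unique(ctmap$target_id)
  withr::with_seed(sub_seed(spec, 4L), {
    k <- spec$disease_overlap_count
    n_hub_part <- min(spec$planted_hub_count, ceiling(0.8 * k))
    hub_part <- sample(ppi$planted_hubs, n_hub_part)
    rest_pool <- setdiff(drug_targets, ppi$planted_hubs)
    other_part <- sample(rest_pool, k - n_hub_part)
    overlap <- c(hub_part, other_part)
    outside <- sample(setdiff(ppi$proteins, drug_targets),
                      spec$n_disease_targets - k)
    out <- sort_c(c(overlap, outside))
    attr(out, "overlap") <- sort_c(overlap)
    out
  })
}

#' Generate synthetic term annotations with one planted enriched term
#'
#' The universe is the full PPI protein pool. The planted term contains
#' `planted_term_hub_overlap` planted hubs plus random non-hub filler;
#' background terms are random draws of 15-60 proteins.
#'
#' @param spec A [synthetic_spec()].
#' @return A [gene_sets()] collection with attributes `"planted_term"` (its
#'   id) and `"universe"`.
#' @export
gen_annotations <- function(spec) {
  ppi <- gen_ppi(spec)
  withr::with_seed(sub_seed(spec, 5L), {
    universe <- ppi$proteins
    planted <- c(sample(ppi$planted_hubs, spec$planted_term_hub_overlap),
                 sample(setdiff(universe, ppi$planted_hubs),
                        spec$planted_term_size - spec$planted_term_hub_overlap))
    ids <- c("T_PLANTED", sprintf("T%03d", seq_len(spec$n_terms - 1L)))
    sets <- c(list(planted),
              lapply(seq_len(spec$n_terms - 1L), function(i) {
                sample(universe, sample(15:60, 1L))
              }))
    gs <- gene_sets(ids,
                    c("planted enriched term",
                      sprintf("background term %03d",
                              seq_len(spec$n_terms - 1L))),
                    sets)
    attr(gs, "planted_term") <- "T_PLANTED"
    attr(gs, "universe") <- universe
    gs
  })
}

#' Write the complete synthetic input bundle to disk
#'
#' Writes every file the pipeline consumes — compound TSV, compound-target
#' TSV, disease target list, PPI SIF, GMT annotations, universe list — plus
#' a ground-truth `manifest.json` (planted hubs, planted term, expected
#' screening counts, planted disease overlap). Byte-identical across runs
#' with the same spec.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Writable output directory (created if absent).
#' @return The manifest, invisibly; files land under `out_dir`.
#' @export
gen_all <- function(spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create directory: %s", out_dir))
  compounds <- gen_compound_table(spec)
  ppi <- gen_ppi(spec)
  ctmap <- gen_compound_target_map(spec)
  disease <- gen_disease_targets(spec)
  annot <- gen_annotations(spec)

  write_compound_table(compounds, file.path(out_dir, "compounds.tsv"))
  utils::write.table(ctmap, file.path(out_dir, "compound_targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gene_list(disease, file.path(out_dir, "disease_targets.txt"))
  write_network(ppi$graph, file.path(out_dir, "ppi.sif"), "sif")
  write_gmt(annot, file.path(out_dir, "annotations.gmt"))
  write_gene_list(ppi$proteins, file.path(out_dir, "universe.txt"))

  manifest <- list(
    seed = spec$seed,
    planted_hubs = ppi$planted_hubs,
    planted_term = attr(annot, "planted_term"),
    planted_disease_overlap = as.character(attr(disease, "overlap")),
    screen = attr(compounds, "ground_truth"),
    n_ppi_nodes = n_nodes(ppi$graph),
    n_ppi_edges = n_edges(ppi$graph),
    n_drug_targets = length(unique(ctmap$target_id)),
    n_disease_targets = length(disease))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
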