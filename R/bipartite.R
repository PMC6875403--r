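#' Build the compound-target bipartite network
#'
#' Nodes are the candidate compounds and targets that carry at least one
#' edge (isolated declared nodes are dropped, matching how such networks are
#' usually drawn; set `keep_isolated_compounds = TRUE` to keep edgeless
#' candidates). Duplicate compound-target assertions collapse to one edge.
#'
#' @param candidates Screened compound records.
#' @param ctmap Data frame with columns `compound_id`, `target_id` (a
#'   compound-target map). Every `compound_id` must be a candidate.
#' @param keep_isolated_compounds Keep candidate compounds with no targets
#'   as isolated nodes (default `FALSE`).
#' @return A `bipartite_network`: list with `compounds`, `targets` (sorted
#'   character vectors) and `edges` (deduplicated two-column data frame).
#' @export
build_bipartite <- function(candidates, ctmap,
                            keep_isolated_compounds = FALSE) {
  stopifnot(all(c("compound_id", "target_id") %in% names(ctmap)))
  unknown <- setdiff(unique(ctmap$compound_id), candidates$compound_id)
  if (length(unknown)) {
    stop(sprintf("compound-target edge references unknown compound: %s",
                 paste(unknown, collapse = ", ")))
  }
  key <- paste(ctmap$compound_id, ctmap$target_id, sep = "\r")
  edges <- ctmap[!duplicated(key), c("compound_id", "target_id"), drop = FALSE]
  edges <- edges[order(match(edges$compound_id, sort_c(unique(edges$compound_id))),
                       match(edges$target_id, sort_c(unique(edges$target_id)))), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  compounds <- sort_c(unique(edges$compound_id))
  if (keep_isolated_compounds) compounds <- sort_c(candidates$compound_id)
  structure(list(compounds = compounds,
                 targets = sort_c(unique(edges$target_id)),
                 edges = edges),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite_network: %d compounds + %d targets, %d edges\n",
              length(x$compounds), length(x$targets), nrow(x$edges)))
  invisible(x)
}

#' Compound degrees in the bipartite network
#'
#' @param net A `bipartite_network`.
#' @return Named integer vector: number of distinct targets per compound
#'   carrying at least one edge.
#' @export
compound_degrees <- function(net) {
  tab <- table(factor(net$edges$compound_id,
                      levels = sort_c(unique(net$edges$compound_id))))
  stats::setNames(as.integer(tab), names(tab))
}

#' Compounds at or above a degree threshold
#'
#' Reporting helper for the "highly connected ingredient" cut.
#'
#' @param net A `bipartite_network`.
#' @param min_degree Degree threshold (default 20).
#' @return Named integer vector of degrees, restricted to compounds with
#'   `degree >= min_degree`, sorted by decreasing degree.
#' @export
high_degree_compounds <- function(net, min_degree = 20L) {
  d <- compound_degrees(net)
  d <- d[d >= min_degree]
  d[order(-d, names(d), method = "radix")]
}

#' Distinct-target counts per herb
#'
#' A herb's count is the size of the union of the target sets of its
#' candidate compounds.
#'
#' @param candidates Screened compound records.
#' @param ctmap Compound-target map data frame.
#' @param herbs Known herb codes.
#' @return Named integer vector over `herbs`.
#' @export
herb_target_counts <- function(candidates, ctmap, herbs = formula_herbs()) {
  vapply(herbs, function(h) {
    ids <- candidates$compound_id[vapply(candidates$herbs,
                                         function(hs) h %in% hs, NA)]
    length(unique(ctmap$target_id[ctmap$compound_id %in% ids]))
  }, integer(1L))
}

#' Overlap of potential drug targets with disease-associated targets
#'
#' @param potential_targets Character vector/set of predicted drug targets.
#' @param disease_targets Character vector/set of disease-associated targets
#'   (same identifier namespace).
#' @return Sorted character vector: the exact intersection.
#' @export
disease_overlap <- function(potential_targets, disease_targets) {
  sort_c(intersect(unique(potential_targets), unique(disease_targets)))
}
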