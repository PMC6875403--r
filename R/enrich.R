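#' Enrichment analysis configuration
#'
#' @param p_cutoff Significance cutoff on the p-value (default 0.05).
#' @param kappa_threshold Minimum kappa for linking two terms into the same
#'   functional group (default 0.4, the conventional default of
#'   kappa-grouping enrichment tools).
#' @param universe_mode `"annotated_union"` (background = union of all
#'   annotated genes, the default) or `"explicit"` (caller supplies the
#'   universe).
#' @param gate_on_adjusted Gate significance on the BH-adjusted p instead of
#'   the raw p (default `FALSE`; the raw-p gate is the classical choice the
#'   workflow reports).
#' @return An `enrichment_config` list.
#' @export
enrichment_config <- function(p_cutoff = 0.05, kappa_threshold = 0.4,
                              universe_mode = c("annotated_union", "explicit"),
                              gate_on_adjusted = FALSE) {
  if (p_cutoff <= 0 || p_cutoff >= 1) stop("p_cutoff must lie in (0, 1)")
  if (kappa_threshold < 0 || kappa_threshold > 1) {
    stop("kappa_threshold must lie in [0, 1]")
  }
  structure(list(p_cutoff = p_cutoff, kappa_threshold = kappa_threshold,
                 universe_mode = match.arg(universe_mode),
                 gate_on_adjusted = isTRUE(gate_on_adjusted)),
            class = "enrichment_config")
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for X hypergeometric with `K` annotated genes in a universe
#' of `N`, drawing `n`: the probability of observing at least `k` annotated
#' genes in the query by chance. Computed through the distribution's
#' survival function, which is numerically stable in the far tail.
#'
#' @param k Observed overlap (0 <= k <= min(K, n)).
#' @param K Term size within the universe.
#' @param n Query size within the universe.
#' @param N Universe size.
#' @return Probability in \[0, 1\]; exactly 1 when `k = 0`.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (K > N || n > N) stop("K and n must not exceed N")
  if (k < 0 || k > min(K, n)) stop("k must lie in [0, min(K, n)]")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation test of a gene set
#'
#' Tests each annotation term for over-representation in the query. The
#' universe is the union of all annotated genes (default) or an explicit
#' set; the query is restricted to the universe. Only terms overlapping the
#' query (`k >= 1`) are reported. Benjamini-Hochberg adjusted p-values are
#' computed across all tested terms; significance is gated on the raw
#' p-value by default (see [enrichment_config()]).
#'
#' @param query Non-empty character vector of gene ids.
#' @param terms A [gene_sets()] annotation collection.
#' @param config An [enrichment_config()].
#' @param universe Explicit background gene set (required when
#'   `universe_mode = "explicit"`).
#' @return Data frame sorted by ascending p then term id, with columns
#'   `term_id`, `description`, `k`, `K`, `n`, `N`, `p_value`, `adj_p`,
#'   `significant`, plus grouping placeholders `group_id`, `leading` (see
#'   [group_terms()]). The universe used is attached as attribute
#'   `"universe"`.
#' @export
enrich <- function(query, terms, config = enrichment_config(),
                   universe = NULL) {
  query <- unique(as.character(query))
  if (!length(query)) stop("query must be non-empty")
  if (config$universe_mode == "explicit") {
    if (is.null(universe)) stop("explicit universe_mode requires a universe")
    universe <- unique(as.character(universe))
  } else {
    universe <- unique(unlist(terms$genes, use.names = FALSE))
  }
  N <- length(universe)
  query <- intersect(query, universe)
  empty <- empty_enrichment()
  if (!length(query)) {
    warning("query does not intersect the universe; empty enrichment result")
    attr(empty, "universe") <- universe
    return(empty)
  }
  n <- length(query)
  rows <- lapply(seq_along(terms$set_id), function(i) {
    genes <- intersect(terms$genes[[i]], universe)
    k <- length(intersect(genes, query))
    if (k < 1L) return(NULL)
    data.frame(term_id = terms$set_id[i], description = terms$description[i],
               k = k, K = length(genes), n = n, N = N,
               p_value = hypergeom_upper_tail(k, length(genes), n, N),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    attr(empty, "universe") <- universe
    return(empty)
  }
  rows$adj_p <- stats::p.adjust(rows$p_value, method = "BH")
  gate <- if (config$gate_on_adjusted) rows$adj_p else rows$p_value
  rows$significant <- gate <= config$p_cutoff
  rows <- rows[order(rows$p_value, rank_c(rows$term_id)), , drop = FALSE]
  rownames(rows) <- NULL
  rows$group_id <- NA_integer_
  rows$leading <- NA
  attr(rows, "universe") <- universe
  rows
}

rank_c <- function(x) match(x, sort_c(unique(x)))

# zero-row enrichment frame with the full column contract
empty_enrichment <- function() {
  data.frame(term_id = character(), description = character(),
             k = integer(), K = integer(), n = integer(),
             N = integer(), p_value = numeric(), adj_p = numeric(),
             significant = logical(), group_id = integer(),
             leading = logical(), stringsAsFactors = FALSE)
}

#' Cohen's kappa between two gene sets over a universe
#'
#' Chance-corrected agreement of the two membership indicators on a 2x2
#' contingency table over the universe. Degenerate case: when expected
#' agreement is 1 (both sets empty or both equal to the universe), kappa is
#' 1 for identical sets and 0 otherwise.
#'
#' @param a,b Character vectors, subsets of `universe`.
#' @param universe Non-empty background set.
#' @return Kappa in \[-1, 1\]; symmetric in `a`, `b`; 1 iff the sets are
#'   identical (when expected agreement < 1).
#' @export
kappa_score <- function(a, b, universe) {
  universe <- unique(as.character(universe))
  N <- length(universe)
  if (!N) stop("universe must be non-empty")
  a <- intersect(unique(as.character(a)), universe)
  b <- intersect(unique(as.character(b)), universe)
  nab <- length(intersect(a, b))
  na <- length(a)
  nb <- length(b)
  po <- (nab + (N - na - nb + nab)) / N
  pe <- (na * nb + (N - na) * (N - nb)) / N^2
  if (pe >= 1) return(if (setequal(a, b)) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Group enriched terms by kappa similarity of their gene memberships
#'
#' Builds a term graph linking two significant terms when the kappa
#' agreement of their (universe-restricted) gene sets reaches the threshold,
#' and takes connected components as functional groups. Groups are numbered
#' by their best (smallest) p-value; within a group the leading term is the
#' one with the smallest p (ties broken by larger term size, then
#' lexicographic term id). Non-significant rows keep `group_id = NA`.
#'
#' @param rows An [enrich()] result.
#' @param terms The [gene_sets()] collection the rows were computed from.
#' @param config An [enrichment_config()].
#' @return `rows` with `group_id` and `leading` filled in for significant
#'   terms.
#' @export
group_terms <- function(rows, terms, config = enrichment_config()) {
  sig <- which(rows$significant)
  if (!length(sig)) return(rows)
  universe <- attr(rows, "universe")
  if (is.null(universe)) universe <- unique(unlist(terms$genes, use.names = FALSE))
  ids <- rows$term_id[sig]
  sets <- lapply(terms$genes[ids], intersect, y = universe)
  m <- length(ids)
  comp <- seq_len(m)
  find <- function(i) {
    while (comp[i] != i) i <- comp[i]
    i
  }
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      for (j in seq((i + 1L), m)) {
        if (kappa_score(sets[[i]], sets[[j]], universe) >=
            config$kappa_threshold) {
          comp[find(j)] <- find(i)
        }
      }
    }
  }
  root <- vapply(seq_len(m), find, integer(1L))
  # order groups by their best p (rows are p-sorted, so first occurrence wins)
  group_of <- match(root, unique(root))
  rows$group_id[sig] <- group_of
  rows$leading[sig] <- FALSE
  for (gid in unique(group_of)) {
    members <- sig[group_of == gid]
    best <- members[order(rows$p_value[members], -rows$K[members],
                          rank_c(rows$term_id)[members])][1L]
    rows$leading[best] <- TRUE
  }
  rows
}

#' Write an enrichment table as TSV
#' @param rows An [enrich()]/[group_terms()] result.
#' @param path Output path.
#' @export
write_enrichment_table <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
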