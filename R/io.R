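#' Table dialect for delimited text input
#'
#' @param delimiter Single field-separator character.
#' @param has_header Does the file carry a header row?
#' @param comment_prefix Lines starting with this (non-empty) string are
#'   skipped before parsing.
#' @return A `table_dialect` list. The default (tab-separated, `#` comments,
#'   header required) matches common Cytoscape exports.
#' @export
table_dialect <- function(delimiter = "\t", has_header = TRUE,
                          comment_prefix = "#") {
  if (!is.character(delimiter) || nchar(delimiter) != 1L) {
    stop("delimiter must be exactly one character")
  }
  if (!nzchar(comment_prefix)) stop("comment_prefix must be non-empty")
  structure(list(delimiter = delimiter, has_header = isTRUE(has_header),
                 comment_prefix = comment_prefix),
            class = "table_dialect")
}

read_table_lines <- function(path, dialect) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, dialect$comment_prefix) & nzchar(lines)
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a herb-ingredient compound table
#'
#' Expects columns `compound_id`, `name`, `herbs`, `ob`, `dl` and optionally
#' `whitelist` (default `FALSE`). The `herbs` field is a semicolon-separated
#' list of herb codes parsed into a set.
#'
#' @param path Path to the delimited text file.
#' @param dialect A [table_dialect()].
#' @return A data frame of compound records with columns `compound_id`,
#'   `name`, `herbs` (list column of character vectors), `ob`, `dl`,
#'   `whitelisted`. Validated: unique ids, non-empty herb sets, `ob >= 0`,
#'   `dl` in \[0, 1\].
#' @export
read_compound_table <- function(path, dialect = table_dialect()) {
  lt <- read_table_lines(path, dialect)
  if (!dialect$has_header || !length(lt$lines)) {
    if (!dialect$has_header) stop("compound tables require a header row")
    stop(sprintf("empty compound table: %s", path))
  }
  header <- strsplit(lt$lines[1L], dialect$delimiter, fixed = TRUE)[[1L]]
  required <- c("compound_id", "name", "herbs", "ob", "dl")
  missing <- setdiff(required, header)
  if (length(missing)) {
    stop(sprintf("compound table format error: missing column(s) %s",
                 paste(missing, collapse = ", ")))
  }
  body <- lt$lines[-1L]
  lineno <- lt$lineno[-1L]
  if (!length(body)) {
    return(compound_records(character(), character(), list(),
                            numeric(), numeric(), logical()))
  }
  fields <- strsplit(body, dialect$delimiter, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < length(header))) {
    bad <- lineno[which(nf < length(header))[1L]]
    stop(sprintf("line %d: expected %d fields, found fewer", bad,
                 length(header)))
  }
  col <- function(nm) vapply(fields, function(f) f[match(nm, header)], "")
  id <- col("compound_id")
  dup <- unique(id[duplicated(id)])
  if (length(dup)) {
    stop(sprintf("duplicated compound_id: %s", paste(dup, collapse = ", ")))
  }
  parse_num <- function(nm) {
    raw <- col(nm)
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val))
    if (length(bad)) {
      stop(sprintf("line %d: non-numeric %s value '%s'", lineno[bad[1L]],
                   nm, raw[bad[1L]]))
    }
    val
  }
  ob <- parse_num("ob")
  dl <- parse_num("dl")
  herbs <- lapply(strsplit(col("herbs"), ";", fixed = TRUE),
                  function(h) sort_c(unique(h[nzchar(h)])))
  empty <- which(!lengths(herbs))
  if (length(empty)) {
    stop(sprintf("line %d: empty herb set for compound %s", lineno[empty[1L]],
                 id[empty[1L]]))
  }
  if ("whitelist" %in% header) {
    wl <- tolower(col("whitelist")) %in% c("true", "t", "1", "yes")
  } else {
    wl <- rep(FALSE, length(id))
  }
  bad <- which(ob < 0)
  if (length(bad)) stop(sprintf("line %d: negative ob", lineno[bad[1L]]))
  bad <- which(dl < 0 | dl > 1)
  if (length(bad)) stop(sprintf("line %d: dl outside [0, 1]", lineno[bad[1L]]))
  compound_records(id, col("name"), herbs, ob, dl, wl)
}

compound_records <- function(compound_id, name, herbs, ob, dl, whitelisted) {
  df <- data.frame(compound_id = as.character(compound_id),
                   name = as.character(name),
                   ob = as.numeric(ob), dl = as.numeric(dl),
                   whitelisted = as.logical(whitelisted),
                   stringsAsFactors = FALSE)
  df$herbs <- if (length(herbs)) unname(herbs) else list()
  df[, c("compound_id", "name", "herbs", "ob", "dl", "whitelisted")]
}

#' Write a compound table (inverse of [read_compound_table()])
#' @param records Compound record data frame.
#' @param path Output path.
#' @param dialect A [table_dialect()].
#' @export
write_compound_table <- function(records, path, dialect = table_dialect()) {
  d <- dialect$delimiter
  hdr <- paste(c("compound_id", "name", "herbs", "ob", "dl", "whitelist"),
               collapse = d)
  rows <- vapply(seq_len(nrow(records)), function(i) {
    paste(c(records$compound_id[i], records$name[i],
            paste(records$herbs[[i]], collapse = ";"),
            format_num(records$ob[i]), format_num(records$dl[i]),
            tolower(as.character(records$whitelisted[i]))), collapse = d)
  }, "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

format_num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)

#' Read an interaction edge list
#'
#' `sif` rows are `A interaction_type B [B2 ...]` (whitespace-separated, the
#' source node fans out to every listed partner; the interaction type is
#' read and discarded). `tsv2` rows are `A<TAB>B`. Raw pairs are returned in
#' file order, duplicates and self-pairs included — deduplication is
#' [build_graph()]'s job. Identifiers are preserved verbatim (case-sensitive).
#'
#' @param path Path to the file.
#' @param format_name `"sif"` or `"tsv2"`.
#' @return Two-column character matrix of raw pairs.
#' @export
read_edge_list <- function(path, format_name = c("sif", "tsv2")) {
  format_name <- match.arg(format_name)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(matrix(character(), ncol = 2L))
  if (format_name == "sif") {
    fields <- strsplit(trimws(lines), "[ \t]+")
    nf <- lengths(fields)
    if (any(nf < 3L)) {
      stop(sprintf("SIF line %d: expected at least 3 fields, found %d",
                   which(nf < 3L)[1L], nf[nf < 3L][1L]))
    }
    pairs <- do.call(rbind, lapply(fields, function(f) {
      cbind(f[1L], f[-(1:2)])
    }))
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 2L)) {
      stop(sprintf("tsv2 line %d: expected 2 fields, found %d",
                   which(nf < 2L)[1L], nf[nf < 2L][1L]))
    }
    pairs <- do.call(rbind, lapply(fields, function(f) cbind(f[1L], f[2L])))
  }
  colnames(pairs) <- c("from", "to")
  pairs
}

#' Read a GMT gene-set annotation file
#'
#' Each row is `set_id<TAB>description<TAB>gene1<TAB>gene2...`. Genes are
#' deduplicated per set; reading is independent of row and gene order.
#'
#' @param path Path to the GMT file.
#' @return A [gene_sets()] collection.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(gene_sets(character(), character(), list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("GMT line %d: expected at least 3 fields, found %d",
                 which(nf < 3L)[1L], nf[nf < 3L][1L]))
  }
  ids <- vapply(fields, `[`, "", 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop(sprintf("duplicated gene-set id: %s", paste(dup, collapse = ", ")))
  }
  gene_sets(ids,
            vapply(fields, `[`, "", 2L),
            lapply(fields, function(f) sort_c(unique(f[-(1:2)]))))
}

#' Gene-set collection (term -> gene annotation)
#'
#' @param set_id Character vector of unique set ids.
#' @param description Character vector of descriptions (same length).
#' @param genes List of non-empty character vectors of gene symbols.
#' @return A `gene_sets` object: list with `set_id`, `description`, `genes`
#'   (each gene vector deduplicated and sorted).
#' @export
gene_sets <- function(set_id, description, genes) {
  set_id <- as.character(set_id)
  if (anyDuplicated(set_id)) stop("gene-set ids must be unique")
  if (length(genes) != length(set_id) || length(description) != length(set_id)) {
    stop("set_id, description and genes must have equal length")
  }
  genes <- lapply(genes, function(g) sort_c(unique(as.character(g))))
  if (length(genes) && any(!lengths(genes))) stop("every gene set must be non-empty")
  structure(list(set_id = set_id, description = as.character(description),
                 genes = stats::setNames(genes, set_id)),
            class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("gene_sets: %d sets, %d distinct genes\n",
              length(x$set_id), length(unique(unlist(x$genes)))))
  invisible(x)
}

#' @rdname read_gmt
#' @param gs A [gene_sets()] collection.
#' @export
write_gmt <- function(gs, path) {
  rows <- vapply(seq_along(gs$set_id), function(i) {
    paste(c(gs$set_id[i], gs$description[i], gs$genes[[i]]), collapse = "\t")
  }, "")
  writeLines(rows, path)
  invisible(path)
}

#' Write / read a network file
#'
#' SIF output writes one `from pp to` row per edge (each unordered pair once);
#' because a SIF edge row needs three fields, isolated nodes are not
#' representable and round-trip identity holds for graphs without them.
#' GraphML (via igraph) preserves isolated nodes and round-trips any graph.
#'
#' @param graph A [ppi_graph()].
#' @param path Output path.
#' @param format_name `"sif"` or `"graphml"`.
#' @export
write_network <- function(graph, path, format_name = c("sif", "graphml")) {
  format_name <- tryCatch(match.arg(format_name),
                          error = function(e) stop(
                            sprintf("unknown network format '%s'",
                                    format_name[1L])))
  if (format_name == "sif") {
    if (n_edges(graph)) {
      writeLines(paste(graph$edges[, 1L], "pp", graph$edges[, 2L]), path)
    } else {
      writeLines(character(), path)
    }
  } else {
    igraph::write_graph(as_igraph(graph), path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format_name = c("sif", "graphml")) {
  format_name <- tryCatch(match.arg(format_name),
                          error = function(e) stop(
                            sprintf("unknown network format '%s'",
                                    format_name[1L])))
  if (format_name == "sif") {
    build_graph(read_edge_list(path, "sif"))
  } else {
    from_igraph(igraph::read_graph(path, format = "graphml"))
  }
}

#' Convert between ppi_graph and igraph
#' @param graph A [ppi_graph()].
#' @return `as_igraph`: an [igraph::graph]; `from_igraph`: a [ppi_graph()].
#' @export
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(as.data.frame(graph$edges,
                                              stringsAsFactors = FALSE),
                                directed = FALSE,
                                vertices = data.frame(name = graph$nodes))
}

#' @rdname as_igraph
#' @param ig An igraph object.
#' @export
from_igraph <- function(ig) {
  nm <- igraph::V(ig)$name
  el <- igraph::as_edgelist(ig, names = TRUE)
  g <- build_graph(el)
  # retain declared isolated nodes
  iso <- setdiff(nm, g$nodes)
  if (length(iso)) g <- ppi_graph(nodes = c(g$nodes, iso), edges = g$edges)
  g
}

#' Read a one-id-per-line gene list
#' @param path Path to the file; blank lines and `#` comments skipped.
#' @return Sorted unique character vector.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  x <- trimws(readLines(path, warn = FALSE))
  sort_c(unique(x[nzchar(x) & !startsWith(x, "#")]))
}

#' @rdname read_gene_list
#' @param genes Character vector to write.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(sort_c(unique(as.character(genes))), path)
  invisible(path)
}
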