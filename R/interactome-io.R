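# Reading, merging and writing protein-protein interaction networks and the
# gene-set / annotation-catalog inputs of the comparison pipeline.

#' Normalize gene symbols
#'
#' Default symbol normalizer: strip surrounding whitespace and uppercase.
#' Interaction and gene-set readers accept any function with this signature,
#' so organism- or resource-specific rules can be injected.
#'
#' @param x Character vector of raw identifiers.
#' @return Character vector of normalized symbols.
#' @export
#' @examples
#' normalize_symbol(c(" tp53 ", "Ep300"))
normalize_symbol <- function(x) {
  toupper(trimws(x))
}

#' Parse an interaction edge-list file
#'
#' Reads a tab-delimited interaction file into one `InteractionRecord` per
#' data line. Two dialects are supported: `"simple_tsv"` (columns 1-2 are
#' interactor symbols, optional column 3 a free-text provenance label) and
#' `"mitab_minimal"` (a PSI-MI-TAB-like layout where only columns 1-2 are
#' read and treated as opaque symbols). Lines starting with `#` or `!` and
#' blank lines are skipped. Records are orderless: (a, b) and (b, a) denote
#' the same interaction.
#'
#' @param path Path to the file.
#' @param dialect `"simple_tsv"` or `"mitab_minimal"`.
#' @param symbol_normalizer Function applied to both endpoint columns
#'   (default [normalize_symbol]).
#' @param default_source Provenance label used when the file carries none
#'   (default `""`).
#' @return A data frame with columns `protein_a`, `protein_b`, `source`.
#' @export
parse_edge_list <- function(path,
                            dialect = c("simple_tsv", "mitab_minimal"),
                            symbol_normalizer = normalize_symbol,
                            default_source = "") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("cannot read interaction file: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines) & !grepl("^[#!]", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.frame(protein_a = character(), protein_b = character(),
                      source = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    bad <- idx[which(nf < 2L)[1L]]
    stop("malformed interaction line ", bad, " in ", path,
         ": fewer than 2 tab-separated columns")
  }
  a <- symbol_normalizer(vapply(fields, `[[`, "", 1L))
  b <- symbol_normalizer(vapply(fields, `[[`, "", 2L))
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    bad <- idx[which(!nzchar(a) | !nzchar(b))[1L]]
    stop("malformed interaction line ", bad, " in ", path,
         ": empty symbol after normalization")
  }
  src <- if (dialect == "simple_tsv") {
    vapply(fields, function(f) if (length(f) >= 3L) f[[3L]] else default_source, "")
  } else {
    rep(default_source, length(a))
  }
  data.frame(protein_a = a, protein_b = b, source = src,
             stringsAsFactors = FALSE)
}

# Internal constructor: wrap an igraph graph (already simple, undirected,
# named, with optional per-edge `sources` attribute) as an interactome.
new_interactome <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  structure(list(graph = graph), class = "interactome")
}

# Accept either an interactome or a bare igraph graph.
as_graph <- function(net) {
  if (inherits(net, "interactome")) return(net$graph)
  if (igraph::is_igraph(net)) return(net)
  stop("expected an interactome or igraph object")
}

#' Build a deduplicated interactome from interaction records
#'
#' Merges interaction records (possibly from several resources) into one
#' simple undirected graph: self-interactions are dropped, duplicate pairs
#' -- including reversed-endpoint duplicates -- are collapsed to a single
#' edge whose provenance is the union of the contributing source labels.
#'
#' @param records Data frame with columns `protein_a`, `protein_b` and
#'   optionally `source`, as returned by [parse_edge_list()] (several files'
#'   records may be row-bound first).
#' @return An `interactome` object; edges carry a `sources` attribute
#'   (`;`-joined sorted labels).
#' @export
build_interactome <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("protein_a", "protein_b") %in% names(records)))
  if (nrow(records) == 0L) stop("no interaction records supplied")
  src <- if ("source" %in% names(records)) records$source else
    rep("", nrow(records))
  a <- pmin(records$protein_a, records$protein_b)
  b <- pmax(records$protein_a, records$protein_b)
  keep <- a != b
  if (!any(keep)) stop("empty network: all records are self-interactions")
  key <- paste(a[keep], b[keep], sep = "\t")
  by_edge <- split(src[keep], key)
  sources <- vapply(by_edge, function(s) {
    s <- sort(unique(s[nzchar(s)]))
    paste(s, collapse = ";")
  }, "")
  parts <- strsplit(names(by_edge), "\t", fixed = TRUE)
  ed <- data.frame(a = vapply(parts, `[[`, "", 1L),
                   b = vapply(parts, `[[`, "", 2L),
                   sources = sources, stringsAsFactors = FALSE)
  ed <- ed[order(ed$a, ed$b), , drop = FALSE]
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  new_interactome(g)
}

#' @export
print.interactome <- function(x, ...) {
  g <- x$graph
  cat(sprintf("interactome: %d proteins, %d interactions\n",
              igraph::vcount(g), igraph::ecount(g)))
  invisible(x)
}

#' Node and edge accessors
#'
#' @param net An `interactome` (or bare igraph graph).
#' @return `interactome_nodes()`: character vector of node symbols;
#'   `interactome_edges()`: data frame `a`, `b`, `sources` with
#'   lexicographically ordered endpoints, sorted rows.
#' @export
interactome_nodes <- function(net) {
  igraph::V(as_graph(net))$name
}

#' @rdname interactome_nodes
#' @export
interactome_edges <- function(net) {
  g <- as_graph(net)
  el <- igraph::as_edgelist(g, names = TRUE)
  src <- igraph::edge_attr(g, "sources")
  if (is.null(src)) src <- rep("", nrow(el))
  ed <- data.frame(a = pmin(el[, 1L], el[, 2L]),
                   b = pmax(el[, 1L], el[, 2L]),
                   sources = src, stringsAsFactors = FALSE)
  ed[order(ed$a, ed$b), , drop = FALSE]
}

#' Write an interactome as a canonical two-column TSV
#'
#' Endpoints are ordered lexicographically within each line and lines are
#' sorted, so repeated runs produce byte-identical files.
#'
#' @param net An `interactome`.
#' @param path Output path.
#' @param sources Include the provenance column? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_interactome <- function(net, path, sources = TRUE) {
  ed <- interactome_edges(net)
  if (!sources) ed$sources <- NULL
  utils::write.table(ed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene set (one symbol per line)
#'
#' @param path Path to the file; `#`/`!` comment lines and blanks skipped.
#' @param symbol_normalizer Normalizer applied to every symbol.
#' @return Character vector of unique normalized symbols.
#' @export
read_gene_set <- function(path, symbol_normalizer = normalize_symbol) {
  if (!file.exists(path)) stop("cannot read gene-set file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) & !grepl("^[#!]", lines)]
  unique(symbol_normalizer(lines))
}

#' Map a gene set into an interactome
#'
#' @param set_genes Character vector of gene symbols.
#' @param net An `interactome`.
#' @param name Label for the set.
#' @return A `protein_set`: list with `name`, `genes` (as given, unique) and
#'   `mapped` (the subset present among the network's nodes). An empty
#'   mapped set triggers a warning, not an error.
#' @export
map_protein_set <- function(set_genes, net, name = "set") {
  genes <- unique(as.character(set_genes))
  mapped <- intersect(genes, interactome_nodes(net))
  if (length(genes) > 0L && length(mapped) == 0L) {
    warning("protein set '", name, "': no genes mapped into the network")
  }
  structure(list(name = name, genes = genes, mapped = mapped),
            class = "protein_set")
}

#' @export
print.protein_set <- function(x, ...) {
  cat(sprintf("protein set '%s': %d genes, %d mapped in network\n",
              x$name, length(x$genes), length(x$mapped)))
  invisible(x)
}

#' Derive a control set by exclusion
#'
#' The control set contains every network node that belongs to none of the
#' excluded sets (their mapped portions), mirroring the construction of a
#' control gene group as "all mapped protein-coding genes minus the disease
#' and essential genes".
#'
#' @param net An `interactome`.
#' @param excluded List of `protein_set` objects to exclude.
#' @param name Label for the control set.
#' @return A `protein_set` whose `genes` and `mapped` coincide.
#' @export
derive_control_set <- function(net, excluded = list(), name = "control") {
  if (inherits(excluded, "protein_set")) excluded <- list(excluded)
  drop <- unique(unlist(lapply(excluded, function(s) s$mapped)))
  keep <- setdiff(interactome_nodes(net), drop)
  structure(list(name = name, genes = keep, mapped = keep),
            class = "protein_set")
}

#' Read a GMT annotation catalog
#'
#' Each line is `pathway_id <TAB> description <TAB> member1 <TAB> member2 ...`
#' Duplicate members within a line are collapsed.
#'
#' @param path Path to the GMT file.
#' @param symbol_normalizer Normalizer applied to member symbols.
#' @return Named list; each element is `list(name = description,
#'   genes = character vector)`, names are pathway ids.
#' @export
read_gmt <- function(path, symbol_normalizer = normalize_symbol) {
  if (!file.exists(path)) stop("cannot read GMT file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) return(structure(list(), names = character()))
  out <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop("malformed GMT line ", i, " in ", path, ": fewer than 3 fields")
    }
    ids[[i]] <- f[[1L]]
    out[[i]] <- list(name = f[[2L]],
                     genes = unique(symbol_normalizer(f[-(1:2)])))
  }
  names(out) <- ids
  out
}

#' Write an annotation catalog in GMT format
#'
#' @param catalog Named list as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(catalog, path) {
  lines <- vapply(names(catalog), function(id) {
    p <- catalog[[id]]
    paste(c(id, p$name, p$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
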