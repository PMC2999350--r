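# Ranking proteins by topological measure, union of top lists, and
# criterion-filtered pathway over-representation analysis (one-sided
# Fisher / hypergeometric test, Benjamini-Hochberg FDR).

#' Top proteins by a topological measure
#'
#' Ranks the profile's proteins by one measure and returns the top `k`.
#' Degree, betweenness and clustering coefficient rank descending (large is
#' "top"); gSPD and cSPD rank ascending (short distances are "top"). Nodes
#' with an undefined value are excluded; ties are broken lexicographically
#' by node id so the ranking is deterministic. If fewer than `k` defined
#' values exist, all are returned with a warning.
#'
#' @param profile A `topology_profile`.
#' @param measure One of `"k"`, `"B"`, `"C"`, `"gSPD"`, `"cSPD"`.
#' @param k Number of proteins to select (default 20).
#' @param direction Override the default ranking direction
#'   (`"descending"`/`"ascending"`).
#' @return Data frame `node`, `value` in rank order.
#' @export
top_by_measure <- function(profile, measure = c("k", "B", "C", "gSPD", "cSPD"),
                           k = 20L, direction = NULL) {
  measure <- match.arg(measure)
  stopifnot(k >= 1L)
  if (is.null(direction)) {
    direction <- if (measure %in% c("gSPD", "cSPD")) "ascending" else "descending"
  }
  direction <- match.arg(direction, c("descending", "ascending"))
  nd <- profile$nodes
  vals <- nd[[measure]]
  ok <- !is.na(vals)
  nd <- nd[ok, , drop = FALSE]
  vals <- vals[ok]
  if (nrow(nd) < k) {
    warning("only ", nrow(nd), " proteins have a defined ", measure,
            "; returning all")
    k <- nrow(nd)
  }
  ord <- if (direction == "descending") order(-vals, nd$node) else
    order(vals, nd$node)
  sel <- ord[seq_len(k)]
  data.frame(node = nd$node[sel], value = vals[sel], stringsAsFactors = FALSE)
}

#' Union of top-ranked lists with membership flags
#'
#' @param lists Named list of character vectors (or data frames with a
#'   `node` column) of top-ranked proteins per measure.
#' @return Data frame with column `gene` (sorted union) plus one logical
#'   membership column per input list.
#' @export
union_top <- function(lists) {
  vecs <- lapply(lists, function(x) if (is.data.frame(x)) x$node else x)
  genes <- sort(unique(unlist(vecs)))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (nm in names(vecs)) out[[nm]] <- genes %in% vecs[[nm]]
  out
}

#' Pathway over-representation by Fisher's exact test
#'
#' One-sided (over-representation) test per pathway: with `N` background
#' genes, `K` of them in the pathway, and `n` selected genes of which `x`
#' fall in the pathway, the p-value is `P(X >= x)` for `X ~
#' Hypergeometric(N, K, n)`. Pathway membership is intersected with the
#' background before counting so the 2x2 table is coherent; pathways with
#' no background member are dropped. Raw p-values are adjusted with
#' [bh_fdr()] across all tested pathways.
#'
#' @param selected Character vector of selected genes; must be a subset of
#'   `background`.
#' @param catalog Named list as from [read_gmt()].
#' @param background Character vector of background genes (e.g. all genes,
#'   or the network's nodes).
#' @return Data frame with one row per pathway: `pathway_id`,
#'   `pathway_name`, `n_overlap`, `n_pathway`, `n_selected`, `n_background`,
#'   `p_value`, `fdr_p`; sorted by `fdr_p` then `p_value` then id.
#' @export
fisher_enrichment <- function(selected, catalog, background) {
  background <- unique(background)
  if (length(background) == 0L) stop("empty background")
  selected <- unique(selected)
  if (length(setdiff(selected, background))) {
    stop("selected genes must be a subset of the background")
  }
  N <- length(background)
  n <- length(selected)
  rows <- lapply(names(catalog), function(id) {
    members <- intersect(catalog[[id]]$genes, background)
    K <- length(members)
    if (K == 0L) return(NULL)
    x <- length(intersect(selected, members))
    p <- stats::phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway_id = id, pathway_name = catalog[[id]]$name,
               n_overlap = x, n_pathway = K, n_selected = n,
               n_background = N, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(pathway_id = character(), pathway_name = character(),
                      n_overlap = integer(), n_pathway = integer(),
                      n_selected = integer(), n_background = integer(),
                      p_value = numeric(), fdr_p = numeric(),
                      stringsAsFactors = FALSE))
  }
  out$fdr_p <- bh_fdr(out$p_value)
  out <- out[order(out$fdr_p, out$p_value, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up procedure: sort p ascending, multiply by `n / rank`, enforce
#' monotonicity by a cumulative minimum from the largest p, cap at 1.
#' Output order matches input order.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  ord <- order(p)
  adj <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[ord] <- adj
  out
}

#' Filter enriched pathways by the reporting criteria
#'
#' Keeps pathways with `fdr_p` strictly below the FDR threshold *and* an
#' overlap of at least `min_overlap` selected genes, the conventional pair
#' of criteria (FDR p < 0.001, >= 5 genes) for calling a pathway enriched.
#'
#' @param rows Data frame from [fisher_enrichment()].
#' @param fdr_threshold Strict upper bound on `fdr_p` (default 0.001).
#' @param min_overlap Minimum `n_overlap` (default 5).
#' @return Filtered rows sorted by `fdr_p` then `p_value`.
#' @export
filter_enriched <- function(rows, fdr_threshold = 0.001, min_overlap = 5L) {
  stopifnot(fdr_threshold >= 0, fdr_threshold <= 1, min_overlap >= 0)
  keep <- rows$fdr_p < fdr_threshold & rows$n_overlap >= min_overlap
  out <- rows[keep, , drop = FALSE]
  out <- out[order(out$fdr_p, out$p_value, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
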