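# Set-specific subnetworks, Erdos-Renyi G(n,m) nulls with empirical
# p-values, and degree-centralization perturbation analysis.

#' Induced subnetwork of a protein set
#'
#' Extracts the graph over the set's mapped members keeping only within-set
#' edges, i.e. "all interactions between the set's proteins". Set members
#' with no within-set edge remain as isolated vertices; `n_linked` counts
#' members with at least one within-set edge and components are reported for
#' the non-isolated part.
#'
#' @param net An `interactome` or igraph graph.
#' @param pset A `protein_set`.
#' @return A `subnetwork`: list with `set_name`, `graph` (igraph over all
#'   mapped members), `n_linked`, `n_edges`, and `components` (list of
#'   node-name vectors for components of size >= 2, largest first).
#' @export
induced_subnetwork <- function(net, pset) {
  g <- as_graph(net)
  members <- pset$mapped
  if (length(members) == 0L) stop("protein set has no mapped members")
  sub <- igraph::induced_subgraph(g, members)
  k <- igraph::degree(sub)
  comp <- igraph::components(sub)
  groups <- split(igraph::V(sub)$name, comp$membership)
  groups <- groups[order(-vapply(groups, length, 1L))]
  groups <- groups[vapply(groups, length, 1L) >= 2L]
  structure(list(set_name = pset$name, graph = sub,
                 n_linked = sum(k > 0), n_edges = igraph::ecount(sub),
                 components = unname(groups)),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf(
    "subnetwork '%s': %d nodes (%d linked), %d edges, %d components (>=2 nodes)\n",
    x$set_name, igraph::vcount(x$graph), x$n_linked, x$n_edges,
    length(x$components)))
  invisible(x)
}

#' Erdos-Renyi G(n,m) random graph
#'
#' Draws exactly `m` edges uniformly without replacement from the unordered
#' node pairs of `n` labeled nodes (a simple undirected graph). Reproducible
#' under `seed`.
#'
#' @param n Node count.
#' @param m Edge count; must satisfy `0 <= m <= n(n-1)/2`.
#' @param seed Optional integer seed.
#' @return An igraph graph.
#' @export
er_gnm <- function(n, m, seed = NULL) {
  if (m < 0 || m > n * (n - 1) / 2) {
    stop("edge count m out of range for n = ", n)
  }
  if (!is.null(seed)) set.seed(seed)
  igraph::sample_gnm(n, m, directed = FALSE)
}

#' Graph-level summaries used by the randomization test
#'
#' Mean betweenness over all nodes, mean clustering coefficient over nodes
#' of degree >= 2 (`NA` if no node qualifies), and mean shortest-path
#' distance L over all *reachable* unordered node pairs. A graph with no
#' reachable pair has no defined L and is an error.
#'
#' @param graph An igraph graph or `interactome`.
#' @return List with numeric `B`, `C`, `L`.
#' @export
null_summaries <- function(graph) {
  g <- as_graph(graph)
  if (igraph::vcount(g) == 0L) stop("empty graph")
  if (igraph::ecount(g) == 0L) stop("no reachable pairs: L undefined")
  B <- mean(igraph::betweenness(g, directed = FALSE))
  cc <- igraph::transitivity(g, type = "local", isolates = "NaN")
  cc <- cc[is.finite(cc)]
  C <- if (length(cc)) mean(cc) else NA_real_
  L <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  list(B = B, C = C, L = L)
}

#' Randomization test of a subnetwork against the G(n,m) null
#'
#' Generates `reps` Erdos-Renyi G(n,m) replicates with the observed
#' subnetwork's node and edge counts, summarizes each with
#' [null_summaries()], and counts replicates more extreme than the observed
#' values with *strict* inequalities: `n_B` and `n_C` count replicates with
#' higher mean betweenness / clustering, `n_L` counts replicates with
#' *shorter* mean path distance. Empirical p-values are `count / reps`.
#' An `NA` observed value yields `NA` count and p for that measure.
#'
#' @param observed A `subnetwork` (summaries computed from its graph) or a
#'   list with components `B`, `C`, `L`.
#' @param n,m Replicate dimensions; default to the observed subnetwork's
#'   linked-node and edge counts.
#' @param reps Number of replicates (>= 1); 1000 is the conventional choice.
#' @param seed Optional integer seed for reproducibility.
#' @return A `null_model_result`: list with `n_nodes`, `n_edges`, `reps`,
#'   `observed` (B, C, L), `null_mean`, `null_sd`, `counts` (n_B, n_C, n_L)
#'   and `p` (p_B, p_C, p_L).
#' @export
randomization_test <- function(observed, n = NULL, m = NULL, reps = 1000L,
                               seed = NULL) {
  if (reps < 1L) stop("reps must be at least 1")
  if (inherits(observed, "subnetwork")) {
    # the observed statistics and replicate dimensions describe the linked
    # part of the subnetwork: members without any within-set edge carry no
    # information about within-set wiring
    k0 <- igraph::degree(observed$graph)
    linked <- igraph::induced_subgraph(observed$graph, names(k0)[k0 > 0])
    if (is.null(n)) n <- igraph::vcount(linked)
    if (is.null(m)) m <- observed$n_edges
    observed <- null_summaries(linked)
  }
  stopifnot(is.list(observed), !is.null(n), !is.null(m))
  obs <- list(B = observed$B %||% NA_real_, C = observed$C %||% NA_real_,
              L = observed$L %||% NA_real_)
  if (!is.null(seed)) set.seed(seed)
  Bs <- Cs <- Ls <- numeric(reps)
  for (i in seq_len(reps)) {
    s <- null_summaries(igraph::sample_gnm(n, m, directed = FALSE))
    Bs[i] <- s$B; Cs[i] <- s$C; Ls[i] <- s$L
  }
  cnt <- function(x) if (is.na(x)) NA_integer_ else x
  counts <- list(n_B = cnt(if (is.na(obs$B)) NA else sum(Bs > obs$B)),
                 n_C = cnt(if (is.na(obs$C)) NA else sum(Cs > obs$C, na.rm = TRUE)),
                 n_L = cnt(if (is.na(obs$L)) NA else sum(Ls < obs$L)))
  structure(list(
    n_nodes = n, n_edges = m, reps = reps, observed = obs,
    null_mean = list(B = mean(Bs), C = mean(Cs, na.rm = TRUE), L = mean(Ls)),
    null_sd = list(B = stats::sd(Bs), C = stats::sd(Cs), L = stats::sd(Ls)),
    counts = counts,
    p = list(p_B = counts$n_B / reps, p_C = counts$n_C / reps,
             p_L = counts$n_L / reps)),
    class = "null_model_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf("G(n=%d, m=%d) null, %d replicates\n", x$n_nodes, x$n_edges,
              x$reps))
  cat(sprintf("  observed  B=%.4g C=%.4g L=%.4g\n", x$observed$B,
              x$observed$C, x$observed$L))
  cat(sprintf("  null mean B=%.4g C=%.4g L=%.4g\n", x$null_mean$B,
              x$null_mean$C, x$null_mean$L))
  cat(sprintf("  empirical p: p_B=%.3g p_C=%.3g p_L=%.3g\n", x$p$p_B,
              x$p$p_C, x$p$p_L))
  invisible(x)
}

#' Freeman degree centralization
#'
#' `sum(k_max - k_v) / ((n - 1)(n - 2))` over all nodes, in [0, 1]: 0 for
#' regular graphs, 1 exactly for the star.
#'
#' @param graph An igraph graph or `interactome` with at least 3 nodes.
#' @return Centralization value in [0, 1].
#' @export
degree_centralization <- function(graph) {
  g <- as_graph(graph)
  n <- igraph::vcount(g)
  if (n < 3L) stop("centralization needs at least 3 nodes")
  k <- igraph::degree(g)
  sum(max(k) - k) / ((n - 1) * (n - 2))
}

#' Centralization change under node removal
#'
#' Removes the given nodes (with their incident edges) and recomputes the
#' Freeman degree centralization, quantifying how much the network "loosens"
#' when its most central proteins are deleted.
#'
#' @param graph An igraph graph or `interactome`.
#' @param nodes Character vector of node names to remove; all must exist and
#'   at least 3 nodes must remain.
#' @return A `centralization_report`: list with `before`, `after`,
#'   `removed`.
#' @export
removal_effect <- function(graph, nodes) {
  g <- as_graph(graph)
  missing <- setdiff(nodes, igraph::V(g)$name)
  if (length(missing)) {
    stop("nodes not in graph: ", paste(missing, collapse = ", "))
  }
  if (igraph::vcount(g) - length(nodes) < 3L) {
    stop("removal leaves fewer than 3 nodes")
  }
  before <- degree_centralization(g)
  after <- degree_centralization(igraph::delete_vertices(g, nodes))
  structure(list(before = before, after = after, removed = nodes),
            class = "centralization_report")
}

#' @export
print.centralization_report <- function(x, ...) {
  cat(sprintf("degree centralization %.4f -> %.4f after removing %d nodes\n",
              x$before, x$after, length(x$removed)))
  invisible(x)
}
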