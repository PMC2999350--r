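# Per-node and per-set topological measures: degree and its distribution,
# clustering coefficient, betweenness (pair-dependency or literal path
# count), BFS shortest paths, and the two set-relative distances:
#   gSPD -- mean shortest-path distance from a set member to reachable
#           nodes OUTSIDE the set;
#   cSPD -- mean shortest-path distance from a set member to reachable
#           OTHER members of the same set.

#' Node degrees
#'
#' @param net An `interactome` or igraph graph.
#' @return Named integer vector, one entry per node.
#' @export
node_degrees <- function(net) {
  g <- as_graph(net)
  if (igraph::vcount(g) == 0L) stop("empty network")
  igraph::degree(g)
}

#' Mean degree of a network or node subset
#'
#' For a whole simple graph this equals `2 * |edges| / |nodes|`.
#'
#' @param net An `interactome` or igraph graph.
#' @param nodes Optional character vector restricting the average to a node
#'   subset.
#' @return Arithmetic mean degree.
#' @export
mean_degree <- function(net, nodes = NULL) {
  k <- node_degrees(net)
  if (!is.null(nodes)) {
    missing <- setdiff(nodes, names(k))
    if (length(missing)) stop("unknown nodes: ", paste(missing, collapse = ", "))
    k <- k[nodes]
  }
  if (length(k) == 0L) stop("no nodes to average over")
  mean(k)
}

#' Empirical degree distribution P(k)
#'
#' P(k) is the probability that a node (of the supplied degree sample) has
#' exactly k links; probabilities sum to one.
#'
#' @param k Integer vector of degrees (e.g. `node_degrees(net)` or a subset).
#' @return Data frame with columns `k` and `p`, sorted by `k`.
#' @export
degree_distribution <- function(k) {
  if (length(k) == 0L) stop("no degrees supplied")
  tab <- table(factor(k, levels = sort(unique(k))))
  data.frame(k = as.integer(names(tab)),
             p = as.numeric(tab) / length(k))
}

#' Local clustering coefficients
#'
#' C(v) = 2 t(v) / (k(v) (k(v) - 1)), where t(v) counts edges among v's
#' neighbors. Undefined (`NA`) for nodes of degree < 2; such nodes are
#' excluded from set averages rather than contributing zeros.
#'
#' @param net An `interactome` or igraph graph.
#' @return Named numeric vector with `NA` where undefined.
#' @export
clustering_coefficients <- function(net) {
  g <- as_graph(net)
  cc <- igraph::transitivity(g, type = "local", isolates = "NaN")
  cc[!is.finite(cc)] <- NA_real_
  names(cc) <- igraph::V(g)$name
  cc
}

#' Betweenness centrality
#'
#' Unweighted shortest-path betweenness of every node. The default
#' `"pair_dependency"` variant is the standard Brandes accumulation
#' sum over unordered pairs (s, t) of sigma_st(v) / sigma_st, endpoints
#' excluded, unnormalized. The `"raw_count"` variant instead counts each
#' shortest path once: sum over unordered pairs of sigma_st(v), i.e. the
#' literal number of shortest paths traversing the node. Nodes in different
#' components contribute nothing to each other.
#'
#' @param net An `interactome` or igraph graph.
#' @param variant `"pair_dependency"` (default) or `"raw_count"`.
#' @return Named numeric vector of betweenness values (>= 0).
#' @export
node_betweenness <- function(net, variant = c("pair_dependency", "raw_count")) {
  variant <- match.arg(variant)
  g <- as_graph(net)
  if (variant == "pair_dependency") {
    b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
    names(b) <- igraph::V(g)$name
    return(b)
  }
  raw_count_betweenness(g)
}

# Literal shortest-path count: for each source s run a BFS computing path
# counts sigma_sv, then accumulate backwards S(v) = sum over BFS-successors w
# of (1 + S(w)), the number of shortest-path suffixes starting at v. The
# contribution of interior node v for source s is sigma_sv * S(v); summing
# over all sources counts every unordered pair twice, so halve at the end.
raw_count_betweenness <- function(g) {
  n <- igraph::vcount(g)
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, as.integer)
  acc <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep.int(NA_integer_, n)
    sigma <- numeric(n)
    dist[s] <- 0L
    sigma[s] <- 1
    frontier <- s
    order_visited <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (is.na(dist[w])) {
            dist[w] <- dist[v] + 1L
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1L) sigma[w] <- sigma[w] + sigma[v]
        }
      }
      order_visited <- c(order_visited, nxt)
      frontier <- unique(nxt)
    }
    S <- numeric(n)
    for (v in rev(unique(order_visited))) {
      for (w in adj[[v]]) {
        if (!is.na(dist[w]) && dist[w] == dist[v] + 1L) {
          S[v] <- S[v] + 1 + S[w]
        }
      }
    }
    interior <- setdiff(which(!is.na(dist)), s)
    acc[interior] <- acc[interior] + sigma[interior] * S[interior]
  }
  out <- acc / 2
  names(out) <- igraph::V(g)$name
  out
}

#' Single-source shortest-path lengths
#'
#' Breadth-first distances from `source`; unreachable nodes are absent from
#' the result, and `distance(source) == 0`.
#'
#' @param net An `interactome` or igraph graph.
#' @param source Node symbol.
#' @return Named numeric vector of finite distances.
#' @export
shortest_path_lengths <- function(net, source) {
  g <- as_graph(net)
  if (!source %in% igraph::V(g)$name) stop("source node not in network: ", source)
  d <- igraph::distances(g, v = source, mode = "all")[1L, ]
  d[is.finite(d)]
}

# Distance matrix rows for a set of nodes; shared by gspd/cspd.
set_distance_rows <- function(g, from) {
  igraph::distances(g, v = from, mode = "all")
}

#' General shortest-path distance (gSPD)
#'
#' For each mapped member v of the set, the mean shortest-path distance from
#' v to every *reachable* node outside the set; `NA` when no outside node is
#' reachable. The set average is the arithmetic mean over members with a
#' defined value.
#'
#' @param net An `interactome` or igraph graph.
#' @param pset A `protein_set` (see [map_protein_set()]).
#' @return List with `values` (named per-node vector) and `average`.
#' @export
gspd <- function(net, pset) {
  g <- as_graph(net)
  members <- pset$mapped
  if (length(members) == 0L) stop("protein set has no mapped members")
  outside <- setdiff(igraph::V(g)$name, members)
  if (length(outside) == 0L) stop("set covers network: no outside nodes for gSPD")
  D <- set_distance_rows(g, members)[, outside, drop = FALSE]
  vals <- apply(D, 1L, function(r) {
    f <- r[is.finite(r)]
    if (length(f)) mean(f) else NA_real_
  })
  names(vals) <- members
  list(values = vals, average = mean(vals, na.rm = TRUE))
}

#' Characteristic shortest-path distance (cSPD)
#'
#' For each mapped member v of the set, the mean shortest-path distance from
#' v to every *reachable* other member of the same set; `NA` when no other
#' member is reachable.
#'
#' @inheritParams gspd
#' @return List with `values` and `average`, as for [gspd()].
#' @export
cspd <- function(net, pset) {
  g <- as_graph(net)
  members <- pset$mapped
  if (length(members) < 2L) stop("cSPD needs at least 2 mapped set members")
  D <- set_distance_rows(g, members)[, members, drop = FALSE]
  diag(D) <- Inf
  vals <- apply(D, 1L, function(r) {
    f <- r[is.finite(r)]
    if (length(f)) mean(f) else NA_real_
  })
  names(vals) <- members
  list(values = vals, average = mean(vals, na.rm = TRUE))
}

#' Classify hubs by a degree cutoff
#'
#' Hubs are nodes with degree *strictly greater* than the cutoff. Two
#' conventional cutoffs in protein interaction analysis are 5 and 12.
#'
#' @param k Named (or plain) integer vector of degrees for the set.
#' @param cutoff Non-negative integer cutoff.
#' @return List with `count` and `fraction` (`count / length(k)`).
#' @export
classify_hubs <- function(k, cutoff) {
  stopifnot(cutoff >= 0)
  if (length(k) == 0L) stop("empty degree set")
  cnt <- sum(k > cutoff)
  list(count = cnt, fraction = cnt / length(k))
}

#' Build the full topology profile of a protein set
#'
#' Computes, for every mapped member of the set, its degree, betweenness and
#' clustering coefficient in the whole network plus its gSPD and cSPD, and
#' summarizes the set by the arithmetic mean of each measure over members
#' with a defined value (the shape of a per-set summary table row). Hub
#' counts and fractions are reported for each cutoff.
#'
#' When the set covers the whole network the gSPD column is undefined (`NA`)
#' rather than an error; likewise cSPD for sets with fewer than two mapped
#' members.
#'
#' @param net An `interactome` or igraph graph.
#' @param pset A `protein_set`.
#' @param hub_cutoffs Integer vector of degree cutoffs (default `c(5, 12)`).
#' @param betweenness_variant Passed to [node_betweenness()].
#' @return A `topology_profile`: list with `set_name`, `nodes` (data frame
#'   `node`, `k`, `B`, `C`, `gSPD`, `cSPD`), `summary` (one-row data frame)
#'   and `hubs` (data frame `cutoff`, `count`, `fraction`).
#' @export
build_profile <- function(net, pset, hub_cutoffs = c(5L, 12L),
                          betweenness_variant = "pair_dependency") {
  g <- as_graph(net)
  members <- pset$mapped
  if (length(members) == 0L) stop("protein set has no mapped members")
  k <- node_degrees(g)[members]
  B <- node_betweenness(g, betweenness_variant)[members]
  C <- clustering_coefficients(g)[members]
  gs <- if (length(setdiff(igraph::V(g)$name, members)) > 0L) {
    gspd(g, pset)$values
  } else {
    stats::setNames(rep(NA_real_, length(members)), members)
  }
  cs <- if (length(members) >= 2L) {
    cspd(g, pset)$values
  } else {
    stats::setNames(rep(NA_real_, length(members)), members)
  }
  nodes <- data.frame(node = members, k = as.integer(k), B = as.numeric(B),
                      C = as.numeric(C), gSPD = as.numeric(gs),
                      cSPD = as.numeric(cs), stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$node), , drop = FALSE]
  rownames(nodes) <- NULL
  avg <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  summary <- data.frame(set = pset$name,
                        n_genes = length(pset$genes),
                        n_mapped = length(members),
                        connectivity = avg(nodes$k),
                        betweenness = avg(nodes$B),
                        clustering = avg(nodes$C),
                        gSPD = avg(nodes$gSPD),
                        cSPD = avg(nodes$cSPD),
                        stringsAsFactors = FALSE)
  hubs <- do.call(rbind, lapply(hub_cutoffs, function(co) {
    h <- classify_hubs(nodes$k, co)
    data.frame(cutoff = co, count = h$count, fraction = h$fraction)
  }))
  structure(list(set_name = pset$name, nodes = nodes, summary = summary,
                 hubs = hubs),
            class = "topology_profile")
}

#' @export
print.topology_profile <- function(x, ...) {
  cat(sprintf("topology profile '%s' (%d proteins)\n", x$set_name,
              nrow(x$nodes)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
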