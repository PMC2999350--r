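# Independent brute-force oracles. Everything here works on a plain
# symmetric 0/1 adjacency matrix with named rows/cols and deliberately
# avoids igraph and the package's own code paths.

# Random simple graph as an adjacency matrix (each pair kept with prob p).
random_adjacency <- function(n, p = 0.35) {
  A <- matrix(0L, n, n, dimnames = list(LETTERS[1:n], LETTERS[1:n]))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (stats::runif(1) < p) A[i, j] <- A[j, i] <- 1L
    }
  }
  A
}

adjacency_to_graph <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

adjacency_to_records <- function(A) {
  idx <- which(A == 1L & upper.tri(A), arr.ind = TRUE)
  data.frame(protein_a = rownames(A)[idx[, 1L]],
             protein_b = colnames(A)[idx[, 2L]],
             source = "oracle", stringsAsFactors = FALSE)
}

# All-pairs shortest distances by Floyd-Warshall (dynamic programming,
# independent of BFS).
bf_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  D[A == 1L] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
    }
  }
  D
}

# Explicit enumeration of every shortest path between s and t: depth-first
# over simple paths, pruned at the known shortest length.
bf_shortest_paths <- function(A, s, t, L) {
  paths <- list()
  walk <- function(u, path) {
    if (length(path) - 1L == L) {
      if (u == t) paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (w in which(A[u, ] == 1L)) {
      if (!w %in% path) walk(w, c(path, w))
    }
  }
  walk(s, s)
  paths
}

# Both betweenness variants from explicit path enumeration: per unordered
# pair, pair_dependency adds (#paths through v) / (#paths), raw_count adds
# the count itself.
bf_betweenness <- function(A, variant = c("pair_dependency", "raw_count")) {
  variant <- match.arg(variant)
  n <- nrow(A)
  D <- bf_distances(A)
  B <- stats::setNames(numeric(n), rownames(A))
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      if (!is.finite(D[s, t]) || D[s, t] < 2) next
      paths <- bf_shortest_paths(A, s, t, D[s, t])
      through <- table(unlist(lapply(paths, function(p) p[-c(1L, length(p))])))
      idx <- as.integer(names(through))
      add <- if (variant == "pair_dependency") {
        as.numeric(through) / length(paths)
      } else {
        as.numeric(through)
      }
      B[idx] <- B[idx] + add
    }
  }
  B
}

# Clustering by neighbor-pair enumeration.
bf_clustering <- function(A) {
  vapply(seq_len(nrow(A)), function(v) {
    nb <- which(A[v, ] == 1L)
    k <- length(nb)
    if (k < 2L) return(NA_real_)
    links <- 0L
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) links <- links + A[nb[i], nb[j]]
    }
    2 * links / (k * (k - 1))
  }, 0) |> stats::setNames(rownames(A))
}

# gSPD / cSPD by an explicit double loop over node pairs.
bf_setdist <- function(A, members, within) {
  D <- bf_distances(A)
  all_nodes <- rownames(A)
  targets_of <- function(v) {
    tt <- if (within) setdiff(members, v) else setdiff(all_nodes, members)
    tt
  }
  vapply(members, function(v) {
    ds <- D[v, targets_of(v)]
    ds <- ds[is.finite(ds)]
    if (length(ds)) mean(ds) else NA_real_
  }, 0)
}

# Exact two-sided rank-sum p by full enumeration of rank assignments.
bf_ranksum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  obs <- sum(rank(pooled)[seq_len(nx)])
  combos <- utils::combn(nx + ny, nx)
  sums <- colSums(matrix(rank(pooled)[combos], nrow = nx))
  mu <- nx * (nx + ny + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# BH adjustment recomputed from the definition.
bf_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in rev(seq_len(n))) {
    prev <- min(prev, p[ord[i]] * n / i)
    adj[ord[i]] <- prev
  }
  adj
}

# Small named graph from an edge string like "A-B,B-C".
graph_from_spec <- function(spec, isolates = character()) {
  pairs <- strsplit(strsplit(spec, ",", fixed = TRUE)[[1L]], "-", fixed = TRUE)
  ed <- data.frame(a = vapply(pairs, `[[`, "", 1L),
                   b = vapply(pairs, `[[`, "", 2L))
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  if (length(isolates)) g <- igraph::add_vertices(g, length(isolates),
                                                  name = isolates)
  g
}
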