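# Synthetic worlds with known ground truth: heavy-tailed interactomes,
# planted protein sets whose sampling is biased toward high degree, and
# annotation catalogs with planted-enriched pathways. Every generator is
# deterministic under its seed, so a world can be regenerated bit-for-bit
# from its recorded parameters.

symbol_names <- function(n) sprintf("G%05d", seq_len(n))

#' Generate a synthetic interactome
#'
#' Three generative models are available:
#' * `"preferential_attachment"` (default): linear preferential attachment,
#'   each new node attaching `m_attach` edges; produces the heavy-tailed
#'   degree distributions characteristic of empirical interactomes.
#' * `"duplication_divergence"`: a new node copies each neighbor of a random
#'   anchor with probability `p_retain` and links to the anchor with
#'   probability `p_anchor`; yields modular heavy-tailed graphs.
#' * `"er"`: Erdos-Renyi G(n, m) with `params$m` edges (see [er_gnm()]).
#'
#' Nodes are named `G00001 ...` so they behave like gene symbols everywhere
#' downstream.
#'
#' @param n Number of nodes (>= 10).
#' @param model Generative model.
#' @param params Model parameters: `m_attach` (default 5) for preferential
#'   attachment; `p_retain` (default 0.4) and `p_anchor` (default 0.1) for
#'   duplication-divergence; `m` (required) for `"er"`.
#' @param seed Integer seed; the same seed always yields the same network.
#' @return An `interactome`.
#' @export
generate_network <- function(n,
                             model = c("preferential_attachment",
                                       "duplication_divergence", "er"),
                             params = list(), seed = 1L) {
  model <- match.arg(model)
  if (n < 10L) stop("need at least 10 nodes")
  set.seed(seed)
  g <- switch(model,
    preferential_attachment = {
      m_attach <- params$m_attach %||% 5L
      if (m_attach < 1L) stop("m_attach must be >= 1")
      igraph::as_undirected(
        igraph::sample_pa(n, power = 1, m = m_attach, directed = TRUE),
        mode = "collapse")
    },
    duplication_divergence = {
      p_retain <- params$p_retain %||% 0.4
      p_anchor <- params$p_anchor %||% 0.1
      if (p_retain < 0 || p_retain > 1 || p_anchor < 0 || p_anchor > 1) {
        stop("p_retain and p_anchor must lie in [0, 1]")
      }
      dd_graph(n, p_retain, p_anchor)
    },
    er = {
      if (is.null(params$m)) stop("er model requires params$m")
      igraph::sample_gnm(n, params$m, directed = FALSE)
    })
  igraph::V(g)$name <- symbol_names(n)
  g <- igraph::set_edge_attr(g, "sources", value = "synthetic")
  new_interactome(igraph::simplify(g))
}

# Duplication-divergence growth over neighbor sets; seeded from a 5-cycle.
# A duplicate that retains no edge is attached to its anchor so the graph
# stays free of isolated nodes.
dd_graph <- function(n, p_retain, p_anchor) {
  nbr <- vector("list", n)
  for (i in 1:5) nbr[[i]] <- setdiff(c(i %% 5L + 1L, (i + 3L) %% 5L + 1L), i)
  for (v in 6:n) {
    anchor <- sample.int(v - 1L, 1L)
    kept <- nbr[[anchor]][stats::runif(length(nbr[[anchor]])) < p_retain]
    if (stats::runif(1L) < p_anchor) kept <- union(kept, anchor)
    if (length(kept) == 0L) kept <- anchor
    nbr[[v]] <- kept
    for (w in kept) nbr[[w]] <- union(nbr[[w]], v)
  }
  edges <- do.call(rbind, lapply(seq_len(n), function(v) {
    ws <- nbr[[v]][nbr[[v]] > v]
    if (length(ws)) cbind(v, ws) else NULL
  }))
  igraph::graph_from_edgelist(edges, directed = FALSE)
}

#' Plant a degree-biased protein set
#'
#' Samples `size` nodes without replacement with probability proportional to
#' `k^alpha`, where `k` is the node's degree. `alpha = 0` gives a uniform
#' (control-like) set; larger `alpha` skews membership toward hubs,
#' emulating the empirical tendency of disease proteins toward high degree.
#'
#' @param net An `interactome`.
#' @param size Set size (<= number of nodes).
#' @param alpha Degree-bias exponent (>= 0).
#' @param seed Integer seed.
#' @param name Set label.
#' @param exclude Optional character vector of nodes not to sample (e.g.
#'   members of a previously planted set, to force disjointness).
#' @return A `protein_set` with attribute `truth` recording the parameters.
#' @export
plant_set <- function(net, size, alpha = 0, seed = 1L, name = "planted",
                      exclude = character()) {
  if (alpha < 0) stop("alpha must be >= 0")
  k <- node_degrees(net)
  pool <- setdiff(names(k), exclude)
  if (size > length(pool)) stop("size exceeds available nodes")
  set.seed(seed)
  w <- as.numeric(k[pool])^alpha   # 0^0 == 1: degree-0 nodes stay eligible at alpha = 0
  genes <- sample(pool, size, prob = w)
  out <- map_protein_set(genes, net, name = name)
  attr(out, "truth") <- list(size = size, alpha = alpha, seed = seed,
                             n_excluded = length(exclude))
  out
}

#' Plant an annotation catalog with enriched pathways
#'
#' Builds `n_pathways` gene sets over the network's nodes. The first
#' `n_enriched` pathways oversample members of `enriched_in` with weight
#' `enrichment_factor` (weight 1 for all other nodes); the rest draw
#' members uniformly. `enrichment_factor = 1` makes planted pathways
#' indistinguishable from the rest.
#'
#' @param nodes Character vector of background node symbols.
#' @param n_pathways Number of pathways.
#' @param size_range Length-2 integer vector; each pathway's size is drawn
#'   uniformly from this range.
#' @param enriched_in A `protein_set` (its mapped members are oversampled),
#'   or `NULL` when `n_enriched = 0`.
#' @param n_enriched Number of enriched pathways (<= `n_pathways`).
#' @param enrichment_factor Sampling-weight multiplier (>= 1) for members of
#'   `enriched_in`.
#' @param seed Integer seed.
#' @return Named list in [read_gmt()] shape with attribute `truth` listing
#'   the enriched pathway ids and generation parameters.
#' @export
plant_catalog <- function(nodes, n_pathways = 120L, size_range = c(10L, 80L),
                          enriched_in = NULL, n_enriched = 0L,
                          enrichment_factor = 20, seed = 1L) {
  if (n_enriched > n_pathways) stop("n_enriched exceeds n_pathways")
  if (n_enriched > 0L && is.null(enriched_in)) {
    stop("n_enriched > 0 requires an enriched_in set")
  }
  if (max(size_range) > length(nodes)) stop("pathway size exceeds node count")
  if (enrichment_factor < 1) stop("enrichment_factor must be >= 1")
  set.seed(seed)
  ids <- sprintf("PW%04d", seq_len(n_pathways))
  target <- if (is.null(enriched_in)) character() else enriched_in$mapped
  catalog <- vector("list", n_pathways)
  names(catalog) <- ids
  size_choices <- seq.int(size_range[1L], size_range[2L])
  for (i in seq_len(n_pathways)) {
    size <- size_choices[sample.int(length(size_choices), 1L)]
    w <- rep(1, length(nodes))
    enriched <- i <= n_enriched
    if (enriched) w[nodes %in% target] <- enrichment_factor
    members <- sample(nodes, size, prob = w)
    catalog[[i]] <- list(
      name = paste0(if (enriched) "planted enriched pathway "
                    else "background pathway ", i),
      genes = sort(members))
  }
  attr(catalog, "truth") <- list(
    enriched_ids = ids[seq_len(n_enriched)], n_pathways = n_pathways,
    size_range = size_range, enrichment_factor = enrichment_factor,
    seed = seed)
  catalog
}

#' Generate a complete synthetic world
#'
#' A world bundles one network, a degree-biased "cancer-like" set, a more
#' weakly biased "essential-like" set, the derived control set, and an
#' annotation catalog in which some pathways are enriched for the
#' cancer-like set. Default sizes scale the empirical proportions of a
#' 10,549-protein interactome with 342 disease and 1,896 essential proteins
#' down to the requested `n`.
#'
#' @param n Network size (default 2000; the full-scale preset is
#'   `n = 10549` with `m_attach = 5`).
#' @param model,params Passed to [generate_network()].
#' @param set_sizes Named integer vector with entries `cancer` and
#'   `essential`; defaults to `round(c(0.0324, 0.1797) * n)`.
#' @param alphas Named numeric vector of degree-bias exponents; default
#'   `c(cancer = 1.5, essential = 0.8)`.
#' @param catalog_params List with `n_pathways`, `size_range`, `n_enriched`,
#'   `enrichment_factor` (defaults 120, c(10, 80), 10, 20).
#' @param seed Integer master seed; stage seeds are derived from it.
#' @return A `synthetic_world`: list with `net`, `sets` (named list of
#'   `protein_set`: cancer, essential, control), `catalog`, and `truth`
#'   (all generator parameters, sufficient to regenerate the world).
#' @export
generate_world <- function(n = 2000L, model = "preferential_attachment",
                           params = list(m_attach = 5L),
                           set_sizes = NULL, alphas = NULL,
                           catalog_params = list(), seed = 1L) {
  if (is.null(set_sizes)) {
    set_sizes <- c(cancer = round(0.0324 * n), essential = round(0.1797 * n))
  }
  if (is.null(alphas)) alphas <- c(cancer = 1.5, essential = 0.8)
  cp <- utils::modifyList(
    list(n_pathways = 120L, size_range = c(10L, 80L), n_enriched = 10L,
         enrichment_factor = 20), catalog_params)
  # derived stage seeds keep stages independent yet reproducible
  seeds <- seed * 11L + c(net = 0L, cancer = 1L, essential = 2L, catalog = 3L)
  net <- generate_network(n, model = model, params = params,
                          seed = seeds[["net"]])
  cancer <- plant_set(net, set_sizes[["cancer"]], alphas[["cancer"]],
                      seed = seeds[["cancer"]], name = "cancer")
  essential <- plant_set(net, set_sizes[["essential"]], alphas[["essential"]],
                         seed = seeds[["essential"]], name = "essential",
                         exclude = cancer$mapped)
  control <- derive_control_set(net, list(cancer, essential))
  catalog <- plant_catalog(interactome_nodes(net),
                           n_pathways = cp$n_pathways,
                           size_range = cp$size_range,
                           enriched_in = cancer,
                           n_enriched = cp$n_enriched,
                           enrichment_factor = cp$enrichment_factor,
                           seed = seeds[["catalog"]])
  structure(list(
    net = net,
    sets = list(cancer = cancer, essential = essential, control = control),
    catalog = catalog,
    truth = list(n = n, model = model, params = params,
                 set_sizes = as.list(set_sizes), alphas = as.list(alphas),
                 catalog = cp,
                 enriched_ids = attr(catalog, "truth")$enriched_ids,
                 seed = seed)),
    class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("synthetic world (seed %d): %d nodes, %d edges\n",
              x$truth$seed, length(interactome_nodes(x$net)),
              nrow(interactome_edges(x$net))))
  for (s in x$sets) {
    cat("  "); print(s)
  }
  cat(sprintf("  catalog: %d pathways, %d planted enriched\n",
              length(x$catalog), length(x$truth$enriched_ids)))
  invisible(x)
}

#' Write a synthetic world to disk
#'
#' Emits `network.tsv` (canonical edge list), one `<set>.txt` per protein
#' set, `catalog.gmt` and `truth.json`. All outputs are byte-stable for a
#' given world.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_interactome(world$net, file.path(dir, "network.tsv"))
  for (s in world$sets) {
    writeLines(sort(s$genes), file.path(dir, paste0(s$name, ".txt")))
  }
  write_gmt(world$catalog, file.path(dir, "catalog.gmt"))
  jsonlite::write_json(world$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
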