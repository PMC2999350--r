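# Orchestration: validate a JSON run configuration and execute the full
# analysis (build/simulate -> profiles -> comparisons -> null model ->
# enrichment) into a deterministic report bundle.

config_defaults <- list(
  hub_cutoffs = c(5L, 12L),
  betweenness = "pair_dependency",
  null = list(reps = 1000L, set = "cancer"),
  top_k = 20L,
  fdr = 0.001,
  min_overlap = 5L,
  n_remove = 4L,
  pairs = list(c("cancer", "essential"), c("cancer", "control")),
  seed = 1L
)

known_config_keys <- c("input", "simulate", "hub_cutoffs", "betweenness",
                       "null", "top_k", "fdr", "min_overlap", "n_remove",
                       "pairs", "seed")

#' Validate a run configuration
#'
#' Accepts a path to a JSON file or an R list. Exactly one of `input`
#' (paths: `network`, named `sets`, `catalog`) or `simulate` (arguments for
#' [generate_world()]) must be present. Missing tunables receive the
#' conventional defaults: hub cutoffs 5 and 12, 1000 null replicates, top-20
#' ranking, FDR threshold 0.001, minimum pathway overlap 5. Unknown keys and
#' out-of-range values are errors.
#'
#' @param config Path to a JSON configuration or a list.
#' @return A validated `run_config` list with all defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  unknown <- setdiff(names(config), known_config_keys)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulate)
  if (has_input && has_sim) stop("config has both 'input' and 'simulate' blocks")
  if (!has_input && !has_sim) {
    stop("config requires one of: 'input' (network, sets, catalog paths) ",
         "or 'simulate' (synthetic-world parameters)")
  }
  cfg <- utils::modifyList(config_defaults, config)
  if (is.list(cfg$pairs) == FALSE && is.character(cfg$pairs)) {
    cfg$pairs <- lapply(strsplit(cfg$pairs, ":", fixed = TRUE), identity)
  }
  if (is.matrix(cfg$pairs)) cfg$pairs <- asplit(cfg$pairs, 1L)
  cfg$null <- utils::modifyList(config_defaults$null, as.list(cfg$null))
  if (cfg$null$reps < 1L) stop("null.reps must be at least 1")
  if (cfg$top_k < 1L) stop("top_k must be at least 1")
  if (cfg$fdr <= 0 || cfg$fdr > 1) stop("fdr must lie in (0, 1]")
  if (cfg$min_overlap < 0L) stop("min_overlap must be >= 0")
  if (any(cfg$hub_cutoffs < 0L)) stop("hub cutoffs must be >= 0")
  if (!cfg$betweenness %in% c("pair_dependency", "raw_count")) {
    stop("betweenness must be 'pair_dependency' or 'raw_count'")
  }
  if (has_input) {
    req <- c("network", "sets", "catalog")
    miss <- setdiff(req, names(cfg$input))
    if (length(miss)) stop("input block missing: ", paste(miss, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6L, format = "g"))
}

write_tsv_stable <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full comparative-topology analysis
#'
#' Executes every stage on one world -- either read from the configured
#' input paths or simulated -- and writes a report bundle to `outdir`:
#'
#' * `summary.tsv`: one row per protein set with mean connectivity,
#'   betweenness, clustering coefficient, gSPD and cSPD, plus hub fractions;
#' * `comparisons.tsv`: between-set tests for each configured pair;
#' * `nullmodel.json`: induced-subnetwork summaries, G(n,m) null, empirical
#'   p-values and the centralization removal report;
#' * `enrichment.tsv`: all pathways with Fisher and BH-FDR p-values, and
#'   `enrichment_filtered.tsv` with the criterion-passing subset;
#' * `run_log.json`: package version, seeds, configuration echo and input
#'   checksums.
#'
#' Identical configuration and seed produce a byte-identical bundle.
#'
#' @param config A `run_config`, list, or path (see [validate_config()]).
#' @param outdir Output directory.
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_all <- function(config, outdir) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  checksums <- if (!is.null(cfg$input)) {
    paths <- c(unlist(cfg$input$network), unlist(cfg$input$sets),
               cfg$input$catalog)
    as.list(tools::md5sum(paths))
  } else {
    list()
  }
  world <- stage("load", {
    if (!is.null(cfg$simulate)) {
      do.call(generate_world, cfg$simulate)
    } else {
      inp <- cfg$input
      records <- do.call(rbind, lapply(unlist(inp$network), parse_edge_list))
      net <- build_interactome(records)
      sets <- lapply(names(inp$sets), function(nm) {
        map_protein_set(read_gene_set(inp$sets[[nm]]), net, name = nm)
      })
      names(sets) <- names(inp$sets)
      if (!"control" %in% names(sets)) {
        sets$control <- derive_control_set(net, sets)
      }
      list(net = net, sets = sets, catalog = read_gmt(inp$catalog),
           truth = NULL)
    }
  })

  profiles <- stage("topology", {
    lapply(world$sets, function(s) {
      build_profile(world$net, s, hub_cutoffs = cfg$hub_cutoffs,
                    betweenness_variant = cfg$betweenness)
    })
  })
  summary_tab <- do.call(rbind, lapply(profiles, function(p) {
    row <- p$summary
    for (i in seq_len(nrow(p$hubs))) {
      row[[paste0("hub_frac_gt", p$hubs$cutoff[i])]] <- p$hubs$fraction[i]
    }
    row
  }))
  rownames(summary_tab) <- NULL
  write_tsv_stable(summary_tab, file.path(outdir, "summary.tsv"))

  comparisons <- stage("compare", {
    pairs <- Filter(function(pr) all(pr %in% names(profiles)), cfg$pairs)
    compare_profiles(profiles, pairs, hub_cutoffs = cfg$hub_cutoffs)
  })
  write_tsv_stable(comparisons, file.path(outdir, "comparisons.tsv"))

  nullres <- stage("nullmodel", {
    target <- cfg$null$set
    if (!target %in% names(world$sets)) {
      stop("null-model set '", target, "' not among the configured sets")
    }
    sub <- induced_subnetwork(world$net, world$sets[[target]])
    nm <- randomization_test(sub, reps = cfg$null$reps, seed = cfg$seed)
    k <- sort(igraph::degree(sub$graph), decreasing = TRUE)
    top_nodes <- names(k)[seq_len(min(cfg$n_remove, length(k)))]
    cr <- if (igraph::vcount(sub$graph) - length(top_nodes) >= 3L) {
      removal_effect(sub$graph, top_nodes)
    } else NULL
    list(subnetwork = sub, null = nm, centralization = cr)
  })
  stage("nullmodel-report", {
    nm <- nullres$null
    rep <- list(
      set = cfg$null$set,
      subnetwork = list(n_mapped = igraph::vcount(nullres$subnetwork$graph),
                        n_linked = nullres$subnetwork$n_linked,
                        n_edges = nullres$subnetwork$n_edges,
                        n_components = length(nullres$subnetwork$components)),
      null = nm[c("n_nodes", "n_edges", "reps", "observed", "null_mean",
                  "null_sd", "counts", "p")],
      centralization = if (!is.null(nullres$centralization)) {
        list(before = nullres$centralization$before,
             after = nullres$centralization$after,
             removed = nullres$centralization$removed)
      })
    jsonlite::write_json(rep, file.path(outdir, "nullmodel.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = 10)
  })

  enrich <- stage("enrich", {
    target <- cfg$null$set
    prof <- profiles[[target]]
    tops <- lapply(c(k = "k", B = "B", C = "C", gSPD = "gSPD", cSPD = "cSPD"),
                   function(m) top_by_measure(prof, m, k = cfg$top_k))
    sel <- union_top(tops)
    rows <- fisher_enrichment(sel$gene, world$catalog,
                              background = interactome_nodes(world$net))
    list(top = tops, union = sel, rows = rows,
         filtered = filter_enriched(rows, cfg$fdr, cfg$min_overlap))
  })
  write_tsv_stable(enrich$rows, file.path(outdir, "enrichment.tsv"))
  write_tsv_stable(enrich$filtered, file.path(outdir, "enrichment_filtered.tsv"))

  stage("log", {
    log <- list(
      package = "netonco",
      version = as.character(utils::packageVersion("netonco")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = cfg$seed,
      config = unclass(cfg),
      input_checksums = checksums,
      truth = world$truth)
    jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = 10)
  })

  invisible(list(config = cfg, world = world, profiles = profiles,
                 summary = summary_tab, comparisons = comparisons,
                 nullmodel = nullres, enrichment = enrich))
}
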