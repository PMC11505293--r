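CONFIG_KEYS <- c("genes", "edges", "gene_sets", "out_dir",
                 "tau", "prior", "channels", "hub_threshold",
                 "connector_mode", "max_depth", "max_connectors",
                 "fdr_threshold", "max_sets", "coverage_target",
                 "subnetwork_tag", "pathway_name", "universe_size", "seed")

CONFIG_DEFAULTS <- list(tau = 0.7, prior = 0.041,
                        channels = c("experiments", "database", "textmining"),
                        hub_threshold = 20L, connector_mode = "exact",
                        max_depth = 2L, max_connectors = 5L,
                        fdr_threshold = 0.05, max_sets = Inf,
                        coverage_target = 1, subnetwork_tag = "fpt_associated",
                        pathway_name = NULL, universe_size = NULL, seed = 1L)

#' Validate a pipeline configuration file
#'
#' Reads a YAML or JSON run configuration, rejects unknown keys (catching
#' typos is preferable to silently ignoring a misspelled threshold), applies
#' documented defaults with a logged message per default, checks numeric
#' ranges, and verifies that every referenced input file exists.
#'
#' Required keys: `genes`, `edges`, `gene_sets` (input paths). Optional keys
#' and defaults: `out_dir`, `tau` (0.7), `prior` (0.041), `channels`
#' (experiments, database, textmining), `hub_threshold` (20),
#' `connector_mode` ("exact"), `max_depth` (2), `max_connectors` (5),
#' `fdr_threshold` (0.05), `max_sets` (unlimited), `coverage_target` (1),
#' `subnetwork_tag` ("fpt_associated"), `pathway_name` (none),
#' `universe_size` (collection universe), `seed` (1).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A validated configuration list of class `run_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(cfg)) stop("configuration must be a mapping of keys to values")
  unknown <- setdiff(names(cfg), CONFIG_KEYS)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  required <- c("genes", "edges", "gene_sets")
  miss <- setdiff(required, names(cfg))
  if (length(miss) > 0L) stop("missing required configuration key(s): ",
                              paste(miss, collapse = ", "))
  base <- dirname(normalizePath(path))
  for (key in required) {
    p <- cfg[[key]]
    if (!file.exists(p)) {
      p2 <- file.path(base, p)
      if (!file.exists(p2)) stop("input file for '", key, "' not found: ", cfg[[key]])
      cfg[[key]] <- p2
    }
  }
  for (key in setdiff(CONFIG_KEYS, c(required, "out_dir"))) {
    if (is.null(cfg[[key]]) && !is.null(CONFIG_DEFAULTS[[key]])) {
      cfg[key] <- CONFIG_DEFAULTS[key]
      message("config default applied: ", key, " = ",
              paste(format(CONFIG_DEFAULTS[[key]]), collapse = ","))
    }
  }
  if (is.null(cfg$out_dir)) cfg$out_dir <- file.path(tempdir(), "pcosnet_run")

  check_range <- function(key, lo, hi, lo_open = FALSE, hi_open = FALSE) {
    v <- cfg[[key]]
    if (is.null(v)) return(invisible())
    bad <- !is.numeric(v) || length(v) != 1L || is.na(v) ||
      v < lo || v > hi || (lo_open && v == lo) || (hi_open && v == hi)
    if (bad) stop("configuration value out of range: ", key, " = ", v,
                  " (expected ", if (lo_open) "(" else "[", lo, ", ", hi,
                  if (hi_open) ")" else "]", ")")
  }
  check_range("tau", 0, 1, lo_open = TRUE)
  check_range("prior", 0, 1, hi_open = TRUE)
  check_range("fdr_threshold", 0, 1, lo_open = TRUE)
  check_range("coverage_target", 0, 1)
  check_range("hub_threshold", 1, Inf)
  check_range("max_depth", 1, 2)
  if (!cfg$connector_mode %in% c("exact", "greedy")) {
    stop("connector_mode must be 'exact' or 'greedy'")
  }
  bad_chan <- setdiff(cfg$channels, CHANNELS)
  if (length(bad_chan) > 0L) stop("unknown channel(s): ", paste(bad_chan, collapse = ", "))
  structure(cfg, class = "run_config")
}

#' Run the full interactome pipeline
#'
#' Executes the end-to-end workflow: read inputs, build the thresholded
#' interaction graph over the selected evidence channels, predict minimal
#' novel connectors for orphan seeds and merge them into the graph, compute
#' the topology summary (average degree, hub table), run hypergeometric
#' over-representation analysis of the network genes with BH-FDR control and
#' weighted set cover summarization, extract the process subnetwork and its
#' linking nodes, and write all result tables. Any stage error aborts the run
#' naming the stage, and partial outputs are removed.
#'
#' @param config A `run_config` from [validate_config()], or a path to a
#'   configuration file.
#' @return A list of class `run_report` with the graph, all stage results and
#'   a `summary` list (also written as `summary.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  started_fresh <- !dir.exists(out_dir)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (started_fresh) unlink(out_dir, recursive = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  set.seed(config$seed)

  genes <- stage("read_inputs", read_gene_table(config$genes))
  edges <- stage("read_inputs", read_string_links(config$edges))
  collection <- stage("read_inputs", read_gmt(config$gene_sets))

  g <- stage("build_graph",
             build_graph(edges, genes, tau = config$tau,
                         channels = config$channels, prior = config$prior))

  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  orphans <- igraph::V(g)$name[comp$membership != big]
  conn <- stage("find_connectors",
                find_connectors(g, orphans, edges, tau = config$tau,
                                L = config$max_depth, mode = config$connector_mode,
                                channels = config$channels, prior = config$prior,
                                max_connectors = config$max_connectors))
  g2 <- stage("annotate_novel", annotate_novel(g, conn))

  topo <- stage("topology_summary",
                topology_summary(g2, h = config$hub_threshold))

  study <- igraph::V(g2)$name
  ora <- stage("hypergeom_ora",
               hypergeom_ora(study, collection, universe = config$universe_size))
  cover <- stage("weighted_set_cover",
                 weighted_set_cover(ora, max_sets = config$max_sets,
                                    coverage_target = config$coverage_target,
                                    fdr_threshold = config$fdr_threshold))
  enr_table <- stage("enrichment_report", enrichment_report(ora, cover))

  pathway_members <- character(0)
  if (!is.null(config$pathway_name)) {
    if (!config$pathway_name %in% names(collection$sets)) {
      stop("pipeline stage 'extract_subnetwork' failed: pathway '",
           config$pathway_name, "' not found in the gene-set collection",
           call. = FALSE)
    }
    pathway_members <- collection$sets[[config$pathway_name]]$members
  }
  sub <- stage("extract_subnetwork",
               extract_subnetwork(g2, literature_tag = config$subnetwork_tag,
                                  pathway_members = pathway_members))
  links <- stage("linking_nodes", linking_nodes(g2, sub))

  summary <- list(
    n_nodes = topo$n_nodes,
    n_edges = topo$n_edges,
    n_novel = sum(igraph::V(g2)$category == "novel_predicted"),
    average_degree = topo$average_degree,
    average_degree_1dp = topo$average_degree_1dp,
    hubs = topo$hub_table,
    n_significant_sets = sum(ora$q < config$fdr_threshold),
    selected_sets = cover$selected,
    subnetwork_seeds = nrow(sub$seeds),
    subnetwork_mediators = length(sub$mediators),
    linking_nodes = as.character(links),
    single_bridge = isTRUE(attr(links, "single_bridge")),
    unresolved_orphans = conn$unresolved,
    config = config[setdiff(names(config), "out_dir")]
  )

  report <- structure(list(graph = g2, topology = topo, connectors = conn,
                           enrichment = ora, cover = cover,
                           enrichment_table = enr_table, subnetwork = sub,
                           linking_nodes = links, summary = summary,
                           config = config),
                      class = "run_report")
  stage("write_results", write_results(report, out_dir))
  report
}

#' @export
print.run_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("Interactome run: %d nodes (%d novel), %d edges, ",
                     "average degree %.1f\n"),
              s$n_nodes, s$n_novel, s$n_edges, s$average_degree_1dp))
  cat(sprintf("hubs: %d; significant gene sets: %d; linking node(s): %s\n",
              nrow(s$hubs), s$n_significant_sets,
              if (length(s$linking_nodes) > 0L)
                paste(s$linking_nodes, collapse = ", ") else "none"))
  invisible(x)
}

#' Write all pipeline result files
#'
#' Writes `nodes.tsv`, `hubs.tsv` (degree descending, lexicographic
#' tie-break), `enrichment.tsv`, `subnetwork.tsv`, `edges.tsv`, a GraphML
#' export of the final graph (`network.graphml`) and `summary.json` into
#' `out_dir`. Output is byte-stable across runs given identical inputs and
#' seed.
#'
#' @param report A `run_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the written file paths, invisibly.
#' @export
write_results <- function(report, out_dir) {
  stopifnot(inherits(report, "run_report"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, mode = 2L) != 0L) {
    stop("output directory is not writable: ", out_dir)
  }
  g <- report$graph
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
    p
  }

  deg <- igraph::degree(g)
  nodes <- data.frame(symbol = igraph::V(g)$name,
                      category = igraph::V(g)$category,
                      flag = igraph::V(g)$flag,
                      degree = as.integer(deg), stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$symbol), , drop = FALSE]

  el <- igraph::as_edgelist(g)
  edges <- data.frame(node_a = pmin(el[, 1L], el[, 2L]),
                      node_b = pmax(el[, 1L], el[, 2L]),
                      weight = igraph::E(g)$weight, stringsAsFactors = FALSE)
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]

  subn <- data.frame(symbol = igraph::V(report$subnetwork$graph)$name,
                     stringsAsFactors = FALSE)
  subn$role <- ifelse(subn$symbol %in% report$subnetwork$seeds$symbol, "seed", "mediator")
  src <- setNames(report$subnetwork$seeds$source, report$subnetwork$seeds$symbol)
  subn$source <- ifelse(subn$role == "seed", src[subn$symbol], "")
  subn$linking <- subn$symbol %in% as.character(report$linking_nodes)
  subn <- subn[order(subn$symbol), , drop = FALSE]

  paths <- c(
    tsv(nodes, "nodes.tsv"),
    tsv(report$topology$hub_table, "hubs.tsv"),
    tsv(report$enrichment_table, "enrichment.tsv"),
    tsv(subn, "subnetwork.tsv"),
    tsv(edges, "edges.tsv")
  )
  gml <- file.path(out_dir, "network.graphml")
  igraph::write_graph(g, gml, format = "graphml")
  js <- file.path(out_dir, "summary.json")
  jsonlite::write_json(report$summary, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(c(paths, gml, js))
}
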