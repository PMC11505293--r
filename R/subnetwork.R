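#' Extract a process-specific subnetwork
#'
#' Builds the subnetwork for one biological process (for example ferroptosis)
#' from a parent interactome. Seed nodes come from two sources: nodes tagged
#' with `literature_tag` in the parent graph's `category` attribute, and
#' members of an over-represented pathway; a node found in both is tagged
#' `both`. If the seeds do not already fall in a single connected component of
#' their induced subgraph, mediating nodes are added: non-seed parent nodes,
#' each adjacent to seeds of at least two different seed components (so every
#' mediator lies on a path of at most two edges between two seed nodes),
#' chosen as a minimal merging set. Small instances are solved exactly by
#' bounded exhaustive search; larger ones fall back to the same greedy rule as
#' the connector search at depth 1.
#'
#' @param parent An `igraph` interaction graph with a `category` vertex
#'   attribute.
#' @param literature_tag Category value identifying literature-tagged seeds;
#'   default `"fpt_associated"`.
#' @param pathway_members Character vector of pathway member symbols.
#' @return A list of class `subnetwork_report` with elements `seeds` (data
#'   frame `symbol`, `source` in literature/pathway/both), `mediators`
#'   (character), `graph` (induced `igraph` on seeds and mediators) and
#'   `connected` (logical: do all seeds share one component after mediation).
#' @export
extract_subnetwork <- function(parent, literature_tag = "fpt_associated",
                               pathway_members = character()) {
  stopifnot(inherits(parent, "igraph"))
  vnames <- igraph::V(parent)$name
  lit <- vnames[igraph::V(parent)$category %in% literature_tag]
  pw <- intersect(toupper(pathway_members), vnames)
  seeds <- sort(union(lit, pw))
  if (length(seeds) == 0L) stop("no subnetwork seed is present in the parent graph")
  source <- ifelse(seeds %in% lit & seeds %in% pw, "both",
                   ifelse(seeds %in% lit, "literature", "pathway"))

  mediators <- select_mediators(parent, seeds)
  nodes <- c(seeds, mediators)
  sub <- igraph::induced_subgraph(parent, nodes)
  comp <- igraph::components(sub)
  seed_comps <- unique(comp$membership[seeds])

  structure(list(
    seeds = data.frame(symbol = seeds, source = source, stringsAsFactors = FALSE),
    mediators = mediators,
    graph = sub,
    connected = length(seed_comps) == 1L
  ), class = "subnetwork_report")
}

# Minimal set of non-seed parent nodes merging the seed components of the
# induced subgraph into one, restricted to nodes adjacent to >= 2 seeds
# (depth-1 mediation). Exact search on small candidate pools, greedy
# otherwise; both deterministic.
select_mediators <- function(parent, seeds, size_bound = 5L, pool_limit = 16L) {
  seed_sub <- igraph::induced_subgraph(parent, seeds)
  comp <- igraph::components(seed_sub)
  if (comp$no <= 1L) return(character(0))
  comp_of <- setNames(comp$membership[seeds], seeds)

  vnames <- igraph::V(parent)$name
  nonseed <- setdiff(vnames, seeds)
  # candidates must touch seeds from at least two different seed components
  touched <- lapply(nonseed, function(u) {
    nb <- igraph::V(parent)$name[igraph::neighbors(parent, u)]
    unique(comp_of[intersect(nb, seeds)])
  })
  names(touched) <- nonseed
  pool <- sort(nonseed[vapply(touched, length, integer(1L)) >= 2L])
  if (length(pool) == 0L) return(character(0))

  n_seed_comps <- function(subset) {
    s <- igraph::induced_subgraph(parent, c(seeds, subset))
    cm <- igraph::components(s)$membership
    length(unique(cm[seeds]))
  }

  greedy <- greedy_mediators(parent, seeds, pool, n_seed_comps)
  if (length(pool) <= pool_limit && length(greedy) > 1L) {
    # look for a strictly smaller exact solution reaching the same (or fewer)
    # number of seed components
    target <- n_seed_comps(greedy)
    for (size in seq_len(min(size_bound, length(greedy) - 1L))) {
      subs <- combn(pool, size, simplify = FALSE)
      feas <- subs[vapply(subs, function(s) n_seed_comps(s) <= target, logical(1L))]
      if (length(feas) > 0L) {
        keytxt <- vapply(feas, function(s) paste(sort(s), collapse = ","), "")
        return(sort(feas[[order(keytxt)[[1L]]]]))
      }
    }
  }
  greedy
}

# Greedy mediator accumulation: repeatedly add the candidate that reduces the
# number of seed-containing components the most (ties: higher summed edge
# weight to the subnetwork, then name).
greedy_mediators <- function(parent, seeds, pool, n_seed_comps) {
  picked <- character(0)
  cur <- n_seed_comps(picked)
  w <- igraph::strength(parent)
  repeat {
    if (cur <= 1L) break
    rest <- setdiff(pool, picked)
    if (length(rest) == 0L) break
    reduction <- vapply(rest, function(u) cur - n_seed_comps(c(picked, u)), numeric(1L))
    if (max(reduction) <= 0) break
    best <- rest[order(-reduction, -w[rest], rest)][[1L]]
    picked <- sort(c(picked, best))
    cur <- n_seed_comps(picked)
  }
  picked
}

#' @export
print.subnetwork_report <- function(x, ...) {
  cat(sprintf("Subnetwork: %d seed(s), %d mediator(s), %d edge(s)%s\n",
              nrow(x$seeds), length(x$mediators), igraph::ecount(x$graph),
              if (x$connected) "" else " [seeds not fully connected]"))
  invisible(x)
}

#' Linking (bridge) nodes of a subnetwork
#'
#' Returns the subnetwork-side endpoints of all edges crossing from the
#' subnetwork to the rest of the parent graph: the nodes through which every
#' path from the subnetwork to the remaining network passes. Removing all
#' returned nodes disconnects the remaining subnetwork nodes from the rest of
#' the parent graph. When the boundary collapses to a single node -- the
#' pattern of one molecule bridging a process subnetwork to the rest of the
#' interactome -- the result carries the attribute `single_bridge = TRUE`.
#'
#' @param parent The parent `igraph`.
#' @param sub A `subnetwork_report` extracted from `parent`.
#' @return Sorted character vector of linking node names (possibly with
#'   attribute `single_bridge`); empty, with a logged notice, when the
#'   subnetwork spans the whole parent graph.
#' @export
linking_nodes <- function(parent, sub) {
  stopifnot(inherits(parent, "igraph"), inherits(sub, "subnetwork_report"))
  inside <- igraph::V(sub$graph)$name
  outside <- setdiff(igraph::V(parent)$name, inside)
  if (length(outside) == 0L) {
    message("subnetwork spans the whole parent graph; no linking nodes")
    return(character(0))
  }
  el <- igraph::as_edgelist(parent)
  cross_a <- el[, 1L] %in% inside & el[, 2L] %in% outside
  cross_b <- el[, 2L] %in% inside & el[, 1L] %in% outside
  bridges <- sort(unique(c(el[cross_a, 1L], el[cross_b, 2L])))
  if (length(bridges) == 1L) attr(bridges, "single_bridge") <- TRUE
  bridges
}
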