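# Independent brute-force oracles and instance generators for the property
# tests. These deliberately avoid the package's own code paths.

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# C(N, n) draws: fraction of draws with at least k marked elements.
enum_hyper_upper <- function(N, K, n, k) {
  draws <- combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2L, function(d) sum(d %in% marked) >= k)
  mean(hits)
}

# Articulation points by removal: nodes of the largest component whose
# deletion increases the component count of that component.
brute_articulation <- function(g) {
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  out <- character(0)
  for (v in igraph::V(sub)$name) {
    reduced <- igraph::delete_vertices(sub, v)
    if (igraph::vcount(reduced) > 0L &&
        igraph::components(reduced)$no > 1L) {
      out <- c(out, v)
    }
  }
  sort(out)
}

# Simple adjacency lookup built straight from an edge data frame.
oracle_adj <- function(edges) {
  adj <- list()
  for (i in seq_len(nrow(edges))) {
    a <- edges$node_a[[i]]; b <- edges$node_b[[i]]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  adj
}

# TRUE when orphan o reaches the core using at most `depth` intermediates,
# every intermediate drawn from `via`.
oracle_reaches <- function(o, core, via, adj, depth) {
  nb <- adj[[o]]
  if (is.null(nb)) return(FALSE)
  if (any(nb %in% core)) return(TRUE)
  if (depth >= 1L) {
    for (x in intersect(nb, via)) {
      if (any(adj[[x]] %in% core)) return(TRUE)
      if (depth >= 2L) {
        for (y in setdiff(intersect(adj[[x]], via), x)) {
          if (any(adj[[y]] %in% core)) return(TRUE)
        }
      }
    }
  }
  FALSE
}

# Minimum-cardinality connector set by exhaustive subset enumeration.
# Returns list(size, connected) where `connected` is the orphan set joined by
# an optimal solution (orphans unreachable under any subset are excluded).
brute_min_connectors <- function(core, orphans, edges, candidates, depth) {
  adj <- oracle_adj(edges)
  reachable <- orphans[vapply(orphans, oracle_reaches, logical(1L),
                              core = core, via = candidates, adj = adj,
                              depth = depth)]
  if (length(reachable) == 0L) return(list(size = 0L, connected = character(0)))
  for (size in 0:length(candidates)) {
    subs <- if (size == 0L) list(character(0)) else combn(candidates, size, simplify = FALSE)
    for (s in subs) {
      ok <- all(vapply(reachable, oracle_reaches, logical(1L),
                       core = core, via = s, adj = adj, depth = depth))
      if (ok) return(list(size = size, connected = reachable))
    }
  }
  list(size = length(candidates), connected = reachable)
}

# Random connector instance: a small core, orphans wired to a candidate pool,
# as an edge table with unit-scale scores above threshold.
random_connector_instance <- function(n_core = 4L, n_orphans, n_candidates,
                                      p_oc = 0.4, p_cc = 0.6) {
  core <- sprintf("C%02d", seq_len(n_core))
  orphans <- sprintf("O%02d", seq_len(n_orphans))
  cand <- sprintf("X%02d", seq_len(n_candidates))
  edges <- data.frame(node_a = character(0), node_b = character(0))
  add <- function(e, a, b) rbind(e, data.frame(node_a = a, node_b = b))
  # connected core (path)
  for (i in seq_len(n_core - 1L)) edges <- add(edges, core[[i]], core[[i + 1L]])
  for (o in orphans) {
    for (x in cand) if (runif(1) < p_oc) edges <- add(edges, o, x)
  }
  for (x in cand) {
    if (runif(1) < p_cc) edges <- add(edges, x, sample(core, 1L))
  }
  # occasional candidate-candidate links enabling depth-2 chains
  if (n_candidates >= 2L) {
    prs <- combn(cand, 2L, simplify = FALSE)
    for (pr in prs) if (runif(1) < 0.15) edges <- add(edges, pr[[1L]], pr[[2L]])
  }
  edges$experiments <- 0.95
  edges$combined_score <- 0.95
  list(core = core, orphans = orphans, candidates = cand, edges = edges)
}

# Small random labelled graph for articulation / handshake properties.
random_small_graph <- function(n, p = 0.3) {
  nodes <- sprintf("V%02d", seq_len(n))
  prs <- combn(nodes, 2L, simplify = FALSE)
  keep <- prs[runif(length(prs)) < p]
  el <- if (length(keep) > 0L) do.call(rbind, keep) else matrix(character(0), ncol = 2L)
  g <- igraph::graph_from_data_frame(as.data.frame(el), directed = FALSE,
                                     vertices = data.frame(name = nodes))
  g
}

# Core graph plus edge table for build_graph-style tests.
toy_gene_table <- function(symbols, category = "pcos_curated") {
  df <- data.frame(symbol = symbols, category = category, name = "",
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_table", "data.frame")
  df
}

toy_edges <- function(a, b, score, channel = "experiments") {
  df <- data.frame(node_a = pmin(a, b), node_b = pmax(a, b),
                   stringsAsFactors = FALSE)
  df[[channel]] <- score
  df$combined_score <- score
  class(df) <- c("edge_table", "data.frame")
  df
}

# Parent graph with a subnetwork attached to the rest through exactly one
# designed bottleneck node; returns the graph and the planted bridge.
make_bottleneck_graph <- function(n_sub = 6L, n_out = 7L) {
  sub_nodes <- sprintf("F%02d", seq_len(n_sub))
  out_nodes <- sprintf("P%02d", seq_len(n_out))
  bridge <- sample(sub_nodes, 1L)
  el <- rbind(t(combn(sub_nodes, 2L)), t(combn(out_nodes, 2L)),
              cbind(bridge, sample(out_nodes, 2L)))
  vdf <- data.frame(name = c(sub_nodes, out_nodes),
                    category = rep(c("fpt_associated", "pcos_curated"),
                                   c(n_sub, n_out)),
                    flag = "seed", stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(as.data.frame(el), directed = FALSE,
                                     vertices = vdf)
  igraph::E(g)$weight <- 0.9
  list(graph = igraph::simplify(g, edge.attr.comb = "max"), bridge = bridge,
       sub_nodes = sub_nodes)
}
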