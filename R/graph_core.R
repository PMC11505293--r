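#' Recombine evidence-channel scores into a combined interaction score
#'
#' STRING-style noisy-OR integration of per-channel evidence scores after
#' subtracting the random-expectation prior `p`. Each channel score `s > p`
#' is first corrected to `s* = (s - p) / (1 - p)`; scores at or below the
#' prior contribute nothing (`s* = 0`, never negative evidence). The combined
#' score is then
#' \deqn{S = 1 - (1 - p) \prod_i (1 - s_i^*)}
#' so that a single channel above the prior is returned unchanged
#' (`S = s`, algebraically exact) and adding channels never decreases `S`.
#' When no channel exceeds the prior the function returns 0: there is no
#' evidence beyond random expectation.
#'
#' Restricting the recombination to a subset of channels (for example
#' experiments, curated databases and text mining only) is how a combined
#' score over selected evidence types is obtained from a detailed
#' per-channel table.
#'
#' @param channel_scores Numeric vector of per-channel scores in \[0, 1\].
#' @param prior Random-expectation prior probability in \[0, 1);
#'   default 0.041, STRING's documented prior.
#' @return A single combined score in \[0, 1\].
#' @export
#' @examples
#' recombine_combined_score(c(experiments = 0.62), prior = 0.041)  # 0.62
#' recombine_combined_score(c(0.9, 0.9))                           # ~0.9896
recombine_combined_score <- function(channel_scores, prior = 0.041) {
  channel_scores <- as.numeric(channel_scores)
  if (length(channel_scores) == 0L) return(0)
  if (anyNA(channel_scores) || any(channel_scores < 0 | channel_scores > 1)) {
    stop("channel scores must lie in [0, 1]")
  }
  if (is.na(prior) || prior < 0 || prior >= 1) stop("prior must lie in [0, 1)")
  if (all(channel_scores <= prior)) return(0)
  s_star <- pmax(0, (channel_scores - prior) / (1 - prior))
  1 - (1 - prior) * prod(1 - s_star)
}

# Vectorized recombination over the rows of an edge table. Returns the
# combined score for each row using the channel columns named in `channels`
# that are present; rows are scored with the edge's own combined_score when
# the table carries no channel columns at all.
score_edges <- function(edges, channels, prior) {
  stopifnot(is.data.frame(edges))
  chan_cols <- intersect(channels, names(edges))
  if (length(chan_cols) == 0L) {
    if (!"combined_score" %in% names(edges)) {
      stop("edge table has neither the selected channel columns nor combined_score")
    }
    message("edge table lacks channel columns; using combined_score as-is")
    return(edges$combined_score)
  }
  m <- as.matrix(edges[chan_cols])
  if (anyNA(m) || any(m < 0 | m > 1)) stop("channel scores must lie in [0, 1]")
  s_star <- pmax((m - prior) / (1 - prior), 0)  # pmax keeps dim of 1st arg
  s <- 1 - (1 - prior) * apply(1 - s_star, 1L, prod)
  # no channel above the prior -> no evidence
  s[rowSums(m > prior) == 0L] <- 0
  s
}

#' Build the thresholded interaction graph
#'
#' Recombines evidence-channel scores over the selected channels (see
#' [recombine_combined_score()]), keeps an edge when both endpoints belong to
#' the seed set (or to `extra_nodes`, e.g. previously accepted connectors) and
#' the combined score exceeds the high-confidence threshold `tau` (strictly:
#' an edge at exactly `tau` is excluded), and assembles an undirected simple
#' graph. Seed genes without any retained edge are kept as isolated nodes.
#'
#' When the edge table has no per-channel columns its `combined_score` is used
#' as-is, with a logged notice.
#'
#' @param edges An `edge_table` (see [read_string_links()]).
#' @param seeds A `gene_table` (see [read_gene_table()]).
#' @param tau High-confidence score threshold in (0, 1\]; default 0.7.
#' @param channels Evidence channels to recombine over; default experiments,
#'   curated databases and text mining.
#' @param prior Random-expectation prior; default 0.041.
#' @param extra_nodes Additional allowed node symbols outside the seed table.
#' @return An `igraph` object with vertex attributes `category` and `flag`
#'   (`"seed"` or `"connector"`), edge attribute `weight` (the combined score),
#'   and graph attribute `tau`.
#' @export
build_graph <- function(edges, seeds, tau = 0.7,
                        channels = c("experiments", "database", "textmining"),
                        prior = 0.041, extra_nodes = character()) {
  stopifnot(is.data.frame(edges), is.data.frame(seeds))
  if (nrow(seeds) == 0L) stop("seed gene table is empty")
  if (is.na(tau) || tau <= 0 || tau > 1) stop("tau must lie in (0, 1]")
  channels <- match.arg(channels, CHANNELS, several.ok = TRUE)

  seed_syms <- toupper(seeds$symbol)
  extra_nodes <- toupper(extra_nodes)
  allowed <- union(seed_syms, extra_nodes)

  if (nrow(edges) > 0L) {
    s <- score_edges(edges, channels, prior)
    keep <- s > tau & edges$node_a %in% allowed & edges$node_b %in% allowed &
      edges$node_a != edges$node_b
    kept <- data.frame(from = edges$node_a[keep], to = edges$node_b[keep],
                       weight = s[keep], stringsAsFactors = FALSE)
  } else {
    kept <- data.frame(from = character(0), to = character(0), weight = numeric(0))
  }

  used_extra <- intersect(extra_nodes, unique(c(kept$from, kept$to)))
  vdf <- data.frame(
    name = c(seed_syms, used_extra),
    category = c(seeds$category, rep("novel_predicted", length(used_extra))),
    flag = c(rep("seed", length(seed_syms)), rep("connector", length(used_extra))),
    stringsAsFactors = FALSE)
  vdf <- vdf[order(vdf$name), , drop = FALSE]

  g <- igraph::graph_from_data_frame(kept, directed = FALSE, vertices = vdf)
  g <- igraph::set_graph_attr(g, "tau", tau)
  g
}

#' Topology summary of an interaction graph
#'
#' Reports the node and edge counts, the average node degree
#' (`2 |E| / |N|`, both full precision and rounded to one decimal), the exact
#' degree of every node, and the hub table: nodes with degree at or above the
#' hub threshold `h`, sorted by degree descending with lexicographic
#' tie-break. A `top_k` mode is provided as an alternative hub definition.
#'
#' @param g An `igraph` interaction graph.
#' @param h Hub degree threshold (inclusive); default 20.
#' @param top_k If non-`NULL`, take the `top_k` highest-degree nodes as hubs
#'   instead of applying `h`.
#' @return A list of class `topology_summary` with elements `n_nodes`,
#'   `n_edges`, `average_degree`, `average_degree_1dp`, `degree` (named
#'   integer vector) and `hub_table` (data frame `node`, `degree`).
#' @export
topology_summary <- function(g, h = 20L, top_k = NULL) {
  stopifnot(inherits(g, "igraph"))
  if (igraph::vcount(g) == 0L) stop("graph has no nodes")
  deg <- igraph::degree(g)
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  ord <- order(-deg, names(deg))
  hubs <- if (is.null(top_k)) {
    ord[deg[ord] >= h]
  } else {
    head(ord, top_k)
  }
  structure(list(
    n_nodes = n,
    n_edges = m,
    average_degree = 2 * m / n,
    average_degree_1dp = round(2 * m / n, 1L),
    degree = deg,
    hub_table = data.frame(node = names(deg)[hubs],
                           degree = as.integer(deg[hubs]),
                           stringsAsFactors = FALSE, row.names = NULL)
  ), class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf("Interaction graph: %d nodes, %d edges, average degree %.1f\n",
              x$n_nodes, x$n_edges, x$average_degree_1dp))
  if (nrow(x$hub_table) > 0L) {
    cat(sprintf("%d hub(s):\n", nrow(x$hub_table)))
    print(x$hub_table, row.names = FALSE)
  } else {
    cat("no hubs at the chosen threshold\n")
  }
  invisible(x)
}

#' Articulation nodes of the largest component
#'
#' Nodes of the largest connected component whose removal increases the
#' number of connected components (cut vertices). These are the graph-level
#' bottlenecks through which separate regions of the interactome communicate.
#'
#' @param g An `igraph` interaction graph.
#' @return Sorted character vector of node names.
#' @export
articulation_nodes <- function(g) {
  stopifnot(inherits(g, "igraph"))
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  sort(igraph::V(sub)$name[igraph::articulation_points(sub)])
}
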