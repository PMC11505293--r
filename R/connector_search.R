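# Adjacency list (named list of sorted character vectors) from an edge data
# frame with columns node_a / node_b.
edge_adjacency <- function(a, b) {
  nbr <- split(c(b, a), c(a, b))
  lapply(nbr, function(x) sort(unique(x)))
}

# TRUE when orphan `o` reaches any node of `core_set` using at most `depth`
# intermediate nodes, all of which must belong to `via`.
orphan_reaches <- function(o, core_set, via, adj, depth) {
  nb <- adj[[o]]
  if (is.null(nb)) return(FALSE)
  if (any(nb %in% core_set)) return(TRUE)
  if (depth < 1L) return(FALSE)
  x1 <- intersect(nb, via)
  for (x in x1) {
    nbx <- adj[[x]]
    if (any(nbx %in% core_set)) return(TRUE)
    if (depth >= 2L) {
      x2 <- intersect(nbx, via)
      for (y in setdiff(x2, x)) {
        if (any(adj[[y]] %in% core_set)) return(TRUE)
      }
    }
  }
  FALSE
}

# Connection options for one orphan at the given depth: a list of candidate
# node sets (size 1 or 2) each of which, added to the core, connects the
# orphan. Candidates are background nodes outside core_set and orphan_set.
orphan_options <- function(o, core_set, orphan_set, adj, depth) {
  opts <- list()
  nb <- adj[[o]]
  if (is.null(nb)) return(opts)
  cand1 <- setdiff(nb, c(core_set, orphan_set))
  for (x in cand1) {
    nbx <- adj[[x]]
    if (any(nbx %in% core_set)) {
      opts[[length(opts) + 1L]] <- x
    } else if (depth >= 2L) {
      ys <- setdiff(nbx, c(core_set, orphan_set, x, o))
      for (y in ys) {
        if (any(adj[[y]] %in% core_set)) opts[[length(opts) + 1L]] <- sort(c(x, y))
      }
    }
  }
  unique(opts)
}

# Sum of edge weights incident to `nodes`, restricted to edges whose other
# endpoint lies in `scope` (deterministic tie-break for equal-size solutions).
incident_score <- function(nodes, scope, edges) {
  sel <- (edges$node_a %in% nodes & edges$node_b %in% scope) |
         (edges$node_b %in% nodes & edges$node_a %in% scope)
  sum(edges$score[sel])
}

# Exact minimum-cardinality hitting set over per-orphan option lists.
# Returns NULL when no subset of size <= size_bound covers every orphan.
exact_cover <- function(options_by_orphan, pool, size_bound, edges, scope) {
  covers <- function(subset) {
    all(vapply(options_by_orphan, function(opts) {
      any(vapply(opts, function(o) all(o %in% subset), logical(1L)))
    }, logical(1L)))
  }
  if (covers(character(0))) return(character(0))
  for (size in seq_len(min(size_bound, length(pool)))) {
    subs <- combn(pool, size, simplify = FALSE)
    ok <- subs[vapply(subs, covers, logical(1L))]
    if (length(ok) > 0L) {
      score <- vapply(ok, incident_score, numeric(1L), scope = scope, edges = edges)
      keytxt <- vapply(ok, function(s) paste(sort(s), collapse = ","), "")
      best <- order(-score, keytxt)[[1L]]
      return(sort(ok[[best]]))
    }
  }
  NULL
}

#' Predict minimal novel connectors for orphan seed genes
#'
#' Finds a small set of background nodes that joins "orphan" seed genes (seed
#' genes not connected to the core network) to the largest connected component
#' of the core graph, mirroring an iterative search for the minimum number of
#' nodes interacting with the existing nodes. The problem is formalized as a
#' restricted Steiner-node search: each connected orphan must obtain a path to
#' the core of at most `L` intermediate nodes, all intermediates drawn from the
#' predicted connector set, using only background edges whose recombined score
#' exceeds `tau`.
#'
#' The search is iterative: depth 1 first, then depth 2 for orphans still
#' unresolved (connectors accepted at depth 1 count as core in the second
#' pass); deeper searches are refused. In `exact` mode the instance is
#' decomposed into independent orphan groups and each group is solved by
#' exhaustive search over candidate subsets of increasing size up to
#' `max_connectors` (falling back to the greedy rule when a group is too large
#' or infeasible within the bound). In `greedy` mode the candidate background
#' node adjacent to the current core that joins the most still-unconnected
#' orphans is added repeatedly (ties: higher summed edge score, then
#' lexicographic name order). Both modes are deterministic.
#'
#' @param core An `igraph` core interaction graph (its largest connected
#'   component is the attachment target).
#' @param orphans Character vector of orphan seed symbols, disjoint from the
#'   core's largest component.
#' @param background An `edge_table` of background interactions (scored and
#'   thresholded with the same rules as [build_graph()]).
#' @param tau Score threshold; default 0.7.
#' @param L Maximum number of intermediate nodes per orphan path (1 or 2);
#'   default 2, explored progressively starting at depth 1.
#' @param mode `"exact"` (bounded minimum-cardinality search) or `"greedy"`.
#' @param channels,prior Evidence-channel selection and prior, as in
#'   [build_graph()].
#' @param max_connectors Exhaustive-search bound on the connector subset size
#'   per orphan group in exact mode; default 5.
#' @return A list of class `connector_result` with elements `connectors`
#'   (sorted character vector), `attachment` (named list: orphan -> path of
#'   node names ending in a core node), `unresolved` (orphans that could not
#'   be connected), and `edges` (qualifying above-threshold edges incident to
#'   the connectors, for [annotate_novel()]).
#' @export
find_connectors <- function(core, orphans, background, tau = 0.7, L = 2L,
                            mode = c("exact", "greedy"),
                            channels = c("experiments", "database", "textmining"),
                            prior = 0.041, max_connectors = 5L) {
  mode <- match.arg(mode)
  stopifnot(inherits(core, "igraph"))
  if (!L %in% 1:2) stop("L must be 1 or 2; deeper connector searches are refused")
  orphans <- sort(unique(toupper(orphans)))

  comp <- igraph::components(core)
  big <- which.max(comp$csize)
  core_set <- igraph::V(core)$name[comp$membership == big]
  if (any(orphans %in% core_set)) {
    stop("orphans must be disjoint from the core's largest component: ",
         paste(intersect(orphans, core_set), collapse = ", "))
  }

  if (nrow(background) > 0L) {
    s <- score_edges(background, channels, prior)
    keep <- s > tau & background$node_a != background$node_b
    edges <- data.frame(node_a = background$node_a[keep],
                        node_b = background$node_b[keep],
                        score = s[keep], stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(node_a = character(0), node_b = character(0),
                        score = numeric(0))
  }
  adj <- edge_adjacency(edges$node_a, edges$node_b)

  chosen <- character(0)
  attachment <- list()
  unresolved <- orphans

  # orphans with a direct above-threshold edge to the core need no connector
  for (o in unresolved) {
    direct <- intersect(if (is.null(adj[[o]])) character(0) else adj[[o]], core_set)
    if (length(direct) > 0L) attachment[[o]] <- c(o, sort(direct)[[1L]])
  }
  unresolved <- setdiff(unresolved, names(attachment))

  for (depth in seq_len(L)) {
    if (length(unresolved) == 0L) break
    cur_core <- c(core_set, chosen)
    opts <- lapply(unresolved, orphan_options, core_set = cur_core,
                   orphan_set = orphans, adj = adj, depth = depth)
    names(opts) <- unresolved
    solvable <- unresolved[vapply(opts, length, integer(1L)) > 0L]
    if (length(solvable) == 0L) next
    opts <- opts[solvable]

    picked <- if (mode == "exact") {
      solve_exact_phase(opts, adj, edges, cur_core, orphans, max_connectors)
    } else {
      solve_greedy_phase(opts, adj, edges, cur_core, orphans, depth)
    }
    chosen <- sort(unique(c(chosen, picked)))

    for (o in solvable) {
      if (orphan_reaches(o, c(core_set, chosen), chosen, adj, depth)) {
        attachment[[o]] <- connector_path(o, core_set, chosen, adj, depth)
      }
    }
    unresolved <- setdiff(orphans, names(attachment))
  }

  scope <- union(igraph::V(core)$name, c(orphans, chosen))
  qual <- edges[(edges$node_a %in% chosen | edges$node_b %in% chosen) &
                edges$node_a %in% scope & edges$node_b %in% scope, , drop = FALSE]
  rownames(qual) <- NULL

  structure(list(connectors = chosen,
                 attachment = attachment[sort(names(attachment))],
                 unresolved = unresolved,
                 edges = qual, mode = mode, L = L, tau = tau),
            class = "connector_result")
}

# Exact phase: decompose orphans into groups sharing candidate nodes and run
# the bounded exhaustive search per group; greedy fallback for oversized or
# infeasible groups.
solve_exact_phase <- function(opts, adj, edges, cur_core, orphans, max_connectors,
                              pool_limit = 18L) {
  onames <- names(opts)
  node_sets <- lapply(opts, function(x) sort(unique(unlist(x))))
  # union-find over orphans via shared candidate nodes
  parent <- seq_along(onames)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  node_owner <- new.env(parent = emptyenv())
  for (i in seq_along(onames)) {
    for (nd in node_sets[[i]]) {
      j <- mget(nd, envir = node_owner, ifnotfound = list(NULL))[[1L]]
      if (is.null(j)) assign(nd, i, envir = node_owner)
      else { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <- rj }
    }
  }
  groups <- split(seq_along(onames), vapply(seq_along(onames), find, integer(1L)))

  picked <- character(0)
  for (grp in groups) {
    gopts <- opts[grp]
    pool <- sort(unique(unlist(node_sets[grp])))
    scope <- c(cur_core, orphans, pool)
    sol <- NULL
    if (length(pool) <= pool_limit) {
      sol <- exact_cover(gopts, pool, max_connectors, edges, scope)
    }
    if (is.null(sol)) {
      sol <- greedy_cover(gopts, edges, scope)
    }
    picked <- c(picked, sol)
  }
  sort(unique(picked))
}

# Greedy phase driver. Candidates adjacent to the current core with positive
# orphan gain are preferred; when depth 2 allows chains, a zero-gain candidate
# that appears in some remaining option may be added to make progress.
solve_greedy_phase <- function(opts, adj, edges, cur_core, orphans, depth) {
  pool <- sort(unique(unlist(opts)))
  scope <- c(cur_core, orphans, pool)
  greedy_cover(opts, edges, scope)
}

# Greedy hitting-set over per-orphan option lists; deterministic tie-breaks:
# most newly connected orphans, then higher incident edge score, then name.
greedy_cover <- function(opts, edges, scope) {
  picked <- character(0)
  remaining <- opts
  repeat {
    if (length(remaining) == 0L) break
    pool <- setdiff(sort(unique(unlist(remaining))), picked)
    if (length(pool) == 0L) break
    gain <- vapply(pool, function(u) {
      sum(vapply(remaining, function(o) {
        any(vapply(o, function(s) all(s %in% c(picked, u)), logical(1L)))
      }, logical(1L)))
    }, numeric(1L))
    if (max(gain) == 0) {
      # progress move for two-node options: pick the candidate appearing in
      # the most remaining options
      seen <- vapply(pool, function(u) {
        sum(vapply(remaining, function(o) {
          any(vapply(o, function(s) u %in% s, logical(1L)))
        }, logical(1L)))
      }, numeric(1L))
      if (max(seen) == 0) break
      score <- vapply(pool, function(u) incident_score(u, scope, edges), numeric(1L))
      best <- pool[order(-seen, -score, pool)][[1L]]
    } else {
      score <- vapply(pool, function(u) incident_score(u, scope, edges), numeric(1L))
      best <- pool[order(-gain, -score, pool)][[1L]]
    }
    picked <- c(picked, best)
    done <- vapply(remaining, function(o) {
      any(vapply(o, function(s) all(s %in% picked), logical(1L)))
    }, logical(1L))
    remaining <- remaining[!done]
  }
  sort(picked)
}

# Shortest attachment path from a connected orphan to the core, allowing only
# chosen connectors as intermediates; deterministic by lexicographic BFS.
connector_path <- function(o, core_set, chosen, adj, depth) {
  prev <- list()
  prev[[o]] <- NA_character_
  frontier <- o
  for (step in seq_len(depth + 2L)) {
    nxt <- character(0)
    for (u in frontier) {
      for (v in sort(adj[[u]])) {
        if (!is.null(prev[[v]])) next
        prev[[v]] <- u
        if (v %in% core_set) {
          path <- v
          while (!is.na(prev[[path[[1L]]]])) path <- c(prev[[path[[1L]]]], path)
          return(path)
        }
        if (v %in% chosen) nxt <- c(nxt, v)
      }
    }
    frontier <- nxt
    if (length(frontier) == 0L) break
  }
  NULL
}

#' @export
print.connector_result <- function(x, ...) {
  cat(sprintf("Connector search (%s mode, L = %d): %d connector(s), %d orphan(s) attached, %d unresolved\n",
              x$mode, x$L, length(x$connectors), length(x$attachment),
              length(x$unresolved)))
  if (length(x$connectors) > 0L) cat("connectors:", paste(x$connectors, collapse = ", "), "\n")
  invisible(x)
}

#' Merge predicted connectors into the interaction graph
#'
#' Adds the connectors found by [find_connectors()] to the graph as
#' `novel_predicted` nodes together with their qualifying above-threshold
#' edges. The node count grows by exactly the number of connectors.
#'
#' @param g The `igraph` interaction graph the search was run against.
#' @param result A `connector_result`.
#' @return The augmented `igraph`.
#' @export
annotate_novel <- function(g, result) {
  stopifnot(inherits(g, "igraph"), inherits(result, "connector_result"))
  if (length(result$connectors) == 0L) return(g)
  present <- intersect(result$connectors, igraph::V(g)$name)
  if (length(present) > 0L) {
    stop("connector already present in the graph: ", paste(present, collapse = ", "))
  }
  g2 <- igraph::add_vertices(g, length(result$connectors),
                             name = result$connectors,
                             category = "novel_predicted",
                             flag = "connector")
  e <- result$edges
  if (nrow(e) > 0L) {
    ord <- order(e$node_a, e$node_b)
    e <- e[ord, , drop = FALSE]
    g2 <- igraph::add_edges(g2, rbind(e$node_a, e$node_b), weight = e$score)
  }
  igraph::simplify(g2, edge.attr.comb = "max")
}
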