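core_graph <- function(nodes, edges) {
  build_graph(edges, toy_gene_table(nodes))
}

test_that("a unique single-node solution is found", {
  core <- core_graph(c("A", "B"), toy_edges("A", "B", 0.9))
  bg <- toy_edges(c("O", "X"), c("X", "A"), 0.9)
  res <- find_connectors(core, "O", bg)
  expect_equal(res$connectors, "X")
  expect_equal(res$attachment$O, c("O", "X", "A"))
  expect_equal(res$unresolved, character(0))
})

test_that("a shared connector beats two private ones (exhaustive oracle agrees)", {
  core <- core_graph(c("A", "B"), toy_edges("A", "B", 0.9))
  bg <- toy_edges(c("O1", "O2", "O1", "O2", "X", "Y1", "Y2"),
                  c("X", "X", "Y1", "Y2", "A", "A", "A"), 0.9)
  res <- find_connectors(core, c("O1", "O2"), bg, mode = "exact")
  expect_equal(res$connectors, "X")
  oracle <- brute_min_connectors(c("A", "B"), c("O1", "O2"), bg,
                                 c("X", "Y1", "Y2"), depth = 1L)
  expect_equal(length(res$connectors), oracle$size)
})

test_that("unreachable orphans are reported unresolved without error", {
  core <- core_graph(c("A", "B"), toy_edges("A", "B", 0.9))
  bg <- toy_edges(c("O", "X", "Y"), c("X", "Y", "Z"), 0.9)  # chain never reaches core
  res <- find_connectors(core, "O", bg, L = 2L)
  expect_equal(res$unresolved, "O")
  expect_equal(res$connectors, character(0))
  # empty background: everything unresolved, no error
  res0 <- find_connectors(core, "O", bg[0, ])
  expect_equal(res0$unresolved, "O")
})

test_that("depth escalates only for orphans unreachable at one intermediate", {
  core <- core_graph(c("A", "B"), toy_edges("A", "B", 0.9))
  # O1 solvable with one intermediate; O2 needs the chain X2-Y2
  bg <- toy_edges(c("O1", "X1", "O2", "X2", "Y2"),
                  c("X1", "A", "X2", "Y2", "B"), 0.9)
  res1 <- find_connectors(core, c("O1", "O2"), bg, L = 1L)
  expect_equal(res1$connectors, "X1")
  expect_equal(res1$unresolved, "O2")
  res2 <- find_connectors(core, c("O1", "O2"), bg, L = 2L)
  expect_equal(res2$connectors, c("X1", "X2", "Y2"))
  expect_equal(res2$unresolved, character(0))
  expect_equal(res2$attachment$O2, c("O2", "X2", "Y2", "B"))
  expect_error(find_connectors(core, "O1", bg, L = 3L), "refused")
})

test_that("exact mode matches the brute-force minimum on random instances", {
  withr::local_seed(103L)
  for (i in 1:60) {
    inst <- random_connector_instance(n_orphans = sample(2:8, 1L),
                                      n_candidates = sample(3:12, 1L))
    core <- core_graph(inst$core, inst$edges[inst$edges$node_a %in% inst$core &
                                             inst$edges$node_b %in% inst$core, ])
    res <- find_connectors(core, inst$orphans, inst$edges, L = 1L,
                           mode = "exact", max_connectors = 8L)
    oracle <- brute_min_connectors(inst$core, inst$orphans, inst$edges,
                                   inst$candidates, depth = 1L)
    expect_equal(length(res$connectors), oracle$size)
    expect_identical(sort(as.character(names(res$attachment))),
                     sort(oracle$connected))
  }
})

test_that("greedy solutions are valid, deterministic and never beat exact", {
  withr::local_seed(211L)
  for (i in 1:25) {
    inst <- random_connector_instance(n_orphans = sample(2:6, 1L),
                                      n_candidates = sample(3:10, 1L))
    core <- core_graph(inst$core, inst$edges[inst$edges$node_a %in% inst$core &
                                             inst$edges$node_b %in% inst$core, ])
    ex <- find_connectors(core, inst$orphans, inst$edges, L = 1L, mode = "exact",
                          max_connectors = 8L)
    gr <- find_connectors(core, inst$orphans, inst$edges, L = 1L, mode = "greedy")
    gr2 <- find_connectors(core, inst$orphans, inst$edges, L = 1L, mode = "greedy")
    expect_identical(gr$connectors, gr2$connectors)
    expect_gte(length(gr$connectors), length(ex$connectors))
    expect_identical(sort(as.character(names(gr$attachment))),
                     sort(as.character(names(ex$attachment))))
  }
})

test_that("annotate_novel merges connectors with exact node/edge bookkeeping", {
  core <- core_graph(c("A", "B", "C"), toy_edges(c("A", "B"), c("B", "C"), 0.9))
  bg <- toy_edges(c("O", "X", "X", "X"), c("X", "A", "B", "C"), 0.9)
  # orphan O is a declared seed of the graph too
  g <- build_graph(toy_edges(c("A", "B"), c("B", "C"), 0.9),
                   toy_gene_table(c("A", "B", "C", "O")))
  res <- find_connectors(g, "O", bg)
  expect_equal(res$connectors, "X")
  g2 <- annotate_novel(g, res)
  expect_equal(igraph::vcount(g2), igraph::vcount(g) + 1L)
  # X carries 4 qualifying edges: to A, B, C and the orphan O
  expect_equal(igraph::ecount(g2), igraph::ecount(g) + 4L)
  expect_equal(igraph::V(g2)$category[igraph::V(g2)$name == "X"], "novel_predicted")
  expect_error(annotate_novel(g2, res), "already present")
  # empty connector set leaves the graph unchanged
  res0 <- find_connectors(g, character(0), bg)
  expect_identical(igraph::vcount(annotate_novel(g, res0)), igraph::vcount(g))
})

test_that("ground-truth connectors are recovered on uniquely solvable instances", {
  for (sd in c(3L, 17L)) {
    net <- generate_network(synthetic_spec(n_seeds = 30L, n_orphans = 5L,
                                           n_connectors = 5L,
                                           planted_hub_degree = 8L,
                                           n_background = 10L, seed = sd))
    g <- build_graph(net$edges, net$genes)
    comp <- igraph::components(g)
    orphans <- igraph::V(g)$name[comp$membership != which.max(comp$csize)]
    expect_setequal(orphans, net$truth$orphans)
    res <- find_connectors(g, orphans, net$edges, mode = "exact")
    expect_setequal(res$connectors, net$truth$connectors)
    g2 <- annotate_novel(g, res)
    expect_equal(igraph::vcount(g2), 35L)
  }
})
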