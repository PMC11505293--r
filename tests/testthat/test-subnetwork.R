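path_graph <- function() {
  edges <- toy_edges(c("A", "B"), c("B", "C"), 0.9)
  genes <- toy_gene_table(c("A", "B", "C"),
                          category = c("fpt_associated", "pcos_curated",
                                       "fpt_associated"))
  build_graph(edges, genes)
}

test_that("mediators connect split seeds and vanish when seeds already connect", {
  g <- path_graph()
  sub <- extract_subnetwork(g, "fpt_associated")   # seeds {A, C} in path A-B-C
  expect_equal(sub$mediators, "B")
  expect_true(sub$connected)
  expect_equal(sub$seeds$symbol, c("A", "C"))
  expect_equal(sub$seeds$source, c("literature", "literature"))

  sub2 <- extract_subnetwork(g, "fpt_associated", pathway_members = "B")
  expect_equal(sub2$mediators, character(0))      # B is now a seed itself
  expect_equal(sub2$seeds$source[sub2$seeds$symbol == "B"], "pathway")
  expect_error(extract_subnetwork(g, "fpt_associated", pathway_members = "Z")$seeds,
               NA)  # unknown pathway member is simply ignored
  expect_error(extract_subnetwork(build_graph(toy_edges("A", "B", 0.9),
                                              toy_gene_table(c("A", "B"))),
                                  "fpt_associated"), "no subnetwork seed")
})

test_that("seed union of literature tag and pathway members has the expected size", {
  genes <- read_gene_table(pcosnet_example("pcos_gene_table.tsv"))
  coll <- read_gmt(pcosnet_example("pcos_kegg_sets.gmt"))
  fpt_set <- coll$sets$Ferroptosis$members
  lit <- genes$symbol[genes$category == "fpt_associated"]
  # a synthetic parent carrying every fixture gene, fully connected star
  hubsym <- "HUBX"
  edges <- toy_edges(rep(hubsym, nrow(genes)), genes$symbol, 0.9)
  parent <- build_graph(edges, rbind(genes, toy_gene_table(hubsym)))
  sub <- extract_subnetwork(parent, "fpt_associated", pathway_members = fpt_set)
  expect_equal(nrow(sub$seeds), length(union(lit, fpt_set)))
  expect_equal(sum(sub$seeds$source == "both"),
               length(intersect(lit, fpt_set)))
})

test_that("mediator sets are minimal on small instances (brute-force check)", {
  withr::local_seed(87L)
  for (i in 1:15) {
    n_seed <- sample(3:6, 1L)
    n_med <- sample(2:5, 1L)
    seeds <- sprintf("S%d", seq_len(n_seed))
    meds <- sprintf("M%d", seq_len(n_med))
    a <- character(0); b <- character(0)
    for (m in meds) {
      touch <- sample(seeds, sample(2:n_seed, 1L))
      a <- c(a, rep(m, length(touch))); b <- c(b, touch)
    }
    g <- build_graph(toy_edges(a, b, 0.9),
                     toy_gene_table(c(seeds, meds),
                                    category = rep(c("fpt_associated", "pcos_curated"),
                                                   c(n_seed, n_med))))
    sub <- extract_subnetwork(g, "fpt_associated")
    if (!sub$connected) next
    # brute force: smallest mediator subset that joins all seeds
    best <- Inf
    for (size in 0:n_med) {
      for (s in combn(meds, size, simplify = FALSE)) {
        gg <- igraph::induced_subgraph(g, c(seeds, s))
        cm <- igraph::components(gg)$membership
        if (length(unique(cm[seeds])) == 1L) { best <- size; break }
      }
      if (is.finite(best)) break
    }
    expect_equal(length(sub$mediators), best)
  }
})

test_that("linking nodes are the subnetwork-side boundary endpoints", {
  # subnetwork {A, B} in path A-B, B-C: single boundary node B
  g <- build_graph(toy_edges(c("A", "B"), c("B", "C"), 0.9),
                   toy_gene_table(c("A", "B", "C"),
                                  category = c("fpt_associated", "fpt_associated",
                                               "pcos_curated")))
  sub <- extract_subnetwork(g, "fpt_associated")
  ln <- linking_nodes(g, sub)
  expect_equal(as.character(ln), "B")
  expect_true(attr(ln, "single_bridge"))

  # two disjoint boundary edges -> both inside endpoints returned
  g2 <- build_graph(toy_edges(c("A", "B", "A", "B"), c("B", "C", "D", "D"), 0.9),
                    toy_gene_table(c("A", "B", "C", "D"),
                                   category = c("fpt_associated", "fpt_associated",
                                                "pcos_curated", "pcos_curated")))
  sub2 <- extract_subnetwork(g2, "fpt_associated")
  expect_equal(as.character(linking_nodes(g2, sub2)), c("A", "B"))

  # subnetwork spanning the whole graph -> empty with a notice
  g3 <- build_graph(toy_edges("A", "B", 0.9),
                    toy_gene_table(c("A", "B"), category = "fpt_associated"))
  sub3 <- extract_subnetwork(g3, "fpt_associated")
  expect_message(ln3 <- linking_nodes(g3, sub3), "whole parent graph")
  expect_equal(ln3, character(0))
})

test_that("removing all linking nodes severs the subnetwork from the parent", {
  withr::local_seed(99L)
  for (i in 1:10) {
    bt <- make_bottleneck_graph(n_sub = sample(4:7, 1L), n_out = sample(4:7, 1L))
    sub <- extract_subnetwork(bt$graph, "fpt_associated")
    ln <- linking_nodes(bt$graph, sub)
    expect_equal(as.character(ln), bt$bridge)   # exactly the planted bottleneck
    reduced <- igraph::delete_vertices(bt$graph, as.character(ln))
    inside <- setdiff(igraph::V(sub$graph)$name, as.character(ln))
    outside <- setdiff(igraph::V(bt$graph)$name,
                       c(igraph::V(sub$graph)$name))
    cm <- igraph::components(reduced)$membership
    if (length(inside) > 0L && length(outside) > 0L) {
      expect_false(any(cm[inside] %in% cm[outside]))
    }
  }
})
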