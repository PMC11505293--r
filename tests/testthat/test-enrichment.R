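make_collection <- function(...) {
  sets <- lapply(list(...), function(m) list(description = "d", members = m))
  if (is.null(names(sets))) names(sets) <- sprintf("S%d", seq_along(sets))
  gene_set_collection(sets)
}

test_that("ORA reproduces the enumerated worked instance and edge cases", {
  # N=10, K=4, n=5, k=3: enumeration over all C(10,5)=252 draws gives 66/252
  universe <- sprintf("G%02d", 1:10)
  coll <- gene_set_collection(list(S = list(description = "d",
                                            members = universe[1:4])),
                              universe = universe)
  res <- hypergeom_ora(c(universe[1:3], universe[9:10]), coll)
  expect_equal(res$p, 66 / 252, tolerance = 1e-12)
  expect_equal(res$p, enum_hyper_upper(10, 4, 5, 3), tolerance = 1e-12)

  # k = K = n = N -> certain event
  coll2 <- gene_set_collection(list(S = list(description = "d", members = universe)),
                               universe = universe)
  expect_equal(hypergeom_ora(universe, coll2)$p, 1)

  # enrichment ratio arithmetic with an integer genome-style universe
  coll3 <- make_collection(sprintf("K%02d", 1:10))
  res3 <- hypergeom_ora(c(sprintf("K%02d", 1:6), sprintf("Z%02d", 1:14)),
                        coll3, universe = 100)
  expect_equal(res3$expected, 2)
  expect_equal(res3$ratio, 3.0)
})

test_that("ORA p-values match exhaustive enumeration on random small instances", {
  withr::local_seed(31L)
  for (i in 1:40) {
    N <- sample(5:12, 1L)
    K <- sample(1:(N - 1L), 1L)
    n <- sample(1:(N - 1L), 1L)
    universe <- sprintf("G%02d", seq_len(N))
    coll <- gene_set_collection(list(S = list(description = "d",
                                              members = universe[seq_len(K)])),
                                universe = universe)
    study <- sample(universe, n)
    k <- length(intersect(study, universe[seq_len(K)]))
    res <- hypergeom_ora(study, coll)
    expect_equal(res$k, k)
    if (k == 0L) {
      expect_equal(res$p, 1)
    } else {
      expect_equal(res$p, enum_hyper_upper(N, K, n, k), tolerance = 1e-10)
    }
  }
})

test_that("ORA drops out-of-universe genes with a message and errors when none remain", {
  coll <- make_collection(c("A", "B", "C"))
  expect_message(res <- hypergeom_ora(c("A", "ZZZ"), coll), "dropped 1")
  expect_equal(res$n, 1L)
  expect_error(suppressMessages(hypergeom_ora("ZZZ", coll)), "no study genes")
  expect_error(hypergeom_ora(character(0), coll), "empty")
})

test_that("BH step-up matches the hand-applied oracle and its invariants", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5L)), rep(1, 5L))
  expect_error(bh_fdr(c(0.5, 1.3)), "\\[0, 1\\]")

  withr::local_seed(57L)
  p <- runif(20)
  q <- bh_fdr(p)
  perm <- sample(20L)
  expect_equal(bh_fdr(p[perm]), q[perm])   # permutation equivariance
  expect_true(all(q <= 1), all(q >= 0))
})

test_that("weighted set cover handles disjoint, nested and empty inputs", {
  universe <- sprintf("G%02d", 1:30)
  coll <- gene_set_collection(list(
    BIG = list(description = "d", members = universe[1:6]),
    SUB = list(description = "d", members = universe[1:3]),
    OTHER = list(description = "d", members = universe[7:10])),
    universe = universe)
  res <- hypergeom_ora(universe[1:10], coll)
  sel <- weighted_set_cover(res, fdr_threshold = 1.01)  # admit everything
  # BIG covers SUB entirely, so SUB is never selected
  expect_false("SUB" %in% sel$selected)
  expect_setequal(sel$selected, c("BIG", "OTHER"))
  expect_equal(sel$coverage, 1)

  empty <- weighted_set_cover(res, fdr_threshold = 1e-9)
  expect_equal(empty$selected, character(0))
  expect_equal(empty$coverage, 0)

  one <- weighted_set_cover(res, fdr_threshold = 1.01, max_sets = 1L)
  expect_equal(length(one$selected), 1L)
})

test_that("greedy cover respects the (1 - 1/e) bound against the best 2-set cover", {
  withr::local_seed(71L)
  universe <- sprintf("G%02d", 1:25)
  for (i in 1:20) {
    sets <- lapply(1:5, function(j) list(description = "d",
                                         members = sample(universe, sample(4:10, 1L))))
    names(sets) <- sprintf("S%d", 1:5)
    coll <- gene_set_collection(sets, universe = universe)
    res <- hypergeom_ora(sample(universe, 12L), coll)
    sel <- weighted_set_cover(res, fdr_threshold = 1.01, max_sets = 2L)
    covered_by <- function(nms) length(unique(unlist(
      res$overlap_genes[match(nms, res$name)])))
    best2 <- max(vapply(combn(res$name, 2L, simplify = FALSE), covered_by, numeric(1L)))
    expect_gte(length(sel$covered), (1 - exp(-1)) * best2)
  }
})

test_that("enrichment report is ranked by q, p, name with a selected flag", {
  universe <- sprintf("G%02d", 1:40)
  coll <- gene_set_collection(list(
    AAA = list(description = "d", members = universe[1:5]),
    BBB = list(description = "d", members = universe[1:5]),  # tie with AAA
    CCC = list(description = "d", members = universe[30:34])),
    universe = universe)
  res <- hypergeom_ora(universe[1:8], coll)
  rep <- enrichment_report(res, weighted_set_cover(res, fdr_threshold = 1.01))
  expect_equal(rep$name, c("AAA", "BBB", "CCC"))  # tie broken by name
  expect_equal(rep$genes[[1L]], paste(universe[1:5], collapse = ";"))
  expect_true(any(rep$selected))

  none <- enrichment_report(res[res$k > 100, ])
  expect_equal(nrow(none), 0L)
  expect_named(none, c("name", "genes", "k", "K", "ratio", "p", "q", "selected"))
})
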