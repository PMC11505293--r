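# Run code with a private RNG stream seeded by `seed`, restoring any
# pre-existing global state afterwards (no global side effects).
with_private_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for synthetic interactome data
#'
#' Describes a synthetic study in the shape of the real one: a literature
#' seed-gene core, orphan seed genes attached to the core only through
#' designated ground-truth connectors, one planted hub, background noise, and
#' a gene-set annotation with one planted enriched set among null decoys.
#'
#' Defaults mirror the study conditions: 120 literature seed genes (82
#' disease-curated + 38 ferroptosis-associated), 20 of them orphans with 20
#' one-to-one ground-truth connectors (so 140 nodes after connector
#' annotation), a planted hub wired to 41 core nodes, and a core edge density
#' giving an average degree near 7. Signal channel scores are drawn from
#' Beta(8, 2) scaled into (0.7, 1\] and noise scores from Beta(2, 8) scaled
#' into \[0, 0.7), so threshold behavior at 0.7 is unambiguous while the
#' recombination math is exercised. Each synthetic edge carries its score on
#' a single evidence channel; multi-channel noise could otherwise recombine
#' above the threshold.
#'
#' @param n_seeds Number of literature seed genes (core + orphans).
#' @param n_background Number of pure-background genes.
#' @param n_orphans Number of orphan seeds (disconnected from the core).
#' @param n_connectors Number of ground-truth connectors (must equal
#'   `n_orphans` in the one-to-one wiring used here).
#' @param planted_hub_degree Exact degree of the planted hub in the
#'   above-threshold graph.
#' @param core_density Edge probability within the seed core.
#' @param tau Score threshold separating signal from noise; default 0.7.
#' @param n_decoy_candidates Background nodes given one above-threshold edge
#'   to the core (candidate-pool decoys that connect no orphan).
#' @param planted_set_size Size `K` of the planted enriched set.
#' @param study_size Study size `n` used by [generate_annotation()].
#' @param ann_universe_size Annotation universe size `N`.
#' @param decoy_sizes Integer vector of decoy gene-set sizes.
#' @param effect Fraction of study genes forced into the planted set
#'   (0 = null).
#' @param seed Integer seed driving all randomness.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_seeds = 120L, n_background = 40L, n_orphans = 20L,
                           n_connectors = 20L, planted_hub_degree = 41L,
                           core_density = 0.075, tau = 0.7,
                           n_decoy_candidates = 10L,
                           planted_set_size = 10L, study_size = 20L,
                           ann_universe_size = 500L,
                           decoy_sizes = rep(10L, 20L),
                           effect = 0.5, seed = 1L) {
  spec <- list(n_seeds = as.integer(n_seeds),
               n_background = as.integer(n_background),
               n_orphans = as.integer(n_orphans),
               n_connectors = as.integer(n_connectors),
               planted_hub_degree = as.integer(planted_hub_degree),
               core_density = core_density, tau = tau,
               n_decoy_candidates = as.integer(n_decoy_candidates),
               planted_set_size = as.integer(planted_set_size),
               study_size = as.integer(study_size),
               ann_universe_size = as.integer(ann_universe_size),
               decoy_sizes = as.integer(decoy_sizes),
               effect = effect, seed = as.integer(seed))
  n_core <- spec$n_seeds - spec$n_orphans
  if (spec$n_orphans > spec$n_seeds) stop("n_orphans must not exceed n_seeds")
  if (spec$n_connectors != spec$n_orphans) {
    stop("one-to-one wiring requires n_connectors == n_orphans")
  }
  if (spec$planted_hub_degree >= n_core) {
    stop("planted_hub_degree must be smaller than the core size (", n_core, ")")
  }
  if (spec$core_density < 0 || spec$core_density > 1) stop("core_density must lie in [0, 1]")
  if (spec$effect < 0 || spec$effect > 1) stop("effect must lie in [0, 1]")
  if (spec$tau <= 0 || spec$tau >= 1) stop("tau must lie in (0, 1)")
  if (spec$planted_set_size > spec$ann_universe_size ||
      any(spec$decoy_sizes > spec$ann_universe_size)) {
    stop("gene-set size exceeds the annotation universe")
  }
  if (spec$study_size > spec$ann_universe_size) stop("study_size exceeds the universe")
  structure(spec, class = "synthetic_spec")
}

signal_score <- function(n, tau) tau + (1 - tau) * rbeta(n, 8, 2)
noise_score <- function(n, tau) tau * rbeta(n, 2, 8)

#' Generate a synthetic interactome with planted ground truth
#'
#' Emits a gene table, a STRING-dialect edge table and a ground-truth record,
#' fully reproducible from the spec seed. The construction guarantees: the
#' seed core is connected (a backbone ring under random density-`core_density`
#' edges); the planted hub `SEED001` has exactly `planted_hub_degree`
#' above-threshold edges; every orphan is attachable to the core only through
#' its designated ground-truth connector (orphan and connector edges are
#' signal-scored, all other orphan-incident edges are noise); decoy candidate
#' background nodes touch the core above threshold but no orphan, so the
#' minimal connector solution is unique.
#'
#' @param spec A `synthetic_spec`.
#' @return A list with elements `genes` (a `gene_table` of the `n_seeds`
#'   literature genes), `edges` (an `edge_table` with `experiments` and
#'   `textmining` channel columns), and `truth` (list: `connectors`, `hub`,
#'   `orphans`, `core_nodes`, `signal_edges`).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_private_seed(spec$seed, {
    n_core <- spec$n_seeds - spec$n_orphans
    core <- sprintf("SEED%03d", seq_len(n_core))
    orphans <- sprintf("ORPH%03d", seq_len(spec$n_orphans))
    connectors <- sprintf("CONN%03d", seq_len(spec$n_connectors))
    backgrounds <- if (spec$n_background > 0L) {
      sprintf("BKGD%03d", seq_len(spec$n_background))
    } else {
      character(0)
    }
    hub <- core[[1L]]
    ring_nodes <- core[-1L]

    sig <- list()  # each: c(a, b)
    # backbone ring over the non-hub core guarantees one core component
    if (length(ring_nodes) >= 3L) {
      sig <- c(sig, Map(c, ring_nodes, c(ring_nodes[-1L], ring_nodes[[1L]])))
    }
    # random core edges at the requested density, hub excluded
    if (length(ring_nodes) >= 2L && spec$core_density > 0) {
      prs <- combn(ring_nodes, 2L, simplify = FALSE)
      draw <- runif(length(prs)) < spec$core_density
      sig <- c(sig, prs[draw])
    }
    # planted hub wired to an exact number of core nodes
    hub_targets <- sort(sample(ring_nodes, spec$planted_hub_degree))
    sig <- c(sig, lapply(hub_targets, function(t) c(hub, t)))
    # orphan -- connector -- core, one-to-one
    anchors <- sample(ring_nodes, spec$n_orphans, replace = TRUE)
    sig <- c(sig, Map(c, orphans, connectors), Map(c, connectors, anchors))
    # decoy candidates: above-threshold edge to the core, none to orphans
    decoys <- head(backgrounds, spec$n_decoy_candidates)
    if (length(decoys) > 0L) {
      sig <- c(sig, Map(c, decoys, sample(ring_nodes, length(decoys), replace = TRUE)))
    }

    sig_df <- unique(data.frame(
      node_a = pmin(vapply(sig, `[[`, "", 1L), vapply(sig, `[[`, "", 2L)),
      node_b = pmax(vapply(sig, `[[`, "", 1L), vapply(sig, `[[`, "", 2L)),
      stringsAsFactors = FALSE))
    sig_df$experiments <- signal_score(nrow(sig_df), spec$tau)
    sig_df$textmining <- 0

    # sub-threshold noise among background, core and orphan nodes
    all_nodes <- c(core, orphans, connectors, backgrounds)
    n_noise <- 3L * max(1L, spec$n_background)
    na <- sample(all_nodes, n_noise, replace = TRUE)
    nb <- sample(all_nodes, n_noise, replace = TRUE)
    ok <- na != nb
    noise_df <- unique(data.frame(node_a = pmin(na[ok], nb[ok]),
                                  node_b = pmax(na[ok], nb[ok]),
                                  stringsAsFactors = FALSE))
    key_sig <- paste(sig_df$node_a, sig_df$node_b)
    noise_df <- noise_df[!paste(noise_df$node_a, noise_df$node_b) %in% key_sig, , drop = FALSE]
    noise_df$experiments <- 0
    noise_df$textmining <- noise_score(nrow(noise_df), spec$tau)

    edges <- rbind(sig_df, noise_df)
    edges$database <- 0
    edges$combined_score <- score_edges(edges, CHANNELS, prior = 0.041)
    edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
    rownames(edges) <- NULL
    class(edges) <- c("edge_table", "data.frame")

    seed_syms <- c(core, orphans)
    n_pcos <- round(spec$n_seeds * 82 / 120)
    genes <- data.frame(
      symbol = seed_syms,
      category = rep(c("pcos_curated", "fpt_associated"),
                     c(n_pcos, spec$n_seeds - n_pcos)),
      name = "", stringsAsFactors = FALSE)
    genes <- genes[order(genes$symbol), , drop = FALSE]
    rownames(genes) <- NULL
    class(genes) <- c("gene_table", "data.frame")

    list(genes = genes, edges = edges,
         truth = list(connectors = connectors, hub = hub, orphans = orphans,
                      core_nodes = core, signal_edges = sig_df[c("node_a", "node_b")]))
  })
}

#' Generate a synthetic gene-set annotation with one planted enriched set
#'
#' Builds a gene-set collection over a universe of `ann_universe_size`
#' symbols: one planted set of size `planted_set_size` holding
#' `round(effect * n)` study genes (capped at the set size; at `effect = 0`
#' the planted set is drawn uniformly and is statistically indistinguishable
#' from the decoys), plus decoy sets drawn uniformly from the universe, whose
#' overlap with any uniformly drawn study is exactly hypergeometric-null.
#'
#' @param spec A `synthetic_spec`.
#' @param study Character vector of study gene symbols.
#' @return A list with elements `collection` (a `gene_set_collection` whose
#'   universe is the full synthetic universe) and `truth` (list with
#'   `planted`, the planted set name, and `forced_overlap`).
#' @export
generate_annotation <- function(spec, study) {
  stopifnot(inherits(spec, "synthetic_spec"))
  study <- unique(toupper(study))
  if (length(study) > spec$ann_universe_size) stop("study larger than the universe")
  with_private_seed(spec$seed + 1L, {
    n_fill <- spec$ann_universe_size - length(study)
    universe <- c(study, sprintf("GENE%05d", seq_len(n_fill)))
    K <- spec$planted_set_size
    k_forced <- min(K, round(spec$effect * length(study)))
    planted <- c(if (k_forced > 0L) sample(study, k_forced),
                 sample(setdiff(universe, study), K - k_forced))
    if (spec$effect == 0) planted <- sample(universe, K)
    sets <- list(PLANTED = list(description = "planted signal set",
                                members = planted))
    for (i in seq_along(spec$decoy_sizes)) {
      sets[[sprintf("DECOY%03d", i)]] <-
        list(description = "null decoy set",
             members = sample(universe, spec$decoy_sizes[[i]]))
    }
    list(collection = gene_set_collection(sets, universe = universe),
         truth = list(planted = "PLANTED", forced_overlap = k_forced))
  })
}
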