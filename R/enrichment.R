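#' Hypergeometric over-representation analysis
#'
#' Tests each gene set of a collection for over-representation in a study gene
#' list. With a universe of `N` genes of which `K` belong to the set, and a
#' study of `n` genes of which `k` overlap the set, the one-sided p-value is
#' the hypergeometric upper tail `P[X >= k]`, evaluated through the survival
#' function (`phyper(k - 1, ..., lower.tail = FALSE)`), never by `1 - CDF`
#' subtraction. The enrichment ratio is `R = (k / n) / (K / N)`, the observed
#' overlap relative to the expected count `e = n K / N`. Sets with `k = 0` are
#' reported with `p = 1` and `R = 0`. Benjamini-Hochberg q-values are attached
#' (see [bh_fdr()]).
#'
#' Study genes outside the universe are dropped with a logged count; dropping
#' everything is an error. The universe defaults to all genes annotated in the
#' collection; alternatively a character vector, or a single integer taken as
#' a genome-style universe size (in which case all study genes and set members
#' are assumed annotated).
#'
#' @param study Character vector of study gene symbols.
#' @param collection A `gene_set_collection` (see [read_gmt()]).
#' @param universe `NULL` (collection universe), a character vector, or a
#'   single numeric universe size.
#' @return A `data.frame` of class `enrichment_result`, one row per set, with
#'   columns `name`, `k`, `K`, `n`, `N`, `expected`, `ratio`, `p`, `q` and the
#'   list column `overlap_genes` (alphabetical).
#' @export
hypergeom_ora <- function(study, collection, universe = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  study <- sort(unique(toupper(trimws(study))))
  study <- study[nzchar(study)]
  if (length(study) == 0L) stop("study gene set is empty")

  if (is.numeric(universe)) {
    stopifnot(length(universe) == 1L, universe >= 1)
    N <- as.integer(universe)
    members <- lapply(collection$sets, `[[`, "members")
    n <- length(study)
    if (n > N) stop("universe size smaller than the study")
  } else {
    univ <- if (is.null(universe)) collection$universe else sort(unique(toupper(trimws(universe))))
    dropped <- setdiff(study, univ)
    if (length(dropped) > 0L) {
      message("dropped ", length(dropped), " study gene(s) outside the universe")
    }
    study <- intersect(study, univ)
    if (length(study) == 0L) stop("no study genes remain after intersecting with the universe")
    N <- length(univ)
    n <- length(study)
    members <- lapply(collection$sets, function(s) intersect(s$members, univ))
  }

  nm <- names(collection$sets)
  K <- vapply(members, length, integer(1L))
  overlap <- lapply(members, intersect, x = study)
  k <- vapply(overlap, length, integer(1L))
  if (any(K > N)) stop("set larger than the universe")

  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  p[k == 0L] <- 1
  expected <- n * K / N
  ratio <- ifelse(k == 0L, 0, (k / n) / (K / N))

  out <- data.frame(name = nm, k = k, K = K, n = n, N = N,
                    expected = expected, ratio = ratio, p = p,
                    q = bh_fdr(p), stringsAsFactors = FALSE, row.names = NULL)
  out$overlap_genes <- unname(overlap)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment:
#' `q(i) = min over j >= i of min(1, m p(j) / j)` on the sorted p-values, with
#' the input order restored in the output.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Weighted set cover over significant gene sets
#'
#' Summarizes a list of significant enrichment results by greedily selecting a
#' small subset of representative sets: at each step the set maximizing
#' (number of newly covered study genes) x weight is chosen, where the weight
#' is `-log10(max(q, eps))`. Ties are broken by larger newly-covered count,
#' then smaller q, then lexicographic name. Selection stops at `max_sets`, at
#' the coverage target (fraction of all study genes annotated to any
#' significant set), or when no set adds a new gene.
#'
#' @param results An `enrichment_result` (see [hypergeom_ora()]).
#' @param max_sets Maximum number of sets to select; default unlimited.
#' @param coverage_target Stop once this fraction of coverable genes is
#'   covered; default 1.
#' @param fdr_threshold Significance filter applied to `q`; default 0.05.
#' @param eps Floor on `q` inside the weight, avoiding infinite weights;
#'   default 1e-16.
#' @return A list of class `cover_selection` with elements `selected` (ordered
#'   set names), `covered` (genes), and `coverage` (fraction in \[0, 1\]).
#' @export
weighted_set_cover <- function(results, max_sets = Inf, coverage_target = 1,
                               fdr_threshold = 0.05, eps = 1e-16) {
  stopifnot(inherits(results, "enrichment_result"))
  sig <- results[results$q < fdr_threshold, , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(structure(list(selected = character(0), covered = character(0),
                          coverage = 0), class = "cover_selection"))
  }
  genes_by_set <- lapply(sig$overlap_genes, sort)
  names(genes_by_set) <- sig$name
  weight <- -log10(pmax(sig$q, eps))
  names(weight) <- sig$name
  qv <- setNames(sig$q, sig$name)
  target <- sort(unique(unlist(genes_by_set)))

  selected <- character(0)
  covered <- character(0)
  while (length(selected) < max_sets &&
         length(covered) / length(target) < coverage_target) {
    remaining <- setdiff(sig$name, selected)
    if (length(remaining) == 0L) break
    new_count <- vapply(remaining, function(nm) {
      length(setdiff(genes_by_set[[nm]], covered))
    }, numeric(1L))
    gain <- new_count * weight[remaining]
    if (max(new_count) == 0) break
    best <- remaining[order(-gain, -new_count, qv[remaining], remaining)][[1L]]
    selected <- c(selected, best)
    covered <- sort(union(covered, genes_by_set[[best]]))
  }
  structure(list(selected = selected, covered = covered,
                 coverage = length(covered) / length(target)),
            class = "cover_selection")
}

#' @export
print.cover_selection <- function(x, ...) {
  cat(sprintf("Weighted set cover: %d set(s) selected covering %d gene(s) (%.1f%%)\n",
              length(x$selected), length(x$covered), 100 * x$coverage))
  if (length(x$selected) > 0L) cat(paste(seq_along(x$selected), x$selected,
                                         collapse = "\n", sep = ". "), "\n")
  invisible(x)
}

#' Ranked enrichment report table
#'
#' Flattens enrichment results into a ranked table: rows sorted by q, then p,
#' then name; the overlapping study genes are listed alphabetically; a
#' `selected` flag marks the sets chosen by the weighted set cover.
#'
#' @param results An `enrichment_result`.
#' @param selection Optional `cover_selection`.
#' @return A `data.frame` with columns `name`, `genes`, `k`, `K`, `ratio`,
#'   `p`, `q`, `selected`.
#' @export
enrichment_report <- function(results, selection = NULL) {
  stopifnot(inherits(results, "enrichment_result"))
  sel_names <- if (is.null(selection)) character(0) else selection$selected
  out <- data.frame(
    name = results$name,
    genes = vapply(results$overlap_genes, function(g) paste(sort(g), collapse = ";"), ""),
    k = results$k, K = results$K, ratio = results$ratio,
    p = results$p, q = results$q,
    selected = results$name %in% sel_names,
    stringsAsFactors = FALSE)
  out <- out[order(out$q, out$p, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
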