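#' Packaged example data
#'
#' Paths to the plain-text fixtures shipped with the package:
#'
#' * `pcos_gene_table.tsv` -- the 140-gene PCOS interactome node list
#'   (82 disease-curated, 38 ferroptosis-associated, 20 predicted-novel
#'   symbols with full gene names). The novel set is the explicitly published
#'   connector list; the ferroptosis/disease split of the remaining genes is
#'   partially reconstructed from the surrounding report, so individual
#'   non-novel tags should be treated as approximate while the category
#'   counts are exact.
#' * `pcos_hub_table.tsv` -- the 12-row major-hub table (TP53 highest,
#'   41 connections) as published; a transcription, not a network
#'   recomputation, since the underlying interaction database content cannot
#'   be shipped.
#' * `pcos_kegg_sets.gmt` -- the 16 over-represented KEGG pathways with their
#'   reported member genes, in GMT format.
#'
#' @param file Fixture file name; with no argument, lists available fixtures.
#' @return Full path to the fixture (or a character vector of names).
#' @export
#' @examples
#' pcosnet_example()
#' genes <- read_gene_table(pcosnet_example("pcos_gene_table.tsv"))
#' nrow(genes)  # 140
pcosnet_example <- function(file = NULL) {
  if (is.null(file)) {
    return(sort(list.files(system.file("extdata", package = "pcosnet"))))
  }
  path <- system.file("extdata", file, package = "pcosnet")
  if (!nzchar(path)) stop("no packaged fixture named '", file, "'")
  path
}
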