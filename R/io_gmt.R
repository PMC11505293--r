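#' Construct a gene-set collection
#'
#' Container for named gene sets used as the annotation side of
#' over-representation analysis. The universe defaults to the union of all
#' member sets; a larger explicit universe (for example, all annotated genes
#' of a reference genome) may be supplied and must contain every member.
#'
#' @param sets Named list; each element a list with fields `description`
#'   (string) and `members` (character vector of gene symbols).
#' @param universe Optional character vector of gene symbols.
#' @return A list with elements `sets` and `universe`, class
#'   `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) == 0L) stop("gene-set collection is empty")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("every gene set must be named")
  }
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names")
  sets <- lapply(sets, function(s) {
    members <- sort(unique(toupper(trimws(s$members))))
    members <- members[nzchar(members)]
    if (length(members) == 0L) stop("gene-set collection contains an empty set")
    list(description = if (is.null(s$description)) "" else s$description,
         members = members)
  })
  all_members <- sort(unique(unlist(lapply(sets, `[[`, "members"), use.names = FALSE)))
  if (is.null(universe)) {
    universe <- all_members
  } else {
    universe <- sort(unique(toupper(trimws(universe))))
    missing <- setdiff(all_members, universe)
    if (length(missing) > 0L) {
      stop("universe does not contain all set members; missing e.g. ",
           paste(head(missing, 3L), collapse = ", "))
    }
  }
  structure(list(sets = sets, universe = universe), class = "gene_set_collection")
}

#' Read gene sets in GMT format
#'
#' Standard Broad-dialect GMT: one set per line,
#' `name TAB description TAB member1 TAB member2 ...`. Members are uppercased;
#' the universe is the union of all members.
#'
#' @param path Path to the GMT file.
#' @return A `gene_set_collection`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".gmt")
#' writeLines("Ferroptosis\tKEGG\tGPX4\tACSL4\tTFRC", tf)
#' read_gmt(tf)
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1L)) < 3L)
  if (length(short) > 0L) {
    stop("GMT line ", short[[1L]], " has fewer than 3 fields")
  }
  sets <- lapply(fields, function(f) {
    list(description = f[[2L]], members = f[-(1:2)])
  })
  names(sets) <- vapply(fields, `[[`, "", 1L)
  gene_set_collection(sets)
}

#' Write gene sets in GMT format
#'
#' Inverse of [read_gmt()]; members are written in alphabetical order.
#'
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    s <- collection$sets[[nm]]
    paste(c(nm, s$description, s$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
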