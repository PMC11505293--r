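#' Read a seed-gene table
#'
#' Reads a curated gene list with optional category tags. Two layouts are
#' accepted: a tab-separated table with a header naming at least a `symbol`
#' column (and optionally `category` and `name`), or a bare one-symbol-per-line
#' list. Symbols are whitespace-trimmed and uppercased before any comparison;
#' no alias or ortholog mapping is attempted.
#'
#' Duplicate symbols are collapsed to a single entry. A duplicate carrying two
#' different categories is an error, because the category encodes the
#' provenance of the gene (literature-curated disease gene, ferroptosis-process
#' gene, or predicted connector) and cannot be merged.
#'
#' @param path Path to the gene table file.
#' @param category_default Category assigned to rows without an explicit
#'   category. One of `"pcos_curated"`, `"fpt_associated"`,
#'   `"novel_predicted"`.
#' @return A `data.frame` with columns `symbol`, `category`, `name` and class
#'   `gene_table`; one row per distinct symbol.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("symbol\tcategory", "tp53\tpcos_curated", "GPX4\tfpt_associated"), tf)
#' read_gene_table(tf)
read_gene_table <- function(path, category_default = "pcos_curated") {
  stopifnot(is.character(path), length(path) == 1L)
  category_default <- match.arg(category_default, CATEGORIES)
  if (!file.exists(path)) stop("gene table file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("gene table file is empty: ", path)

  first <- tolower(trimws(strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]))
  if ("symbol" %in% first) {
    tab <- read.table(path, header = TRUE, sep = "\t", quote = "",
                      stringsAsFactors = FALSE, comment.char = "",
                      check.names = TRUE)
    names(tab) <- tolower(names(tab))
    if (!"symbol" %in% names(tab)) stop("gene table header lacks a 'symbol' column")
    symbol <- tab$symbol
    category <- if ("category" %in% names(tab)) tab$category else rep(NA_character_, nrow(tab))
    name <- if ("name" %in% names(tab)) tab$name else rep(NA_character_, nrow(tab))
  } else {
    if (any(grepl("\t", lines, fixed = TRUE))) {
      stop("gene table has tab-delimited rows but no 'symbol' header; ",
           "expected columns symbol[, category, name] or a bare symbol list")
    }
    symbol <- lines
    category <- rep(NA_character_, length(lines))
    name <- rep(NA_character_, length(lines))
  }

  symbol <- toupper(trimws(symbol))
  keep <- nzchar(symbol)
  symbol <- symbol[keep]; category <- category[keep]; name <- name[keep]
  if (length(symbol) == 0L) stop("gene table contains no symbols: ", path)
  category <- trimws(category)
  category[is.na(category) | !nzchar(category)] <- category_default
  bad <- setdiff(unique(category), CATEGORIES)
  if (length(bad) > 0L) {
    stop("unknown gene category: ", paste(bad, collapse = ", "),
         " (expected one of ", paste(CATEGORIES, collapse = ", "), ")")
  }

  # collapse duplicates; conflicting categories are a hard error
  split_cat <- split(category, symbol)
  conflict <- names(split_cat)[vapply(split_cat, function(x) length(unique(x)) > 1L, logical(1L))]
  if (length(conflict) > 0L) {
    stop("duplicate symbol with conflicting categories: ",
         paste(sort(conflict), collapse = ", "))
  }
  first_idx <- !duplicated(symbol)
  out <- data.frame(symbol = symbol[first_idx],
                    category = category[first_idx],
                    name = ifelse(is.na(name[first_idx]), "", name[first_idx]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$symbol), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_table", "data.frame")
  out
}

#' Write a seed-gene table
#'
#' Inverse of [read_gene_table()]: writes a tab-separated `symbol`, `category`,
#' `name` table.
#'
#' @param genes A `gene_table` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  stopifnot(is.data.frame(genes), all(c("symbol", "category") %in% names(genes)))
  df <- data.frame(symbol = genes$symbol, category = genes$category,
                   name = if ("name" %in% names(genes)) genes$name else "",
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}
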