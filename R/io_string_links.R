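#' Read a STRING-style protein-links edge table
#'
#' Parses a whitespace- or tab-delimited interaction table in the STRING
#' "protein links" flat-file dialect: two node columns, an optional column per
#' evidence channel, and a `combined_score` column. Recognized node-column
#' pairs are `protein1`/`protein2`, `node_a`/`node_b` and `node1`/`node2`;
#' the STRING column name `experimental` is accepted as an alias for the
#' `experiments` channel.
#'
#' Scores on STRING's native milli scale (integers in 0--1000) are divided by
#' 1000 so that every score lies in \[0, 1\]. With `score_scale = "auto"` the
#' milli scale is assumed when all scores are integers and at least one
#' exceeds 1, otherwise the unit scale. Self-loops are dropped with a warning
#' (STRING exports occasionally contain them). Duplicate undirected rows
#' (A,B)/(B,A) are merged keeping the per-channel maximum, a conservative
#' union of the evidence.
#'
#' @param path Path to the edge table.
#' @param score_scale `"auto"`, `"unit"` or `"milli"`.
#' @return A `data.frame` with columns `node_a`, `node_b`, any evidence-channel
#'   columns present in the file, and `combined_score`; class `edge_table`.
#'   One row per unordered node pair, ordered by (`node_a`, `node_b`).
#' @export
#' @examples
#' tf <- tempfile()
#' writeLines(c("protein1 protein2 combined_score", "TP53 ESR1 900"), tf)
#' read_string_links(tf)
read_string_links <- function(path, score_scale = c("auto", "unit", "milli")) {
  score_scale <- match.arg(score_scale)
  if (!file.exists(path)) stop("edge table file not found: ", path)
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                    quote = "", comment.char = "")
  names(tab) <- tolower(names(tab))
  names(tab)[names(tab) == "experimental"] <- "experiments"

  pairs <- list(c("protein1", "protein2"), c("node_a", "node_b"), c("node1", "node2"))
  node_cols <- NULL
  for (pr in pairs) if (all(pr %in% names(tab))) { node_cols <- pr; break }
  if (is.null(node_cols) || !"combined_score" %in% names(tab)) {
    stop("unrecognized edge table header; recognized dialects name the node ",
         "columns protein1/protein2, node_a/node_b or node1/node2 and include ",
         "a combined_score column, with optional per-channel columns (",
         paste(CHANNELS, collapse = ", "), ")")
  }
  chan_cols <- intersect(CHANNELS, names(tab))
  score_cols <- c(chan_cols, "combined_score")
  for (cc in score_cols) {
    if (!is.numeric(tab[[cc]])) stop("non-numeric scores in column '", cc, "'")
  }

  vals <- unlist(tab[score_cols], use.names = FALSE)
  if (score_scale == "auto") {
    score_scale <- if (length(vals) > 0L && all(vals == round(vals)) && any(vals > 1)) {
      "milli"
    } else {
      "unit"
    }
  }
  hi <- if (score_scale == "milli") 1000 else 1
  bad <- which(Reduce(`|`, lapply(tab[score_cols], function(x) x < 0 | x > hi)))
  if (length(bad) > 0L) {
    stop("score outside declared ", score_scale, " scale [0, ", hi, "] at data line ",
         bad[[1L]])
  }
  if (score_scale == "milli") for (cc in score_cols) tab[[cc]] <- tab[[cc]] / 1000

  a <- toupper(trimws(tab[[node_cols[[1L]]]]))
  b <- toupper(trimws(tab[[node_cols[[2L]]]]))
  self <- a == b
  if (any(self)) {
    warning("dropped ", sum(self), " self-loop row(s)")
    tab <- tab[!self, , drop = FALSE]; a <- a[!self]; b <- b[!self]
  }
  if (nrow(tab) == 0L) {
    out <- data.frame(node_a = character(0), node_b = character(0))
    for (cc in score_cols) out[[cc]] <- numeric(0)
    class(out) <- c("edge_table", "data.frame")
    return(out)
  }

  out <- data.frame(node_a = pmin(a, b), node_b = pmax(a, b), stringsAsFactors = FALSE)
  for (cc in score_cols) out[[cc]] <- tab[[cc]]
  key <- paste(out$node_a, out$node_b, sep = "\r")
  if (anyDuplicated(key)) {
    keys <- sort(unique(key))
    parts <- strsplit(keys, "\r", fixed = TRUE)
    merged <- data.frame(node_a = vapply(parts, `[[`, "", 1L),
                         node_b = vapply(parts, `[[`, "", 2L),
                         stringsAsFactors = FALSE)
    for (cc in score_cols) {
      tv <- tapply(out[[cc]], key, max)
      merged[[cc]] <- as.numeric(tv[keys])
    }
    out <- merged
  }
  out <- out[order(out$node_a, out$node_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("edge_table", "data.frame")
  out
}

#' Write an edge table
#'
#' Writes interaction edges in the dialect read by [read_string_links()]
#' (unit-scale scores, tab-delimited, `node_a`/`node_b` node columns).
#'
#' @param edges An `edge_table` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_string_links <- function(edges, path) {
  stopifnot(is.data.frame(edges),
            all(c("node_a", "node_b", "combined_score") %in% names(edges)))
  cols <- c("node_a", "node_b", intersect(CHANNELS, names(edges)), "combined_score")
  write.table(edges[cols], path, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}
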