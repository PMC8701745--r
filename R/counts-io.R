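#' Read a gene-by-sample count table
#'
#' First column holds gene identifiers, the header row sample identifiers.
#' Cells must be nonnegative integers; identifiers must be unique on both
#' axes.  Malformed cells are rejected, never coerced, and errors name the
#' offending gene/sample coordinate.
#'
#' @param path file path.
#' @param dialect \code{"tsv"} (default) or \code{"csv"}.
#' @return integer matrix with gene rownames and sample colnames, in file
#'   order.
#' @export
read_counts <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE, quote = "")
  gene_ids <- df[[1]]
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(gene_ids))
    stop("read_counts: duplicate gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("read_counts: duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(as.numeric(vals))
  bad <- is.na(num) | num < 0 | num != floor(num)
  if (any(bad)) {
    idx <- which(bad)[1]
    r <- (idx - 1) %% nrow(vals) + 1
    c <- (idx - 1) %/% nrow(vals) + 1
    stop(sprintf(
      "read_counts: invalid count '%s' at gene '%s', sample '%s'",
      vals[r, c], gene_ids[r], sample_ids[c]))
  }
  matrix(as.integer(num), nrow = nrow(vals), ncol = ncol(vals),
         dimnames = list(gene_ids, sample_ids))
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]: the written file reads back to an equal
#' matrix.
#'
#' @param counts integer matrix with dimnames.
#' @param path destination file.
#' @param dialect \code{"tsv"} or \code{"csv"}.
#' @export
write_counts <- function(counts, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  gene_ids <- rownames(counts)
  if (is.null(gene_ids)) gene_ids <- character(nrow(counts))
  df <- data.frame(gene = gene_ids, counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' TSV/CSV with a \code{sample_id} column, a two-level \code{group} column
#' (DCM / HS) and optional \code{batch} and clinical columns.  Missing
#' clinical values may be empty, \code{NA} or \code{n.a.}.
#'
#' @inheritParams read_counts
#' @return data.frame, one row per sample.
#' @export
read_metadata <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA", "n.a."), quote = "")
  if (!all(c("sample_id", "group") %in% colnames(df)))
    stop("read_metadata: need 'sample_id' and 'group' columns")
  if (anyDuplicated(df$sample_id))
    stop("read_metadata: duplicate sample ids")
  df
}

#' Read a GMT gene-set file
#'
#' One set per line: name TAB description TAB member ids.  Members are
#' deduplicated preserving first-occurrence order.
#'
#' @param path GMT file path.
#' @return named list of character vectors (set name -> members), with a
#'   \code{"descriptions"} attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- list()
    attr(out, "descriptions") <- character(0)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, 0L) < 3)
  if (length(short))
    stop("read_gene_sets: line ", short[1], " has fewer than 3 fields")
  nm <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(nm))
    stop("read_gene_sets: duplicate set name(s)")
  out <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(out) <- nm
  attr(out, "descriptions") <- stats::setNames(vapply(parts, `[[`, "", 2), nm)
  out
}

#' Read a STRING-export-style protein interaction edge list
#'
#' TSV with columns \code{protein_a}, \code{protein_b}, \code{channel}
#' (physical / textmining / database / combined) and \code{score} in
#' [0, 1].  Self-loops and out-of-range scores are format errors; exact
#' duplicate undirected edges are kept but flagged with a warning.
#'
#' @param path TSV file path.
#' @return data.frame of edges.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  need <- c("protein_a", "protein_b", "channel", "score")
  if (!all(need %in% colnames(df)))
    stop("read_edge_list: need columns ", paste(need, collapse = ", "))
  df$score <- suppressWarnings(as.numeric(df$score))
  bad <- which(is.na(df$score) | df$score < 0 | df$score > 1)
  if (length(bad))
    stop("read_edge_list: score outside [0,1] at line ", bad[1] + 1L)
  loops <- which(df$protein_a == df$protein_b)
  if (length(loops))
    stop("read_edge_list: self-loop at line ", loops[1] + 1L)
  key <- ifelse(df$protein_a < df$protein_b,
                paste(df$protein_a, df$protein_b, df$channel),
                paste(df$protein_b, df$protein_a, df$channel))
  if (anyDuplicated(key))
    warning("read_edge_list: duplicate undirected edge(s) kept as listed")
  df
}
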