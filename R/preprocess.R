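#' Remove genes without reliable detection
#'
#' Keeps a gene when its raw count reaches \code{min_count} in at least
#' \code{ceiling(min_fraction * n_samples)} samples.  The sample axis is
#' never touched.
#'
#' @param counts integer matrix, genes x samples.
#' @param min_count minimum count per qualifying sample; 0 keeps everything.
#' @param min_fraction fraction of samples that must qualify, in (0, 1].
#' @return the filtered count matrix.
#' @export
filter_low_expression <- function(counts, min_count = 10, min_fraction = 0.25) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  need <- ceiling(min_fraction * ncol(counts))
  keep <- rowSums(counts >= min_count) >= need
  if (!any(keep))
    warning("filter_low_expression: no gene passes the filter")
  counts[keep, , drop = FALSE]
}

#' Normalize counts to log2 counts-per-million
#'
#' \code{value = log2(count / library_size * 1e6 + pseudocount)}.  With the
#' default pseudocount of 1 zeros stay at 0 and all values are nonnegative.
#'
#' @param counts integer matrix, genes x samples.
#' @param pseudocount added on the CPM scale before the log.
#' @return numeric matrix, same dimnames.
#' @export
cpm_log2 <- function(counts, pseudocount = 1) {
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("cpm_log2: zero library size in sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  log2(sweep(counts, 2, lib, `/`) * 1e6 + pseudocount)
}

#' Remove additive batch effects by gene-wise mean centering
#'
#' Per gene, every batch's values are shifted so each batch mean equals the
#' gene's global mean.  A pure location adjustment: within-batch rank order
#' and spread are preserved, and class labels are never consulted.  With one
#' batch the input is returned unchanged.
#'
#' @param expr expression matrix, genes x samples.
#' @param batches batch label per sample (named by sample id, or positional).
#' @param target optional sample subset (ids or logical) used to *estimate*
#'   batch and global means; the correction is still applied to all columns.
#'   Used by the cross-validation driver to keep the held-out sample out of
#'   the estimates.
#' @return corrected matrix.
#' @export
batch_correct <- function(expr, batches, target = NULL) {
  if (length(batches) != ncol(expr))
    stop("batch_correct: one batch label per sample required")
  if (anyNA(batches))
    stop("batch_correct: sample without batch label")
  batches <- as.character(batches)
  if (length(unique(batches)) == 1) return(expr)
  est_cols <- seq_len(ncol(expr))
  if (!is.null(target)) {
    est_cols <- if (is.logical(target)) which(target)
                else match(target, colnames(expr))
    if (anyNA(est_cols)) stop("batch_correct: unknown target sample id")
  }
  global <- rowMeans(expr[, est_cols, drop = FALSE])
  out <- expr
  for (b in unique(batches)) {
    in_b <- which(batches == b)
    est_b <- intersect(in_b, est_cols)
    if (!length(est_b))
      stop("batch_correct: batch '", b, "' has no estimation sample")
    shift <- global - rowMeans(expr[, est_b, drop = FALSE])
    out[, in_b] <- out[, in_b, drop = FALSE] + shift
  }
  out
}
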