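# cache of n! permutation matrices for the exact Spearman null
.perm_cache <- new.env(parent = emptyenv())

.permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  rec <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    out <- NULL
    for (i in seq_along(v))
      out <- rbind(out, cbind(v[i], rec(v[-i])))
    out
  }
  P <- rec(seq_len(n))
  .perm_cache[[key]] <- P
  P
}

#' Spearman rank correlation with exact small-sample p-values
#'
#' Rho is the Pearson correlation of midranks.  The two-sided p-value is
#' exact for n <= 8 — computed by full enumeration of all n! orderings of
#' the observed (possibly tied) rank vector — and uses the t approximation
#' \eqn{t = \rho\sqrt{n-2}/\sqrt{1-\rho^2}} with n - 2 degrees of freedom
#' for larger n.  Incomplete pairs are dropped first.
#'
#' @param x,y numeric vectors of equal length; at least 3 complete pairs.
#' @return list with \code{rho}, \code{p}, \code{n_used}, and
#'   \code{degenerate} (TRUE when either variable has zero rank variance,
#'   in which case rho and p are NA).
#' @export
spearman_test <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("spearman_test: need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n_used = n,
                degenerate = TRUE))
  rho <- stats::cor(rx, ry)
  if (n <= 8) {
    P <- .permutations(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    # rho for every permutation of the observed y midranks
    perm_rho <- (matrix(ryc[P], nrow(P), n) %*% rxc) /
      sqrt(sum(rxc^2) * sum(ryc^2))
    p <- mean(abs(perm_rho) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
    p <- min(p, 1)
  }
  list(rho = rho, p = p, n_used = n, degenerate = FALSE)
}

#' Correlate panel genes with clinical covariates
#'
#' Computes the full gene-by-covariate grid of Spearman correlations on
#' pairwise-complete, optionally stratum-filtered samples.  An unadjusted
#' pass flag applies the configured thresholds; a Benjamini-Hochberg column
#' over the grid is added for transparency.
#'
#' @param expr expression matrix, genes x samples.
#' @param panel gene ids (rows of \code{expr}).
#' @param clinical data.frame with \code{sample_id} and covariate columns.
#' @param covariates covariate column names; default: all numeric columns.
#' @param stratum optional filter \code{"column=value"} (e.g.
#'   \code{"nyha=3"}) applied before correlating.
#' @param rho_min strict absolute-rho threshold for the pass flag.
#' @param p_max inclusive p-value threshold for the pass flag.
#' @return data.frame with columns gene, covariate, rho, p, n_used, fdr,
#'   pass.
#' @export
correlate_panel <- function(expr, panel, clinical, covariates = NULL,
                            stratum = NULL, rho_min = 0.5, p_max = 0.05) {
  stopifnot(all(panel %in% rownames(expr)))
  stopifnot("sample_id" %in% colnames(clinical))
  clinical <- clinical[match(colnames(expr), clinical$sample_id), ,
                       drop = FALSE]
  if (!is.null(stratum)) {
    kv <- strsplit(stratum, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2 || !kv[1] %in% colnames(clinical))
      stop("correlate_panel: bad stratum '", stratum, "'")
    keep <- !is.na(clinical[[kv[1]]]) &
      as.character(clinical[[kv[1]]]) == kv[2]
    if (sum(keep) < 3)
      stop("correlate_panel: stratum '", stratum, "' leaves n = ",
           sum(keep), " < 3 samples")
    clinical <- clinical[keep, , drop = FALSE]
    expr <- expr[, keep, drop = FALSE]
  }
  if (is.null(covariates)) {
    num <- vapply(clinical, is.numeric, FALSE)
    covariates <- setdiff(colnames(clinical)[num], "sample_id")
  }
  if (!length(covariates)) stop("correlate_panel: no covariates")

  grid <- expand.grid(gene = panel, covariate = covariates,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    spearman_test(expr[grid$gene[i], ], clinical[[grid$covariate[i]]])
  })
  grid$rho <- vapply(res, `[[`, 0, "rho")
  grid$p <- vapply(res, `[[`, 0, "p")
  grid$n_used <- vapply(res, `[[`, 0L, "n_used")
  pp <- grid$p
  grid$fdr <- NA_real_
  grid$fdr[!is.na(pp)] <- bh_adjust(pp[!is.na(pp)])
  grid$pass <- !is.na(grid$rho) & abs(grid$rho) > rho_min & grid$p <= p_max
  grid
}

#' Significant gene-covariate pairs
#'
#' Pairs with \code{|rho| > rho_min} (strict) and \code{p <= p_max}
#' (inclusive, so a pair reported at exactly the threshold is kept),
#' sorted by ascending p.
#'
#' @param res result of [correlate_panel()].
#' @param rho_min strict absolute-rho bound.
#' @param p_max inclusive p bound.
#' @return subset of \code{res}, sorted by p.
#' @export
significant_pairs <- function(res, rho_min = 0.5, p_max = 0.05) {
  keep <- !is.na(res$rho) & abs(res$rho) > rho_min & res$p <= p_max
  out <- res[keep, , drop = FALSE]
  out[order(out$p), , drop = FALSE]
}
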