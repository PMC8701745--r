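#' Per-gene two-group differential expression (Welch t)
#'
#' Row-wise Welch two-sample t-tests on log2 expression.  log2FC is the
#' difference of group means (first level minus second; with the default
#' DCM/HS labelling, DCM minus HS).  Genes with zero variance in both groups
#' get p = 1 when the means are equal and p = 0 (with a warning) when they
#' differ — a deterministic convention for degenerate rows.
#'
#' @param expr expression matrix (genes x samples), log2 scale.
#' @param groups class label per sample; exactly two levels, each with at
#'   least 2 samples.
#' @return data.frame with columns \code{gene}, \code{log2fc}, \code{t},
#'   \code{p}, \code{fdr} (Benjamini-Hochberg), \code{direction}
#'   (up/down/flat), one row per gene in input order.
#' @export
de_test <- function(expr, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2)
    stop("de_test: exactly two groups required")
  lv <- levels(groups)
  # DCM-vs-HS orientation when those labels are present
  if (all(c("DCM", "HS") %in% lv)) lv <- c("DCM", "HS")
  i1 <- groups == lv[1]
  i2 <- groups == lv[2]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2)
    stop("de_test: each group needs >= 2 samples")

  x1 <- expr[, i1, drop = FALSE]
  x2 <- expr[, i2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  lfc <- m1 - m2

  se2 <- v1 / n1 + v2 / n2
  tstat <- lfc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)

  degen <- se2 == 0
  if (any(degen)) {
    eq <- degen & lfc == 0
    ne <- degen & lfc != 0
    tstat[eq] <- 0;   p[eq] <- 1
    tstat[ne] <- Inf * sign(lfc[ne]); p[ne] <- 0
    if (any(ne))
      warning("de_test: ", sum(ne),
              " zero-variance gene(s) with unequal means assigned p = 0")
  }

  data.frame(
    gene = rownames(expr),
    log2fc = unname(lfc),
    t = unname(tstat),
    p = unname(p),
    fdr = bh_adjust(unname(p)),
    direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "flat")),
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Validated wrapper over the standard step-up procedure: input order is
#' preserved, adjusted values are clipped at 1 and monotone in p-value rank.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("bh_adjust: p-values must be in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' First-tier DEG filter: unadjusted p-value
#'
#' Keeps genes with p strictly below \code{p_max}, sorted by ascending p.
#'
#' @param res result of [de_test()].
#' @param p_max strict upper bound on the unadjusted p-value.
#' @return character vector of gene ids.
#' @export
filter_degs <- function(res, p_max = 0.01) {
  hits <- res[res$p < p_max, , drop = FALSE]
  hits$gene[order(hits$p)]
}

#' Second-tier DEG filter: FDR and fold change
#'
#' Keeps genes with \code{fdr < fdr_max} and \code{|log2fc| > lfc_min}
#' (both strict), mirroring a top-DEG shortlist.  The up/down partition
#' sizes are attached as attributes.
#'
#' @param res result of [de_test()].
#' @param fdr_max strict FDR bound.
#' @param lfc_min strict absolute log2 fold-change bound.
#' @return character vector of gene ids sorted by ascending fdr, with
#'   attributes \code{n_up} and \code{n_down}.
#' @export
filter_top_degs <- function(res, fdr_max = 0.05, lfc_min = 1) {
  keep <- res$fdr < fdr_max & abs(res$log2fc) > lfc_min
  hits <- res[keep, , drop = FALSE]
  hits <- hits[order(hits$fdr), , drop = FALSE]
  out <- hits$gene
  attr(out, "n_up") <- sum(hits$log2fc > 0)
  attr(out, "n_down") <- sum(hits$log2fc < 0)
  out
}
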