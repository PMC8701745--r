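#' Hypergeometric over-representation analysis
#'
#' One-sided (upper-tail) hypergeometric test of a query gene list against
#' each supplied gene set: \eqn{p = P(X \ge k)} for overlap k, set size K
#' (after intersecting with the universe), query size n and universe size
#' N, with Benjamini-Hochberg adjustment across sets.
#'
#' @param query character vector of genes; must be contained in
#'   \code{universe}.
#' @param universe character vector, the background gene universe.
#' @param sets named list of gene-set member vectors (see
#'   [read_gene_sets()]).
#' @return data.frame with columns set, k, K, n, N, p, fdr, sorted by
#'   ascending p.
#' @export
hypergeom_ora <- function(query, universe, sets) {
  universe <- unique(universe)
  query <- unique(query)
  off <- setdiff(query, universe)
  if (length(off))
    stop("hypergeom_ora: query genes outside the universe: ",
         paste(utils::head(off, 5), collapse = ", "))
  if (!length(sets))
    return(data.frame(set = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      fdr = numeric(0)))
  N <- length(universe)
  n <- length(query)
  K <- vapply(sets, function(s) length(intersect(s, universe)), 0L)
  k <- vapply(sets, function(s) length(intersect(s, query)), 0L)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(set = names(sets), k = k, K = K, n = n, N = N,
                    p = unname(p), fdr = bh_adjust(unname(p)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p, out$set), , drop = FALSE]
}

#' Extract a score-thresholded first-neighbor subnetwork
#'
#' Keeps edges with score strictly above \code{score_min}, channel in
#' \code{channels}, and at least one endpoint in the seed set.
#'
#' @param edges edge list data.frame (see [read_edge_list()]).
#' @param seeds character vector of seed genes/proteins.
#' @param score_min strict lower score bound in [0, 1].
#' @param channels interaction channels to keep.
#' @return list with \code{edges} (retained rows), \code{nodes}, and
#'   \code{seeds}.
#' @export
extract_subnetwork <- function(edges, seeds,
                               score_min = 0.7,
                               channels = c("physical", "textmining",
                                            "database", "combined")) {
  stopifnot(score_min >= 0, score_min <= 1)
  known <- c("physical", "textmining", "database", "combined")
  bad <- setdiff(channels, known)
  if (length(bad))
    stop("extract_subnetwork: unknown channel(s): ",
         paste(bad, collapse = ", "))
  keep <- edges$score > score_min &
    edges$channel %in% channels &
    (edges$protein_a %in% seeds | edges$protein_b %in% seeds)
  sub <- edges[keep, , drop = FALSE]
  list(edges = sub,
       nodes = sort(unique(c(sub$protein_a, sub$protein_b))),
       seeds = seeds)
}
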