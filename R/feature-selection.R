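#' Cluster gene expression profiles with deterministic k-means
#'
#' Lloyd's algorithm over genes (samples are the coordinates) with
#' k-means++-style seeding driven entirely by the supplied seed.  Tie-breaks
#' are fixed so that identical inputs and seed always give identical
#' clusterings: an equidistant gene joins the lower-indexed cluster, and an
#' emptied cluster is reseeded with the point farthest from its current
#' center.
#'
#' @param expr expression matrix, genes x samples; genes are the points.
#' @param k number of clusters, at most the number of genes.
#' @param seed integer seed for the k-means++ initialization.
#' @param max_iter iteration cap for Lloyd updates.
#' @return list with \code{assignment} (named integer vector, gene ->
#'   cluster), \code{centroids} (k x samples matrix), \code{inertia}
#'   (total within-cluster sum of squares), \code{iterations}.
#' @export
cluster_genes <- function(expr, k, seed = 1L, max_iter = 100L) {
  n <- nrow(expr)
  if (k > n) stop("cluster_genes: k exceeds the number of genes")
  if (k < 1) stop("cluster_genes: k must be >= 1")
  X <- unname(as.matrix(expr))

  set.seed(seed)
  # k-means++ seeding: first center uniform, then proportional to squared
  # distance to the nearest chosen center
  centers <- matrix(0, k, ncol(X))
  idx <- sample.int(n, 1)
  centers[1, ] <- X[idx, ]
  if (k > 1) {
    d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
    for (j in 2:k) {
      if (all(d2 == 0)) idx <- sample.int(n, 1)
      else idx <- sample.int(n, 1, prob = d2)
      centers[j, ] <- X[idx, ]
      d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X),
                                         byrow = TRUE))^2))
    }
  }

  sq <- function(A, B) {
    # squared euclidean distances, points x centers
    outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  }

  assign_old <- integer(n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    D <- sq(X, centers)
    assignment <- max.col(-D, ties.method = "first")  # lower index on ties
    # reseed empty clusters with the globally farthest point
    for (j in which(tabulate(assignment, k) == 0)) {
      far <- which.max(D[cbind(seq_len(n), assignment)])
      centers[j, ] <- X[far, ]
      assignment[far] <- j
      D[, j] <- rowSums((X - matrix(centers[j, ], n, ncol(X),
                                    byrow = TRUE))^2)
    }
    for (j in seq_len(k))
      centers[j, ] <- colMeans(X[assignment == j, , drop = FALSE])
    if (identical(assignment, assign_old) || iter >= max_iter) break
    assign_old <- assignment
  }

  D <- sq(X, centers)
  inertia <- sum(D[cbind(seq_len(n), assignment)])
  colnames(centers) <- colnames(expr)
  list(assignment = stats::setNames(assignment, rownames(expr)),
       centroids = centers,
       inertia = max(inertia, 0),
       iterations = iter)
}

#' Drop whole clusters with no detectable centroid signal
#'
#' A cluster survives when its centroid reaches \code{tau_detect} (on the
#' log2(CPM+1) scale) in at least one sample; all genes of surviving
#' clusters are kept, all genes of the rest dropped.
#'
#' @param clustering result of [cluster_genes()].
#' @param tau_detect detection threshold, inclusive.
#' @return character vector of retained gene ids.
#' @export
detectability_filter <- function(clustering, tau_detect = 1.0) {
  stopifnot(tau_detect >= 0)
  keep_cluster <- apply(clustering$centroids, 1, max) >= tau_detect
  names(clustering$assignment)[keep_cluster[clustering$assignment]]
}

#' Keep genes with a minimum between-group expression shift
#'
#' Retains a gene when the absolute difference of group means on the log2
#' scale is at least \code{delta_min} (inclusive).
#'
#' @param expr expression matrix.
#' @param groups two-level class label per sample.
#' @param genes candidate gene ids (subset of rownames).
#' @param delta_min inclusive threshold on |mean(DCM) - mean(HS)|.
#' @return retained gene ids, input order preserved.
#' @export
fold_change_filter <- function(expr, groups, genes, delta_min = 0.5) {
  stopifnot(all(genes %in% rownames(expr)))
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) stop("fold_change_filter: two groups required")
  sub <- expr[genes, , drop = FALSE]
  d <- rowMeans(sub[, groups == lv[1], drop = FALSE]) -
       rowMeans(sub[, groups == lv[2], drop = FALSE])
  genes[abs(d) >= delta_min]
}

#' Run the per-fold selection cascade
#'
#' Clustering/detectability filter, then fold-change filter, on training
#' data only.  Returns the per-stage retained sets (the fold's selection
#' trace).
#'
#' @param expr training expression matrix.
#' @param groups training class labels.
#' @param k,tau_detect,delta_min cascade parameters, see
#'   [cluster_genes()], [detectability_filter()], [fold_change_filter()].
#' @param seed k-means seed for this fold.
#' @return list with \code{after_cluster}, \code{after_fc} gene sets.
#' @export
select_features <- function(expr, groups, k = 100, tau_detect = 1.0,
                            delta_min = 0.5, seed = 1L) {
  k <- min(k, nrow(expr))
  cl <- cluster_genes(expr, k, seed = seed)
  after_cluster <- detectability_filter(cl, tau_detect)
  after_fc <- fold_change_filter(expr, groups, after_cluster, delta_min)
  list(after_cluster = after_cluster, after_fc = after_fc)
}

#' Cross-fold appearance frequencies
#'
#' For every gene retained after the fold-change filter in any fold, the
#' fraction of folds in which it was retained.
#'
#' @param traces list of selection traces (see [select_features()]).
#' @return list with \code{freq} (named numeric, descending), and
#'   \code{n_folds}.
#' @export
aggregate_frequencies <- function(traces) {
  if (!length(traces)) stop("aggregate_frequencies: no traces")
  all_genes <- sort(unique(unlist(lapply(traces, `[[`, "after_fc"))))
  n_folds <- length(traces)
  counts <- vapply(all_genes, function(g)
    sum(vapply(traces, function(tr) g %in% tr$after_fc, FALSE)), 0L)
  freq <- sort(counts / n_folds, decreasing = TRUE)
  # deterministic order: frequency descending, gene id ascending
  ord <- order(-freq, names(freq))
  list(freq = freq[ord], n_folds = n_folds)
}

#' Final panel by frequency filtering
#'
#' Genes whose cross-fold appearance frequency reaches \code{f_min},
#' ordered by frequency (descending) then gene id.
#'
#' @param freqs result of [aggregate_frequencies()].
#' @param f_min inclusive minimum frequency in [0, 1].
#' @return list with \code{panel} (gene ids), \code{freq} (their
#'   frequencies), \code{f_min}, \code{n_folds}.
#' @export
frequency_filter <- function(freqs, f_min = 0.75) {
  stopifnot(f_min >= 0, f_min <= 1)
  keep <- freqs$freq >= f_min
  if (!any(keep)) warning("frequency_filter: empty panel")
  list(panel = names(freqs$freq)[keep],
       freq = freqs$freq[keep],
       f_min = f_min,
       n_folds = freqs$n_folds)
}
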