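#' Default pipeline configuration
#'
#' Every tunable parameter of the pipeline with its default.  Supply
#' overrides as a nested list; unknown keys are rejected.
#'
#' @param overrides nested list of values to replace defaults.
#' @return nested configuration list.
#' @export
default_config <- function(overrides = NULL) {
  cfg <- list(
    filter = list(min_count = 10, min_fraction = 0.25),
    normalization = list(pseudocount = 1),
    batch = list(column = "batch"),
    diffexp = list(p_max = 0.01, fdr_max = 0.05, lfc_min = 1),
    selection = list(k = 100, tau_detect = 1.0, delta_min = 0.5,
                     f_min = 0.75),
    tree = list(criterion = "stable", max_depth = 3L, min_leaf = 2L,
                quantum = 0.5),
    clinical = list(rho_min = 0.5, p_max = 0.05, stratum = NULL),
    enrich = list(fdr_max = 0.05),
    network = list(score_min = 0.7, channels = "physical"),
    seed = 1L
  )
  if (!is.null(overrides)) cfg <- .merge_config(cfg, overrides, "")
  cfg
}

.merge_config <- function(base, over, path) {
  for (nm in names(over)) {
    here <- paste0(path, nm)
    if (!nm %in% names(base))
      stop("unknown configuration key: ", here)
    if (is.list(base[[nm]]) && is.list(over[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], over[[nm]], paste0(here, "."))
    else
      base[[nm]] <- over[[nm]]
  }
  base
}

#' Leave-one-out cross-validated panel discovery and tree training
#'
#' Runs the full machine-learning workflow: for each fold, the held-out
#' sample is removed and every data-driven step — detectability gene
#' filtering, batch-shift estimation, k-means clustering, the fold-change
#' filter — is recomputed on the training samples alone (the held-out
#' sample is only normalized and shifted with training-derived estimates,
#' so a fold's selection trace cannot depend on it).  After all folds
#' complete, cross-fold appearance frequencies are aggregated, the
#' frequency filter fixes the final panel, and a second pass fits one
#' decision tree per fold on the panel genes (the aggregate frequencies
#' acting as the stable criterion's tie-breaking prior) and classifies the
#' held-out sample.
#'
#' @param counts raw count matrix, genes x samples.
#' @param metadata data.frame with \code{sample_id}, \code{group}, and the
#'   batch column named by \code{config$batch$column} (optional: a single
#'   batch is assumed when absent).
#' @param config see [default_config()].
#' @return object of class \code{loocv_result}: per-fold traces, trees,
#'   held-out predictions and truths, the frequency table, the panel, the
#'   tree census, and the LOO accuracy.
#' @export
run_loocv <- function(counts, metadata, config = default_config()) {
  stopifnot(identical(colnames(counts), metadata$sample_id))
  groups <- as.character(metadata$group)
  if (length(unique(groups)) != 2)
    stop("run_loocv: exactly two classes required")
  if (min(table(groups)) < 2)
    stop("run_loocv: need >= 2 samples per class")
  bcol <- config$batch$column
  batches <- if (!is.null(bcol) && bcol %in% colnames(metadata))
    as.character(metadata[[bcol]]) else rep("single", ncol(counts))

  n <- ncol(counts)
  set.seed(config$seed)
  fold_seeds <- sample.int(.Machine$integer.max, n)

  # pass 1: per-fold preprocessing + selection cascade
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    if (length(unique(groups[train])) < 2) {
      warning("run_loocv: fold ", i, " lost a class; skipped")
      folds[[i]] <- list(held_out = colnames(counts)[i], ok = FALSE)
      next
    }
    keep <- rowSums(counts[, train, drop = FALSE] >=
                      config$filter$min_count) >=
      ceiling(config$filter$min_fraction * length(train))
    sub <- counts[keep, , drop = FALSE]
    expr <- cpm_log2(sub, config$normalization$pseudocount)
    expr <- batch_correct(expr, batches, target = colnames(counts)[train])
    trace <- select_features(expr[, train, drop = FALSE], groups[train],
                             k = config$selection$k,
                             tau_detect = config$selection$tau_detect,
                             delta_min = config$selection$delta_min,
                             seed = fold_seeds[i])
    folds[[i]] <- list(held_out = colnames(counts)[i],
                       truth = groups[i],
                       expr = expr,
                       train = train,
                       trace = trace,
                       ok = TRUE)
  }
  done <- which(vapply(folds, `[[`, FALSE, "ok"))
  if (!length(done)) stop("run_loocv: no completed folds")

  freqs <- aggregate_frequencies(lapply(folds[done], `[[`, "trace"))
  panel <- frequency_filter(freqs, config$selection$f_min)

  # pass 2: per-fold tree on the aggregate panel
  for (i in done) {
    f <- folds[[i]]
    cand <- intersect(panel$panel, rownames(f$expr))
    if (!length(cand)) {
      folds[[i]]$ok <- FALSE
      warning("run_loocv: fold ", i, " has no panel gene available; skipped")
      next
    }
    tree <- fit_tree(f$expr[, f$train, drop = FALSE], groups[f$train],
                     candidate_genes = cand,
                     criterion = config$tree$criterion,
                     stability_prior = freqs$freq,
                     max_depth = config$tree$max_depth,
                     min_leaf = config$tree$min_leaf,
                     quantum = config$tree$quantum)
    folds[[i]]$tree <- tree
    folds[[i]]$prediction <- predict(tree, f$expr[, i])
    folds[[i]]$expr <- NULL   # drop the bulky matrix from the result
  }
  done <- which(vapply(folds, `[[`, FALSE, "ok"))

  census <- tree_census(lapply(folds[done], `[[`, "tree"))
  correct <- vapply(folds[done],
                    function(f) identical(f$prediction, f$truth), FALSE)

  structure(list(
    n_folds = n,
    completed = done,
    folds = folds,
    frequencies = freqs,
    panel = panel,
    census = census,
    accuracy = mean(correct),
    config = config
  ), class = "loocv_result")
}

#' Leave-one-out accuracy
#'
#' @param result a \code{loocv_result}.
#' @return fraction of completed folds whose held-out sample was classified
#'   correctly.
#' @export
loocv_accuracy <- function(result) {
  if (!length(result$completed)) stop("loocv_accuracy: no completed folds")
  result$accuracy
}

#' @export
print.loocv_result <- function(x, ...) {
  cat("leave-one-out run: ", length(x$completed), "/", x$n_folds,
      " folds completed\n", sep = "")
  cat("panel (", length(x$panel$panel), " genes): ",
      paste(utils::head(x$panel$panel, 10), collapse = ", "),
      if (length(x$panel$panel) > 10) ", ..." else "", "\n", sep = "")
  cat("tree census: ", x$census$n_types, " type(s); accuracy ",
      format(x$accuracy), "\n", sep = "")
  invisible(x)
}

#' Serialize a leave-one-out result to canonical JSON
#'
#' A deterministic text rendering of everything a run produced (panel,
#' frequencies, per-fold trees, predictions, census, accuracy); two runs
#' with identical inputs and seed serialize to identical bytes.
#'
#' @param result a \code{loocv_result}.
#' @return a JSON string.
#' @export
loocv_to_json <- function(result) {
  folds <- lapply(result$folds, function(f) {
    out <- list(held_out = f$held_out, ok = f$ok)
    if (isTRUE(f$ok)) {
      out$truth <- f$truth
      out$prediction <- f$prediction
      out$after_cluster <- sort(f$trace$after_cluster)
      out$after_fc <- sort(f$trace$after_fc)
      out$tree <- jsonlite::fromJSON(serialize_tree(f$tree),
                                     simplifyVector = FALSE)
    }
    out
  })
  obj <- list(
    n_folds = result$n_folds,
    panel = as.list(result$panel$panel),
    frequencies = as.list(result$frequencies$freq),
    folds = folds,
    census = list(n_types = result$census$n_types,
                  class_of = result$census$class_of,
                  specializations = result$census$specializations),
    accuracy = result$accuracy
  )
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
}
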