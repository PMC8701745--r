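#' Simulate a two-group RNA-seq count matrix with planted effects
#'
#' Generates a gene-by-sample matrix of negative-binomial counts emulating a
#' small two-group (DCM vs HS) bulk RNA-seq cohort: per-gene baseline
#' abundances, planted log2 fold-change effects on designated genes, an
#' additive two-batch shift on the log2 mean, log-normal library sizes, and
#' clinical covariates monotonically linked to designated genes.  The NB is
#' parameterized by mean \eqn{\mu} and dispersion \eqn{\phi} with variance
#' \eqn{\mu + \phi \mu^2}; \code{dispersion = 0} degenerates to Poisson.
#'
#' Baseline abundances are drawn uniformly on \code{baseline_log2_mean_range},
#' interpreted as log2 expected counts at the reference library size of 1e7.
#' Library sizes are log-normal (sdlog 0.2) around 1e7 so that normalization
#' is non-trivial.  A planted effect of \code{log2fc} on gene g shifts the
#' DCM-group log2 mean by \code{+log2fc/2} and the HS-group mean by
#' \code{-log2fc/2}, so the DCM/HS mean ratio is \code{2^log2fc} in
#' expectation while the expected total RNA mass stays balanced between the
#' groups (asymmetric planting would bias counts-per-million normalization
#' for every unplanted gene).
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per class; classes are labelled \code{"DCM"}
#'   and \code{"HS"}.
#' @param baseline_log2_mean_range length-2 numeric, the interval (log2
#'   expected counts at library size 1e7) baselines are drawn from.
#' @param dispersion NB dispersion \eqn{\phi \ge 0}, recycled over genes.
#' @param planted_de data frame with columns \code{gene} and \code{log2fc},
#'   or \code{NULL} for a fully null matrix.  Gene ids must exist in the
#'   simulated gene universe (\code{gene0001}, \code{gene0002}, ...).
#' @param batch_assignment character vector of batch labels, one per sample
#'   (DCM samples first, then HS), or \code{NULL} for a balanced two-batch
#'   design alternating within each group.
#' @param batch_shift named numeric vector of additive log2 offsets, one per
#'   batch label.
#' @param clinical_links data frame with columns \code{covariate},
#'   \code{gene}, \code{slope}, \code{noise_sd}; each covariate is
#'   \code{slope * log2-CPM expression + N(0, noise_sd)}.  \code{NULL} plants
#'   no linked covariates.
#' @param seed integer RNG seed; identical seed and parameters give
#'   bit-identical output.
#'
#' @return a list with components
#'   \describe{
#'     \item{counts}{integer matrix, genes x samples, with dimnames.}
#'     \item{metadata}{data.frame with \code{sample_id}, \code{group},
#'       \code{batch}, the linked covariates, and unlinked clinical noise
#'       covariates \code{age}, \code{sex}, \code{nyha}.}
#'     \item{truth}{ground truth: \code{de_genes} (gene, log2fc),
#'       \code{linked_covariates} (covariate -> gene map), \code{batch}
#'       assignment, \code{library_sizes}, and the generating per-gene
#'       \code{mu} matrix before sampling noise.}
#'   }
#' @examples
#' sim <- simulate_counts(n_genes = 200, n_per_group = 5, seed = 1)
#' dim(sim$counts)
#' @export
simulate_counts <- function(n_genes = 9000,
                            n_per_group = 11,
                            baseline_log2_mean_range = c(-2, 8),
                            dispersion = 0.1,
                            planted_de = NULL,
                            batch_assignment = NULL,
                            batch_shift = c(A = 0, B = 1),
                            clinical_links = NULL,
                            seed = 1L) {
  if (n_genes < 1 || n_per_group < 2)
    stop("simulate_counts: need n_genes >= 1 and n_per_group >= 2")
  if (any(dispersion < 0))
    stop("simulate_counts: dispersion must be >= 0")
  stopifnot(length(baseline_log2_mean_range) == 2)

  n_samples <- 2L * n_per_group
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  sample_ids <- c(sprintf("DCM%02d", seq_len(n_per_group)),
                  sprintf("HS%02d", seq_len(n_per_group)))
  group <- factor(rep(c("DCM", "HS"), each = n_per_group),
                  levels = c("DCM", "HS"))

  if (is.null(batch_assignment)) {
    # balanced: alternate batches within each group so batch is not
    # confounded with class
    batch_assignment <- rep(rep(names(batch_shift),
                                length.out = n_per_group), 2)
  }
  if (length(batch_assignment) != n_samples)
    stop("simulate_counts: batch_assignment must have one label per sample")
  if (!all(batch_assignment %in% names(batch_shift)))
    stop("simulate_counts: batch labels missing from batch_shift")

  lfc <- stats::setNames(numeric(n_genes), gene_ids)
  if (!is.null(planted_de) && nrow(planted_de) > 0) {
    bad <- setdiff(planted_de$gene, gene_ids)
    if (length(bad))
      stop("simulate_counts: planted genes not in gene universe: ",
           paste(bad, collapse = ", "))
    if (anyDuplicated(planted_de$gene))
      stop("simulate_counts: duplicate planted gene ids")
    lfc[planted_de$gene] <- planted_de$log2fc
  }

  set.seed(seed)
  baseline <- stats::runif(n_genes, baseline_log2_mean_range[1],
                           baseline_log2_mean_range[2])
  lib_size <- stats::rlnorm(n_samples, meanlog = log(1e7), sdlog = 0.2)

  # log2 mean for gene i, sample j at reference library size; planted
  # effects applied symmetrically (+lfc/2 in DCM, -lfc/2 in HS) so the
  # group-mean ratio is 2^lfc while the expected total RNA mass stays
  # balanced between groups (composition-preserving planting)
  log2mu <- outer(baseline, rep(0, n_samples), `+`)
  log2mu[, group == "DCM"] <- log2mu[, group == "DCM"] + lfc / 2
  log2mu[, group == "HS"] <- log2mu[, group == "HS"] - lfc / 2
  log2mu <- sweep(log2mu, 2, batch_shift[batch_assignment], `+`)
  mu <- sweep(2^log2mu, 2, lib_size / 1e7, `*`)
  dimnames(mu) <- list(gene_ids, sample_ids)

  phi <- rep_len(dispersion, n_genes)
  counts <- matrix(0L, n_genes, n_samples,
                   dimnames = list(gene_ids, sample_ids))
  for (j in seq_len(n_samples)) {
    pois <- phi == 0
    col <- numeric(n_genes)
    if (any(pois)) col[pois] <- stats::rpois(sum(pois), mu[pois, j])
    if (any(!pois)) col[!pois] <- stats::rnbinom(sum(!pois),
                                                 mu = mu[!pois, j],
                                                 size = 1 / phi[!pois])
    counts[, j] <- as.integer(col)
  }

  metadata <- data.frame(sample_id = sample_ids,
                         group = as.character(group),
                         batch = batch_assignment,
                         stringsAsFactors = FALSE)

  # clinical covariates from the realized expression
  expr <- cpm_log2(counts)
  linked_map <- character(0)
  if (!is.null(clinical_links) && nrow(clinical_links) > 0) {
    clin <- generate_clinical(expr, clinical_links, seed = seed + 1L)
    metadata <- cbind(metadata, clin)
    linked_map <- stats::setNames(clinical_links$gene,
                                  clinical_links$covariate)
  }
  # unlinked covariates: pure noise controls for the association module
  metadata$age <- round(stats::rnorm(n_samples, 50, 10))
  metadata$sex <- sample(c("M", "F"), n_samples, replace = TRUE)
  metadata$nyha <- sample(3:4, n_samples, replace = TRUE)

  truth <- list(
    de_genes = data.frame(gene = gene_ids[lfc != 0],
                          log2fc = unname(lfc[lfc != 0]),
                          stringsAsFactors = FALSE),
    linked_covariates = linked_map,
    batch = stats::setNames(batch_assignment, sample_ids),
    library_sizes = stats::setNames(lib_size, sample_ids),
    mu = mu
  )
  list(counts = counts, metadata = metadata, truth = truth)
}

#' Generate clinical covariates linked to gene expression
#'
#' Each requested covariate is a linear function of one gene's expression
#' plus Gaussian noise: \code{slope * expr[gene, ] + N(0, noise_sd)}.  With
#' zero noise the covariate is a strictly monotone transform of expression,
#' so Spearman correlation with the source gene is exactly +/-1.
#'
#' @param expr expression matrix (genes x samples) on the log2(CPM+1) scale.
#' @param links data frame with columns \code{covariate}, \code{gene},
#'   \code{slope}, \code{noise_sd}.
#' @param seed integer RNG seed.
#' @return data.frame of covariates, one row per sample.
#' @export
generate_clinical <- function(expr, links, seed = 1L) {
  stopifnot(is.matrix(expr))
  bad <- setdiff(links$gene, rownames(expr))
  if (length(bad))
    stop("generate_clinical: unknown gene id(s): ", paste(bad, collapse = ", "))
  set.seed(seed)
  out <- lapply(seq_len(nrow(links)), function(i) {
    links$slope[i] * expr[links$gene[i], ] +
      stats::rnorm(ncol(expr), 0, links$noise_sd[i])
  })
  names(out) <- links$covariate
  as.data.frame(out, row.names = colnames(expr))
}

#' Standard synthetic benchmarks for the pipeline
#'
#' Fixed study-condition datasets used throughout the test suite and the
#' validation script:
#' \describe{
#'   \item{strong}{2,000 genes, 11 + 11 samples, 5 planted genes at
#'     |log2FC| between 1.5 and 2.5 (mixed signs) on high-abundance
#'     baselines, dispersion 0.1, two balanced batches with a +1 log2
#'     shift, and clinical covariates LVEDD / LVESD linked to two planted
#'     genes (noise 0.25 x the expression SD).  The strong-signal panel
#'     recovery and tree-stability benchmark.}
#'   \item{null}{same shape, no planted effects; calibration benchmark.}
#'   \item{separable}{4 genes, 2 + 2 samples, one hugely separated gene;
#'     minimal sanity benchmark.}
#' }
#'
#' @param seed integer master seed.
#' @param type one of \code{"strong"}, \code{"null"}, \code{"separable"}.
#' @return as [simulate_counts()].
#' @export
synthetic_benchmark <- function(seed = 17L,
                                type = c("strong", "null", "separable")) {
  type <- match.arg(type)
  if (type == "separable") {
    return(simulate_counts(
      n_genes = 4, n_per_group = 2,
      baseline_log2_mean_range = c(6, 8), dispersion = 0.05,
      planted_de = data.frame(gene = "gene0001", log2fc = 5),
      batch_shift = c(A = 0), batch_assignment = rep("A", 4),
      seed = seed))
  }
  planted <- NULL
  links <- NULL
  if (type == "strong") {
    planted <- data.frame(
      gene = sprintf("gene%04d", 1:5),
      log2fc = c(2.0, -2.5, 1.5, -1.8, 2.2))
    # LVEDD tracks a down-regulated planted gene, LVESD an up-regulated one,
    # with noise at a quarter of the typical expression SD
    links <- data.frame(
      covariate = c("LVEDD", "LVESD"),
      gene = c("gene0002", "gene0001"),
      slope = c(-6, 5),
      noise_sd = c(0.3, 0.3),
      stringsAsFactors = FALSE)
  }
  sim <- simulate_counts(
    n_genes = 2000, n_per_group = 11,
    baseline_log2_mean_range = c(-2, 8), dispersion = 0.1,
    planted_de = planted,
    batch_shift = c(A = 0, B = 1),
    clinical_links = links,
    seed = seed)
  if (type == "strong") {
    # pin planted genes to high, well-detectable baselines by regenerating:
    # simulate_counts draws baselines uniformly; the planted five are the
    # first five gene ids, whose draws may be low.  Re-simulate with the
    # planted rows' baselines forced high via a dedicated pass.
    sim <- .simulate_strong(seed)
  }
  sim
}

# strong benchmark with planted genes forced onto high baselines so they
# always clear the detectability filter
.simulate_strong <- function(seed) {
  planted <- data.frame(
    gene = sprintf("gene%04d", 1:5),
    log2fc = c(2.0, -2.5, 1.5, -1.8, 2.2))
  links <- data.frame(
    covariate = c("LVEDD", "LVESD"),
    gene = c("gene0002", "gene0001"),
    slope = c(-6, 5),
    noise_sd = c(0.3, 0.3),
    stringsAsFactors = FALSE)
  n_genes <- 2000L
  n_per_group <- 11L
  n_samples <- 22L
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  sample_ids <- c(sprintf("DCM%02d", 1:n_per_group),
                  sprintf("HS%02d", 1:n_per_group))
  group <- rep(c("DCM", "HS"), each = n_per_group)
  batch_shift <- c(A = 0, B = 1)
  batch_assignment <- rep(rep(c("A", "B"), length.out = n_per_group), 2)

  set.seed(seed)
  baseline <- stats::runif(n_genes, -2, 8)
  baseline[1:5] <- stats::runif(5, 6.5, 7.5)
  lib_size <- stats::rlnorm(n_samples, meanlog = log(1e7), sdlog = 0.2)
  lfc <- stats::setNames(numeric(n_genes), gene_ids)
  lfc[planted$gene] <- planted$log2fc

  log2mu <- outer(baseline, rep(0, n_samples), `+`)
  log2mu[, group == "DCM"] <- log2mu[, group == "DCM"] + lfc / 2
  log2mu[, group == "HS"] <- log2mu[, group == "HS"] - lfc / 2
  log2mu <- sweep(log2mu, 2, batch_shift[batch_assignment], `+`)
  mu <- sweep(2^log2mu, 2, lib_size / 1e7, `*`)
  dimnames(mu) <- list(gene_ids, sample_ids)
  counts <- matrix(0L, n_genes, n_samples,
                   dimnames = list(gene_ids, sample_ids))
  for (j in seq_len(n_samples))
    counts[, j] <- as.integer(stats::rnbinom(n_genes, mu = mu[, j],
                                             size = 1 / 0.1))
  metadata <- data.frame(sample_id = sample_ids, group = group,
                         batch = batch_assignment, stringsAsFactors = FALSE)
  expr <- cpm_log2(counts)
  clin <- generate_clinical(expr, links, seed = seed + 1L)
  metadata <- cbind(metadata, clin)
  metadata$age <- round(stats::rnorm(n_samples, 50, 10))
  metadata$sex <- sample(c("M", "F"), n_samples, replace = TRUE)
  metadata$nyha <- sample(3:4, n_samples, replace = TRUE)
  truth <- list(
    de_genes = planted,
    linked_covariates = stats::setNames(links$gene, links$covariate),
    batch = stats::setNames(batch_assignment, sample_ids),
    library_sizes = stats::setNames(lib_size, sample_ids),
    mu = mu)
  list(counts = counts, metadata = metadata, truth = truth)
}
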