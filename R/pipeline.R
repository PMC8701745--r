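#' Run the full discovery pipeline
#'
#' Executes both workflows end to end and writes a reproducible output
#' bundle: preprocessing (detectability filter, log2 CPM, batch
#' correction), classic differential expression with the two filter tiers,
#' the leave-one-out feature-selection / stable-tree workflow, Spearman
#' association of the discovered panel with clinical covariates, and — when
#' a gene-set file or edge list is supplied — hypergeometric
#' over-representation of the top DEGs and a score-thresholded
#' subnetwork around the panel genes.  A manifest with an MD5 checksum per
#' output file closes the bundle.
#'
#' @param counts count matrix or path to a TSV/CSV count table.
#' @param metadata metadata data.frame or path (needs \code{sample_id},
#'   \code{group}, optionally a batch column and clinical covariates).
#' @param out_dir output directory, created if needed.
#' @param config see [default_config()].
#' @param gmt optional path to a GMT gene-set file; skipped with a notice
#'   when absent.
#' @param edges optional path to a STRING-style edge list; skipped with a
#'   notice when absent.
#' @return (invisibly) a list with the in-memory results of every stage
#'   and the manifest.
#' @export
run_full <- function(counts, metadata, out_dir,
                     config = default_config(),
                     gmt = NULL, edges = NULL) {
  if (is.character(counts)) counts <- read_counts(counts)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  stopifnot(identical(colnames(counts), metadata$sample_id))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  bcol <- config$batch$column
  batches <- if (!is.null(bcol) && bcol %in% colnames(metadata))
    as.character(metadata[[bcol]]) else rep("single", ncol(counts))

  # red workflow: preprocess + differential expression on all samples
  kept <- filter_low_expression(counts, config$filter$min_count,
                                config$filter$min_fraction)
  expr <- cpm_log2(kept, config$normalization$pseudocount)
  expr <- batch_correct(expr, batches)
  de <- de_test(expr, metadata$group)
  degs <- filter_degs(de, config$diffexp$p_max)
  top <- filter_top_degs(de, config$diffexp$fdr_max, config$diffexp$lfc_min)

  utils::write.table(de, file.path(out_dir, "de_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(degs, file.path(out_dir, "degs_pvalue.txt"))
  writeLines(top, file.path(out_dir, "degs_top.txt"))

  # blue workflow: LOO-CV feature selection + stable trees
  loocv <- run_loocv(counts, metadata, config)
  writeLines(loocv_to_json(loocv), file.path(out_dir, "loocv_result.json"))
  utils::write.table(
    data.frame(gene = names(loocv$frequencies$freq),
               frequency = unname(loocv$frequencies$freq)),
    file.path(out_dir, "frequency_table.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(loocv$panel$panel, file.path(out_dir, "panel.txt"))

  # clinical association of the panel
  clin_grid <- NULL
  if (length(loocv$panel$panel)) {
    num <- vapply(metadata, is.numeric, FALSE)
    covs <- setdiff(colnames(metadata)[num], "sample_id")
    if (length(covs)) {
      clin_grid <- correlate_panel(expr,
                                   intersect(loocv$panel$panel,
                                             rownames(expr)),
                                   metadata, covariates = covs,
                                   stratum = config$clinical$stratum,
                                   rho_min = config$clinical$rho_min,
                                   p_max = config$clinical$p_max)
      utils::write.table(clin_grid, file.path(out_dir, "clinical_grid.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(significant_pairs(clin_grid,
                                           config$clinical$rho_min,
                                           config$clinical$p_max),
                         file.path(out_dir, "clinical_pairs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # enrichment of the p-value tier DEGs
  enr <- NULL
  if (!is.null(gmt) && file.exists(gmt)) {
    sets <- read_gene_sets(gmt)
    enr <- hypergeom_ora(intersect(degs, rownames(expr)), rownames(expr),
                         sets)
    utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else message("run_full: no gene-set file; enrichment skipped")

  # PPI neighborhood of the panel
  net <- NULL
  if (!is.null(edges) && file.exists(edges)) {
    el <- read_edge_list(edges)
    net <- extract_subnetwork(el, loocv$panel$panel,
                              score_min = config$network$score_min,
                              channels = config$network$channels)
    utils::write.table(net$edges, file.path(out_dir, "subnetwork.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else message("run_full: no edge list; subnetwork skipped")

  # manifest with checksums
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    seed = config$seed,
    config = config,
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    files = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(file.path(out_dir, f))))
  )
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                           pretty = TRUE, digits = NA)),
             file.path(out_dir, "manifest.json"))

  invisible(list(de = de, degs = degs, top_degs = top, loocv = loocv,
                 clinical = clin_grid, enrichment = enr, network = net,
                 manifest = manifest))
}
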