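test_that("k-means recovers separable structure and exact fixed points", {
  profiles <- rbind(matrix(rep(c(1, 1, 1, 1), 10), 10, 4, byrow = TRUE),
                    matrix(rep(c(9, 9, 9, 9), 7), 7, 4, byrow = TRUE))
  rownames(profiles) <- sprintf("g%02d", 1:17)
  cl <- cluster_genes(profiles, k = 2, seed = 1)
  expect_equal(length(unique(cl$assignment[1:10])), 1)
  expect_equal(length(unique(cl$assignment[11:17])), 1)
  expect_true(any(apply(cl$centroids, 1, function(x) all(x == 1))))
  expect_true(any(apply(cl$centroids, 1, function(x) all(x == 9))))
  expect_equal(cl$inertia, 0)

  one <- cluster_genes(profiles, k = 1, seed = 1)
  expect_equal(as.vector(one$centroids), unname(colMeans(profiles)))

  expect_error(cluster_genes(profiles, k = 18), "exceeds")
})

test_that("converged inertia matches a many-restart reference on blobs", {
  set.seed(12)
  blobs <- rbind(matrix(rnorm(50 * 5, 0, 0.3), 50, 5),
                 matrix(rnorm(50 * 5, 8, 0.3), 50, 5))
  rownames(blobs) <- sprintf("g%03d", 1:100)
  cl <- cluster_genes(blobs, k = 2, seed = 3)
  ref <- kmeans(blobs, centers = 2, nstart = 20)
  expect_equal(cl$inertia, ref$tot.withinss, tolerance = 1e-8)
  # same seed, same result
  expect_identical(cl$assignment, cluster_genes(blobs, k = 2, seed = 3)$assignment)
})

test_that("detectability filter keeps whole clusters inclusively", {
  clustering <- list(
    assignment = setNames(c(1L, 1L, 2L, 3L, 3L), sprintf("g%d", 1:5)),
    centroids = rbind(c(0.1, 0.2), c(0.3, 1.0), c(5.0, 2.0)))
  kept <- detectability_filter(clustering, tau_detect = 1)
  expect_setequal(kept, c("g3", "g4", "g5"))   # centroid max 1.0 inclusive
  expect_equal(length(detectability_filter(clustering, tau_detect = 6)), 0)
  expect_equal(length(detectability_filter(clustering, tau_detect = 0)), 5)
})

test_that("fold-change filter threshold is inclusive on |delta|", {
  expr <- rbind(small = c(1, 1, 1.2, 1.2),
                edge  = c(1, 1, 1.5, 1.5),
                big   = c(1, 1, 1.8, 1.8))
  colnames(expr) <- sprintf("s%d", 1:4)
  groups <- c("DCM", "DCM", "HS", "HS")
  kept <- fold_change_filter(expr, groups, rownames(expr), delta_min = 0.5)
  expect_setequal(kept, c("edge", "big"))
  expect_equal(length(fold_change_filter(expr, groups, rownames(expr), 10)), 0)
})

test_that("frequencies aggregate and filter by the stated arithmetic", {
  traces <- lapply(1:22, function(i)
    list(after_fc = c("always", if (i <= 11) "half", if (i == 1) "rare")))
  fr <- aggregate_frequencies(traces)
  expect_equal(unname(fr$freq["always"]), 1.0)
  expect_equal(unname(fr$freq["half"]), 0.5)
  expect_equal(length(fr$freq), 3)             # completeness
  expect_true(all(fr$freq * fr$n_folds == round(fr$freq * fr$n_folds)))

  pan <- frequency_filter(fr, f_min = 0.75)
  expect_equal(pan$panel, "always")
  expect_equal(frequency_filter(fr, 0)$panel, names(fr$freq))
  expect_equal(frequency_filter(fr, 1.0)$panel, "always")
})

test_that("the cascade is monotone and recovers planted panel genes", {
  sim <- synthetic_benchmark(5, "strong")
  kept <- filter_low_expression(sim$counts)
  expr <- batch_correct(cpm_log2(kept), sim$metadata$batch)
  tr <- select_features(expr, sim$metadata$group, seed = 5)
  expect_true(all(tr$after_fc %in% tr$after_cluster))
  expect_lte(length(tr$after_fc), length(tr$after_cluster))
  expect_true(all(sprintf("gene%04d", 1:5) %in% tr$after_fc))
})
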