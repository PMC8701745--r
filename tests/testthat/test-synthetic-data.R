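test_that("simulation is deterministic and respects the null case", {
  a <- simulate_counts(n_genes = 100, n_per_group = 4, seed = 7)
  b <- simulate_counts(n_genes = 100, n_per_group = 4, seed = 7)
  expect_identical(a$counts, b$counts)
  expect_identical(a$metadata, b$metadata)
  c <- simulate_counts(n_genes = 100, n_per_group = 4, seed = 8)
  expect_false(identical(a$counts, c$counts))

  expect_equal(nrow(a$truth$de_genes), 0)
  expect_true(all(a$counts >= 0))
  expect_true(is.integer(a$counts))
  expect_equal(dim(a$counts), c(100, 8))
})

test_that("planted effects set the group mean ratio to 2^log2fc", {
  sim <- simulate_counts(
    n_genes = 20, n_per_group = 500,
    baseline_log2_mean_range = c(6, 8), dispersion = 0.1,
    planted_de = data.frame(gene = "gene0003", log2fc = 1),
    batch_shift = c(A = 0), batch_assignment = rep("A", 1000),
    seed = 42)
  grp <- sim$metadata$group
  # normalize out library sizes before comparing group means
  cpm <- sweep(sim$counts, 2, colSums(sim$counts), `/`) * 1e6
  ratio <- mean(cpm["gene0003", grp == "DCM"]) /
    mean(cpm["gene0003", grp == "HS"])
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)

  # ground-truth closure holds exactly on the generating means
  mu_ratio <- rowMeans(sim$truth$mu[, grp == "DCM"]) /
    rowMeans(sim$truth$mu[, grp == "HS"])
  lib_ratio <- mean(sim$truth$library_sizes[grp == "DCM"]) /
    mean(sim$truth$library_sizes[grp == "HS"])
  expect_equal(unname(mu_ratio["gene0003"] /
                        mu_ratio["gene0005"]), 2, tolerance = 1e-10)
})

test_that("negative-binomial moments match the mu/phi parameterization", {
  phi <- 0.15
  sim <- simulate_counts(
    n_genes = 5, n_per_group = 1500,
    baseline_log2_mean_range = c(7, 7), dispersion = phi,
    batch_shift = c(A = 0), batch_assignment = rep("A", 3000),
    seed = 11)
  grp <- sim$metadata$group == "HS"
  for (g in rownames(sim$counts)) {
    x <- as.numeric(sim$counts[g, grp])
    mu <- sim$truth$mu[g, grp]
    # law of total variance: NB noise around each sample's mu, plus the
    # spread of mu itself induced by the log-normal library sizes
    expected_var <- mean(mu + phi * mu^2) + var(mu)
    s2 <- var(x)
    n <- length(x)
    # Monte-Carlo SE of the sample variance from empirical fourth moments
    m4 <- mean((x - mean(x))^4)
    se <- sqrt((m4 - s2^2) / n)
    expect_lt(abs(s2 - expected_var), 3 * se + 0.05 * expected_var)
  }
})

test_that("clinical covariates are monotone in their source gene", {
  sim <- simulate_counts(n_genes = 30, n_per_group = 10,
                         baseline_log2_mean_range = c(5, 8), seed = 3)
  expr <- cpm_log2(sim$counts)
  up <- generate_clinical(expr, data.frame(
    covariate = "lvedd", gene = "gene0001", slope = 2, noise_sd = 0),
    seed = 1)
  expect_equal(spearman_test(up$lvedd, expr["gene0001", ])$rho, 1)
  dn <- generate_clinical(expr, data.frame(
    covariate = "lvedd", gene = "gene0001", slope = -2, noise_sd = 0),
    seed = 1)
  expect_equal(spearman_test(dn$lvedd, expr["gene0001", ])$rho, -1)
})

test_that("heavy link noise attenuates the correlation", {
  sim <- simulate_counts(n_genes = 10, n_per_group = 100,
                         baseline_log2_mean_range = c(6, 8), seed = 5)
  expr <- cpm_log2(sim$counts)
  g <- "gene0002"
  noisy <- generate_clinical(expr, data.frame(
    covariate = "x", gene = g, slope = 1,
    noise_sd = 10 * sd(expr[g, ])), seed = 9)
  expect_lt(abs(spearman_test(noisy$x, expr[g, ])$rho), 0.3)
})

test_that("invalid simulation requests are rejected", {
  expect_error(simulate_counts(n_genes = 10, n_per_group = 1), "n_per_group")
  expect_error(simulate_counts(n_genes = 10, n_per_group = 3,
                               dispersion = -1), "dispersion")
  expect_error(
    simulate_counts(n_genes = 10, n_per_group = 3,
                    planted_de = data.frame(gene = "nope", log2fc = 1)),
    "universe")
  expect_error(
    simulate_counts(n_genes = 10, n_per_group = 3,
                    planted_de = data.frame(gene = rep("gene0001", 2),
                                            log2fc = c(1, 2))),
    "duplicate")
  expect_error(
    generate_clinical(matrix(0, 2, 2, dimnames = list(c("a", "b"), NULL)),
                      data.frame(covariate = "x", gene = "zz", slope = 1,
                                 noise_sd = 0)),
    "unknown gene")
})
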