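mk_expr <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  m
}

test_that("pure training data yields a single leaf", {
  expr <- mk_expr(g1 = c(1, 2, 3))
  t <- fit_tree(expr, rep("DCM", 3), "g1")
  expect_equal(t$type, "leaf")
  expect_equal(t$label, "DCM")
})

test_that("the stable criterion places the max-margin quantized threshold", {
  expr <- mk_expr(g1 = c(1, 2, 6, 8))
  t <- fit_tree(expr, c("DCM", "DCM", "HS", "HS"), "g1",
                criterion = "stable")
  expect_equal(t$type, "node")
  expect_equal(t$threshold, 4.0)     # midpoint of the 2..6 gap, on-grid
  expect_equal(t$left$label, "DCM")
  expect_equal(t$right$label, "HS")

  # off-grid gap falls back to the exact midpoint
  expr2 <- mk_expr(g1 = c(1.0, 1.1, 1.3, 1.4))
  t2 <- fit_tree(expr2, c("DCM", "DCM", "HS", "HS"), "g1")
  expect_equal(t2$threshold, 1.2)
})

test_that("gain ties break by stability-prior frequency", {
  # both genes separate perfectly; prior prefers g1 even though g2 comes
  # first in candidate order and has the wider margin
  expr <- mk_expr(g2 = c(0, 1, 9, 10), g1 = c(1, 2, 6, 8))
  labels <- c("DCM", "DCM", "HS", "HS")
  prior <- c(g1 = 1.0, g2 = 0.8)
  t <- fit_tree(expr, labels, c("g2", "g1"), criterion = "stable",
                stability_prior = prior)
  expect_equal(t$gene, "g1")
  # without a prior the standard criterion takes the first candidate
  t2 <- fit_tree(expr, labels, c("g2", "g1"), criterion = "standard")
  expect_equal(t2$gene, "g2")
})

test_that("prediction descends with an inclusive left boundary", {
  expr <- mk_expr(g1 = c(1, 2, 6, 8))
  t <- fit_tree(expr, c("DCM", "DCM", "HS", "HS"), "g1")
  expect_equal(predict(t, c(g1 = 4.0)), "DCM")     # boundary goes left
  expect_equal(predict(t, c(g1 = 4.0001)), "HS")
  expect_error(predict(t, c(other = 1)), "no value")

  leaf <- fit_tree(expr, rep("HS", 4), "g1")
  expect_equal(predict(leaf, c(g1 = -99)), "HS")
})

test_that("specialization has the collapse semantics, checked by brute force", {
  leafD <- list(type = "leaf", label = "DCM", support = list(DCM = 3, HS = 0))
  leafH <- list(type = "leaf", label = "HS", support = list(DCM = 0, HS = 4))
  coarse <- structure(list(type = "node", gene = "g1", threshold = 2,
                           left = leafD, right = leafH), class = "dcm_tree")
  refined <- coarse
  refined$right <- list(type = "node", gene = "g2", threshold = 5,
                        left = list(type = "leaf", label = "HS",
                                    support = list(DCM = 1, HS = 4)),
                        right = list(type = "leaf", label = "DCM",
                                     support = list(DCM = 2, HS = 1)))

  expect_true(is_specialization(coarse, coarse))        # reflexive
  expect_true(is_specialization(refined, coarse))       # single collapse
  expect_false(is_specialization(coarse, refined))
  other <- coarse; other$gene <- "g9"
  expect_false(is_specialization(other, coarse))

  set.seed(31)
  for (i in 1:100) {
    a <- random_tree(c("g1", "g2", "g3"), depth = 3)
    b <- random_tree(c("g1", "g2", "g3"), depth = 3)
    expect_equal(is_specialization(a, b), specialization_oracle(a, b),
                 info = paste("pair", i))
  }
})

test_that("the census partitions trees and finds specialization edges", {
  leafD <- list(type = "leaf", label = "DCM", support = list(DCM = 5, HS = 0))
  leafH <- list(type = "leaf", label = "HS", support = list(DCM = 0, HS = 5))
  base <- structure(list(type = "node", gene = "g1", threshold = 3,
                         left = leafD, right = leafH), class = "dcm_tree")
  refined <- base
  refined$left <- list(type = "node", gene = "g2", threshold = 1,
                       left = list(type = "leaf", label = "DCM",
                                   support = list(DCM = 4, HS = 0)),
                       right = list(type = "leaf", label = "DCM",
                                    support = list(DCM = 1, HS = 0)))

  cen <- tree_census(c(rep(list(base), 21), list(refined)))
  expect_equal(cen$n_types, 2)
  expect_equal(sort(cen$sizes), c(1, 21))
  expect_equal(nrow(cen$specializations), 1)
  expect_true(is_specialization(cen$representatives[[cen$specializations$fine]],
                                cen$representatives[[cen$specializations$coarse]]))

  uniform <- tree_census(rep(list(base), 22))
  expect_equal(uniform$n_types, 1)
  expect_equal(nrow(uniform$specializations), 0)

  set.seed(77)
  distinct <- lapply(1:6, function(i) {
    t <- base; t$gene <- paste0("gg", i); t$threshold <- i * 2 + 0.25; t
  })
  cen2 <- tree_census(distinct)
  expect_equal(cen2$n_types, 6)
  expect_equal(nrow(cen2$specializations), 0)
})

test_that("trees round-trip through JSON with full threshold precision", {
  set.seed(5)
  for (i in 1:100) {
    t <- random_tree(sprintf("g%d", 1:4), depth = sample(1:4, 1))
    # perturb thresholds off-grid to exercise precision
    jitter <- function(n) {
      if (n$type == "leaf") return(n)
      n$threshold <- n$threshold + runif(1, -1e-3, 1e-3)
      n$left <- jitter(n$left); n$right <- jitter(n$right); n
    }
    t <- jitter(t)
    back <- parse_tree(serialize_tree(t))
    expect_true(tree_equal(t, back, tol = 0))
  }
  leaf <- structure(list(type = "leaf", label = "HS",
                         support = list(DCM = 0, HS = 2)),
                    class = "dcm_tree")
  expect_true(tree_equal(parse_tree(serialize_tree(leaf)), leaf))
  expect_error(parse_tree('{"type": "node", "gene": "g"}'), "malformed")
})

test_that("standard root splits attain the exhaustive best Gini gain", {
  root_gain <- function(expr, y, tree) {
    if (tree$type == "leaf") return(0)
    n <- length(y)
    g <- function(lab) {
      if (!length(lab)) return(0)
      tab <- table(lab); 1 - sum((tab / length(lab))^2)
    }
    l <- expr[tree$gene, ] <= tree$threshold
    g(y) - (sum(l) * g(y[l]) + sum(!l) * g(y[!l])) / n
  }
  set.seed(19)
  for (i in 1:100) {
    n <- sample(4:8, 1)
    ng <- sample(1:4, 1)
    expr <- matrix(sample(1:6, n * ng, replace = TRUE), ng, n,
                   dimnames = list(sprintf("g%d", seq_len(ng)),
                                   sprintf("s%d", seq_len(n))))
    y <- sample(c("DCM", "HS"), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- setdiff(c("DCM", "HS"), y[1])
    t <- fit_tree(expr, y, rownames(expr), criterion = "standard",
                  max_depth = 1, min_leaf = 1)
    expect_equal(root_gain(expr, y, t),
                 best_gain_oracle(expr, y, min_leaf = 1),
                 tolerance = 1e-10, info = paste("dataset", i))
  }
})
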