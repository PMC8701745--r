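# Independent brute-force oracles used across the suite.  Each one is a
# from-first-principles implementation kept deliberately separate from the
# package code paths it checks.

# Benjamini-Hochberg step-up by the textbook definition: for each p(i) the
# minimum over j >= i of m * p(j) / j, clipped at 1, mapped back to input
# order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# upper-tail hypergeometric by direct combinatorial summation
hyper_oracle <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# all permutations of 1..n by Heap's algorithm (different machinery from the
# package's recursive generator)
heap_perms <- function(n) {
  a <- seq_len(n)
  out <- matrix(0L, factorial(n), n)
  row <- 0L
  c_ <- integer(n)
  row <- row + 1L; out[row, ] <- a
  i <- 1L
  while (i <= n) {
    if (c_[i] < i - 1L) {
      if (i %% 2L == 1L) a[c(1L, i)] <- a[c(i, 1L)]
      else { j <- c_[i] + 1L; a[c(j, i)] <- a[c(i, j)] }
      row <- row + 1L; out[row, ] <- a
      c_[i] <- c_[i] + 1L
      i <- 1L
    } else { c_[i] <- 0L; i <- i + 1L }
  }
  out
}

# exact two-sided Spearman p for tie-free data via the closed form
# rho = 1 - 6 sum(d^2) / (n (n^2 - 1)) over every permutation
spearman_oracle <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_of <- function(r) 1 - 6 * sum((rx - r)^2) / (n * (n^2 - 1))
  obs <- rho_of(ry)
  P <- heap_perms(n)
  Ry <- matrix(ry[P], nrow(P), n)
  D2 <- rowSums((Ry - matrix(rx, nrow(P), n, byrow = TRUE))^2)
  rhos <- 1 - 6 * D2 / (n * (n^2 - 1))
  list(rho = obs, p = mean(abs(rhos) >= abs(obs) - 1e-12))
}

# exhaustive best Gini gain over all (gene, threshold) axis-aligned splits
best_gain_oracle <- function(X, y, min_leaf = 1) {
  g <- function(lab) {
    if (!length(lab)) return(0)
    p <- mean(lab == lab[1]); tab <- table(lab)
    1 - sum((tab / length(lab))^2)
  }
  n <- length(y)
  g0 <- g(y)
  best <- 0
  for (i in seq_len(nrow(X))) {
    v <- sort(unique(X[i, ]))
    if (length(v) < 2) next
    for (t in (v[-1] + v[-length(v)]) / 2) {
      l <- X[i, ] <= t
      if (sum(l) < min_leaf || sum(!l) < min_leaf) next
      gain <- g0 - (sum(l) * g(y[l]) + sum(!l) * g(y[!l])) / n
      if (gain > best) best <- gain
    }
  }
  best
}

# --- tree helpers ---------------------------------------------------------

# random binary tree over the given genes with integer-ish thresholds
random_tree <- function(genes, depth, labels = c("DCM", "HS"),
                        p_leaf = 0.35) {
  build <- function(d) {
    if (d >= depth || stats::runif(1) < p_leaf) {
      sup <- as.list(stats::setNames(sample(0:5, 2), labels))
      lab <- sample(labels, 1)
      return(list(type = "leaf", label = lab, support = sup))
    }
    list(type = "node",
         gene = sample(genes, 1),
         threshold = sample(seq(0, 10, by = 0.5), 1),
         left = build(d + 1), right = build(d + 1))
  }
  t <- build(0)
  if (t$type == "leaf")  # ensure at least one split for interesting cases
    t <- list(type = "node", gene = sample(genes, 1),
              threshold = sample(seq(0, 10, by = 0.5), 1),
              left = build(depth), right = build(depth))
  structure(t, class = "dcm_tree")
}

tree_internal_count <- function(node) {
  if (node$type == "leaf") return(0L)
  1L + tree_internal_count(node$left) + tree_internal_count(node$right)
}

# brute-force specialization: enumerate every subset of internal nodes of
# t_fine (preorder-indexed), collapse each chosen subtree to its
# support-majority leaf, and compare node-for-node with t_coarse
specialization_oracle <- function(t_fine, t_coarse, tol = 1e-9) {
  support_tally <- function(n) {
    if (n$type == "leaf") return(unlist(n$support))
    support_tally(n$left) + support_tally(n$right)
  }
  collapse <- function(node, chosen, counter) {
    # counter: environment holding the preorder index
    if (node$type == "leaf") return(node)
    counter$i <- counter$i + 1L
    me <- counter$i
    l <- collapse(node$left, chosen, counter)
    r <- collapse(node$right, chosen, counter)
    if (me %in% chosen) {
      sup <- support_tally(node)
      if (max(sup) * 2 == sum(sup)) return(NULL)   # uncollapsible
      return(list(type = "leaf", label = names(sup)[which.max(sup)],
                  support = as.list(sup)))
    }
    if (is.null(l) || is.null(r)) return(NULL)
    list(type = "node", gene = node$gene, threshold = node$threshold,
         left = l, right = r)
  }
  same <- function(a, b) {
    if (a$type != b$type) return(FALSE)
    if (a$type == "leaf") return(a$label == b$label)
    a$gene == b$gene && abs(a$threshold - b$threshold) <= tol &&
      same(a$left, b$left) && same(a$right, b$right)
  }
  m <- tree_internal_count(t_fine)
  for (bits in 0:(2^m - 1)) {
    chosen <- which(bitwAnd(bits, 2^(0:(max(m, 1) - 1))) > 0)
    counter <- new.env(); counter$i <- 0L
    collapsed <- collapse(t_fine, chosen, counter)
    if (!is.null(collapsed) && same(collapsed, t_coarse)) return(TRUE)
  }
  FALSE
}

# small fixture: write the printed NPPA interaction scores as an edge list
nppa_fixture_path <- function() {
  system.file("extdata", "nppa_string_edges.tsv", package = "dcmpanel")
}
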