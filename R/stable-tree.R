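#' Fit a binary axis-aligned decision tree
#'
#' Recursive partitioning on gene expression maximizing Gini impurity
#' decrease, with two splitting criteria:
#'
#' \describe{
#'   \item{standard}{textbook CART behaviour: candidate thresholds at every
#'     adjacent-value midpoint, ties in gain broken by candidate order
#'     (gene order as supplied, thresholds ascending).  Deliberately
#'     order-sensitive; small training-set changes readily move the chosen
#'     split.}
#'   \item{stable}{a stability-oriented criterion.  For each gene the
#'     optimal partition is found as usual, but the threshold is placed
#'     inside the widest gap consistent with that partition (max margin)
#'     and snapped to a coarse grid (multiples of \code{quantum}, default
#'     0.5 log2 units) — the grid point inside the gap closest to the gap
#'     midpoint, falling back to the exact midpoint when the gap contains
#'     no grid point.  Ties in gain across genes break by higher
#'     \code{stability_prior} frequency, then lexicographic gene id —
#'     deliberately fold-invariant quantities, so independently trained
#'     folds agree on the tested gene.  Quantization makes the threshold
#'     invariant
#'     to single-sample perturbations whenever the decision gap is wide,
#'     which is what lets independently trained folds agree node-for-node.}
#' }
#'
#' A node becomes a leaf when pure, at \code{max_depth}, with fewer than
#' \code{2 * min_leaf} samples, or when no admissible split improves the
#' impurity.  Leaf labels are the majority class; exact ties go to the
#' first class level (DCM in the standard labelling).
#'
#' @param expr expression matrix, genes x samples (training samples only).
#' @param labels class label per sample (two classes).
#' @param candidate_genes genes the tree may test; must be rows of
#'   \code{expr}.
#' @param criterion \code{"stable"} or \code{"standard"}.
#' @param stability_prior optional named numeric vector of cross-fold
#'   appearance frequencies used for tie-breaking under the stable
#'   criterion.
#' @param max_depth maximum tree depth (root = depth 0).
#' @param min_leaf minimum samples per leaf.
#' @param quantum threshold grid step for the stable criterion.
#' @return an object of class \code{dcm_tree}: nested list of internal
#'   nodes (\code{gene}, \code{threshold}, \code{left}, \code{right};
#'   left = values <= threshold) and leaves (\code{label},
#'   \code{support}).
#' @export
fit_tree <- function(expr, labels, candidate_genes,
                     criterion = c("stable", "standard"),
                     stability_prior = NULL,
                     max_depth = 3L, min_leaf = 2L, quantum = 0.5) {
  criterion <- match.arg(criterion)
  if (!length(candidate_genes)) stop("fit_tree: empty candidate gene set")
  if (!all(candidate_genes %in% rownames(expr)))
    stop("fit_tree: candidate genes missing from expression matrix")
  labels <- as.character(labels)
  classes <- if (all(c("DCM", "HS") %in% labels)) c("DCM", "HS")
             else sort(unique(labels))
  if (length(classes) > 2) stop("fit_tree: two classes required")
  if (length(classes) == 1) classes <- c(classes, ".none")
  X <- expr[candidate_genes, , drop = FALSE]

  prior_of <- function(g) {
    if (is.null(stability_prior)) return(0)
    v <- stability_prior[g]
    if (is.na(v)) 0 else unname(v)
  }

  gini <- function(y) {
    n <- length(y)
    if (!n) return(0)
    p <- sum(y == classes[1]) / n
    2 * p * (1 - p)
  }

  leaf_of <- function(y) {
    sup <- c(sum(y == classes[1]), sum(y == classes[2]))
    names(sup) <- classes
    lab <- if (sup[2] > sup[1]) classes[2] else classes[1]
    list(type = "leaf", label = lab, support = as.list(sup))
  }

  # best split for one gene on the node's samples; returns NULL or a list
  # with gain, threshold, margin, left index mask
  best_split_gene <- function(g, idx, y) {
    v <- unname(X[g, idx])
    ord <- order(v)
    vs <- v[ord]; ys <- y[ord]
    n <- length(vs)
    uniq_cut <- which(diff(vs) > 0)       # split after position i
    if (!length(uniq_cut)) return(NULL)
    g0 <- gini(y)
    best <- NULL
    for (i in uniq_cut) {
      nl <- i; nr <- n - i
      if (nl < min_leaf || nr < min_leaf) next
      gain <- g0 - (nl * gini(ys[seq_len(i)]) +
                    nr * gini(ys[(i + 1):n])) / n
      if (gain <= 1e-12) next
      gap <- vs[i + 1] - vs[i]
      better <- is.null(best) ||
        gain > best$gain + 1e-12 ||
        (criterion == "stable" && abs(gain - best$gain) <= 1e-12 &&
           gap > best$margin + 1e-12)
      if (better)
        best <- list(gain = gain, lo = vs[i], hi = vs[i + 1],
                     margin = gap, nl = nl)
    }
    if (is.null(best)) return(NULL)
    if (criterion == "stable") {
      best$threshold <- .quantized_midpoint(best$lo, best$hi, quantum)
    } else {
      best$threshold <- (best$lo + best$hi) / 2
    }
    best$gene <- g
    best
  }

  grow <- function(idx, depth) {
    y <- labels[idx]
    if (length(unique(y)) == 1 || depth >= max_depth ||
        length(idx) < 2 * min_leaf)
      return(leaf_of(y))
    best <- NULL
    for (g in candidate_genes) {
      s <- best_split_gene(g, idx, y)
      if (is.null(s)) next
      if (is.null(best)) { best <- s; next }
      if (s$gain > best$gain + 1e-12) { best <- s; next }
      if (criterion == "stable" && abs(s$gain - best$gain) <= 1e-12) {
        # ties: higher prior frequency, then lexicographic gene id — both
        # invariant to which sample a fold holds out; a data-derived
        # quantity (e.g. the margin) here would re-introduce instability
        if (prior_of(s$gene) > prior_of(best$gene) + 1e-12 ||
            (abs(prior_of(s$gene) - prior_of(best$gene)) <= 1e-12 &&
               s$gene < best$gene))
          best <- s
      }
      # standard: first encountered (candidate order) wins, nothing to do
    }
    if (is.null(best)) return(leaf_of(y))
    go_left <- X[best$gene, idx] <= best$threshold
    list(type = "node",
         gene = best$gene,
         threshold = best$threshold,
         left = grow(idx[go_left], depth + 1L),
         right = grow(idx[!go_left], depth + 1L))
  }

  tree <- grow(seq_len(ncol(X)), 0L)
  structure(tree, class = "dcm_tree",
            classes = classes, criterion = criterion)
}

# grid point (multiple of quantum) strictly inside (lo, hi) closest to the
# midpoint, ties toward the lower point; exact midpoint when none exists
.quantized_midpoint <- function(lo, hi, quantum) {
  mid <- (lo + hi) / 2
  if (quantum <= 0) return(mid)
  cand <- seq(ceiling(lo / quantum + 1e-9),
              floor(hi / quantum - 1e-9)) * quantum
  cand <- cand[cand > lo & cand < hi]
  if (!length(cand)) return(mid)
  cand[which.min(abs(cand - mid))]
}

#' Predict the class of a sample from a fitted tree
#'
#' Deterministic root-to-leaf descent; a value equal to the threshold goes
#' left.
#'
#' @param object a \code{dcm_tree}.
#' @param newdata named numeric vector of expression values (or a one-column
#'   slice of an expression matrix) covering every gene the tree tests.
#' @param ... unused.
#' @return the predicted class label.
#' @export
predict.dcm_tree <- function(object, newdata, ...) {
  node <- object
  while (node$type == "node") {
    v <- newdata[node$gene]
    if (is.null(v) || is.na(v))
      stop("predict: no value for gene '", node$gene, "'")
    node <- if (v <= node$threshold) node$left else node$right
  }
  node$label
}

#' @export
print.dcm_tree <- function(x, ...) {
  rec <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(pad, "leaf: ", node$label, " (",
          paste(names(node$support), unlist(node$support),
                sep = "=", collapse = ", "), ")\n", sep = "")
    } else {
      cat(pad, node$gene, " <= ", format(node$threshold), "\n", sep = "")
      rec(node$left, indent + 1)
      rec(node$right, indent + 1)
    }
  }
  cat("decision tree (criterion: ",
      attr(x, "criterion") %||% "?", ")\n", sep = "")
  rec(x, 0)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Node-for-node tree equality
#'
#' Identical structure, tested genes, leaf labels, and thresholds equal
#' within an absolute tolerance.
#'
#' @param a,b trees.
#' @param tol absolute threshold tolerance.
#' @return logical.
#' @export
tree_equal <- function(a, b, tol = 1e-9) {
  if (a$type != b$type) return(FALSE)
  if (a$type == "leaf") return(a$label == b$label)
  a$gene == b$gene &&
    abs(a$threshold - b$threshold) <= tol &&
    tree_equal(a$left, b$left, tol) &&
    tree_equal(a$right, b$right, tol)
}

# majority label of a subtree weighted by training support; NA when no
# strict majority
.subtree_majority <- function(node) {
  tally <- function(n) {
    if (n$type == "leaf") return(unlist(n$support))
    tally(n$left) + tally(n$right)
  }
  sup <- tally(node)
  if (max(sup) * 2 == sum(sup)) return(NA_character_)
  names(sup)[which.max(sup)]
}

#' Is one tree a specialization of another?
#'
#' \code{t_fine} specializes \code{t_coarse} when collapsing some of its
#' subtrees to leaves — each labelled with the subtree's strict-majority
#' leaf label, weighted by training support — yields a tree node-for-node
#' identical to \code{t_coarse}.  A subtree without a strict majority
#' cannot be collapsed.  Equality counts as (trivial) specialization.
#'
#' @param t_fine the candidate refinement.
#' @param t_coarse the candidate coarsening.
#' @param tol threshold tolerance.
#' @return logical.
#' @export
is_specialization <- function(t_fine, t_coarse, tol = 1e-9) {
  rec <- function(f, c) {
    if (c$type == "leaf") {
      if (f$type == "leaf") return(f$label == c$label)
      maj <- .subtree_majority(f)
      return(!is.na(maj) && maj == c$label)
    }
    if (f$type != "node") return(FALSE)
    f$gene == c$gene &&
      abs(f$threshold - c$threshold) <= tol &&
      rec(f$left, c$left) && rec(f$right, c$right)
  }
  rec(t_fine, t_coarse)
}

#' Census of tree equality classes and specialization relations
#'
#' Partitions a collection of trees (typically the per-fold trees of a
#' leave-one-out run) into node-for-node equality classes and records every
#' specialization relation between distinct class representatives.
#'
#' @param trees list of \code{dcm_tree} objects.
#' @param tol threshold tolerance for equality.
#' @return list with \code{n_types} (number of equality classes),
#'   \code{class_of} (class index per input tree), \code{representatives}
#'   (one tree per class, first occurrence), \code{sizes}, and
#'   \code{specializations} — data.frame of (fine, coarse) class index
#'   pairs where class \code{fine} specializes class \code{coarse},
#'   excluding the trivial self-pairs.
#' @export
tree_census <- function(trees, tol = 1e-9) {
  if (!length(trees)) stop("tree_census: no trees")
  reps <- list()
  class_of <- integer(length(trees))
  for (i in seq_along(trees)) {
    hit <- 0L
    for (j in seq_along(reps))
      if (tree_equal(trees[[i]], reps[[j]], tol)) { hit <- j; break }
    if (!hit) { reps[[length(reps) + 1L]] <- trees[[i]]; hit <- length(reps) }
    class_of[i] <- hit
  }
  k <- length(reps)
  edges <- NULL
  if (k > 1) {
    for (a in seq_len(k)) for (b in seq_len(k)) {
      if (a != b && is_specialization(reps[[a]], reps[[b]], tol))
        edges <- rbind(edges, data.frame(fine = a, coarse = b))
    }
  }
  if (is.null(edges)) edges <- data.frame(fine = integer(0),
                                          coarse = integer(0))
  list(n_types = k,
       class_of = class_of,
       representatives = reps,
       sizes = tabulate(class_of, k),
       specializations = edges)
}

#' Serialize a decision tree to JSON
#'
#' Thresholds are printed as full-precision decimal strings so that
#' \code{parse_tree(serialize_tree(t))} reproduces the tree exactly.
#'
#' @param tree a \code{dcm_tree}.
#' @return a JSON string.
#' @export
serialize_tree <- function(tree) {
  enc <- function(node) {
    if (node$type == "leaf")
      list(type = "leaf", label = node$label, support = node$support)
    else
      list(type = "node", gene = node$gene,
           threshold = format(node$threshold, digits = 17),
           left = enc(node$left), right = enc(node$right))
  }
  as.character(jsonlite::toJSON(enc(tree), auto_unbox = TRUE))
}

#' Parse a decision tree from JSON
#'
#' @param text JSON produced by [serialize_tree()].
#' @return a \code{dcm_tree}.
#' @export
parse_tree <- function(text) {
  obj <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  dec <- function(o, path) {
    if (is.null(o$type))
      stop("parse_tree: missing 'type' at ", path)
    if (o$type == "leaf") {
      if (is.null(o$label) || is.null(o$support))
        stop("parse_tree: malformed leaf at ", path)
      list(type = "leaf", label = o$label,
           support = lapply(o$support, as.numeric))
    } else if (o$type == "node") {
      if (is.null(o$gene) || is.null(o$threshold))
        stop("parse_tree: malformed node at ", path)
      list(type = "node", gene = o$gene,
           threshold = as.numeric(o$threshold),
           left = dec(o$left, paste0(path, "/left")),
           right = dec(o$right, paste0(path, "/right")))
    } else stop("parse_tree: unknown node type at ", path)
  }
  structure(dec(obj, "$"), class = "dcm_tree")
}
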