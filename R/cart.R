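## Minimal CART for numeric predictors (Gini impurity, unpruned).
##
## Internal engine behind the bagged classifier. Trees are grown to purity
## (subject to minsplit/minbucket/max_depth), splits chosen by maximal
## Gini decrease with random tie-breaking among equal-gain predictors, and
## per-predictor importance accumulated as node-weighted impurity decrease
## (the CART convention). Kept dependency-free and fast enough for
## permutation suites: labels are integers, split search is one cumsum per
## class over radix-sorted values.

gini_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

# Best split over presorted column values; returns c(gain, thresh) or NULL.
best_split_sorted <- function(xs, ys, K, parent_gini, minbucket) {
  n <- length(xs)
  pos <- which(xs[-1] > xs[-n])
  pos <- pos[pos >= minbucket & (n - pos) >= minbucket]
  if (!length(pos)) return(NULL)
  nl <- pos
  nr <- n - pos
  suml <- numeric(length(pos))
  sumr <- numeric(length(pos))
  for (k in seq_len(K)) {
    ck <- cumsum(ys == k)
    tk <- ck[n]
    ckp <- ck[pos]
    suml <- suml + ckp * ckp
    sumr <- sumr + (tk - ckp)^2
  }
  child <- (nl * (1 - suml / (nl * nl)) + nr * (1 - sumr / (nr * nr))) / n
  j <- which.min(child)
  c(parent_gini - child[j], (xs[pos[j]] + xs[pos[j] + 1]) / 2)
}

cart_fit <- function(X, y, minsplit = 2L, minbucket = 1L, max_depth = 30L) {
  stopifnot(is.matrix(X), is.factor(y), nrow(X) == length(y))
  p <- ncol(X)
  K <- nlevels(y)
  yi <- as.integer(y)
  n_total <- nrow(X)
  importance <- stats::setNames(numeric(p), colnames(X))
  ## presort every column once; nodes filter the sorted orders by membership
  ord <- lapply(seq_len(p), function(j) order(X[, j]))
  inmask <- logical(n_total)
  nodes <- list()
  grow <- function(idx, depth) {
    counts <- tabulate(yi[idx], K)
    g <- gini_counts(counts)
    make_leaf <- function() {
      list(leaf = TRUE, pred = which.max(counts), counts = counts)
    }
    if (g <= 0 || length(idx) < minsplit || depth >= max_depth) {
      nodes[[length(nodes) + 1L]] <<- make_leaf()
      return(length(nodes))
    }
    gains <- rep(-Inf, p)
    thresh <- numeric(p)
    inmask[idx] <<- TRUE
    for (j in seq_len(p)) {
      oj <- ord[[j]]
      os <- oj[inmask[oj]]
      s <- best_split_sorted(X[os, j], yi[os], K, g, minbucket)
      if (!is.null(s)) { gains[j] <- s[1]; thresh[j] <- s[2] }
    }
    inmask[idx] <<- FALSE
    if (all(!is.finite(gains)) || max(gains) <= 1e-12) {
      nodes[[length(nodes) + 1L]] <<- make_leaf()
      return(length(nodes))
    }
    tied <- which(gains >= max(gains) - 1e-12)
    j <- if (length(tied) > 1L) tied[sample.int(length(tied), 1L)] else tied
    importance[j] <<- importance[j] + (length(idx) / n_total) * gains[j]
    go_left <- X[idx, j] <= thresh[j]
    li <- grow(idx[go_left], depth + 1L)
    ri <- grow(idx[!go_left], depth + 1L)
    nodes[[length(nodes) + 1L]] <<- list(leaf = FALSE, var = j,
                                         thresh = thresh[j],
                                         left = li, right = ri)
    length(nodes)
  }
  root <- grow(seq_len(n_total), 0L)
  structure(list(nodes = nodes, root = root, importance = importance,
                 classes = levels(y), vars = colnames(X)),
            class = "cart_tree")
}

cart_predict <- function(tree, X) {
  stopifnot(is.matrix(X))
  out <- integer(nrow(X))
  route <- function(node_id, idx) {
    nd <- tree$nodes[[node_id]]
    if (nd$leaf) { out[idx] <<- nd$pred; return(invisible()) }
    go_left <- X[idx, nd$var] <= nd$thresh
    if (any(go_left)) route(nd$left, idx[go_left])
    if (any(!go_left)) route(nd$right, idx[!go_left])
  }
  route(tree$root, seq_len(nrow(X)))
  out
}
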