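# Independent oracles: a brute-force exhaustive split scan and a plain R
# recursive variance-criterion regression forest. These deliberately share no
# code with the package's C++ learner; costs are computed with the direct
# centred-deviation formula.

oracle_cost <- function(Y, lambda) {
  Y <- as.matrix(Y)
  ctr <- sweep(Y, 2, colMeans(Y))
  sum(diag(ctr %*% as.matrix(lambda) %*% t(ctr)))
}

# Exhaustive scan over every (feature, midpoint-threshold) pair; same
# tie-break (lowest feature, lowest threshold) and strict-gain rule as the
# learner contract. Returns NULL for no-split.
oracle_best_split <- function(X, Y, lambda, min_leaf = 2) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  parent <- oracle_cost(Y, lambda)
  best <- NULL
  best_cost <- Inf
  tie_eps <- 1e-9 * max(1, parent) # contract: ties keep the earliest candidate
  for (f in seq_len(ncol(X))) {
    vals <- sort(unique(X[, f]))
    if (length(vals) < 2) next
    thrs <- (vals[-length(vals)] + vals[-1]) / 2
    for (thr in thrs) {
      left <- X[, f] <= thr
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      tot <- oracle_cost(Y[left, , drop = FALSE], lambda) +
        oracle_cost(Y[!left, , drop = FALSE], lambda)
      if (tot < best_cost - tie_eps) {
        best_cost <- tot
        best <- list(feature = f, threshold = thr, cost_children = tot)
      }
    }
  }
  if (is.null(best)) {
    return(NULL)
  }
  if (!(parent - best$cost_children > 1e-12 * max(1, parent))) {
    return(NULL)
  }
  best
}

# Univariate variance-criterion tree grown recursively; no feature
# subsampling (use with dsr = 1 fits only).
oracle_uni_tree <- function(X, y, max_depth, min_leaf = 2) {
  grow <- function(rows, depth) {
    node <- list(
      n = length(rows), mean = mean(y[rows]),
      feature = NA_integer_, threshold = NA_real_
    )
    if (depth >= max_depth || length(rows) < 2 * min_leaf) {
      return(node)
    }
    sp <- oracle_best_split(X[rows, , drop = FALSE],
      matrix(y[rows], ncol = 1), matrix(1),
      min_leaf = min_leaf
    )
    if (is.null(sp)) {
      return(node)
    }
    node$feature <- sp$feature
    node$threshold <- sp$threshold
    left <- rows[X[rows, sp$feature] <= sp$threshold]
    right <- setdiff(rows, left)
    node$left <- grow(left, depth + 1)
    node$right <- grow(right, depth + 1)
    node
  }
  grow(seq_along(y), 0)
}

oracle_tree_predict <- function(tree, X) {
  apply(X, 1, function(x) {
    nd <- tree
    while (!is.na(nd$feature)) {
      nd <- if (x[nd$feature] <= nd$threshold) nd$left else nd$right
    }
    nd$mean
  })
}

# Univariate forest drawing its bootstrap indices with the same R RNG
# sequence as mahal_forest(): set.seed(seed) then one sample.int() call.
oracle_uni_forest <- function(X, y, trees, max_depth, min_leaf = 2, seed = 1,
                              bootstrap = TRUE) {
  n <- nrow(X)
  set.seed(as.integer(seed))
  boot <- if (bootstrap) {
    matrix(sample.int(n, n * trees, replace = TRUE), nrow = n)
  } else {
    matrix(rep(seq_len(n), trees), nrow = n)
  }
  fits <- lapply(seq_len(trees), function(t) {
    idx <- boot[, t]
    oracle_uni_tree(X[idx, , drop = FALSE], y[idx],
      max_depth = max_depth,
      min_leaf = min_leaf
    )
  })
  list(
    trees = fits,
    predict = function(Xnew) {
      rowMeans(vapply(
        fits, function(tr) oracle_tree_predict(tr, Xnew),
        numeric(nrow(Xnew))
      ))
    }
  )
}

random_pd <- function(k) {
  A <- matrix(rnorm(k * k), k)
  crossprod(A) + diag(k) * 0.1
}
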