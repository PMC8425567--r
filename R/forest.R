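# Model core: multivariate regression forests with a Mahalanobis split cost,
# feasible-GLS precision estimation, mean-decrease-impurity importance.

#' Mahalanobis leaf cost
#'
#' Cost of a set of outcome vectors under a precision matrix `lambda`:
#' `sum_i (y_i - ybar)' lambda (y_i - ybar)` with `ybar` the componentwise
#' mean. With `lambda` the inverse residual covariance this is the sum of
#' variances of the decorrelated outcomes; it is zero iff all rows are
#' identical.
#'
#' @param y Numeric matrix (rows = observations, columns = outcomes) or a
#'   vector for a single outcome.
#' @param lambda Symmetric positive-definite precision matrix (k x k), or a
#'   positive scalar when `y` has one column.
#' @return Non-negative scalar cost.
#' @export
#' @examples
#' mahalanobis_cost(matrix(c(1, 3), ncol = 1), matrix(2))
mahalanobis_cost <- function(y, lambda) {
  y <- as.matrix(y)
  if (is_scalar_number(lambda)) lambda <- matrix(lambda)
  lambda <- as.matrix(lambda)
  if (ncol(lambda) != ncol(y)) {
    abort("`lambda` dimension must match the number of outcome columns.")
  }
  stopifnot_pd(lambda, "lambda")
  ctr <- sweep(y, 2, colMeans(y))
  sum(rowSums((ctr %*% lambda) * ctr))
}

#' Identity precision matrix
#'
#' The precision used by the independent-forest baseline: outcomes are treated
#' as uncorrelated with unit weight, so the Mahalanobis cost reduces to the
#' per-dimension sum of squared errors.
#'
#' @param k Number of outcomes.
#' @return A `precision_matrix` with provenance `"identity"`.
#' @export
identity_precision <- function(k) {
  new_precision(diag(k), provenance = "identity", sigma = diag(k))
}

new_precision <- function(lambda, provenance, sigma = NULL, ridge = 0) {
  structure(lambda,
    provenance = provenance, sigma = sigma, ridge = ridge,
    class = c("precision_matrix", "matrix", "array")
  )
}

#' @export
print.precision_matrix <- function(x, ...) {
  cat(sprintf(
    "<precision_matrix> %dx%d, provenance: %s\n",
    nrow(x), ncol(x), attr(x, "provenance")
  ))
  print(unclass(structure(x, provenance = NULL, sigma = NULL, ridge = NULL)))
  invisible(x)
}

#' Feasible-GLS estimate of the outcome precision matrix
#'
#' Fits one univariate forest per outcome (same hyperparameters as the joint
#' model, scalar precision), takes training residuals `y - yhat`, estimates
#' the residual covariance as their sample covariance, and inverts it after a
#' small diagonal ridge. The ridge starts at `1e-6 * mean(diag(sigma))` and
#' doubles until the condition number falls below `1e8`, so near-collinear
#' residuals still yield a usable precision.
#'
#' @param data Data frame with no missing values in `outcomes`/`features`.
#' @param outcomes Character vector of outcome column names.
#' @param features Character vector of feature column names; default all
#'   numeric columns not in `outcomes`.
#' @param trees,max_depth,dsr,bootstrap,min_leaf Forest hyperparameters, as in
#'   [mahal_forest()].
#' @param seed Integer seed controlling the univariate forests.
#' @return A `precision_matrix` with provenance `"estimated"` and attributes
#'   `sigma` (the estimated residual covariance) and `ridge` (the diagonal
#'   inflation used).
#' @export
estimate_precision <- function(data, outcomes, features = NULL,
                               trees = 2000, max_depth = 4, dsr = 1 / 3,
                               bootstrap = TRUE, min_leaf = 2, seed = 1) {
  features <- features %||% default_features(data, outcomes)
  k <- length(outcomes)
  if (nrow(data) < k + 2) {
    abort("estimate_precision() needs at least k + 2 training rows.")
  }
  resid <- matrix(NA_real_, nrow(data), k, dimnames = list(NULL, outcomes))
  for (j in seq_len(k)) {
    fj <- mahal_forest(data, outcomes[j],
      features = features,
      lambda = matrix(1), trees = trees, max_depth = max_depth, dsr = dsr,
      bootstrap = bootstrap, min_leaf = min_leaf, seed = sub_seed(seed, j)
    )
    pj <- predict(fj, data)
    resid[, j] <- data[[outcomes[j]]] - pj[[paste0(".pred_", outcomes[j])]]
  }
  sigma <- stats::cov(resid)
  base <- mean(diag(sigma))
  # residuals that are zero up to float rounding mean a perfect in-sample fit
  if (!is.finite(base) || base <= 0 || max(abs(resid)) < 1e-12) {
    warn("All training residuals are zero; falling back to an identity-direction precision.")
    return(new_precision(diag(nrow = k),
      provenance = "estimated",
      sigma = sigma, ridge = NA_real_
    ))
  }
  delta <- 1e-6
  repeat {
    sig_r <- sigma + delta * base * diag(k)
    if (kappa(sig_r, exact = TRUE) < 1e8) break
    delta <- delta * 2
  }
  lambda <- solve(sig_r)
  lambda <- (lambda + t(lambda)) / 2
  dimnames(lambda) <- dimnames(sigma)
  new_precision(lambda,
    provenance = "estimated", sigma = sigma,
    ridge = delta * base
  )
}

default_features <- function(data, outcomes) {
  num <- names(data)[vapply(data, is.numeric, logical(1))]
  setdiff(num, outcomes)
}

#' Best Mahalanobis split of a single node
#'
#' Exhaustive scan over every feature and every midpoint between consecutive
#' distinct sorted values, minimising the summed Mahalanobis cost of the two
#' children. Ties are broken by lowest feature index, then lowest threshold.
#' Returns `NULL` when no candidate strictly reduces the cost or children
#' would fall below `min_leaf`.
#'
#' @param x Feature matrix or data frame (numeric).
#' @param y Outcome matrix (rows match `x`).
#' @param lambda Precision matrix; default identity.
#' @param min_leaf Minimum rows per child.
#' @return `NULL`, or a list with `feature` (column index), `feature_name`,
#'   `threshold`, `cost_parent`, `cost_children`.
#' @export
best_split <- function(x, y, lambda = NULL, min_leaf = 2) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  lambda <- lambda %||% diag(ncol(y))
  if (is_scalar_number(lambda)) lambda <- matrix(lambda)
  stopifnot_pd(as.matrix(lambda), "lambda")
  z <- y %*% t(chol(as.matrix(lambda)))
  res <- .best_split_cpp(x, z, as.integer(min_leaf))
  if (!res$found) {
    return(NULL)
  }
  list(
    feature = res$feature,
    feature_name = colnames(x)[res$feature] %||% NA_character_,
    threshold = res$threshold,
    cost_parent = res$cost_parent,
    cost_children = res$cost_children
  )
}

#' Fit a Mahalanobis random forest
#'
#' Grows `trees` multivariate regression trees of depth at most `max_depth`.
#' Node splits minimise the Mahalanobis cost of the children under the
#' precision matrix `lambda`; terminal nodes predict the componentwise mean of
#' the outcome vectors they contain, and the forest prediction is the
#' across-tree average. Each tree is grown on its own bootstrap resample
#' (unless `bootstrap = FALSE`) with a fresh random subset of
#' `ceiling(dsr * p)` candidate features at every node.
#'
#' With a single outcome and any positive scalar `lambda` the learner is the
#' ordinary variance-criterion regression forest: positive scaling of the
#' cost never changes an argmin.
#'
#' @param data Data frame of training rows; must contain no missing values in
#'   the modelling columns (apply [filter_missing()] first).
#' @param outcomes Character vector of outcome columns (the five prevalence
#'   rates in the survey application, but any k >= 1 works).
#' @param features Character vector of feature columns; default every numeric
#'   column not in `outcomes`.
#' @param lambda Precision matrix (k x k, symmetric positive definite), e.g.
#'   from [estimate_precision()]; default [identity_precision()], which is the
#'   independent-baseline weighting.
#' @param trees Forest size T (default 2000).
#' @param max_depth Maximum tree depth d (default 4); `max_depth = 0` gives a
#'   forest of root-only stumps.
#' @param dsr Feature downsampling rate in (0, 1], applied per node
#'   (default 1/3).
#' @param bootstrap Draw a bootstrap resample per tree (default TRUE).
#' @param min_leaf Minimum rows per leaf (default 2).
#' @param seed Integer seed; fitting is deterministic given the seed.
#' @return A `mahal_forest` object with [predict.mahal_forest()],
#'   [mdi_importance()], [tidy.mahal_forest()] and [glance.mahal_forest()]
#'   methods.
#' @export
#' @examples
#' d <- tibble::tibble(x = runif(40), y1 = x + 0.1 * rnorm(40), y2 = 1 - x)
#' f <- mahal_forest(d, c("y1", "y2"), trees = 25, seed = 1)
#' predict(f, d[1:3, ])
mahal_forest <- function(data, outcomes, features = NULL, lambda = NULL,
                         trees = 2000, max_depth = 4, dsr = 1 / 3,
                         bootstrap = TRUE, min_leaf = 2, seed = 1) {
  stopifnot(is.data.frame(data), trees >= 1, max_depth >= 0)
  if (!(dsr > 0 && dsr <= 1)) abort("`dsr` must lie in (0, 1].")
  features <- features %||% default_features(data, outcomes)
  miss_cols <- setdiff(c(outcomes, features), names(data))
  if (length(miss_cols) > 0) {
    abort(paste0("Missing columns: ", paste(miss_cols, collapse = ", ")))
  }
  X <- as.matrix(data[features])
  Y <- as.matrix(data[outcomes])
  if (anyNA(X) || anyNA(Y)) {
    abort("Training data contain missing values; run filter_missing() first.")
  }
  k <- length(outcomes)
  lambda <- lambda %||% identity_precision(k)
  if (is_scalar_number(lambda)) lambda <- matrix(lambda)
  lam <- as.matrix(lambda)
  stopifnot_pd(lam, "lambda")
  Z <- Y %*% t(chol(lam))

  n <- nrow(X)
  p <- ncol(X)
  mtry <- max(1L, as.integer(ceiling(dsr * p)))
  trees <- as.integer(trees)

  set.seed(as.integer(seed))
  boot <- if (isTRUE(bootstrap)) {
    matrix(sample.int(n, n * trees, replace = TRUE), nrow = n)
  } else {
    matrix(rep(seq_len(n), trees), nrow = n)
  }
  tree_seeds <- sample.int(.Machine$integer.max - 1L, trees, replace = TRUE)

  fit <- .fit_forest_cpp(
    X, Y, Z, boot - 1L, as.integer(max_depth),
    as.integer(min_leaf), mtry, tree_seeds
  )
  mdi_mat <- fit$mdi
  rownames(mdi_mat) <- features
  structure(
    list(
      trees = fit$trees,
      mdi = mdi_mat,
      lambda = lam,
      lambda_provenance = attr(lambda, "provenance") %||% "supplied",
      outcomes = outcomes,
      features = features,
      n_train = n,
      config = list(
        trees = trees, max_depth = as.integer(max_depth), dsr = dsr,
        bootstrap = isTRUE(bootstrap), min_leaf = as.integer(min_leaf),
        seed = as.integer(seed), mtry = mtry
      )
    ),
    class = "mahal_forest"
  )
}

#' @export
print.mahal_forest <- function(x, ...) {
  cat(sprintf(
    "<mahal_forest> %d trees (depth <= %d, dsr = %.3g), %d outcomes, %d features, n = %d\n",
    x$config$trees, x$config$max_depth, x$config$dsr,
    length(x$outcomes), length(x$features), x$n_train
  ))
  cat(sprintf("  precision: %s\n", x$lambda_provenance))
  invisible(x)
}

#' Predict from a Mahalanobis random forest
#'
#' Forest predictions are the componentwise average of the per-tree leaf
#' means; `.sd_*` columns carry the across-tree (population) standard
#' deviation of the per-tree predictions, the per-cluster uncertainty measure
#' used for nowcast maps.
#'
#' @param object A [mahal_forest()] fit.
#' @param new_data Data frame containing every training feature, no missing
#'   values in them.
#' @param ... Unused.
#' @return A tibble with one row per row of `new_data` and columns
#'   `.pred_<outcome>` and `.sd_<outcome>`.
#' @export
predict.mahal_forest <- function(object, new_data, ...) {
  miss <- setdiff(object$features, names(new_data))
  if (length(miss) > 0) {
    abort(paste0("new_data lacks features: ", paste(miss, collapse = ", ")))
  }
  X <- as.matrix(as.data.frame(new_data)[object$features])
  if (anyNA(X)) abort("new_data contains missing feature values.")
  res <- .predict_forest_cpp(object$trees, X, length(object$outcomes))
  out <- cbind(
    as.data.frame(res$mean), as.data.frame(res$sd)
  )
  names(out) <- c(
    paste0(".pred_", object$outcomes),
    paste0(".sd_", object$outcomes)
  )
  as_tibble(out)
}

#' Mean-decrease-impurity feature importance
#'
#' For each split on a feature the decrease in impurity is the fraction of
#' that tree's training samples reaching the node times the per-sample
#' decrease in Mahalanobis cost produced by the split; a feature's MDI is the
#' across-tree average of its summed decreases. Features never split on score
#' exactly zero.
#'
#' @param forest A [mahal_forest()] fit.
#' @return Tibble with columns `feature`, `mdi`, sorted by decreasing `mdi`.
#' @export
mdi_importance <- function(forest) {
  stopifnot(inherits(forest, "mahal_forest"))
  tibble(
    feature = rownames(forest$mdi),
    mdi = unname(rowMeans(forest$mdi))
  ) |>
    arrange(desc(.data$mdi))
}

#' @rdname mdi_importance
#' @param x A `mahal_forest` object.
#' @param ... Unused.
#' @export
tidy.mahal_forest <- function(x, ...) mdi_importance(x)

#' One-row summary of a fitted forest
#' @param x A `mahal_forest` object.
#' @param ... Unused.
#' @return A one-row tibble of hyperparameters and fit dimensions.
#' @export
glance.mahal_forest <- function(x, ...) {
  tibble(
    trees = x$config$trees, max_depth = x$config$max_depth,
    dsr = x$config$dsr, min_leaf = x$config$min_leaf,
    bootstrap = x$config$bootstrap, n_train = x$n_train,
    n_features = length(x$features), n_outcomes = length(x$outcomes),
    lambda_provenance = x$lambda_provenance, seed = x$config$seed
  )
}

#' Serialise / restore a fitted forest
#'
#' Writes a versioned plain-text (JSON) representation containing the config,
#' the precision matrix, the seed, and every tree, so nowcast maps can be
#' reproduced without refitting.
#'
#' @param forest A `mahal_forest` object.
#' @param path File path.
#' @return `write_forest()` returns `path` invisibly; `read_forest()` returns
#'   the restored `mahal_forest`.
#' @export
write_forest <- function(forest, path) {
  stopifnot(inherits(forest, "mahal_forest"))
  payload <- list(
    format = "mrfnowcast-forest", version = 1L,
    config = forest$config,
    lambda = unclass(as.matrix(forest$lambda)),
    lambda_provenance = forest$lambda_provenance,
    outcomes = forest$outcomes, features = forest$features,
    n_train = forest$n_train,
    mdi_matrix = apply(forest$mdi, 2, identity, simplify = FALSE),
    trees = lapply(forest$trees, function(tr) {
      list(
        feature = tr$feature, threshold = tr$threshold, left = tr$left,
        right = tr$right, n = tr$n,
        leaf_mean = apply(tr$leaf_mean, 1, identity, simplify = FALSE)
      )
    })
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_forest
#' @export
read_forest <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(p$format, "mrfnowcast-forest")) {
    abort("Not a serialised mahal_forest file.")
  }
  num <- function(x) vapply(x, as.numeric, numeric(1))
  int <- function(x) vapply(x, function(v) as.integer(v), integer(1))
  trees <- lapply(p$trees, function(tr) {
    lm <- do.call(rbind, lapply(tr$leaf_mean, num))
    list(
      feature = int(tr$feature), threshold = num(tr$threshold),
      left = int(tr$left), right = int(tr$right), n = int(tr$n),
      leaf_mean = lm
    )
  })
  features <- unlist(p$features)
  mdi <- do.call(cbind, lapply(p$mdi_matrix, num))
  rownames(mdi) <- features
  lambda <- do.call(rbind, lapply(p$lambda, num))
  cfg <- p$config
  cfg[c("trees", "max_depth", "min_leaf", "seed", "mtry")] <-
    lapply(cfg[c("trees", "max_depth", "min_leaf", "seed", "mtry")], as.integer)
  structure(
    list(
      trees = trees, mdi = mdi, lambda = lambda,
      lambda_provenance = p$lambda_provenance,
      outcomes = unlist(p$outcomes), features = features,
      n_train = as.integer(p$n_train),
      config = cfg
    ),
    class = "mahal_forest"
  )
}
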