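# Model core: Mahalanobis cost, split search, forest fitting/prediction,
# precision estimation, MDI importance.

test_that("mahalanobis_cost matches direct evaluations", {
  # identical members -> 0 for any PD lambda
  Y <- matrix(rep(c(0.3, 0.7), each = 4), 4, 2)
  expect_equal(mahalanobis_cost(Y, random_pd(2)), 0)
  # univariate {1, 3} with lambda = 2: deviations +-1, cost 2 + 2 = 4
  expect_equal(mahalanobis_cost(matrix(c(1, 3), 2, 1), matrix(2)), 4)
  # identity lambda reduces to the per-dimension SSE sum: (1,0) vs (3,2) -> 4
  expect_equal(mahalanobis_cost(rbind(c(1, 0), c(3, 2)), diag(2)), 4)
  expect_error(mahalanobis_cost(Y, matrix(c(1, 2, 2, 1), 2)), "positive definite")
})

test_that("mahalanobis_cost equals whitened-outcome SSE (decorrelation identity)", {
  set.seed(101)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    n <- sample(3:20, 1)
    Y <- matrix(rnorm(n * k), n, k)
    lam <- random_pd(k)
    W <- chol(lam)
    Z <- Y %*% t(W)
    sse <- sum(sweep(Z, 2, colMeans(Z))^2)
    expect_equal(mahalanobis_cost(Y, lam), sse, tolerance = 1e-10)
  }
})

test_that("best_split finds the exact optimum and refuses useless splits", {
  # X = 1..4, Y = (0,0,1,1): threshold 2.5 gives zero child cost
  sp <- best_split(matrix(1:4), matrix(c(0, 0, 1, 1)), matrix(1), min_leaf = 1)
  expect_equal(sp$threshold, 2.5)
  expect_equal(sp$cost_children, 0)
  expect_equal(sp$feature, 1)
  # identical outcomes: no cost reduction possible
  expect_null(best_split(matrix(1:6), matrix(rep(0.4, 6)), matrix(1)))
})

test_that("best_split agrees with the brute-force oracle on random instances", {
  set.seed(202)
  for (i in 1:40) {
    n <- sample(5:30, 1)
    p <- sample(1:5, 1)
    k <- sample(1:3, 1)
    X <- matrix(runif(n * p), n, p)
    Y <- matrix(rnorm(n * k), n, k)
    lam <- random_pd(k)
    got <- best_split(X, Y, lam)
    want <- oracle_best_split(X, Y, lam)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$feature, want$feature)
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$cost_children, want$cost_children, tolerance = 1e-9)
    }
  }
})

test_that("depth-0 and single-row forests degenerate as contracted", {
  d <- tibble::tibble(x = 1:8 / 8, y1 = c(1:8) / 10, y2 = rev(1:8) / 10)
  # d = 0, no bootstrap: every tree is one leaf, prediction = training mean
  f0 <- mahal_forest(d, c("y1", "y2"),
    trees = 5, max_depth = 0,
    bootstrap = FALSE, seed = 1
  )
  p0 <- predict(f0, d[3, ])
  expect_equal(p0$.pred_y1, mean(d$y1))
  expect_equal(p0$.pred_y2, mean(d$y2))
  # one training row: every prediction equals that row's outcomes
  f1 <- mahal_forest(d[4, ], c("y1", "y2"), features = "x", trees = 7, seed = 1)
  p1 <- predict(f1, tibble::tibble(x = c(-5, 0.7, 99)))
  expect_equal(p1$.pred_y1, rep(d$y1[4], 3))
  expect_true(all(p1$.sd_y1 == 0))
})

test_that("predictions are convex combinations of training outcomes", {
  set.seed(7)
  d <- tibble::tibble(
    a = runif(50), b = runif(50),
    y1 = runif(50, 0.2, 0.8), y2 = runif(50, 0.1, 0.4)
  )
  f <- mahal_forest(d, c("y1", "y2"), trees = 40, seed = 2)
  p <- predict(f, tibble::tibble(a = runif(20, -1, 2), b = runif(20, -1, 2)))
  expect_true(all(p$.pred_y1 >= min(d$y1) & p$.pred_y1 <= max(d$y1)))
  expect_true(all(p$.pred_y2 >= min(d$y2) & p$.pred_y2 <= max(d$y2)))
})

test_that("a hand-built two-tree forest averages leaves and reports across-tree sd", {
  leaf_tree <- function(m) {
    list(
      feature = -1L, threshold = 0, left = -1L, right = -1L, n = 1L,
      leaf_mean = matrix(m, 1, 1)
    )
  }
  fake <- structure(
    list(
      trees = list(leaf_tree(0.2), leaf_tree(0.4)),
      mdi = matrix(0, 1, 2, dimnames = list("x", NULL)),
      lambda = matrix(1), lambda_provenance = "identity",
      outcomes = "y", features = "x", n_train = 2,
      config = list(
        trees = 2L, max_depth = 0L, dsr = 1, bootstrap = FALSE,
        min_leaf = 2L, seed = 1L, mtry = 1L
      )
    ),
    class = "mahal_forest"
  )
  p <- predict(fake, tibble::tibble(x = 0))
  expect_equal(p$.pred_y, 0.3)
  # population sd across {0.2, 0.4}
  expect_equal(p$.sd_y, 0.1)
  # single tree -> zero sd
  fake$trees <- fake$trees[1]
  fake$config$trees <- 1L
  expect_equal(predict(fake, tibble::tibble(x = 0))$.sd_y, 0)
})

test_that("with one outcome the learner is an ordinary variance-criterion forest", {
  set.seed(303)
  for (i in 1:10) {
    n <- sample(15:30, 1)
    p <- sample(2:3, 1)
    d <- as.data.frame(matrix(runif(n * p), n, p))
    names(d) <- paste0("x", seq_len(p))
    d$y <- rnorm(n)
    for (lam in c(1, 0.37, 12)) {
      f <- mahal_forest(d, "y",
        lambda = matrix(lam), trees = 4, max_depth = 3,
        dsr = 1, seed = 50 + i
      )
      orc <- oracle_uni_forest(as.matrix(d[paste0("x", seq_len(p))]), d$y,
        trees = 4, max_depth = 3, seed = 50 + i
      )
      # identical structure, tree by tree
      for (t in 1:4) {
        flat_oracle <- function(nd) {
          if (is.na(nd$feature)) {
            return(NULL)
          }
          rbind(
            c(nd$feature, nd$threshold),
            flat_oracle(nd$left), flat_oracle(nd$right)
          )
        }
        ours <- f$trees[[t]]
        internal <- ours$feature >= 0
        got <- cbind(ours$feature[internal] + 1, ours$threshold[internal])
        want <- flat_oracle(orc$trees[[t]])
        expect_equal(sort(got[, 1]), sort(want[, 1]))
        expect_equal(sort(got[, 2]), sort(want[, 2]), tolerance = 1e-12)
      }
      Xnew <- matrix(runif(12 * p), 12, p)
      colnames(Xnew) <- paste0("x", seq_len(p))
      expect_equal(
        predict(f, as.data.frame(Xnew))$.pred_y,
        orc$predict(Xnew),
        tolerance = 1e-12
      )
    }
  }
})

test_that("total leaf cost never increases with depth", {
  set.seed(404)
  d <- as.data.frame(matrix(runif(60 * 3), 60, 3))
  names(d) <- c("x1", "x2", "x3")
  Y <- matrix(rnorm(60 * 2), 60, 2)
  d$y1 <- Y[, 1]
  d$y2 <- Y[, 2]
  lam <- random_pd(2)
  costs <- vapply(0:4, function(dep) {
    f <- mahal_forest(d, c("y1", "y2"),
      lambda = lam, trees = 1,
      max_depth = dep, bootstrap = FALSE, dsr = 1, seed = 9
    )
    pr <- predict(f, d)
    resid <- Y - cbind(pr$.pred_y1, pr$.pred_y2)
    sum(rowSums((resid %*% lam) * resid))
  }, numeric(1))
  expect_true(all(diff(costs) <= 1e-10))
})

test_that("estimate_precision inverts the residual covariance (FGLS)", {
  set.seed(11)
  n <- 120
  d <- tibble::tibble(
    x = runif(n),
    y1 = 0.5 + 0.3 * x + rnorm(n, 0, 0.2),
    y2 = 0.4 - 0.2 * x + rnorm(n, 0, 0.1)
  )
  lam <- estimate_precision(d, c("y1", "y2"), trees = 60, seed = 3)
  expect_s3_class(lam, "precision_matrix")
  expect_identical(attr(lam, "provenance"), "estimated")
  sigma <- attr(lam, "sigma")
  ridge <- attr(lam, "ridge")
  # lambda is the exact inverse of the ridge-regularised covariance
  expect_equal(
    unclass(lam) %*% (sigma + ridge * diag(2)),
    diag(2),
    tolerance = 1e-8, ignore_attr = TRUE
  )
  # 2x2 closed form 1/(1 - rho^2) * [[1/s1^2, ...]] via direct inversion
  closed <- solve(sigma + ridge * diag(2))
  expect_equal(unclass(lam), closed, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("estimate_precision falls back with a warning on zero residuals", {
  d <- tibble::tibble(x = runif(30), y1 = 0.4, y2 = 0.6)
  expect_warning(
    lam <- estimate_precision(d, c("y1", "y2"), trees = 10, seed = 1),
    "identity"
  )
  expect_equal(unclass(lam), diag(2), ignore_attr = TRUE)
})

test_that("MDI is the sample-fraction-weighted impurity decrease", {
  # constant feature can never split -> exactly zero
  d <- tibble::tibble(x = c(1, 2, 3, 4), flat = 1, y = c(0, 0, 1, 1))
  f <- mahal_forest(d, "y",
    features = c("x", "flat"), trees = 6, dsr = 1,
    min_leaf = 1, seed = 4
  )
  imp <- mdi_importance(f)
  expect_equal(imp$mdi[imp$feature == "flat"], 0)
  # single tree, single root split on 100% of samples:
  # parent cost 1 (SSE of two 0s and two 1s), children 0 -> MDI = 1/4
  f1 <- mahal_forest(d, "y",
    features = "x", trees = 1, max_depth = 1,
    bootstrap = FALSE, dsr = 1, min_leaf = 1, seed = 4
  )
  expect_equal(mdi_importance(f1)$mdi, 0.25)
  # two identical trees average to the single-tree value
  f2 <- mahal_forest(d, "y",
    features = "x", trees = 2, max_depth = 1,
    bootstrap = FALSE, dsr = 1, min_leaf = 1, seed = 4
  )
  expect_equal(mdi_importance(f2)$mdi, 0.25)
})

test_that("forests serialise to JSON and back without changing predictions", {
  set.seed(5)
  d <- tibble::tibble(
    a = runif(30), b = runif(30),
    y1 = runif(30), y2 = runif(30)
  )
  f <- mahal_forest(d, c("y1", "y2"), trees = 8, seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_forest(f, path)
  g <- read_forest(path)
  expect_equal(predict(g, d), predict(f, d), tolerance = 1e-12)
  expect_equal(mdi_importance(g), mdi_importance(f), tolerance = 1e-12)
})

test_that("fitting is deterministic given the seed and errors on missing data", {
  d <- tibble::tibble(a = runif(20), y1 = runif(20), y2 = runif(20))
  f1 <- mahal_forest(d, c("y1", "y2"), trees = 10, seed = 77)
  f2 <- mahal_forest(d, c("y1", "y2"), trees = 10, seed = 77)
  expect_equal(predict(f1, d), predict(f2, d))
  d_na <- d
  d_na$a[3] <- NA
  expect_error(mahal_forest(d_na, c("y1", "y2")), "missing")
  expect_error(predict(f1, tibble::tibble(a = NA_real_)), "missing")
  expect_error(predict(f1, tibble::tibble(b = 1)), "lacks features")
})
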