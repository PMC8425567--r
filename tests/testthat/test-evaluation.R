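# Regimes, metrics, aggregation, grouped importance, nowcast maps.

test_that("sequential splits follow the cumulative-history rule", {
  d <- tidyr::crossing(
    country = c("A", "B"), year = c(2008L, 2013L),
    i = 1:3
  )
  d <- d[!(d$country == "B" & d$year == 2008), ] # B has a single year
  sp <- make_sequential_splits(d)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$country, "A")
  expect_equal(sp$test_year, 2013L)
  expect_equal(sp$train_years[[1]], 2008L)

  d3 <- tidyr::crossing(country = "C", year = c(2006L, 2010L, 2014L), i = 1:2)
  sp3 <- make_sequential_splits(d3)
  expect_equal(sp3$test_year, c(2010L, 2014L))
  expect_equal(sp3$train_years, list(2006L, c(2006L, 2010L)))
  # never any temporal leakage
  expect_true(all(vapply(
    seq_len(nrow(sp3)),
    function(i) max(sp3$train_years[[i]]) < sp3$test_year[i], logical(1)
  )))
})

test_that("contemporaneous folds partition the survey and are seed-stable", {
  d <- tibble::tibble(
    country = "A", year = 2012L,
    ea_id = sprintf("e%03d", 1:100)
  )
  sp <- make_contemporaneous_splits(d, n_folds = 5, seed = 4)
  expect_equal(nrow(sp), 5)
  sizes <- lengths(sp$test_ids)
  expect_true(all(sizes == 20))
  expect_setequal(unlist(sp$test_ids), d$ea_id)
  expect_equal(anyDuplicated(unlist(sp$test_ids)), 0)
  # with no prior surveys the training fold is exactly 4/5 of the survey
  expect_equal(sp$train_years[[1]], integer(0))
  expect_equal(100 - sizes[1], 80)
  sp2 <- make_contemporaneous_splits(d, n_folds = 5, seed = 4)
  expect_identical(sp$test_ids, sp2$test_ids)
  expect_error(
    make_contemporaneous_splits(d[1:3, ], n_folds = 5),
    "at least"
  )
})

test_that("r-squared and NRMSE match their definitions", {
  y <- c(0, 1, 2)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(y, c(0, 0, 2)), 0.5) # 1 - 1/2
  expect_warning(expect_true(is.na(r_squared(c(1, 1), c(0, 1)))), "constant")
  expect_equal(nrmse(y, y), 0)
  expect_equal(nrmse(c(0, 1), c(1, 0)), 1)
  # scale invariance under y, yhat -> c * (y, yhat)
  set.seed(9)
  yy <- runif(20)
  hh <- runif(20)
  expect_equal(nrmse(3.7 * yy, 3.7 * hh), nrmse(yy, hh))
  expect_warning(expect_true(is.na(nrmse(c(1, 1), c(0, 1)))), "range")
})

make_preds <- function(df) {
  # helper: long prediction table from per-row spec
  tibble::tibble(
    variant = "mrf", country = df$country, year = df$year,
    fold = NA_integer_, outcome = "asset_poverty",
    y = df$y, yhat = df$yhat, ea_id = seq_len(nrow(df))
  )
}

test_that("aggregation levels coincide for a single survey", {
  set.seed(12)
  p <- make_preds(tibble::tibble(
    country = "A", year = 2010L,
    y = runif(30), yhat = runif(30)
  ))
  m <- aggregate_metrics(p)
  vals <- m[m$level %in% c("aggregate", "country", "survey"), ]
  expect_equal(length(unique(round(vals$r2, 12))), 1)
  expect_equal(length(unique(round(vals$nrmse, 12))), 1)
})

test_that("country means are size-weighted and differ from pooled r2", {
  set.seed(13)
  pa <- tibble::tibble(country = "A", year = 2010L, y = runif(100), yhat = runif(100))
  pb <- tibble::tibble(country = "B", year = 2010L, y = runif(300, 2, 4), yhat = runif(300, 2, 4))
  p <- dplyr::bind_rows(make_preds(pa), make_preds(pb))
  m <- aggregate_metrics(p)
  ctry <- m[m$level == "country", ]
  r2a <- ctry$r2[ctry$country == "A"]
  r2b <- ctry$r2[ctry$country == "B"]
  w <- m[m$level == "country_mean" & m$weighting == "size", ]
  expect_equal(w$r2, (100 * r2a + 300 * r2b) / 400)
  u <- m[m$level == "country_mean" & m$weighting == "equal", ]
  expect_equal(u$r2, (r2a + r2b) / 2)
  # pooled aggregate r2 is not the weighted mean of country r2s:
  # the pooled baseline mean straddles the two clusters
  agg <- m[m$level == "aggregate", ]
  expect_gt(abs(agg$r2 - w$r2), 0.05)
})

test_that("the weighted-mean arithmetic matches the worked example", {
  # two countries, r2 0.2 with 100 rows and 0.5 with 300 rows -> 0.425
  expect_equal(stats::weighted.mean(c(0.2, 0.5), c(100, 300)), 0.425)
})

test_that("grouped importance sums member features", {
  imp <- tibble::tibble(feature = c("a", "b", "c"), mdi = c(0.1, 0.2, 0.3))
  g <- grouped_importance(imp, c(a = "g1", b = "g1", c = "g2"))
  expect_equal(g$mdi[g$group == "g1"], 0.3)
  expect_equal(g$mdi[g$group == "g2"], 0.3)
  one <- grouped_importance(
    tibble::tibble(feature = "solo", mdi = 0.7),
    c(solo = "g")
  )
  expect_equal(one$mdi, 0.7)
  allg <- grouped_importance(imp, c(a = "g", b = "g", c = "g"))
  expect_equal(allg$mdi, sum(imp$mdi))
  expect_error(grouped_importance(imp, c(a = "g")), "not mapped")
  # default name-based grouping covers the generated feature set
  w <- tiny_world()
  feats <- modelling_features(w$ea_table)
  grp <- feature_groups(feats)
  expect_false(any(grp == "other"))
  expect_setequal(
    unique(unname(grp)),
    c(
      "location", "remoteness", "vegetation", "weather", "market",
      "conflict", "time"
    )
  )
})

test_that("nowcast maps carry one record per EA and outcome with valid sd", {
  w <- tiny_world()
  flat <- export_flat_table(w)
  train <- flat[flat$year == 2008 & flat$country == "C01", ]
  test <- flat[flat$year == 2011 & flat$country == "C01", ]
  f <- mahal_forest(train, OUTCOMES, modelling_features(flat),
    trees = 10, seed = 2
  )
  map <- emit_nowcast_map(f, test)
  expect_equal(nrow(map), nrow(test) * 5)
  expect_true(all(map$sd >= 0))
  # identical feature rows give identical records
  dup <- emit_nowcast_map(f, test[c(1, 1), ])
  expect_identical(dup[dup$outcome == "asset_poverty", ][1, ], dup[dup$outcome == "asset_poverty", ][2, ])
  # a single-tree forest is certain of itself
  f1 <- mahal_forest(train, OUTCOMES, modelling_features(flat),
    trees = 1, seed = 2
  )
  expect_true(all(emit_nowcast_map(f1, test)$sd == 0))
})

test_that("evaluate_regime runs both variants on shared folds", {
  flat <- export_flat_table(tiny_world())
  ev <- evaluate_regime(flat, "sequential", trees = 20, seed = 5)
  expect_s3_class(ev, "regime_evaluation")
  expect_setequal(unique(ev$predictions$variant), c("irf", "mrf"))
  # same test rows under both variants (shared folds)
  by_var <- split(ev$predictions$ea_id, ev$predictions$variant)
  expect_setequal(by_var$irf, by_var$mrf)
  # every test year strictly after its training years
  expect_true(all(ev$predictions$year == 2011))
  # metrics cover all levels and outcomes
  expect_setequal(
    unique(ev$metrics$level),
    c("aggregate", "country", "survey", "country_mean")
  )
  expect_setequal(unique(ev$metrics$outcome), OUTCOMES)
  expect_true(all(ev$metrics$r2 <= 1, na.rm = TRUE))
  expect_true(all(ev$metrics$nrmse >= 0, na.rm = TRUE))
  # glance/tidy accessors
  expect_s3_class(tidy(ev), "tbl_df")
  expect_equal(nrow(glance(ev)), 2)
})

test_that("contemporaneous evaluation averages across folds and keeps single-year countries", {
  cfg <- world_config(
    n_countries = 2, years = list(c(2008, 2011), 2011),
    eas_per_survey = 30, seed = 6
  )
  flat <- export_flat_table(generate_world(cfg))
  seq_ev <- evaluate_regime(flat, "sequential", trees = 15, seed = 7)
  expect_false("C02" %in% seq_ev$predictions$country)
  con_ev <- evaluate_regime(flat, "contemporaneous",
    trees = 15, n_folds = 3,
    seed = 7
  )
  expect_true("C02" %in% con_ev$predictions$country)
  agg <- con_ev$metrics[con_ev$metrics$level == "aggregate", ]
  expect_true(all(is.finite(agg$r2_sd)))
  # folds partition each survey's rows
  folds <- con_ev$predictions[con_ev$predictions$variant == "mrf" &
    con_ev$predictions$outcome == OUTCOMES[1], ]
  per_survey <- split(folds$ea_id, paste(folds$country, folds$year))
  for (ids in per_survey) expect_equal(anyDuplicated(ids), 0)
})
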