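# Evaluation regimes (sequential nowcasting; contemporaneous 5-fold),
# out-of-sample metrics, three-level aggregation, grouped importance and
# nowcast map emission.

#' Modelling feature columns of a flat EA table
#'
#' Every numeric column except the outcomes and the survey-key year (the
#' survey date enters as the `survey_date_num` feature instead).
#'
#' @param data Flat EA table.
#' @param outcomes Outcome column names (default [OUTCOMES]).
#' @return Character vector of feature names.
#' @export
modelling_features <- function(data, outcomes = OUTCOMES) {
  setdiff(default_features(data, outcomes), "year")
}

#' Sequential nowcasting splits
#'
#' One split per (country, test year t) with at least one prior survey in the
#' same country: training membership is every survey year strictly before t.
#' Countries with a single survey year produce no splits.
#'
#' @param data Flat EA table with `country` and `year` columns.
#' @return Tibble with columns `regime`, `country`, `test_year`,
#'   `train_years` (list-column), `fold` (NA).
#' @export
make_sequential_splits <- function(data) {
  surveys <- dplyr::distinct(data, .data$country, .data$year) |>
    arrange(.data$country, .data$year)
  surveys |>
    group_by(.data$country) |>
    group_modify(function(df, key) {
      yrs <- sort(df$year)
      if (length(yrs) < 2) {
        return(tibble(
          test_year = integer(), train_years = list(), fold = integer()
        ))
      }
      tibble(
        test_year = yrs[-1],
        train_years = lapply(seq_along(yrs[-1]), function(i) yrs[seq_len(i)]),
        fold = NA_integer_
      )
    }) |>
    ungroup() |>
    mutate(regime = "sequential", .before = 1)
}

#' Contemporaneous five-fold splits
#'
#' For each (country, survey year t): the year-t rows are partitioned into
#' `n_folds` near-equal folds by a seeded shuffle; each split trains on all
#' prior same-country surveys plus the other folds and tests on the held-out
#' fold. Fold membership is keyed by `ea_id`.
#'
#' @param data Flat EA table with `country`, `year`, `ea_id`.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed for the fold shuffle.
#' @return Tibble with columns `regime`, `country`, `test_year`,
#'   `train_years` (list-column of prior years), `fold`, `test_ids`
#'   (list-column of held-out `ea_id`s).
#' @export
make_contemporaneous_splits <- function(data, n_folds = 5, seed = 1) {
  surveys <- dplyr::distinct(data, .data$country, .data$year) |>
    arrange(.data$country, .data$year)
  out <- purrr::map_dfr(seq_len(nrow(surveys)), function(i) {
    cc <- surveys$country[i]
    yy <- surveys$year[i]
    ids <- data$ea_id[data$country == cc & data$year == yy]
    if (length(ids) < n_folds) {
      abort(sprintf(
        "Survey %s %d has %d rows; need at least n_folds = %d.",
        cc, yy, length(ids), n_folds
      ))
    }
    set.seed(sub_seed(seed, 101 + i))
    fold <- rep_len(seq_len(n_folds), length(ids))[order(runif(length(ids)))]
    prior <- sort(surveys$year[surveys$country == cc & surveys$year < yy])
    tibble(
      country = cc, test_year = yy, fold = seq_len(n_folds),
      train_years = rep(list(prior), n_folds),
      test_ids = lapply(seq_len(n_folds), function(f) ids[fold == f])
    )
  })
  mutate(out, regime = "contemporaneous", .before = 1)
}

#' Out-of-sample r-squared
#'
#' `1 - SSE/SST`, with the baseline the scalar mean of the observed test
#' outcomes of the reporting unit; may be negative. Constant observed
#' outcomes make the statistic undefined (returned as `NA` with a warning).
#'
#' @param y Observed values.
#' @param yhat Predictions.
#' @return Scalar r-squared (or `NA`).
#' @export
r_squared <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  if (length(y) < 2) abort("r_squared() needs at least 2 observations.")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    warn("Observed outcomes are constant; r-squared undefined.")
    return(NA_real_)
  }
  1 - sum((y - yhat)^2) / sst
}

#' Normalised root-mean-squared error
#'
#' RMSE divided by the observed range of the reporting unit's outcomes (or an
#' explicitly supplied range, e.g. the training-sample range).
#'
#' @param y Observed values.
#' @param yhat Predictions.
#' @param range Normalising range; default `max(y) - min(y)`.
#' @return Scalar NRMSE (or `NA` when the range is zero, with a warning).
#' @export
nrmse <- function(y, yhat, range = NULL) {
  stopifnot(length(y) == length(yhat))
  range <- range %||% (max(y) - min(y))
  if (!is.finite(range) || range <= 0) {
    warn("Zero or invalid outcome range; NRMSE undefined.")
    return(NA_real_)
  }
  sqrt(mean((y - yhat)^2)) / range
}

metric_block <- function(df, range_source = "test") {
  unit_range <- function(sub) {
    if (range_source == "train" && all(c("y_train_min", "y_train_max") %in% names(sub))) {
      max(sub$y_train_max) - min(sub$y_train_min)
    } else {
      NULL
    }
  }
  if (all(is.na(df$fold))) {
    tibble(
      r2 = r_squared(df$y, df$yhat),
      nrmse = nrmse(df$y, df$yhat, unit_range(df)),
      r2_sd = NA_real_, nrmse_sd = NA_real_, n = nrow(df)
    )
  } else {
    per <- purrr::map_dfr(split(df, df$fold), function(sub) {
      tibble(
        r2 = r_squared(sub$y, sub$yhat),
        nrmse = nrmse(sub$y, sub$yhat, unit_range(sub))
      )
    })
    tibble(
      r2 = mean(per$r2), nrmse = mean(per$nrmse),
      r2_sd = stats::sd(per$r2), nrmse_sd = stats::sd(per$nrmse),
      n = nrow(df)
    )
  }
}

#' Aggregate prediction metrics at three pooling levels
#'
#' Computes out-of-sample r-squared and NRMSE per model variant and outcome
#' at the aggregate level (all predictions pooled), the country level
#' (pooled within country), and the survey level (per country-year), plus
#' country-mean rows (size-weighted by pooled country row counts, and
#' unweighted). When predictions carry fold labels the score of a unit is
#' the across-fold mean, with the across-fold standard deviation reported
#' alongside.
#'
#' @param predictions Long tibble with columns `variant`, `country`, `year`,
#'   `fold` (may be NA), `outcome`, `y`, `yhat` (e.g. from
#'   [evaluate_regime()]).
#' @param range_source `"test"` (default): NRMSE normalised by the reporting
#'   unit's observed test range; `"train"`: by the training-sample range
#'   carried in `y_train_min`/`y_train_max` columns.
#' @return Tibble with columns `level`, `variant`, `outcome`, `country`,
#'   `year`, `weighting`, `r2`, `nrmse`, `r2_sd`, `nrmse_sd`, `n`.
#' @export
aggregate_metrics <- function(predictions, range_source = c("test", "train")) {
  range_source <- match.arg(range_source)
  p <- predictions
  agg <- p |>
    group_by(.data$variant, .data$outcome) |>
    group_modify(~ metric_block(.x, range_source)) |>
    ungroup() |>
    mutate(level = "aggregate", country = NA_character_, year = NA_integer_)
  ctry <- p |>
    group_by(.data$variant, .data$outcome, .data$country) |>
    group_modify(~ metric_block(.x, range_source)) |>
    ungroup() |>
    mutate(level = "country", year = NA_integer_)
  surv <- p |>
    group_by(.data$variant, .data$outcome, .data$country, .data$year) |>
    group_modify(~ metric_block(.x, range_source)) |>
    ungroup() |>
    mutate(level = "survey")
  cmean <- ctry |>
    group_by(.data$variant, .data$outcome) |>
    summarise(
      r2_w = stats::weighted.mean(.data$r2, .data$n),
      nrmse_w = stats::weighted.mean(.data$nrmse, .data$n),
      r2_u = mean(.data$r2), nrmse_u = mean(.data$nrmse),
      n = sum(.data$n), .groups = "drop"
    )
  cmean <- dplyr::bind_rows(
    cmean |> transmute(.data$variant, .data$outcome,
      r2 = .data$r2_w, nrmse = .data$nrmse_w, n = .data$n,
      weighting = "size"
    ),
    cmean |> transmute(.data$variant, .data$outcome,
      r2 = .data$r2_u, nrmse = .data$nrmse_u, n = .data$n,
      weighting = "equal"
    )
  ) |>
    mutate(
      level = "country_mean", country = NA_character_, year = NA_integer_,
      r2_sd = NA_real_, nrmse_sd = NA_real_
    )
  dplyr::bind_rows(agg, ctry, surv, cmean) |>
    select(
      "level", "variant", "outcome", "country", "year", "weighting",
      "r2", "nrmse", "r2_sd", "nrmse_sd", "n"
    ) |>
    arrange(.data$level, .data$variant, .data$outcome)
}

#' Default feature-to-group mapping
#'
#' Maps feature names to the reporting groups used for grouped importance:
#' location (latitude, longitude, altitude, slope), remoteness (urban flag,
#' travel time to a major city), vegetation (pasture, tree cover, SIF
#' anomaly), weather (precipitation and LST anomalies), market (all food
#' price features), conflict, and time (survey date).
#'
#' @param features Character vector of feature names.
#' @return Named character vector: `features` -> group.
#' @export
feature_groups <- function(features) {
  grp <- dplyr::case_when(
    features %in% c("lat", "lon", "altitude", "slope") ~ "location",
    features %in% c("urban", "travel_time") ~ "remoteness",
    features %in% c("pasture", "tree_cover") | grepl("^sif", features) ~ "vegetation",
    grepl("^(precip|lst)", features) ~ "weather",
    grepl("^price_", features) ~ "market",
    grepl("^conflict_", features) ~ "conflict",
    grepl("^survey_date", features) ~ "time",
    TRUE ~ "other"
  )
  setNames(grp, features)
}

#' Combine per-feature MDI into per-group MDI
#'
#' Group importance is the sum of the member features' mean-decrease-impurity
#' scores. Every feature must be mapped to exactly one group.
#'
#' @param importance Tibble with columns `feature`, `mdi` (e.g. from
#'   [mdi_importance()]), or a named numeric vector.
#' @param groups Named character vector `feature -> group` (default
#'   [feature_groups()] of the feature names), or a tibble with `feature`
#'   and `group` columns.
#' @return Tibble with columns `group`, `mdi`, sorted by decreasing `mdi`.
#' @export
grouped_importance <- function(importance, groups = NULL) {
  if (is.numeric(importance) && !is.null(names(importance))) {
    importance <- tibble(feature = names(importance), mdi = unname(importance))
  }
  stopifnot(all(c("feature", "mdi") %in% names(importance)))
  groups <- groups %||% feature_groups(importance$feature)
  if (is.data.frame(groups)) groups <- setNames(groups$group, groups$feature)
  unmapped <- setdiff(importance$feature, names(groups))
  if (length(unmapped) > 0) {
    abort(paste0(
      "Features not mapped to a group: ",
      paste(unmapped, collapse = ", ")
    ))
  }
  importance |>
    mutate(group = unname(groups[.data$feature])) |>
    group_by(.data$group) |>
    summarise(mdi = sum(.data$mdi), .groups = "drop") |>
    arrange(desc(.data$mdi))
}

#' Emit a nowcast map for a test survey
#'
#' Per enumeration area and outcome: coordinates, the forest-mean prediction,
#' and the across-tree standard deviation (the per-cluster uncertainty).
#'
#' @param forest A fitted [mahal_forest()].
#' @param test_data Test rows with `lat`, `lon` and every training feature.
#' @param path Optional CSV path to write the map to.
#' @return Tibble with columns `lat`, `lon`, `outcome`, `mean`, `sd` (one
#'   row per EA x outcome).
#' @export
emit_nowcast_map <- function(forest, test_data, path = NULL) {
  pred <- predict(forest, test_data)
  out <- purrr::map_dfr(forest$outcomes, function(oc) {
    tibble(
      lat = test_data$lat, lon = test_data$lon, outcome = oc,
      mean = pred[[paste0(".pred_", oc)]],
      sd = pred[[paste0(".sd_", oc)]]
    )
  })
  if (!is.null(path)) readr::write_csv(out, path)
  out
}

#' Run a full test/train regime with both model variants
#'
#' For every split of the chosen regime: stacks the split's training and
#' testing rows, applies the missingness filter to that regime table, fits
#' the multivariate Mahalanobis forest (precision estimated feasible-GLS
#' style from univariate training residuals) and the independent-forest
#' baseline (one variance-criterion univariate forest per outcome, identity
#' weighting) on identical folds, predicts the held-out rows, and collects
#' long-format predictions, metrics at all aggregation levels, and MDI
#' importance.
#'
#' @param data Flat EA table (e.g. [export_flat_table()] output or
#'   [read_flat_table()]).
#' @param regime `"sequential"` or `"contemporaneous"`.
#' @param outcomes Outcome columns (default [OUTCOMES]).
#' @param n_folds Folds for the contemporaneous regime (default 5).
#' @param trees,max_depth,dsr,bootstrap,min_leaf Forest hyperparameters (see
#'   [mahal_forest()]); defaults T = 2000, d = 4, dsr = 1/3.
#' @param variants Model variants to run (`"mrf"`, `"irf"`, or both).
#' @param range_source NRMSE normalisation, see [aggregate_metrics()].
#' @param seed Master seed: controls fold assignment and every forest.
#' @return A `regime_evaluation` list: `predictions` (long tibble with
#'   coordinates and across-tree sd), `metrics`, `importance` (per split x
#'   variant x feature), `splits`, `filter_log`, `config`.
#' @export
evaluate_regime <- function(data, regime = c("sequential", "contemporaneous"),
                            outcomes = OUTCOMES, n_folds = 5,
                            trees = 2000, max_depth = 4, dsr = 1 / 3,
                            bootstrap = TRUE, min_leaf = 2,
                            variants = c("irf", "mrf"),
                            range_source = "test", seed = 1) {
  regime <- match.arg(regime)
  variants <- match.arg(variants, several.ok = TRUE)
  if (!"ea_id" %in% names(data)) {
    data$ea_id <- sprintf("row%06d", seq_len(nrow(data)))
  }
  splits <- if (regime == "sequential") {
    make_sequential_splits(data)
  } else {
    make_contemporaneous_splits(data, n_folds = n_folds, seed = seed)
  }
  if (nrow(splits) == 0) {
    abort("No splits: the regime needs at least one country with two survey years.")
  }
  feats_all <- modelling_features(data, outcomes)

  preds <- list()
  imps <- list()
  logs <- list()
  for (si in seq_len(nrow(splits))) {
    sp <- splits[si, ]
    cc <- sp$country
    ty <- sp$test_year
    in_country <- data$country == cc
    if (regime == "sequential") {
      train_mask <- in_country & data$year %in% sp$train_years[[1]]
      test_mask <- in_country & data$year == ty
    } else {
      test_ids <- sp$test_ids[[1]]
      train_mask <- in_country &
        (data$year %in% sp$train_years[[1]] |
          (data$year == ty & !(data$ea_id %in% test_ids)))
      test_mask <- in_country & data$year == ty & data$ea_id %in% test_ids
    }
    regime_tbl <- dplyr::bind_rows(
      mutate(data[train_mask, ], .role = "train"),
      mutate(data[test_mask, ], .role = "test")
    )
    fl <- filter_missing(regime_tbl, outcomes, features = feats_all)
    train <- fl$data[fl$data$.role == "train", ]
    test <- fl$data[fl$data$.role == "test", ]
    logs[[si]] <- tibble(
      split = si, country = cc, test_year = ty, fold = sp$fold,
      dropped_features = list(fl$dropped_features),
      n_dropped_rows = length(fl$dropped_rows),
      n_train = nrow(train), n_test = nrow(test)
    )
    if (nrow(train) < 2 || nrow(test) < 1) next
    feats <- fl$features
    split_seed <- sub_seed(seed, 500 + si)

    fits <- list()
    if ("mrf" %in% variants) {
      lambda <- estimate_precision(train, outcomes, feats,
        trees = trees, max_depth = max_depth, dsr = dsr,
        bootstrap = bootstrap, min_leaf = min_leaf, seed = split_seed
      )
      fits$mrf <- mahal_forest(train, outcomes, feats,
        lambda = lambda,
        trees = trees, max_depth = max_depth, dsr = dsr,
        bootstrap = bootstrap, min_leaf = min_leaf, seed = split_seed
      )
    }
    if ("irf" %in% variants) {
      fits$irf <- lapply(setNames(outcomes, outcomes), function(oc) {
        mahal_forest(train, oc, feats,
          lambda = matrix(1),
          trees = trees, max_depth = max_depth, dsr = dsr,
          bootstrap = bootstrap, min_leaf = min_leaf,
          seed = sub_seed(split_seed, match(oc, outcomes))
        )
      })
    }
    y_train <- as.matrix(train[outcomes])
    for (v in names(fits)) {
      pred <- if (v == "mrf") {
        predict(fits$mrf, test)
      } else {
        dplyr::bind_cols(lapply(fits$irf, function(f) predict(f, test)))
      }
      long <- purrr::map_dfr(outcomes, function(oc) {
        tibble(
          regime = regime, variant = v, country = cc, year = ty,
          fold = sp$fold, ea_id = test$ea_id,
          lat = test$lat, lon = test$lon, outcome = oc,
          y = test[[oc]], yhat = pred[[paste0(".pred_", oc)]],
          sd = pred[[paste0(".sd_", oc)]],
          y_train_min = min(y_train[, oc]), y_train_max = max(y_train[, oc])
        )
      })
      preds[[length(preds) + 1]] <- long
      imp <- if (v == "mrf") {
        mdi_importance(fits$mrf)
      } else {
        purrr::map_dfr(fits$irf, mdi_importance) |>
          group_by(.data$feature) |>
          summarise(mdi = mean(.data$mdi), .groups = "drop")
      }
      imps[[length(imps) + 1]] <- mutate(imp,
        regime = regime, variant = v,
        country = cc, year = ty, fold = sp$fold, .before = 1
      )
    }
  }
  predictions <- dplyr::bind_rows(preds)
  if (nrow(predictions) == 0) abort("No split produced usable train/test data.")
  structure(
    list(
      regime = regime,
      predictions = predictions,
      metrics = aggregate_metrics(predictions, range_source = range_source),
      importance = dplyr::bind_rows(imps),
      splits = splits,
      filter_log = dplyr::bind_rows(logs),
      config = list(
        outcomes = outcomes, n_folds = n_folds, trees = trees,
        max_depth = max_depth, dsr = dsr, bootstrap = bootstrap,
        min_leaf = min_leaf, variants = variants,
        range_source = range_source, seed = seed
      )
    ),
    class = "regime_evaluation"
  )
}

#' @export
print.regime_evaluation <- function(x, ...) {
  cat(sprintf(
    "<regime_evaluation> %s: %d splits, %d predictions, variants: %s\n",
    x$regime, nrow(x$splits),
    nrow(dplyr::distinct(x$predictions, .data$ea_id, .data$year, .data$fold)),
    paste(x$config$variants, collapse = ", ")
  ))
  agg <- x$metrics[x$metrics$level == "aggregate", ]
  print(as.data.frame(agg[c("variant", "outcome", "r2", "nrmse")]), digits = 3)
  invisible(x)
}

#' @rdname evaluate_regime
#' @param x A `regime_evaluation` object.
#' @param ... Unused.
#' @export
tidy.regime_evaluation <- function(x, ...) x$metrics

#' @rdname evaluate_regime
#' @export
glance.regime_evaluation <- function(x, ...) {
  agg <- x$metrics[x$metrics$level == "aggregate", ]
  agg |>
    group_by(.data$variant) |>
    summarise(
      mean_r2 = mean(.data$r2), mean_nrmse = mean(.data$nrmse),
      .groups = "drop"
    ) |>
    mutate(regime = x$regime, n_splits = nrow(x$splits), .before = 1)
}
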