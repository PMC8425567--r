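# Covariate construction: nearest-in-space static assignment, seasonal
# z-score anomalies of gridded monthly series, food-price windows, conflict
# windowing, and the missingness filters applied per test/train regime.

#' Assign the spatially nearest static feature value
#'
#' Matches to an enumeration area the candidate value physically closest to
#' its centroid (great-circle distance). Ties are broken by lowest point id
#' (row order when no `id` column is present).
#'
#' @param points Data frame with columns `lat`, `lon`, `value`, and
#'   optionally `id`.
#' @param ea_lat,ea_lon Enumeration-area coordinates (degrees).
#' @return The `value` of the nearest candidate point.
#' @export
#' @examples
#' pts <- tibble::tibble(lat = c(1, 2), lon = 0, value = c("a", "b"))
#' assign_nearest_static(pts, 0, 0)
assign_nearest_static <- function(points, ea_lat, ea_lon) {
  if (!is.data.frame(points) || nrow(points) == 0) {
    abort("`points` must be a non-empty data frame of candidate locations.")
  }
  d <- haversine_km(points$lat, points$lon, ea_lat, ea_lon)
  id <- points$id %||% seq_len(nrow(points))
  points$value[order(d, id)[1]]
}

# Survey-anchored season blocks: the 12 months strictly before the survey
# start month, split into four consecutive 3-month blocks counted backwards.
# Returns a list of integer month-index vectors, most recent season first.
season_blocks <- function(survey_start, calendar_fixed = FALSE) {
  m0 <- month_index(survey_start)
  if (calendar_fixed) {
    # calendar-quarter seasons (Q1 = Jan-Mar, ...): the four complete
    # quarters ending strictly before the survey start month
    qstart <- m0 - ((m0 %% 3L) + 12L)
    lapply(3:0, function(q) qstart + q * 3L + 0:2)
  } else {
    lapply(1:4, function(s) (m0 - 3L * s) + 0:2)
  }
}

#' Seasonal z-score anomaly of a gridded monthly series
#'
#' Splits the 12 months before `survey_start` into four consecutive
#' non-overlapping 3-month seasons. For each season, the anomaly numerator is
#' the mean value at the sensed cell closest to the enumeration area during
#' that season; the reference mean and sample standard deviation pool all raw
#' values within `radius_km` whose calendar month falls in that season's
#' months, across the full record of the series. The returned feature is the
#' mean of the four z-scores; a season with zero reference standard deviation
#' contributes z = 0.
#'
#' @param series Data frame with columns `lat`, `lon`, `month` (consecutive
#'   month index, see [month_index()]), `value`.
#' @param ea_lat,ea_lon Enumeration-area coordinates.
#' @param survey_start Survey start `Date` (or anything [month_index()]
#'   accepts).
#' @param radius_km Pooling radius for the seasonal reference statistics
#'   (default 100 km).
#' @param calendar_fixed Use calendar-quarter seasons instead of
#'   survey-anchored blocks (default FALSE).
#' @return A list with `anomaly` (mean of the four seasonal z-scores) and
#'   `z` (the four per-season z-scores, most recent season first).
#' @export
seasonal_zscore <- function(series, ea_lat, ea_lon, survey_start,
                            radius_km = 100, calendar_fixed = FALSE) {
  stopifnot(is.data.frame(series))
  need <- setdiff(c("lat", "lon", "month", "value"), names(series))
  if (length(need) > 0) {
    abort(paste0("`series` lacks columns: ", paste(need, collapse = ", ")))
  }
  blocks <- season_blocks(survey_start, calendar_fixed)
  m0 <- month_index(survey_start)
  prior <- (m0 - 12L):(m0 - 1L)
  have <- unique(series$month)
  if (!all(prior %in% have)) {
    abort("`series` must cover all 12 months before `survey_start`.")
  }
  cells <- dplyr::distinct(series, .data$lat, .data$lon)
  cells$dist <- haversine_km(cells$lat, cells$lon, ea_lat, ea_lon)
  within <- cells[cells$dist <= radius_km, , drop = FALSE]
  if (nrow(within) == 0) {
    abort(sprintf("No sensed cell within %.0f km of the enumeration area.", radius_km))
  }
  nearest <- within[order(within$dist), , drop = FALSE][1, ]
  ser <- dplyr::semi_join(series, within, by = c("lat", "lon"))
  ser$moy <- month_of_year(ser$month)

  z <- vapply(blocks, function(bl) {
    moy <- month_of_year(bl)
    ref <- ser$value[ser$moy %in% moy]
    at <- series$value[series$lat == nearest$lat & series$lon == nearest$lon &
      series$month %in% bl]
    if (length(at) == 0) {
      return(NA_real_)
    }
    s <- stats::sd(ref)
    if (!is.finite(s) || s == 0) {
      return(0)
    }
    (mean(at) - mean(ref)) / s
  }, numeric(1))
  list(anomaly = mean(z), z = z)
}

#' Food-price window features
#'
#' For each (market, commodity) pair, the mean and sample variance of monthly
#' prices over the 12 months strictly before the survey start. Commodity
#' series missing any month of the window are excluded. Markets are emitted
#' in order of great-circle distance from the enumeration area, so the n-th
#' block of price features belongs to the n-th nearest market.
#'
#' @param prices Data frame with columns `market`, `market_lat`, `market_lon`,
#'   `commodity`, `month` (month index), `price`; an optional `unit` column is
#'   carried through untouched.
#' @param ea_lat,ea_lon Enumeration-area coordinates.
#' @param survey_start Survey start date.
#' @param n_markets Number of nearest markets to keep (default all).
#' @return Tibble with columns `market_rank`, `market`, `distance_km`,
#'   `commodity`, `price_mean`, `price_var` (and `unit` if supplied), ordered
#'   by `market_rank` then `commodity`. Empty (with a warning) when no
#'   complete commodity series exists at any market.
#' @export
price_window_features <- function(prices, ea_lat, ea_lon, survey_start,
                                  n_markets = Inf) {
  stopifnot(is.data.frame(prices))
  need <- setdiff(
    c("market", "market_lat", "market_lon", "commodity", "month", "price"),
    names(prices)
  )
  if (length(need) > 0) {
    abort(paste0("`prices` lacks columns: ", paste(need, collapse = ", ")))
  }
  m0 <- month_index(survey_start)
  window <- (m0 - 12L):(m0 - 1L)
  win <- prices[prices$month %in% window, , drop = FALSE]
  keep_unit <- "unit" %in% names(prices)

  feats <- win |>
    group_by(.data$market, .data$market_lat, .data$market_lon, .data$commodity) |>
    summarise(
      n_months = dplyr::n_distinct(.data$month),
      price_mean = mean(.data$price),
      price_var = stats::var(.data$price),
      unit = if (keep_unit) dplyr::first(.data$unit) else NA_character_,
      .groups = "drop"
    ) |>
    filter(.data$n_months == 12L) # incomplete records excluded
  if (nrow(feats) == 0) {
    warn("No complete 12-month commodity price series in the window; empty feature set.")
    out <- tibble(
      market_rank = integer(), market = character(), distance_km = numeric(),
      commodity = character(), price_mean = numeric(), price_var = numeric()
    )
    if (keep_unit) out$unit <- character()
    return(out)
  }
  mk <- dplyr::distinct(feats, .data$market, .data$market_lat, .data$market_lon)
  mk$distance_km <- haversine_km(mk$market_lat, mk$market_lon, ea_lat, ea_lon)
  mk <- mk[order(mk$distance_km, mk$market), , drop = FALSE]
  mk$market_rank <- seq_len(nrow(mk))
  mk <- head(mk, n = if (is.finite(n_markets)) n_markets else nrow(mk))

  out <- feats |>
    inner_join(mk, by = c("market", "market_lat", "market_lon")) |>
    arrange(.data$market_rank, .data$commodity) |>
    select(
      "market_rank", "market", "distance_km", "commodity",
      "price_mean", "price_var", if (keep_unit) "unit" else NULL
    )
  out
}

#' Conflict counts in the year before a survey
#'
#' Counts violent events in a country whose start date lies within the year
#' strictly before the survey start, plus longer (multi-day) events whose end
#' date lies in that window; each qualifying event is counted once and its
#' deaths summed. Events lacking coordinates or timestamps are removed first.
#'
#' @param events Data frame with columns `country`, `start` (Date), `end`
#'   (Date), `deaths`, and `lat`/`lon` (used only for the georeference
#'   filter).
#' @param country Country to count events for.
#' @param survey_start Survey start date.
#' @return A list with `events` and `deaths` counts; `(0, 0)` when nothing
#'   qualifies.
#' @export
conflict_window_counts <- function(events, country, survey_start) {
  stopifnot(is.data.frame(events))
  if (nrow(events) == 0) {
    return(list(events = 0L, deaths = 0))
  }
  ev <- events[events$country == country, , drop = FALSE]
  has_geo <- if (all(c("lat", "lon") %in% names(ev))) {
    !is.na(ev$lat) & !is.na(ev$lon)
  } else {
    rep(TRUE, nrow(ev))
  }
  has_time <- !is.na(ev$start) & !is.na(ev$end)
  ev <- ev[has_geo & has_time, , drop = FALSE]
  if (nrow(ev) == 0) {
    return(list(events = 0L, deaths = 0))
  }
  s0 <- as.Date(survey_start)
  w_lo <- seq(s0, by = "-1 year", length.out = 2)[2]
  start_in <- ev$start >= w_lo & ev$start < s0
  end_in <- ev$end >= w_lo & ev$end < s0
  hit <- start_in | end_in
  list(events = sum(hit), deaths = sum(ev$deaths[hit]))
}

#' Missingness filter for one test/train regime
#'
#' Applied to the stacked training + testing table of a regime: first drops
#' every feature column whose missing fraction is strictly greater than
#' `max_missing` (default 0.20); then drops every row that still has a
#' missing feature or outcome. Idempotent.
#'
#' @param data Stacked regime table.
#' @param outcomes Outcome column names (never dropped as columns; rows with
#'   missing outcomes are dropped).
#' @param features Feature column names to screen; default every numeric
#'   column not in `outcomes`.
#' @param max_missing Column-wise missing-fraction threshold (strict
#'   inequality; default 0.20).
#' @return A list: `data` (filtered tibble), `dropped_features` (character),
#'   `dropped_rows` (integer row indices of `data` input), `report` (tibble
#'   of per-feature missing fractions).
#' @export
filter_missing <- function(data, outcomes, features = NULL, max_missing = 0.2) {
  stopifnot(is.data.frame(data))
  features <- features %||% default_features(data, outcomes)
  miss_frac <- vapply(
    data[features], function(x) mean(is.na(x)),
    numeric(1)
  )
  drop_cols <- features[miss_frac > max_missing]
  keep_feats <- setdiff(features, drop_cols)
  if (length(keep_feats) == 0) {
    abort("All feature columns exceed the missingness threshold.")
  }
  keep_tbl <- data[setdiff(names(data), drop_cols)]
  row_ok <- stats::complete.cases(keep_tbl[c(keep_feats, outcomes)])
  list(
    data = as_tibble(keep_tbl[row_ok, , drop = FALSE]),
    features = keep_feats,
    dropped_features = drop_cols,
    dropped_rows = which(!row_ok),
    report = tibble(feature = features, missing_fraction = unname(miss_frac))
  )
}

# --- vectorised internals used by the world builder ---------------------------

# haversine distance matrix (km), rows = points1, cols = points2, R = 6371 km
haversine_matrix <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  phi1 <- lat1 * rad
  phi2 <- lat2 * rad
  dphi <- outer(phi1, phi2, function(a, b) (b - a) / 2)
  dlam <- outer(lon1 * rad, lon2 * rad, function(a, b) (b - a) / 2)
  a <- sin(dphi)^2 + outer(cos(phi1), cos(phi2)) * sin(dlam)^2
  2 * 6371 * asin(sqrt(pmin(a, 1)))
}

# Seasonal z-score anomaly for many EAs at once; identical definition to
# seasonal_zscore() (see tests), evaluated with per-cell aggregates.
seasonal_anomaly_features <- function(series, ea_lat, ea_lon, survey_start,
                                      radius_km = 100) {
  blocks <- season_blocks(survey_start)
  cells <- dplyr::distinct(series, .data$lat, .data$lon)
  D <- haversine_matrix(cells$lat, cells$lon, ea_lat, ea_lon)
  W <- D <= radius_km # cells x EAs
  if (any(colSums(W) == 0)) {
    abort(sprintf("Some EAs have no sensed cell within %.0f km.", radius_km))
  }
  nearest <- apply(
    D + ifelse(W, 0, Inf), 2,
    which.min
  ) # nearest cell within radius
  key <- paste(series$lat, series$lon)
  cell_of <- match(key, paste(cells$lat, cells$lon))
  moy <- month_of_year(series$month)

  zs <- vapply(blocks, function(bl) {
    in_block <- series$month %in% bl
    in_season <- moy %in% month_of_year(bl)
    # numerator: mean value at each cell over the actual block months
    at <- vapply(seq_len(nrow(cells)), function(ci) {
      v <- series$value[in_block & cell_of == ci]
      if (length(v) == 0) NA_real_ else mean(v)
    }, numeric(1))
    # reference: per-cell count/sum/sumsq over the full record of the season
    n_c <- s_c <- q_c <- numeric(nrow(cells))
    agg <- tapply(series$value[in_season], cell_of[in_season], function(v) {
      c(length(v), sum(v), sum(v^2))
    })
    idx <- as.integer(names(agg))
    m <- do.call(rbind, agg)
    n_c[idx] <- m[, 1]
    s_c[idx] <- m[, 2]
    q_c[idx] <- m[, 3]
    n_e <- as.numeric(crossprod(W, n_c))
    s_e <- as.numeric(crossprod(W, s_c))
    q_e <- as.numeric(crossprod(W, q_c))
    mu <- s_e / n_e
    sdv <- sqrt(pmax(0, (q_e - n_e * mu^2) / (n_e - 1)))
    z <- (at[nearest] - mu) / sdv
    z[!is.finite(z) | sdv == 0] <- 0
    z
  }, numeric(length(ea_lat)))
  rowMeans(matrix(zs, nrow = length(ea_lat)))
}

# Wide per-EA block of market price features: the n-th nearest market's
# window mean/variance per commodity, columns price_m<rank>_<commodity>_*.
price_feature_block <- function(prices, ea_lat, ea_lon, survey_start) {
  m0 <- month_index(survey_start)
  window <- (m0 - 12L):(m0 - 1L)
  win <- prices[prices$month %in% window, , drop = FALSE]
  feats <- win |>
    group_by(.data$market, .data$market_lat, .data$market_lon, .data$commodity) |>
    summarise(
      n_months = dplyr::n_distinct(.data$month),
      price_mean = mean(.data$price),
      price_var = stats::var(.data$price),
      .groups = "drop"
    ) |>
    filter(.data$n_months == 12L)
  mk <- dplyr::distinct(prices, .data$market, .data$market_lat, .data$market_lon)
  commodities <- sort(unique(prices$commodity))
  n_ea <- length(ea_lat)
  out <- list()
  D <- haversine_matrix(mk$market_lat, mk$market_lon, ea_lat, ea_lon)
  rank_of <- apply(D, 2, order) # markets x EAs: row r = index of r-th nearest
  for (r in seq_len(nrow(mk))) {
    mk_r <- mk$market[rank_of[r, ]] # per-EA market at rank r
    for (cm in commodities) {
      sub <- feats[feats$commodity == cm, ]
      pos <- match(mk_r, sub$market)
      out[[sprintf("price_m%d_%s_mean", r, cm)]] <- sub$price_mean[pos]
      out[[sprintf("price_m%d_%s_var", r, cm)]] <- sub$price_var[pos]
    }
  }
  as_tibble(out)
}
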