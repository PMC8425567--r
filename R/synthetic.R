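# Synthetic world generator: countries, survey rounds, enumeration areas with
# jittered coordinates, gridded monthly covariate series, market price tables
# and conflict events, with a known ground-truth signal and outcome-noise
# covariance so every downstream stage is testable without any download.

#' The five prevalence outcomes
#'
#' Column names of the modelled enumeration-area prevalence rates, in the
#' order used throughout the package.
#' @export
OUTCOMES <- c(
  "child_stunting", "child_wasting", "healthy_weight",
  "asset_poverty", "underweight_women"
)

#' Configuration of a synthetic world
#'
#' Validated configuration for [generate_world()]. Defaults describe a small
#' multi-country, multi-round survey world: a few hundred enumeration areas
#' (EAs) per survey with coordinates jittered by up to `offset_km`
#' (anonymisation-style), five correlated bounded outcomes driven by a smooth
#' logistic link of the covariates plus multivariate noise, and monthly
#' gridded / market / conflict sources with seasonal structure.
#'
#' @param n_countries Number of countries (default 3).
#' @param years Survey years: a numeric vector shared by all countries, or a
#'   list of length `n_countries` (default `c(2008, 2011, 2014)`).
#' @param eas_per_survey EAs per (country, year) survey; at least 5
#'   (default 200).
#' @param outcome_noise_cov 5x5 symmetric positive-definite covariance of the
#'   prevalence-scale outcome noise. Default: standard deviation 0.05 per
#'   outcome with pairwise correlation 0.3.
#' @param signal_strength Non-negative multiplier per outcome on the
#'   ground-truth logit signal; 0 makes that outcome pure noise (default 1s).
#' @param signal_drift Strength of the per-year drift of the link, which
#'   makes contemporaneous prediction genuinely easier than sequential
#'   nowcasting (default 0.3).
#' @param grid_resolution_deg Raster cell size in degrees (default 0.5; the
#'   synthetic stand-in for the finer grids of real monthly products).
#' @param months_span Inclusive month-index range `c(first, last)` covered by
#'   the monthly sources; default from January two years before the earliest
#'   survey to December of the latest.
#' @param n_markets Monitored markets per country (default 5).
#' @param n_commodities Food commodities per country (default 3).
#' @param conflict_rate Mean violent events per country-year (default 20).
#' @param offset_km Maximum EA coordinate jitter in km (default 10).
#' @param survey_month Month-of-year in which every survey starts
#'   (default 4, April).
#' @param seed Master integer seed; per-source sub-seeds are derived from it
#'   by fixed offsets so adding a source never perturbs another source's
#'   draws.
#' @return A `world_config` list.
#' @export
world_config <- function(n_countries = 3,
                         years = c(2008, 2011, 2014),
                         eas_per_survey = 200,
                         outcome_noise_cov = NULL,
                         signal_strength = rep(1, 5),
                         signal_drift = 0.3,
                         grid_resolution_deg = 0.5,
                         months_span = NULL,
                         n_markets = 5,
                         n_commodities = 3,
                         conflict_rate = 20,
                         offset_km = 10,
                         survey_month = 4,
                         seed = 1) {
  if (is.null(outcome_noise_cov)) {
    outcome_noise_cov <- 0.05^2 * (0.3 + 0.7 * diag(5))
  }
  outcome_noise_cov <- as.matrix(outcome_noise_cov)
  dimnames(outcome_noise_cov) <- list(OUTCOMES, OUTCOMES)
  stopifnot_pd(outcome_noise_cov, "outcome_noise_cov")
  if (eas_per_survey < 5) abort("`eas_per_survey` must be at least 5.")
  if (offset_km < 0) abort("`offset_km` must be non-negative.")
  if (any(signal_strength < 0) || length(signal_strength) != 5) {
    abort("`signal_strength` must be 5 non-negative reals.")
  }
  if (!is.list(years)) years <- rep(list(sort(unique(years))), n_countries)
  if (length(years) != n_countries) {
    abort("`years` must have one entry per country.")
  }
  all_years <- sort(unique(unlist(years)))
  if (is.null(months_span)) {
    months_span <- c(
      month_index(min(all_years) - 2, 1),
      month_index(max(all_years), 12)
    )
  }
  earliest_start <- month_index(min(all_years), survey_month)
  if (months_span[1] > earliest_start - 12 || months_span[2] < earliest_start) {
    abort("`months_span` must cover at least the 12 months before every survey start.")
  }
  structure(
    list(
      n_countries = as.integer(n_countries), years = years,
      eas_per_survey = as.integer(eas_per_survey),
      outcome_noise_cov = outcome_noise_cov,
      signal_strength = signal_strength, signal_drift = signal_drift,
      grid_resolution_deg = grid_resolution_deg,
      months_span = as.integer(months_span),
      n_markets = as.integer(n_markets),
      n_commodities = as.integer(n_commodities),
      conflict_rate = conflict_rate, offset_km = offset_km,
      survey_month = as.integer(survey_month), seed = as.integer(seed)
    ),
    class = "world_config"
  )
}

# Fixed per-source seed offsets (see sub_seed()).
.SRC <- c(
  geography = 1L, ea = 2L, noise = 3L, sif = 4L, lst = 5L,
  precip = 6L, markets = 7L, conflicts = 8L
)

country_table <- function(config) {
  i <- seq_len(config$n_countries)
  tibble(
    country = sprintf("C%02d", i),
    lon_min = 10 * (i - 1), lon_max = 10 * (i - 1) + 6,
    lat_min = -3, lat_max = 3
  )
}

# Deterministic smooth geographic fields (units noted); the world's static
# covariates are exact functions of location so their signal is recoverable.
field_altitude <- function(lat, lon) 500 + 400 * sin(0.8 * lon) + 300 * cos(1.1 * lat)
field_slope <- function(lat, lon) 2 + 1.5 * sin(1.3 * lon + 0.7 * lat)
field_tree <- function(lat, lon) 50 * (0.5 + 0.5 * sin(0.5 * lon) * cos(0.6 * lat))
field_pasture <- function(lat, lon) 0.5 + 0.4 * cos(0.9 * lon - 0.4 * lat)

# Ground-truth link: logistic of a linear + one-interaction function of the
# standardised covariates, per outcome, scaled by signal_strength and shifted
# by a per-year drift. Chosen to be learnable by depth-4 trees.
.B <- rbind(
  #          trav   tree    alt   urban    lat  inter
  child_stunting    = c(-1.0, 0.8, 0.3, -0.4, 0.2, 0.4),
  child_wasting     = c(-0.8, -0.6, 0.4, -0.3, -0.2, 0.3),
  healthy_weight    = c(0.9, 0.5, -0.3, 0.4, 0.1, -0.4),
  asset_poverty     = c(-1.2, 0.6, 0.2, -0.8, 0.3, 0.5),
  underweight_women = c(-0.9, -0.5, 0.3, -0.5, 0.2, 0.3)
)
.B0 <- c(-0.3, -1.2, 0.8, -0.5, -0.8) # logit intercepts -> realistic rates
.DRIFT <- c(0.6, -0.4, 0.3, 0.8, -0.5) # direction of the per-year drift

truth_logit <- function(ea, config, year_centred) {
  u_trav <- (ea$travel_time - 200) / 150
  u_tree <- (ea$tree_cover - 25) / 15
  u_alt <- (ea$altitude - 500) / 350
  u_urb <- ea$urban - 0.5
  u_lat <- ea$lat / 3
  U <- cbind(u_trav, u_tree, u_alt, u_urb, u_lat, u_trav * u_tree)
  eta <- sweep(U %*% t(.B), 2, .B0, "+") +
    outer(year_centred, config$signal_drift * .DRIFT)
  sweep(eta, 2, config$signal_strength, "*")
}

#' Generate a synthetic world
#'
#' Builds the full synthetic data structure: per-survey enumeration-area
#' tables with static geographic covariates and engineered features (seasonal
#' anomalies of the three gridded sources, ordered market price windows,
#' conflict window counts, survey date, urban flag), the raw monthly sources
#' themselves, and ground-truth bookkeeping (`truth$pre_clip`, `truth$mu`,
#' `truth$clip_fraction`). Outcomes are
#' `clip01(plogis(signal) + noise)` with noise drawn from
#' `config$outcome_noise_cov`; clipped entries are counted in
#' `truth$clip_fraction`. Deterministic given `config$seed`.
#'
#' @param config A [world_config()].
#' @return A `synthetic_world` list: `ea_table`, `rasters` (named list of
#'   long-format monthly series), `markets`, `conflicts`, `countries`,
#'   `truth`, `config`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  ctry <- country_table(config)
  seed <- config$seed

  # geography: market cities (also used for travel time)
  set.seed(sub_seed(seed, .SRC[["geography"]]))
  cities <- purrr::map_dfr(seq_len(nrow(ctry)), function(i) {
    b <- ctry[i, ]
    tibble(
      country = b$country,
      city = sprintf("%s_city%d", b$country, seq_len(config$n_markets)),
      lat = runif(config$n_markets, b$lat_min + 0.5, b$lat_max - 0.5),
      lon = runif(config$n_markets, b$lon_min + 0.5, b$lon_max - 0.5)
    )
  })

  # enumeration areas: true centroid uniform in the country box, reported
  # location jittered uniformly in a disc of radius offset_km (local tangent)
  set.seed(sub_seed(seed, .SRC[["ea"]]))
  km_per_deg <- pi * 6371 / 180
  ea <- purrr::map_dfr(seq_len(nrow(ctry)), function(i) {
    b <- ctry[i, ]
    yrs <- config$years[[i]]
    purrr::map_dfr(yrs, function(yr) {
      n <- config$eas_per_survey
      lat0 <- runif(n, b$lat_min, b$lat_max)
      lon0 <- runif(n, b$lon_min, b$lon_max)
      r <- config$offset_km * sqrt(runif(n))
      th <- runif(n, 0, 2 * pi)
      tibble(
        country = b$country, year = as.integer(yr),
        ea_id = sprintf("%s_%d_%04d", b$country, yr, seq_len(n)),
        lat = lat0 + r * sin(th) / km_per_deg,
        lon = lon0 + r * cos(th) / (km_per_deg * cos(lat0 * pi / 180)),
        survey_start = as.Date(sprintf("%d-%02d-01", yr, config$survey_month))
      )
    })
  })

  # static covariates at the reported location
  city_near <- function(lat, lon, cc) {
    sub <- cities[cities$country == cc, ]
    vapply(seq_along(lat), function(j) {
      min(haversine_km(lat[j], lon[j], sub$lat, sub$lon))
    }, numeric(1))
  }
  ea <- ea |>
    group_by(.data$country) |>
    mutate(city_dist = city_near(.data$lat, .data$lon, .data$country[1])) |>
    ungroup() |>
    mutate(
      travel_time = 30 + 3 * .data$city_dist,
      urban = as.integer(.data$travel_time < 150),
      altitude = field_altitude(.data$lat, .data$lon),
      slope = field_slope(.data$lat, .data$lon),
      tree_cover = field_tree(.data$lat, .data$lon),
      pasture = field_pasture(.data$lat, .data$lon),
      survey_date_num = month_index(.data$survey_start)
    ) |>
    select(-"city_dist")

  months <- seq(config$months_span[1], config$months_span[2])
  rasters <- list(
    sif = raster_series(ctry, months, config, .SRC[["sif"]],
      base = function(lat, lon) 1 + 0.4 * sin(0.7 * lon) * cos(0.9 * lat),
      amp = 0.3, sd_noise = 0.08, yr_sd = 0.15, floor = NULL
    ),
    lst = raster_series(ctry, months, config, .SRC[["lst"]],
      base = function(lat, lon) 30 + 4 * cos(0.6 * lon + 0.3 * lat),
      amp = 5, sd_noise = 1, yr_sd = 1.5, floor = NULL
    ),
    precip = raster_series(ctry, months, config, .SRC[["precip"]],
      base = function(lat, lon) 100 + 50 * sin(0.5 * lon - 0.4 * lat),
      amp = 60, sd_noise = 12, yr_sd = 20, floor = 0
    )
  )

  markets <- market_prices(ctry, cities, months, config)
  conflicts <- conflict_events(ctry, config)

  # engineered features, survey by survey
  ea <- ea |>
    group_by(.data$country, .data$year) |>
    group_modify(function(df, key) {
      start <- df$survey_start[1]
      for (src in names(rasters)) {
        ser <- rasters[[src]][rasters[[src]]$country == key$country, ]
        df[[paste0(src, "_anom")]] <-
          seasonal_anomaly_features(ser, df$lat, df$lon, start)
      }
      cw <- conflict_window_counts(conflicts, key$country, start)
      df$conflict_events <- cw$events
      df$conflict_deaths <- cw$deaths
      pr <- markets[markets$country == key$country, ]
      df <- dplyr::bind_cols(df, price_feature_block(pr, df$lat, df$lon, start))
      df
    }) |>
    ungroup()

  # outcomes: logistic ground truth + correlated noise, clipped to [0, 1]
  base_year <- mean(range(unlist(config$years)))
  eta <- truth_logit(ea, config, (ea$year - base_year) / 2)
  # logistic link scaled into [0.12, 0.88]: keeps the noisy prevalences away
  # from the clipping bounds so the clip fraction stays negligible
  mu <- 0.12 + 0.76 * plogis(eta)
  set.seed(sub_seed(seed, .SRC[["noise"]]))
  eps <- matrix(rnorm(nrow(ea) * 5), nrow(ea)) %*% chol(config$outcome_noise_cov)
  pre_clip <- mu + eps
  y <- clip01(pre_clip)
  colnames(y) <- OUTCOMES
  ea <- dplyr::bind_cols(ea, as_tibble(y))

  structure(
    list(
      ea_table = ea,
      rasters = rasters,
      markets = markets,
      conflicts = conflicts,
      countries = ctry,
      truth = list(
        mu = mu, pre_clip = pre_clip,
        noise_cov = config$outcome_noise_cov,
        clip_fraction = mean(pre_clip < 0 | pre_clip > 1),
        link = truth_logit
      ),
      config = config
    ),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> %d countries, %d surveys, %d EAs (clip fraction %.3g)\n",
    nrow(x$countries),
    nrow(dplyr::distinct(x$ea_table, .data$country, .data$year)),
    nrow(x$ea_table), x$truth$clip_fraction
  ))
  invisible(x)
}

# One gridded monthly source over all country boxes: smooth base field +
# seasonal harmonic + per-(country, year) anomaly + cell-month noise.
raster_series <- function(ctry, months, config, seed_offset, base, amp,
                          sd_noise, yr_sd, floor = NULL) {
  set.seed(sub_seed(config$seed, seed_offset))
  res <- config$grid_resolution_deg
  purrr::map_dfr(seq_len(nrow(ctry)), function(i) {
    b <- ctry[i, ]
    lats <- seq(b$lat_min + res / 2, b$lat_max - res / 2, by = res)
    lons <- seq(b$lon_min + res / 2, b$lon_max - res / 2, by = res)
    cells <- expand.grid(lat = lats, lon = lons, KEEP.OUT.ATTRS = FALSE)
    yrs <- sort(unique(2000 + months %/% 12))
    yr_eff <- setNames(rnorm(length(yrs), 0, yr_sd), yrs)
    phase <- runif(1, 0, 12)
    grid <- tidyr::crossing(cells, month = months)
    moy <- month_of_year(grid$month)
    v <- base(grid$lat, grid$lon) +
      amp * cos(2 * pi * (moy - phase) / 12) +
      yr_eff[as.character(2000 + grid$month %/% 12)] +
      rnorm(nrow(grid), 0, sd_noise)
    if (!is.null(floor)) v <- pmax(floor, v)
    tibble(
      country = b$country, lat = grid$lat, lon = grid$lon,
      month = grid$month, value = unname(v)
    )
  })
}

# Monthly market price tables: commodity base level x country factor x
# seasonal cycle x slow random walk, always positive.
market_prices <- function(ctry, cities, months, config) {
  set.seed(sub_seed(config$seed, .SRC[["markets"]]))
  commodities <- head(
    c("maize", "rice", "beans", "sorghum", "wheat", "millet"),
    config$n_commodities
  )
  base_price <- setNames(
    runif(length(commodities), 0.3, 2),
    commodities
  )
  purrr::map_dfr(seq_len(nrow(ctry)), function(i) {
    b <- ctry[i, ]
    mk <- cities[cities$country == b$country, ]
    purrr::map_dfr(seq_len(nrow(mk)), function(m) {
      purrr::map_dfr(commodities, function(cm) {
        n <- length(months)
        rw <- cumsum(rnorm(n, 0, 0.01))
        price <- base_price[[cm]] * (1 + 0.2 * runif(1)) *
          (1 + 0.1 * sin(2 * pi * month_of_year(months) / 12) + rw)
        tibble(
          country = b$country, market = mk$city[m],
          market_lat = mk$lat[m], market_lon = mk$lon[m],
          commodity = cm, month = months,
          price = pmax(0.05, price), unit = "USD/kg"
        )
      })
    })
  })
}

# Violent events: Poisson count per country-year, uniform dates, mostly
# single-day with a geometric tail of multi-day events; ~5% lack a
# georeference and ~3% lack an end timestamp (to exercise the prefilter).
conflict_events <- function(ctry, config) {
  set.seed(sub_seed(config$seed, .SRC[["conflicts"]]))
  yr_range <- range(unlist(config$years))
  yrs <- (yr_range[1] - 2):yr_range[2]
  purrr::map_dfr(seq_len(nrow(ctry)), function(i) {
    b <- ctry[i, ]
    purrr::map_dfr(yrs, function(yr) {
      n <- rpois(1, config$conflict_rate)
      if (n == 0) {
        return(NULL)
      }
      start <- as.Date(sprintf("%d-01-01", yr)) +
        sample.int(365, n, replace = TRUE) - 1
      dur <- ifelse(runif(n) < 0.2, rpois(n, 20), 0)
      no_geo <- runif(n) < 0.05
      no_time <- runif(n) < 0.03
      tibble(
        country = b$country,
        lat = ifelse(no_geo, NA_real_, runif(n, b$lat_min, b$lat_max)),
        lon = ifelse(no_geo, NA_real_, runif(n, b$lon_min, b$lon_max)),
        start = start,
        end = dplyr::if_else(no_time, as.Date(NA), start + dur),
        deaths = 1L + rpois(n, 2)
      )
    })
  })
}

#' Export the flat enumeration-area table
#'
#' One row per EA in the released-data schema: country, survey year,
#' coordinates, urban flag, the five prevalence outcomes, and every
#' engineered feature. Round-trips losslessly through [read_flat_table()].
#'
#' @param world A [generate_world()] result.
#' @return A tibble.
#' @export
export_flat_table <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  first <- c(
    "country", "year", "ea_id", "lat", "lon", "urban",
    "survey_start", OUTCOMES
  )
  world$ea_table[c(first, setdiff(names(world$ea_table), first))]
}
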