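# Flat-table IO (released-data schema), auxiliary CSV readers, configuration
# and the end-to-end pipeline entry point.

REQUIRED_COLS <- c("country", "year", "lat", "lon", "urban")

#' Read a flat enumeration-area table
#'
#' Reads the released-data CSV schema: country code, survey year, latitude,
#' longitude, urban flag, the five prevalence outcomes, and any number of
#' feature columns. Column names can be mapped through an alias list (canonical
#' name -> file column name), since released headers vary. Outcomes outside
#' `[0, 1]` and coordinates outside valid ranges are flagged in the schema
#' report and set to missing so the downstream missingness filter removes
#' them.
#'
#' @param path CSV file with a header row; missing values as empty cells.
#' @param aliases Optional named character vector or YAML file path mapping
#'   canonical column names to the file's column names.
#' @return A tibble, with the validation report in `attr(., "schema_report")`
#'   (see [schema_report()]).
#' @export
read_flat_table <- function(path, aliases = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tbl) == 0) abort("Flat table is empty.")
  if (is.character(aliases) && length(aliases) == 1 && file.exists(aliases)) {
    aliases <- unlist(yaml::read_yaml(aliases))
  }
  if (!is.null(aliases)) {
    for (canon in names(aliases)) {
      if (aliases[[canon]] %in% names(tbl)) {
        names(tbl)[names(tbl) == aliases[[canon]]] <- canon
      }
    }
  }
  missing_req <- setdiff(c(REQUIRED_COLS, OUTCOMES), names(tbl))
  if (length(missing_req) > 0) {
    abort(paste0(
      "Flat table lacks required columns: ",
      paste(missing_req, collapse = ", ")
    ))
  }
  report <- list()
  for (oc in OUTCOMES) {
    bad <- which(!is.na(tbl[[oc]]) & (tbl[[oc]] < 0 | tbl[[oc]] > 1))
    if (length(bad) > 0) {
      report[[length(report) + 1]] <- tibble(
        column = oc, rows = list(bad), issue = "outcome outside [0, 1]"
      )
      tbl[[oc]][bad] <- NA_real_
    }
  }
  bad_coord <- which(abs(tbl$lat) > 90 | abs(tbl$lon) > 180)
  if (length(bad_coord) > 0) {
    report[[length(report) + 1]] <- tibble(
      column = "lat/lon", rows = list(bad_coord), issue = "invalid coordinates"
    )
  }
  attr(tbl, "schema_report") <- dplyr::bind_rows(report)
  tbl
}

#' @rdname read_flat_table
#' @param data A table returned by [read_flat_table()].
#' @export
schema_report <- function(data) {
  attr(data, "schema_report") %||% tibble()
}

#' Write a flat enumeration-area table
#'
#' CSV with a header row, UTF-8, `.` decimal separator, missing values as
#' empty cells.
#'
#' @param data Flat EA tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flat_table <- function(data, path) {
  readr::write_csv(data, path, na = "")
  invisible(path)
}

#' Read a long-format raster CSV
#'
#' Columns `lat`, `lon`, `month` (consecutive month index), `value`, and
#' optionally `country`.
#' @param path CSV path.
#' @return Tibble.
#' @export
read_raster_csv <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- setdiff(c("lat", "lon", "month", "value"), names(tbl))
  if (length(need) > 0) {
    abort(paste0("Raster CSV lacks columns: ", paste(need, collapse = ", ")))
  }
  tbl
}

#' Read a market price CSV
#'
#' Columns `market`, `market_lat`, `market_lon`, `commodity`, `month`,
#' `price`, optionally `unit` and `country`.
#' @param path CSV path.
#' @return Tibble.
#' @export
read_prices_csv <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- setdiff(
    c("market", "market_lat", "market_lon", "commodity", "month", "price"),
    names(tbl)
  )
  if (length(need) > 0) {
    abort(paste0("Price CSV lacks columns: ", paste(need, collapse = ", ")))
  }
  tbl
}

#' Read a conflict-event CSV
#'
#' Columns `country`, `start`, `end` (ISO-8601 dates), `deaths`, and
#' optionally `lat`, `lon`.
#' @param path CSV path.
#' @return Tibble with `Date` columns.
#' @export
read_conflicts_csv <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- setdiff(c("country", "start", "end", "deaths"), names(tbl))
  if (length(need) > 0) {
    abort(paste0("Conflict CSV lacks columns: ", paste(need, collapse = ", ")))
  }
  tbl$start <- as.Date(tbl$start)
  tbl$end <- as.Date(tbl$end)
  tbl
}

default_pipeline_config <- function() {
  list(
    input = NULL, # path to a flat table; NULL -> simulate
    world = list(), # world_config() overrides when simulating
    regimes = c("sequential", "contemporaneous"),
    variants = c("irf", "mrf"),
    forest = list(trees = 2000, max_depth = 4, dsr = 1 / 3),
    n_folds = 5,
    range_source = "test",
    seed = 1
  )
}

#' Run the full pipeline
#'
#' Orchestrates simulate (or read) -> evaluate (each requested regime, both
#' model variants) -> reports. Every artifact is a CSV stamped in the run log
#' with the configuration hash and seeds; reruns with the same config and
#' seed produce identical files.
#'
#' @param config A list (see `default_pipeline_config()` internals for the
#'   fields) or the path to a YAML file with the same structure. Unspecified
#'   fields take their defaults.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the per-regime `regime_evaluation` objects
#'   and the written file paths.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("mrf_run_")) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- modifyList(default_pipeline_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_lines <- c(
    sprintf("config_hash: %s", rlang::hash(cfg)),
    sprintf("seed: %d", cfg$seed)
  )
  stage <- function(name, expr) {
    st <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
    log_lines <<- c(log_lines, sprintf(
      "stage %s: %.2fs", name,
      as.numeric(difftime(Sys.time(), st, units = "secs"))
    ))
    res
  }

  flat <- stage("input", {
    if (is.null(cfg$input)) {
      wc <- do.call(world_config, modifyList(
        list(seed = cfg$seed),
        cfg$world
      ))
      export_flat_table(generate_world(wc))
    } else {
      read_flat_table(cfg$input, aliases = cfg$aliases)
    }
  })

  evals <- list()
  paths <- character()
  for (rg in cfg$regimes) {
    ev <- stage(rg, evaluate_regime(
      flat,
      regime = rg, n_folds = cfg$n_folds,
      trees = cfg$forest$trees, max_depth = cfg$forest$max_depth,
      dsr = cfg$forest$dsr,
      bootstrap = cfg$forest$bootstrap %||% TRUE,
      min_leaf = cfg$forest$min_leaf %||% 2,
      variants = cfg$variants, range_source = cfg$range_source,
      seed = cfg$seed
    ))
    evals[[rg]] <- ev
    p <- file.path(out_dir, sprintf("metrics_%s.csv", rg))
    readr::write_csv(ev$metrics, p)
    paths <- c(paths, p)
    p <- file.path(out_dir, sprintf("importance_%s.csv", rg))
    readr::write_csv(ev$importance, p)
    paths <- c(paths, p)
    gi <- ev$importance |>
      group_by(.data$variant, .data$feature) |>
      summarise(mdi = mean(.data$mdi), .groups = "drop") |>
      group_by(.data$variant) |>
      group_modify(~ grouped_importance(.x)) |>
      ungroup()
    p <- file.path(out_dir, sprintf("grouped_importance_%s.csv", rg))
    readr::write_csv(gi, p)
    paths <- c(paths, p)
    maps <- ev$predictions |>
      filter(.data$variant == dplyr::last(sort(ev$config$variants))) |>
      select(
        "country", "year", "fold", "lat", "lon", "outcome",
        mean = "yhat", "sd"
      )
    p <- file.path(out_dir, sprintf("nowcast_map_%s.csv", rg))
    readr::write_csv(maps, p)
    paths <- c(paths, p)
    p <- file.path(out_dir, sprintf("filter_log_%s.csv", rg))
    readr::write_csv(
      tidyr::unnest(ev$filter_log,
        cols = "dropped_features",
        keep_empty = TRUE
      ), p
    )
    paths <- c(paths, p)
  }
  log_lines <- c(log_lines, sprintf(
    "total: %.2fs",
    as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(
    evaluations = evals, paths = c(paths, file.path(out_dir, "run_log.txt")),
    out_dir = out_dir, config = cfg
  ))
}
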