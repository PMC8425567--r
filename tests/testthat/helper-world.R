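# Shared small-world fixtures, built once per test run.

tiny_config <- function(...) {
  world_config(
    n_countries = 2, years = c(2008, 2011), eas_per_survey = 40, seed = 42,
    ...
  )
}

# memoised default tiny world (several test files reuse it)
tiny_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_world(tiny_config())
    cache
  }
})

# a 12-month single-season-varying series around the origin:
# cells on a small grid, one value per (cell, month)
flat_series <- function(value = 5, months = NULL, cells = NULL) {
  months <- months %||% (month_index(2011, 4) - 12):(month_index(2011, 4) - 1)
  cells <- cells %||% expand.grid(lat = c(0, 0.3, 0.6), lon = c(0, 0.3))
  out <- merge(cells, data.frame(month = months))
  out$value <- value
  out
}
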