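# Shared helpers: great-circle distance, month arithmetic, seed derivation.

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km. Inputs are recycled to a
#' common length.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Numeric vector of distances in km.
#' @export
#' @examples
#' haversine_km(0, 0, 0, 1) # ~111 km
haversine_km <- function(lat1, lon1, lat2, lon2) {
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = 6371000) / 1000
}

# Consecutive calendar-month index: Jan 2000 -> 0, Feb 2000 -> 1, ...
# All monthly series (rasters, prices) are keyed by this index so that window
# arithmetic is plain integer arithmetic.

#' Convert dates or (year, month) pairs to a consecutive month index
#'
#' The index counts calendar months with January 2000 at zero, so windows such
#' as "the 12 months strictly before a survey start" are integer ranges.
#'
#' @param x A `Date` vector, or an integer year when `month` is given.
#' @param month Optional month-of-year (1-12) when `x` is a year.
#' @return Integer month indices.
#' @export
#' @examples
#' month_index(as.Date("2013-03-15"))
#' month_index(2013, 3)
month_index <- function(x, month = NULL) {
  if (!is.null(month)) {
    return(as.integer((as.integer(x) - 2000L) * 12L + as.integer(month) - 1L))
  }
  x <- as.Date(x)
  lt <- as.POSIXlt(x)
  as.integer((lt$year + 1900L - 2000L) * 12L + lt$mon)
}

#' Month-of-year (1-12) of a month index
#' @param mi Integer month index (see [month_index()]).
#' @return Integer in 1..12.
#' @export
month_of_year <- function(mi) {
  as.integer(((mi %% 12L) + 12L) %% 12L + 1L)
}

# Fixed per-source seed offsets: adding a data source never perturbs another
# source's draws. Kept < 2^31 by taking the sum modulo a large prime.
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% 2147483629)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopifnot_pd <- function(m, name = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort(sprintf("`%s` must be a square matrix.", name))
  }
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) {
    abort(sprintf("`%s` must be symmetric.", name))
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    abort(sprintf(
      "`%s` must be positive definite (smallest eigenvalue %.3g).",
      name, min(ev)
    ))
  }
  invisible(m)
}
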