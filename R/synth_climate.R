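#' Specification for a synthetic daily climate series
#'
#' Each of the five driver variables is generated as a seasonal sinusoid
#' plus AR(1) Gaussian anomalies:
#' \deqn{x(d) = \mu + A \cos(2\pi (d - d_{peak}) / 365.25) + a(d)}
#' with `a(d) = rho * a(d-1) + e(d)`, `e ~ N(0, sd^2 (1 - rho^2))`, so the
#' marginal anomaly standard deviation is `sd` and the lag-1
#' autocorrelation is `rho`. Precipitation anomalies act multiplicatively
#' on a log scale (the seasonal cycle is scaled by `exp(a)`), which keeps
#' precipitation nonnegative without hard clipping; insolation and wind are
#' clipped at zero. Minimum temperature is derived as maximum temperature
#' minus a stochastic diurnal range (itself AR(1), floored at
#' `min_drange`), so `tmin <= tmax` holds on every day.
#'
#' Defaults emulate a temperate monsoon-climate site: mid-July temperature
#' peak, summer-peaked rainfall and insolation, spring-peaked wind.
#'
#' @param n_years number of complete calendar years to generate.
#' @param start_year first calendar year.
#' @param tmax,pre,ins,win per-variable parameter lists with elements
#'   `mean`, `amplitude`, `peak_doy`, `sd` (anomaly standard deviation) and
#'   `rho` (AR(1) coefficient in `[0, 1)`).
#' @param drange diurnal-range parameters (`mean`, `amplitude`, `peak_doy`,
#'   `sd`, `rho`); tmin = tmax - range.
#' @param min_drange floor on the diurnal range (deg C).
#' @param seed integer random seed.
#' @return An object of class `climate_gen_spec`.
#' @export
climate_gen_spec <- function(n_years = 40, start_year = 1979,
                             tmax = list(mean = 18, amplitude = 14,
                                         peak_doy = 197, sd = 3.5,
                                         rho = 0.75),
                             drange = list(mean = 10, amplitude = 2,
                                           peak_doy = 120, sd = 1.5,
                                           rho = 0.5),
                             pre = list(mean = 2.5, amplitude = 2,
                                        peak_doy = 190, sd = 1,
                                        rho = 0.5),
                             ins = list(mean = 15, amplitude = 8,
                                        peak_doy = 172, sd = 3,
                                        rho = 0.6),
                             win = list(mean = 2.5, amplitude = 0.5,
                                        peak_doy = 100, sd = 0.8,
                                        rho = 0.5),
                             min_drange = 0.5, seed = 1) {
  spec <- list(n_years = as.integer(n_years),
               start_year = as.integer(start_year),
               tmax = tmax, drange = drange, pre = pre, ins = ins,
               win = win, min_drange = min_drange, seed = as.integer(seed))
  if (spec$n_years < 1) stopf("n_years must be >= 1")
  for (v in c("tmax", "drange", "pre", "ins", "win")) {
    p <- spec[[v]]
    if (p$amplitude < 0) stopf("%s amplitude must be >= 0", v)
    if (p$sd < 0) stopf("%s anomaly sd must be >= 0", v)
    if (p$rho < 0 || p$rho >= 1) stopf("%s rho must lie in [0, 1)", v)
  }
  structure(spec, class = "climate_gen_spec")
}

# stationary AR(1) with marginal sd `sd` and lag-1 autocorrelation `rho`
ar1_series <- function(n, rho, sd) {
  if (sd == 0) return(numeric(n))
  e <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  e[1] <- stats::rnorm(1, 0, sd)
  as.numeric(stats::filter(e, rho, method = "recursive"))
}

seasonal_cycle <- function(doy, p) {
  p$mean + p$amplitude * cos(2 * pi * (doy - p$peak_doy) / 365.25)
}

#' Generate a synthetic daily climate table
#'
#' @param spec a [climate_gen_spec()].
#' @param site_id site label for the generated rows.
#' @return A `climate_table` data frame with columns `site_id`, `date`,
#'   `tmax`, `tmin`, `pre`, `ins`, `win`. Identical specs (including the
#'   seed) give identical tables.
#' @export
#' @examples
#' cl <- gen_climate(climate_gen_spec(n_years = 2, seed = 7), "demo")
#' range(cl$date)
gen_climate <- function(spec, site_id = "site1") {
  stopifnot(inherits(spec, "climate_gen_spec"))
  set.seed(spec$seed)
  d0 <- as.Date(sprintf("%d-01-01", spec$start_year))
  d1 <- as.Date(sprintf("%d-12-31", spec$start_year + spec$n_years - 1L))
  dates <- seq(d0, d1, by = "day")
  doy <- doy_of(dates)
  n <- length(dates)
  tmax <- seasonal_cycle(doy, spec$tmax) +
    ar1_series(n, spec$tmax$rho, spec$tmax$sd)
  dr <- pmax(spec$min_drange,
             seasonal_cycle(doy, spec$drange) +
               ar1_series(n, spec$drange$rho, spec$drange$sd))
  tmin <- tmax - dr
  # multiplicative (log-scale) anomalies keep precipitation nonnegative
  pre_base <- pmax(0, seasonal_cycle(doy, spec$pre))
  pre <- pre_base * exp(ar1_series(n, spec$pre$rho, spec$pre$sd) -
                          spec$pre$sd^2 / 2)
  ins <- pmax(0, seasonal_cycle(doy, spec$ins) +
                ar1_series(n, spec$ins$rho, spec$ins$sd))
  win <- pmax(0, seasonal_cycle(doy, spec$win) +
                ar1_series(n, spec$win$rho, spec$win$sd))
  df <- data.frame(site_id = site_id, date = dates, tmax = tmax,
                   tmin = tmin, pre = pre, ins = ins, win = win,
                   stringsAsFactors = FALSE)
  class(df) <- c("climate_table", "data.frame")
  df
}
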