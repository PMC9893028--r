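#' Specification for a synthetic phenological response
#'
#' Encodes the linear driver structure assumed by the interannual analysis:
#' for year `y`,
#' \deqn{doy_y = base + trend (y - y_0) + \sum_v \beta_v \bar{x}_{v,y} +
#'   \gamma FLD_y + \epsilon_y,\quad \epsilon \sim N(0, \sigma^2)}
#' where `x_{v,y}` is the mean of climate variable `v` over its true
#' preseason window of `lengths[v]` days ending the day before `base_doy`,
#' expressed as an anomaly (centered on the across-year mean of that window
#' series), and `FLD_y` is likewise centered. Centering makes `base_doy`
#' the expected series mean, so the anchor recovered by
#' [optimal_preseason()] coincides with the windows the series was built
#' from.
#'
#' Default window lengths follow typical observed preseason durations for
#' temperate autumn phenology (about 1.5-2.5 months, longest for maximum
#' temperature).
#'
#' @param base_doy expected day-of-year of the event.
#' @param lengths named integer vector of true preseason lengths in days
#'   (1..150) for `tmax`, `tmin`, `pre`, `ins`, `win`.
#' @param beta named numeric vector of response coefficients, days per unit
#'   of the aggregated variable.
#' @param fld_coeff days of response per day of (centered) first-leaf-date
#'   anomaly.
#' @param noise_sd interannual noise standard deviation, days.
#' @param trend linear trend, days per year (anchored at the first year).
#' @param seed integer random seed.
#' @return An object of class `response_spec`.
#' @export
response_spec <- function(base_doy = 280,
                          lengths = c(tmax = 78, tmin = 60, pre = 45,
                                      ins = 58, win = 43),
                          beta = c(tmax = 0, tmin = 0, pre = 0,
                                   ins = 0, win = 0),
                          fld_coeff = 0, noise_sd = 3, trend = 0,
                          seed = 1) {
  vars <- c("tmax", "tmin", "pre", "ins", "win")
  lengths <- lengths[vars]
  beta <- beta[vars]
  names(lengths) <- names(beta) <- vars
  beta[is.na(beta)] <- 0
  if (anyNA(lengths) || any(lengths < 1) || any(lengths > 150))
    stopf("all window lengths must be given and lie in [1, 150]")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(base_doy = as.integer(base_doy),
                 lengths = setNames(as.integer(lengths), vars),
                 beta = setNames(as.numeric(beta), vars),
                 fld_coeff = fld_coeff, noise_sd = noise_sd, trend = trend,
                 seed = as.integer(seed)),
            class = "response_spec")
}

#' Generate a synthetic phenological series from daily climate
#'
#' Builds one species x site series as a linear response to climate
#' aggregated over known preseason windows (see [response_spec()]), plus an
#' optional dependence on a spring series and Gaussian noise. With
#' `noise_sd = 0` and a single nonzero coefficient the construction is
#' exactly invertible by the preseason search.
#'
#' @param climate a `climate_table` covering one site.
#' @param spec a [response_spec()].
#' @param event `"LCD"` or `"FLD"` label for the output series.
#' @param fld optional [pheno_series] supplying the spring predictor when
#'   `spec$fld_coeff != 0`.
#' @param species_id,site_id labels for the output series; `site_id`
#'   defaults to the (single) site in `climate`.
#' @param round_doy round responses to whole days (the observational
#'   convention). Set `FALSE` for exact-arithmetic checks.
#' @return A [pheno_series].
#' @export
gen_phenology <- function(climate, spec, event = "LCD", fld = NULL,
                          species_id = "sp1", site_id = NULL,
                          round_doy = TRUE) {
  stopifnot(inherits(spec, "response_spec"))
  sites <- unique(climate$site_id)
  if (is.null(site_id)) {
    if (length(sites) != 1)
      stopf("climate covers %d sites; pass site_id", length(sites))
    site_id <- sites
  }
  vars <- names(spec$lengths)
  if (spec$base_doy - max(spec$lengths) < 1)
    stopf("preseason window extends before the start of the calendar year")
  years <- sort(unique(year_of(climate$date[climate$site_id == site_id])))
  wm <- matrix(NA_real_, length(years), length(vars),
               dimnames = list(years, vars))
  for (v in vars) {
    w <- window_aggregate(climate, v, spec$base_doy, spec$lengths[[v]],
                          years, site_id = site_id)
    wm[names(w), v] <- w
  }
  keep <- stats::complete.cases(wm)
  if (!any(keep))
    stopf("no year has complete climate coverage of the response windows")
  years <- years[keep]
  wm <- wm[keep, , drop = FALSE]
  # anomalies: coefficients act on departures from the period climatology
  wm <- sweep(wm, 2, colMeans(wm))
  doy <- spec$base_doy + spec$trend * (years - years[1]) +
    as.numeric(wm %*% spec$beta)
  if (spec$fld_coeff != 0) {
    if (is.null(fld))
      stopf("fld series required when fld_coeff != 0")
    m <- match(years, fld$year)
    if (anyNA(m))
      stopf("fld series missing year(s): %s",
            paste(years[is.na(m)], collapse = ", "))
    doy <- doy + spec$fld_coeff * (fld$doy[m] - mean(fld$doy[m]))
  }
  set.seed(spec$seed)
  doy <- doy + stats::rnorm(length(years), 0, spec$noise_sd)
  if (round_doy) doy <- round(doy)
  pheno_series(species_id, site_id, event, years, doy)
}

#' Generate a synthetic spring (first leaf date) series
#'
#' Convenience wrapper: a spring series driven by minimum temperature over
#' an early-season window, generated with the same machinery as
#' [gen_phenology()].
#'
#' @param climate a `climate_table` covering one site.
#' @param base_doy expected first-leaf day-of-year.
#' @param beta_tmin response to the spring minimum-temperature anomaly,
#'   days per deg C (negative: warm springs advance leaf-out).
#' @param length_tmin spring window length, days.
#' @param noise_sd,trend,seed as in [response_spec()].
#' @param species_id,site_id,round_doy as in [gen_phenology()].
#' @return A [pheno_series] with `event = "FLD"`.
#' @export
gen_fld <- function(climate, base_doy = 120, beta_tmin = -3,
                    length_tmin = 40, noise_sd = 3, trend = 0, seed = 1,
                    species_id = "sp1", site_id = NULL, round_doy = TRUE) {
  spec <- response_spec(base_doy = base_doy,
                        lengths = c(tmax = 1, tmin = length_tmin, pre = 1,
                                    ins = 1, win = 1),
                        beta = c(tmax = 0, tmin = beta_tmin, pre = 0,
                                 ins = 0, win = 0),
                        noise_sd = noise_sd, trend = trend, seed = seed)
  gen_phenology(climate, spec, event = "FLD", species_id = species_id,
                site_id = site_id, round_doy = round_doy)
}
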