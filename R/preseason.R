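# Preseason window determination: climate aggregation over windows of
# 1..150 days ending the day before the multi-year mean event date, and
# the search for the window length with the strongest Pearson correlation.

# year x doy (1..366) matrix of one climate variable at one site
climate_doy_matrix <- function(climate, variable, site_id, years = NULL) {
  if (!variable %in% c("tmax", "tmin", "pre", "ins", "win"))
    stopf("unknown climate variable '%s'", variable)
  cl <- climate[climate$site_id == site_id, ]
  if (nrow(cl) == 0) stopf("no climate rows for site '%s'", site_id)
  yr <- year_of(cl$date)
  if (is.null(years)) years <- sort(unique(yr))
  keep <- yr %in% years
  M <- matrix(NA_real_, length(years), 366,
              dimnames = list(years, NULL))
  M[cbind(match(yr[keep], years), doy_of(cl$date[keep]))] <-
    cl[[variable]][keep]
  M
}

#' Aggregate a climate variable over a fixed preseason window
#'
#' Computes, for each requested year, the arithmetic mean of the daily
#' variable over the `length_days` days ending the day before `anchor_doy`
#' (days `anchor - length .. anchor - 1`, inclusive, within the calendar
#' year). Years with any missing day in the window are excluded and
#' reported via the `"excluded_years"` attribute.
#'
#' @param climate a `climate_table` (see [read_climate()]).
#' @param variable one of `"tmax"`, `"tmin"`, `"pre"`, `"ins"`, `"win"`.
#' @param anchor_doy 1-based day-of-year the window ends before.
#' @param length_days window length in days (>= 1).
#' @param years integer vector of years to aggregate (default: all years
#'   present for the site).
#' @param site_id site to aggregate; defaults to the single site present.
#' @return Named numeric vector of per-year window means (names = years),
#'   with attribute `excluded_years`.
#' @export
window_aggregate <- function(climate, variable, anchor_doy, length_days,
                             years = NULL, site_id = NULL) {
  if (is.null(site_id)) {
    sites <- unique(climate$site_id)
    if (length(sites) != 1)
      stopf("climate covers %d sites; pass site_id", length(sites))
    site_id <- sites
  }
  length_days <- as.integer(length_days)
  anchor_doy <- as.integer(anchor_doy)
  if (length_days < 1) stopf("length_days must be >= 1")
  if (anchor_doy - length_days < 1)
    stopf("window extends before the start of the calendar year")
  M <- climate_doy_matrix(climate, variable, site_id, years)
  win <- (anchor_doy - length_days):(anchor_doy - 1L)
  vals <- rowMeans(M[, win, drop = FALSE])
  yrs <- as.integer(rownames(M))
  out <- stats::setNames(vals[!is.na(vals)], yrs[!is.na(vals)])
  attr(out, "excluded_years") <- yrs[is.na(vals)]
  out
}

#' Find the optimal preseason window for one climate variable
#'
#' Anchored at the rounded multi-year mean day-of-year of the series, scans
#' candidate window lengths 1..`max_length` days and returns the length
#' whose window-mean series has the strongest Pearson correlation with the
#' phenological series. Ties go to the shortest window. By default
#' "strongest" is the largest `|r|`, so drivers acting in either direction
#' are detectable; set `criterion = "max"` for the largest signed r.
#'
#' @param series a [pheno_series] (typically leaf coloring dates).
#' @param climate a `climate_table`.
#' @param variable one of `"tmax"`, `"tmin"`, `"pre"`, `"ins"`, `"win"`.
#' @param max_length longest window scanned (default 150 days); truncated
#'   with a warning if the anchor leaves fewer days in the calendar year.
#' @param criterion `"abs"` (default) or `"max"`.
#' @param min_years minimum years shared by the series and every candidate
#'   window (default 15).
#' @return An object of class `preseason_spec`: list with `variable`,
#'   `length_days`, `anchor_doy`, `pearson_r`, `n_years`, and the full
#'   `r_profile` over candidate lengths.
#' @export
optimal_preseason <- function(series, climate, variable, max_length = 150,
                              criterion = c("abs", "max"), min_years = 15) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(series, "pheno_series"))
  anchor <- as.integer(round(mean(series$doy)))
  max_length <- as.integer(max_length)
  if (anchor - max_length < 1) {
    warnf("anchor %d leaves only %d candidate day(s); scan truncated",
          anchor, anchor - 1L)
    max_length <- anchor - 1L
  }
  M <- climate_doy_matrix(climate, variable, series$site_id, series$year)
  scan_cols <- M[, seq_len(anchor - 1L), drop = FALSE]
  ok <- !is.na(rowSums(scan_cols[, (anchor - max_length):(anchor - 1L),
                                 drop = FALSE]))
  if (sum(ok) < min_years)
    stopf("only %d year(s) shared by series and candidate windows (< %d)",
          sum(ok), min_years)
  S <- t(apply(scan_cols[ok, , drop = FALSE], 1, cumsum))
  y <- series$doy[ok]
  # window mean for length L: (S[, anchor-1] - S[, anchor-1-L]) / L
  lens <- seq_len(max_length)
  upper <- S[, anchor - 1L]
  wm <- vapply(lens, function(L) {
    lo <- anchor - 1L - L
    (upper - (if (lo >= 1L) S[, lo] else 0)) / L
  }, numeric(sum(ok)))
  r <- suppressWarnings(as.numeric(stats::cor(y, wm)))
  score <- if (criterion == "abs") abs(r) else r
  score[is.na(score)] <- -Inf
  best <- which.max(score)  # first (shortest) maximizer on ties
  structure(list(variable = variable, length_days = as.integer(best),
                 anchor_doy = anchor, pearson_r = r[best],
                 n_years = sum(ok),
                 r_profile = stats::setNames(r, lens)),
            class = "preseason_spec")
}

#' @export
print.preseason_spec <- function(x, ...) {
  cat(sprintf("<preseason_spec> %s: %d days before DOY %d (r = %.3f, n = %d)\n",
              x$variable, x$length_days, x$anchor_doy, x$pearson_r,
              x$n_years))
  invisible(x)
}
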