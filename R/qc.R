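#' MAD-based outlier screen for a phenological series
#'
#' Removes years whose day-of-year deviates from the series median by more
#' than `k` times the (unscaled) median absolute deviation. The median and
#' MAD are computed once on the input series (single pass), and removal
#' uses a strict inequality, so boundary values are kept and at most half
#' of the records can ever be removed.
#'
#' @param series a [pheno_series].
#' @param k multiplier on the MAD (default 2).
#' @return A list with `series` (the filtered [pheno_series]) and
#'   `removed_years` (integer vector, possibly empty).
#' @export
#' @examples
#' s <- pheno_series("sp1", "a", "LCD", 1990:1994, c(281, 282, 280, 283, 360))
#' mad_outlier_filter(s)$removed_years  # the 360 record only
mad_outlier_filter <- function(series, k = 2) {
  stopifnot(inherits(series, "pheno_series"))
  if (length(series$doy) == 0) stopf("series is empty")
  med <- stats::median(series$doy)
  dev <- abs(series$doy - med)
  mad_ <- stats::median(dev)
  drop <- dev > k * mad_
  out <- series
  out$year <- series$year[!drop]
  out$doy <- series$doy[!drop]
  list(series = out, removed_years = series$year[drop])
}

#' Minimum-record-length filter across paired LCD/FLD series
#'
#' A species x site combination is retained only if its leaf-coloring
#' series and (when `require_both`) its first-leaf series each cover at
#' least `min_years` years. Apply after [mad_outlier_filter()].
#'
#' @param series_list list of [pheno_series] (both events, any order).
#' @param min_years minimum years per event series (default 15, boundary
#'   inclusive).
#' @param require_both require both LCD and FLD to meet the minimum
#'   (default `TRUE`); if `FALSE`, only LCD is checked.
#' @return Data frame of retained combinations (`species_id`, `site_id`),
#'   in input order of first appearance.
#' @export
min_years_filter <- function(series_list, min_years = 15,
                             require_both = TRUE) {
  if (!length(series_list))
    return(data.frame(species_id = character(), site_id = character()))
  key <- vapply(series_list, function(s)
    paste(s$species_id, s$site_id, sep = "\r"), character(1))
  ev <- vapply(series_list, function(s) s$event, character(1))
  ny <- vapply(series_list, function(s) length(s$year), integer(1))
  keys <- unique(key)
  ok <- vapply(keys, function(k) {
    lcd <- ny[key == k & ev == "LCD"]
    fld <- ny[key == k & ev == "FLD"]
    has_lcd <- length(lcd) > 0 && max(lcd) >= min_years
    if (!require_both) return(has_lcd)
    has_lcd && length(fld) > 0 && max(fld) >= min_years
  }, logical(1))
  parts <- strsplit(keys[ok], "\r", fixed = TRUE)
  data.frame(species_id = vapply(parts, `[`, character(1), 1),
             site_id = vapply(parts, `[`, character(1), 2),
             stringsAsFactors = FALSE)
}

#' Quality-control report over a set of series
#'
#' Runs [mad_outlier_filter()] on every series and [min_years_filter()] on
#' the result, returning the filtered series plus a per-series report.
#'
#' @param series_list list of [pheno_series].
#' @param mad_k MAD multiplier (see [mad_outlier_filter()]).
#' @param mad_fld also apply the MAD screen to FLD series (default `TRUE`).
#' @param min_years,require_both see [min_years_filter()].
#' @return A list with `series` (filtered list, retained combinations
#'   only), `report` (data frame: `species_id`, `site_id`, `event`,
#'   `years_in`, `years_removed`, `retained`) and `retained` (data frame of
#'   retained species x site pairs).
#' @export
qc_filter <- function(series_list, mad_k = 2, mad_fld = TRUE,
                      min_years = 15, require_both = TRUE) {
  filtered <- lapply(series_list, function(s) {
    if (s$event == "LCD" || mad_fld) mad_outlier_filter(s, k = mad_k)
    else list(series = s, removed_years = integer())
  })
  fser <- lapply(filtered, `[[`, "series")
  retained <- min_years_filter(fser, min_years = min_years,
                               require_both = require_both)
  rkey <- paste(retained$species_id, retained$site_id)
  report <- do.call(rbind, lapply(seq_along(filtered), function(i) {
    s0 <- series_list[[i]]
    data.frame(species_id = s0$species_id, site_id = s0$site_id,
               event = s0$event, years_in = length(s0$year),
               years_removed = length(filtered[[i]]$removed_years),
               retained = paste(s0$species_id, s0$site_id) %in% rkey,
               stringsAsFactors = FALSE)
  }))
  keep <- vapply(fser, function(s)
    paste(s$species_id, s$site_id) %in% rkey, logical(1))
  list(series = fser[keep], report = report, retained = retained)
}
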