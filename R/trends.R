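#' Linear trend of a phenological series
#'
#' Ordinary least squares of day-of-year on calendar year. The two-sided
#' p-value for the slope comes from the t distribution with `n - 2`
#' degrees of freedom; a perfectly constant series has slope 0 and p = 1,
#' and an exactly linear nonconstant series has p = 0.
#'
#' @param series a [pheno_series] with at least 3 years.
#' @return A one-row data frame: `species_id`, `site_id`, `event`, `slope`
#'   (days/year), `slope_decade` (= 10 * slope), `intercept`, `p_value`,
#'   `n_years`.
#' @export
fit_trend <- function(series) {
  stopifnot(inherits(series, "pheno_series"))
  n <- length(series$year)
  if (n < 3) stopf("trend estimation needs >= 3 years (got %d)", n)
  x <- as.numeric(series$year)
  y <- as.numeric(series$doy)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- sum(xc * y) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  rss <- sum(res^2)
  se <- sqrt(rss / (n - 2) / sxx)
  if (se == 0) {
    p <- if (slope == 0) 1 else 0
  } else {
    p <- 2 * stats::pt(abs(slope / se), df = n - 2, lower.tail = FALSE)
  }
  data.frame(species_id = series$species_id, site_id = series$site_id,
             event = series$event, slope = slope,
             slope_decade = 10 * slope, intercept = intercept,
             p_value = p, n_years = n, stringsAsFactors = FALSE)
}

#' Summarize trend results over species
#'
#' Reports the share of delaying trends (slope strictly greater than 0),
#' the share both delaying and significant, and the mean decadal trend.
#' Because "significant among delayed" and "significant among all" differ
#' only in the denominator and either convention appears in the
#' literature, both are returned.
#'
#' @param results data frame of [fit_trend()] rows.
#' @param alpha significance level (default 0.05).
#' @param region optional region label carried into the output.
#' @return A one-row data frame: `region`, `n_species`, `frac_delayed`,
#'   `frac_delayed_significant` (denominator: all species),
#'   `frac_significant_of_delayed` (denominator: delayed species, `NA` if
#'   none), `mean_slope_decade`.
#' @export
summarize_trends <- function(results, alpha = 0.05, region = "all") {
  if (is.null(results) || nrow(results) == 0)
    stopf("no trend results to summarize")
  delayed <- results$slope > 0
  sig_delayed <- delayed & results$p_value < alpha
  data.frame(region = region, n_species = nrow(results),
             frac_delayed = mean(delayed),
             frac_delayed_significant = mean(sig_delayed),
             frac_significant_of_delayed =
               if (any(delayed)) sum(sig_delayed) / sum(delayed) else NA_real_,
             mean_slope_decade = mean(results$slope_decade),
             stringsAsFactors = FALSE)
}
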