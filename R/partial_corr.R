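#' Partial correlation with an arbitrary control set
#'
#' With no controls this is the Pearson correlation. With one control `z`
#' it is
#' \deqn{R(x,y|z) = \frac{R_{xy} - R_{xz} R_{yz}}
#'   {\sqrt{1 - R_{xz}^2}\sqrt{1 - R_{yz}^2}}}
#' and with several controls the same first-order formula is applied
#' recursively, peeling off one control at a time. This is algebraically
#' identical to correlating the residuals of `x` and `y` after
#' least-squares projection onto the controls (available as
#' `method = "residual"`, used as an internal cross-check). The two-sided
#' p-value uses `t = R sqrt(df / (1 - R^2))` with
#' `df = n - n_controls - 2`.
#'
#' @param x,y numeric vectors of equal length.
#' @param controls list (possibly empty) of control vectors, same length.
#' @param method `"recursion"` (default) or `"residual"`.
#' @return List with `R`, `p`, `n`, `df`.
#' @export
#' @examples
#' partial_corr(c(1, 2, 3), c(2, 4, 6))$R  # 1
partial_corr <- function(x, y, controls = list(),
                         method = c("recursion", "residual")) {
  method <- match.arg(method)
  if (!is.list(controls)) controls <- list(controls)
  n <- length(x)
  if (length(y) != n || any(lengths(controls) != n))
    stopf("all series must have the same length")
  k <- length(controls)
  df <- n - k - 2L
  if (df < 1) stopf("need n - n_controls - 2 >= 1 (n = %d, controls = %d)",
                    n, k)
  vars <- c(list(x, y), controls)
  if (any(vapply(vars, stats::sd, numeric(1)) == 0))
    stopf("zero-variance series supplied")
  if (method == "recursion") {
    Rm <- suppressWarnings(stats::cor(do.call(cbind, vars)))
    R <- pcor_recurse(Rm, 1L, 2L, if (k) 2L + seq_len(k) else integer())
  } else {
    if (k) {
      Z <- cbind(1, do.call(cbind, controls))
      rx <- stats::lm.fit(Z, x)$residuals
      ry <- stats::lm.fit(Z, y)$residuals
      if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
        stopf("a series is collinear with the controls")
      R <- stats::cor(rx, ry)
    } else {
      R <- stats::cor(x, y)
    }
  }
  R <- max(-1, min(1, R))
  t_stat <- R * sqrt(df / max(1 - R^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(t_stat), df = df, lower.tail = FALSE)
  list(R = R, p = p, n = n, df = df)
}

# first-order recursion on a correlation matrix; S indexes the controls
pcor_recurse <- function(Rm, i, j, S) {
  if (!length(S)) return(Rm[i, j])
  z <- S[length(S)]
  S2 <- S[-length(S)]
  rij <- pcor_recurse(Rm, i, j, S2)
  riz <- pcor_recurse(Rm, i, z, S2)
  rjz <- pcor_recurse(Rm, j, z, S2)
  den2 <- (1 - riz^2) * (1 - rjz^2)
  if (den2 <= 1e-12)
    stopf("collinear control: partial correlation undefined")
  (rij - riz * rjz) / sqrt(den2)
}

#' Attribute interannual variation to six drivers by partial correlation
#'
#' For one species x site: finds the optimal preseason for each of the
#' five climate variables (see [optimal_preseason()]), builds the six
#' predictor series (five window means at their own optima, plus same-year
#' first leaf date), restricts all series to the common year set, and
#' computes the partial correlation of each predictor with the leaf
#' coloring series while controlling for the other five.
#'
#' @param lcd [pheno_series] of leaf coloring dates (quality-filtered).
#' @param fld [pheno_series] of first leaf dates, same species and site.
#' @param climate a `climate_table` covering the site.
#' @param max_preseason longest candidate window (default 150 days).
#' @param min_years minimum number of complete-case years (default 15).
#' @param criterion preseason optimality criterion (see
#'   [optimal_preseason()]).
#' @return Object of class `driver_attribution`: list with `table` (long
#'   data frame: `species_id`, `site_id`, `predictor`, `R`, `p`,
#'   `preseason_length`, `n_years`), `anchor_doy` and `preseasons`.
#' @export
attribute_drivers <- function(lcd, fld, climate, max_preseason = 150,
                              min_years = 15, criterion = "abs") {
  stopifnot(inherits(lcd, "pheno_series"), inherits(fld, "pheno_series"))
  if (lcd$event != "LCD" || fld$event != "FLD")
    stopf("expected an LCD series and an FLD series")
  vars <- c("tmax", "tmin", "pre", "ins", "win")
  ps <- lapply(vars, function(v)
    optimal_preseason(lcd, climate, v, max_length = max_preseason,
                      criterion = criterion, min_years = min_years))
  names(ps) <- vars
  wins <- lapply(ps, function(p)
    window_aggregate(climate, p$variable, p$anchor_doy, p$length_days,
                     years = lcd$year, site_id = lcd$site_id))
  years <- Reduce(intersect,
                  c(list(lcd$year, fld$year),
                    lapply(wins, function(w) as.integer(names(w)))))
  years <- sort(years)
  if (length(years) < min_years)
    stopf("only %d complete-case year(s) across all predictors (< %d)",
          length(years), min_years)
  y <- lcd$doy[match(years, lcd$year)]
  preds <- c(lapply(wins, function(w) unname(w[as.character(years)])),
             list(fld = fld$doy[match(years, fld$year)]))
  rows <- lapply(names(preds), function(p) {
    pc <- partial_corr(preds[[p]], y, preds[names(preds) != p])
    data.frame(species_id = lcd$species_id, site_id = lcd$site_id,
               predictor = p, R = pc$R, p = pc$p,
               preseason_length = if (p == "fld") NA_integer_
                                  else ps[[p]]$length_days,
               n_years = length(years), stringsAsFactors = FALSE)
  })
  structure(list(table = do.call(rbind, rows),
                 anchor_doy = ps[[1]]$anchor_doy, preseasons = ps),
            class = "driver_attribution")
}

#' @export
print.driver_attribution <- function(x, ...) {
  cat(sprintf("<driver_attribution> %s @ %s (anchor DOY %d)\n",
              x$table$species_id[1], x$table$site_id[1], x$anchor_doy))
  print(x$table[, c("predictor", "R", "p", "preseason_length")],
        row.names = FALSE)
  invisible(x)
}

#' Regional summary of driver attributions
#'
#' For each region and predictor: the mean absolute partial correlation,
#' and the percentages of species with positive / negative coefficients
#' and with significant coefficients of either sign. Percentages are
#' taken over species with nonzero R (an exactly zero coefficient belongs
#' to neither sign class), so positive + negative = 100.
#'
#' @param attributions data frame combining the `table` components of
#'   [attribute_drivers()] results.
#' @param region_map data frame with columns `site_id`, `region`.
#' @param alpha significance level (default 0.05).
#' @return Data frame: `region`, `predictor`, `n_species`, `mean_abs_R`,
#'   `pct_positive`, `pct_negative`, `pct_sig_positive`,
#'   `pct_sig_negative`, `mean_preseason`.
#' @export
summarize_region <- function(attributions, region_map, alpha = 0.05) {
  assert_cols(attributions, c("site_id", "predictor", "R", "p"),
              "attribution table")
  assert_cols(region_map, c("site_id", "region"), "region map")
  m <- match(attributions$site_id, region_map$site_id)
  if (anyNA(m))
    stopf("site(s) missing from region map: %s",
          paste(unique(attributions$site_id[is.na(m)]), collapse = ", "))
  attributions$region <- region_map$region[m]
  grp <- split(attributions,
               list(attributions$region, attributions$predictor),
               drop = TRUE)
  if (!length(grp)) stopf("empty attribution table")
  out <- do.call(rbind, lapply(grp, function(g) {
    nz <- g$R != 0
    n_nz <- sum(nz)
    data.frame(region = g$region[1], predictor = g$predictor[1],
               n_species = nrow(g), mean_abs_R = mean(abs(g$R)),
               pct_positive = if (n_nz) 100 * sum(g$R > 0) / n_nz else NA_real_,
               pct_negative = if (n_nz) 100 * sum(g$R < 0) / n_nz else NA_real_,
               pct_sig_positive =
                 if (n_nz) 100 * sum(g$R > 0 & g$p < alpha) / n_nz else NA_real_,
               pct_sig_negative =
                 if (n_nz) 100 * sum(g$R < 0 & g$p < alpha) / n_nz else NA_real_,
               mean_preseason = mean(g$preseason_length),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$region, out$predictor), ]
}
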