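test_that("window aggregation averages the right days", {
  cl <- linear_climate(1990:1992)
  # constant variable: any window returns the constant
  w <- window_aggregate(cl, "pre", 280, 30)
  expect_true(all(w == 1))
  # length 1: the value of day anchor-1
  w1 <- window_aggregate(cl, "tmax", 280, 1)
  expect_true(all(w1 == 27.9))
  # tmax = doy/10, anchor 280, length 10: mean of 270..279 over 10
  w10 <- window_aggregate(cl, "tmax", 280, 10)
  expect_true(all(abs(w10 - 27.45) < 1e-12))
  expect_error(window_aggregate(cl, "tmax", 100, 120), "before the start")
})

test_that("years with missing window days are excluded, not imputed", {
  cl <- linear_climate(1990:1992)
  drop <- cl$site_id == "s1" &
    cl$date == as.Date("1991-10-01")  # DOY 274, inside the window
  cl2 <- cl[!drop, ]
  class(cl2) <- class(cl)
  w <- window_aggregate(cl2, "tmax", 280, 10)
  expect_false("1991" %in% names(w))
  expect_equal(attr(w, "excluded_years"), 1991L)
})

test_that("optimal preseason matches a brute-force scan oracle", {
  cl <- gen_climate(climate_gen_spec(n_years = 30, seed = 61), "s1")
  set.seed(62)
  lcd <- pheno_series("sp1", "s1", "LCD", 1979:2008,
                      round(280 + rnorm(30, 0, 4)))
  got <- optimal_preseason(lcd, cl, "tmin", max_length = 120)
  rs <- vapply(1:120, function(L) {
    w <- window_aggregate(cl, "tmin", got$anchor_doy, L, years = lcd$year)
    stats::cor(lcd$doy[match(as.integer(names(w)), lcd$year)], as.numeric(w))
  }, numeric(1))
  expect_equal(got$length_days, which.max(abs(rs)))
  expect_equal(abs(got$pearson_r), max(abs(rs)), tolerance = 1e-12)
})

test_that("ties in the scan go to the shortest window", {
  # within-year constant tmax (varies by year): all lengths give the same r
  cl <- linear_climate(1990:2009)
  yr <- as.integer(format(cl$date, "%Y"))
  cl$tmax <- (yr - 1990) * 0.5
  set.seed(8)
  lcd <- pheno_series("sp1", "s1", "LCD", 1990:2009,
                      round(280 + (0:19) * 0.3 + rnorm(20, 0, 1)))
  got <- optimal_preseason(lcd, cl, "tmax")
  expect_equal(got$length_days, 1L)
})

test_that("partial correlation follows the first-order formula", {
  expect_equal(partial_corr(c(1, 2, 3), c(2, 4, 6))$R, 1)
  # Rxy = Rxz = Ryz = 0.5 -> (0.5 - 0.25) / 0.75 = 1/3
  Rm <- matrix(0.5, 3, 3); diag(Rm) <- 1
  expect_equal(autumnsig:::pcor_recurse(Rm, 1, 2, 3L), 1 / 3)
  set.seed(5)
  n <- 40
  x <- rnorm(n); y <- rnorm(n)
  ctrl <- replicate(4, rnorm(n), simplify = FALSE)
  a <- partial_corr(x, y, ctrl)
  b <- partial_corr(x, y, ctrl, method = "residual")
  expect_equal(a$R, b$R, tolerance = 1e-10)
  expect_equal(a$p, b$p, tolerance = 1e-8)
  # symmetry in x and y
  expect_equal(partial_corr(y, x, ctrl)$R, a$R, tolerance = 1e-12)
  expect_error(partial_corr(x, rep(1, n), ctrl), "zero-variance")
  expect_error(partial_corr(x, y, list(x)), "collinear")
})

test_that("a control orthogonal to both series leaves Pearson r unchanged", {
  set.seed(9)
  n <- 50
  x <- rnorm(n); y <- x + rnorm(n)
  z0 <- rnorm(n)
  # project out x and y so the control is exactly orthogonal to both
  z <- stats::lm.fit(cbind(1, x, y), z0)$residuals
  expect_equal(partial_corr(x, y, list(z))$R, stats::cor(x, y),
               tolerance = 1e-12)
})

test_that("driver attribution recovers a spring-phenology effect", {
  hits <- vapply(1:30, function(s) {
    cl <- gen_climate(climate_gen_spec(n_years = 40, seed = 9000 + s), "s1")
    fld <- gen_fld(cl, noise_sd = 3, seed = 9100 + s)
    spec <- response_spec(fld_coeff = 0.8, noise_sd = 2, seed = s)
    lcd <- gen_phenology(cl, spec, fld = fld)
    tb <- attribute_drivers(lcd, fld, cl)$table
    tb$R[tb$predictor == "fld"] > 0 && tb$p[tb$predictor == "fld"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("attribution uses one common year set and labels preseasons", {
  cl <- gen_climate(climate_gen_spec(n_years = 40, seed = 71), "s1")
  fld <- gen_fld(cl, noise_sd = 3, seed = 72)
  lcd <- gen_phenology(cl, response_spec(
    beta = c(tmax = 1.5, tmin = 0, pre = 0, ins = 0, win = 0),
    noise_sd = 2, seed = 73), fld = fld)
  res <- attribute_drivers(lcd, fld, cl)
  expect_setequal(res$table$predictor,
                  c("tmax", "tmin", "pre", "ins", "win", "fld"))
  expect_equal(length(unique(res$table$n_years)), 1)
  expect_true(all(abs(res$table$R) <= 1))
  expect_true(is.na(res$table$preseason_length[res$table$predictor == "fld"]))
  expect_error(attribute_drivers(lcd, fld, cl, min_years = 999),
               "complete-case|shared")
})

test_that("regional summaries aggregate signs and significance", {
  at <- data.frame(site_id = c("a", "a"), predictor = "tmax",
                   R = c(0.4, -0.2), p = c(0.01, 0.5),
                   preseason_length = c(60, 70))
  rm <- data.frame(site_id = "a", region = "north")
  sm <- summarize_region(at, rm)
  expect_equal(sm$mean_abs_R, 0.3)
  expect_equal(sm$pct_positive, 50)
  expect_equal(sm$pct_negative, 50)
  expect_equal(sm$pct_sig_positive, 50)
  expect_equal(sm$pct_sig_negative, 0)
  # all positive, all significant
  at2 <- data.frame(site_id = "a", predictor = "tmax", R = c(0.5, 0.3),
                    p = c(0.01, 0.001), preseason_length = c(60, 70))
  sm2 <- summarize_region(at2, rm)
  expect_equal(sm2$pct_positive, 100)
  expect_equal(sm2$pct_sig_positive, 100)
  # exact zero belongs to neither sign class
  at3 <- data.frame(site_id = "a", predictor = "tmax", R = c(0, 0.5),
                    p = c(1, 0.01), preseason_length = c(60, 60))
  sm3 <- summarize_region(at3, rm)
  expect_equal(sm3$pct_positive, 100)
  expect_equal(sm3$pct_negative, 0)
})
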