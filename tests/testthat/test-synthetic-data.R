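test_that("climate generator is deterministic and respects degenerate specs", {
  flat <- function(p) { p$amplitude <- 0; p$sd <- 0; p }
  base <- climate_gen_spec(n_years = 2, seed = 5)
  spec <- climate_gen_spec(n_years = 2, seed = 5,
                           tmax = flat(base$tmax), drange = flat(base$drange),
                           pre = flat(base$pre), ins = flat(base$ins),
                           win = flat(base$win))
  cl <- gen_climate(spec, "s1")
  expect_true(all(cl$tmax == base$tmax$mean))
  expect_true(all(cl$win == base$win$mean))
  expect_true(all(cl$tmin <= cl$tmax))
  cl1 <- gen_climate(climate_gen_spec(n_years = 3, seed = 9), "s1")
  cl2 <- gen_climate(climate_gen_spec(n_years = 3, seed = 9), "s1")
  expect_identical(cl1, cl2)
})

test_that("AR(1) anomalies have the requested lag-1 autocorrelation", {
  spec <- climate_gen_spec(n_years = 40, seed = 21,
                           tmax = list(mean = 18, amplitude = 14,
                                       peak_doy = 197, sd = 2, rho = 0.7))
  cl <- gen_climate(spec, "s1")
  doy <- as.integer(strftime(cl$date, "%j"))
  anom <- cl$tmax - ave(cl$tmax, doy)  # deseasonalize by per-DOY mean
  r1 <- stats::acf(anom, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(r1 - 0.7), 0.1)
})

test_that("phenology generator reduces to its deterministic parts", {
  cl <- gen_climate(climate_gen_spec(n_years = 20, seed = 3), "s1")
  const <- gen_phenology(cl, response_spec(noise_sd = 0), "LCD")
  expect_true(all(const$doy == 280))
  tr <- gen_phenology(cl, response_spec(noise_sd = 0, trend = 0.28), "LCD",
                      round_doy = FALSE)
  expect_equal(fit_trend(tr)$slope, 0.28, tolerance = 1e-10)
})

test_that("noise-free single-driver phenology is exactly invertible", {
  cl <- gen_climate(climate_gen_spec(n_years = 40, seed = 11), "s1")
  spec <- response_spec(beta = c(tmax = 2, tmin = 0, pre = 0, ins = 0, win = 0),
                        lengths = c(tmax = 60, tmin = 60, pre = 45,
                                    ins = 58, win = 43), noise_sd = 0)
  lcd <- gen_phenology(cl, spec, round_doy = FALSE)
  ps <- optimal_preseason(lcd, cl, "tmax")
  expect_equal(ps$length_days, 60)
  expect_equal(abs(ps$pearson_r), 1, tolerance = 1e-10)
  expect_equal(ps$anchor_doy, 280)
})

test_that("Yule trees are valid, reproducible and have the expected depth", {
  expect_error(gen_yule_tree(1), ">= 2")
  cherry <- gen_yule_tree(2, 1, seed = 5)
  expect_equal(ape::Ntip(cherry), 2)
  expect_true(all(cherry$edge.length > 0))
  expect_identical(ape::write.tree(gen_yule_tree(15, 1, seed = 7)),
                   ape::write.tree(gen_yule_tree(15, 1, seed = 7)))
  # expected root-to-tip depth of a rate-1 pure-birth tree stopped after
  # the n-th tip: sum_{k=2}^{n} 1/k
  n <- 100
  depths <- vapply(1:200, function(s)
    max(ape::node.depth.edgelength(gen_yule_tree(n, 1, seed = 5000 + s))),
    numeric(1))
  expect_lt(abs(mean(depths) - sum(1 / (2:n))), 0.1 * sum(1 / (2:n)))
})

test_that("Brownian traits have the covariance implied by the tree", {
  tr <- gen_yule_tree(8, 1, seed = 2)
  tiny <- gen_bm_trait(tr, bm_spec(sigma2 = 1e-12, root_state = 5, seed = 1))
  expect_equal(unname(tiny), rep(5, 8), tolerance = 1e-4)
  # star tree: independent tips with variance sigma2 * t
  st <- star_tree(10, t = 2)
  X <- vapply(1:2000, function(s)
    gen_bm_trait(st, bm_spec(sigma2 = 1.5, seed = s)), numeric(10))
  S <- stats::cov(t(X))
  expect_lt(abs(mean(diag(S)) - 3), 0.3)
  expect_lt(max(abs(S[upper.tri(S)])), 0.3)
  # fixed tree: empirical covariance tracks sigma2 * C elementwise
  C <- phylo_vcv(tr)
  X2 <- vapply(1:2000, function(s)
    gen_bm_trait(tr, bm_spec(sigma2 = 2, seed = 10000 + s)), numeric(8))
  S2 <- stats::cov(t(X2))
  expect_lt(max(abs(S2 - 2 * C)), 0.15 * max(2 * C))
})

test_that("species ensemble validates weights and encodes its ground truth", {
  tr <- gen_yule_tree(30, 1, seed = 4)
  expect_error(gen_species_ensemble(tr, 0.5, 0.5, 0.5), "sum to 1")
  e1 <- gen_species_ensemble(tr, 0.5, 0.3, 0.2, seed = 9)
  e2 <- gen_species_ensemble(tr, 0.5, 0.3, 0.2, seed = 9)
  expect_identical(e1$mean_lcd, e2$mean_lcd)
  # pure climate: mean LCD is an exact linear function of the optima
  ec <- gen_species_ensemble(tr, 1, 0, 0, seed = 3)
  fit <- stats::lm(ec$mean_lcd ~ mat + map + srad, data = ec$truth$optima)
  expect_gt(suppressWarnings(summary(fit)$r.squared), 1 - 1e-10)
  # occurrence records respect the temperature ordering invariant
  occ <- e1$occurrences
  expect_true(all(occ$tmin_cold <= occ$mat & occ$mat <= occ$tmax_warm))
  expect_true(all(occ$map >= 0))
})
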