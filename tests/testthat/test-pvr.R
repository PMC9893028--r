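test_that("patristic distances are path sums", {
  D <- patristic_distances(tree3())
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_equal(D["B", "C"], 4)
  expect_true(all(diag(D) == 0))
  two <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(patristic_distances(two)["A", "B"], 2)
  Dy <- patristic_distances(gen_yule_tree(20, 1, seed = 31))
  expect_equal(Dy, t(Dy))
})

test_that("PCoA reproduces closed forms and embeds tree distances", {
  # two points at distance d: one axis, eigenvalue d^2/2, coordinates +-d/2
  d <- 3.2
  D2 <- matrix(c(0, d, d, 0), 2, 2, dimnames = list(c("A", "B"),
                                                    c("A", "B")))
  pc <- pcoa_axes(D2)
  expect_length(pc$values, 1)
  expect_equal(pc$values, d^2 / 2)
  expect_equal(unname(sort(pc$vectors[, 1])), c(-d / 2, d / 2))
  # degenerate: all distances zero -> no axes
  expect_length(pcoa_axes(matrix(0, 3, 3))$values, 0)
  # patristic distances are Euclidean-embeddable: reconstruction is exact
  for (s in 1:3) {
    tr <- gen_yule_tree(30, 1, seed = 40 + s)
    D <- patristic_distances(tr)
    pc <- pcoa_axes(D)
    expect_lt(max(abs(as.matrix(dist(pc$vectors)) - D)), 1e-6)
    # columns scaled to eigenvalue and mutually orthogonal
    expect_equal(unname(colSums(pc$vectors^2)), unname(pc$values),
                 tolerance = 1e-8)
    G <- crossprod(pc$vectors)
    expect_lt(max(abs(G - diag(diag(G)))), 1e-6)
  }
})

test_that("Moran's I matches a literal-formula oracle", {
  set.seed(51)
  for (i in 1:5) {
    n <- sample(3:8, 1)
    D <- as.matrix(dist(matrix(runif(n * 2), n)))
    vals <- rnorm(n)
    got <- morans_i(vals, D)
    W <- 1 / D; diag(W) <- 0; W <- W / rowSums(W)
    z <- vals - mean(vals)
    I <- (n / sum(W)) * as.numeric(t(z) %*% W %*% z) / sum(z^2)
    expect_equal(got$I, I, tolerance = 1e-12)
    expect_equal(got$expected_I, -1 / (n - 1), tolerance = 1e-12)
  }
  expect_error(morans_i(rep(1, 5), as.matrix(dist(matrix(runif(10), 5)))),
               "constant")
})

test_that("Moran's I null mean and positive-autocorrelation detection", {
  set.seed(52)
  tr <- gen_yule_tree(25, 1, seed = 53)
  D <- patristic_distances(tr)
  vals <- rnorm(25)
  perms <- vapply(1:1000, function(i) morans_i(sample(vals), D)$I, numeric(1))
  expect_lt(abs(mean(perms) + 1 / 24), 0.02)
  # the leading PCoA axis is maximally autocorrelated
  pc <- pcoa_axes(D)
  m <- morans_i(pc$vectors[, 1], D)
  expect_gt(m$I, m$expected_I)
  expect_lt(m$p_value, 0.05)
})

test_that("eigenvector selection gates on trait autocorrelation", {
  tr <- gen_yule_tree(60, 1, seed = 54)
  D <- patristic_distances(tr)
  pc <- pcoa_axes(D)
  # iid traits: mostly empty selections
  sizes <- vapply(1:20, function(s) {
    set.seed(600 + s)
    length(select_eigenvectors(stats::setNames(rnorm(60), tr$tip.label),
                               pc, D))
  }, numeric(1))
  expect_gte(mean(sizes == 0), 0.7)
  # exact function of axes {1, 3} plus tiny noise: both recovered
  hits <- vapply(1:20, function(s) {
    set.seed(700 + s)
    y <- stats::setNames(2 * pc$vectors[, 1] - 1.5 * pc$vectors[, 3] +
                           rnorm(60, 0, 0.01 * sd(pc$vectors[, 1])),
                         tr$tip.label)
    all(c(1, 3) %in% select_eigenvectors(y, pc, D))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # alpha >= 1: any autocorrelation counts as nonsignificant
  set.seed(55)
  y <- stats::setNames(rnorm(60), tr$tip.label)
  expect_length(select_eigenvectors(y, pc, D, alpha = 1), 0)
})

test_that("stepwise climate selection finds strong signals, stays small on noise", {
  tr <- gen_yule_tree(80, 1, seed = 56)
  prof <- build_profiles(dedup_occurrences(
    gen_species_ensemble(tr, 0.5, 0.3, 0.2, seed = 57)$occurrences))
  hits <- vapply(1:20, function(s) {
    set.seed(800 + s)
    y <- stats::setNames(2 * prof$mat_mean +
                           rnorm(80, 0, 0.5 * sd(prof$mat_mean)),
                         prof$species_id)
    "mat_mean" %in% stepwise_climate(y, prof)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  sizes <- vapply(1:20, function(s) {
    set.seed(900 + s)
    length(stepwise_climate(stats::setNames(rnorm(80), prof$species_id),
                            prof))
  }, numeric(1))
  expect_lt(mean(sizes), 3)  # AIC keeps spurious selections small
  # duplicated (perfectly collinear) predictors: at most one enters
  prof2 <- prof
  prof2$tmax_warm_mean <- prof2$mat_mean
  set.seed(58)
  y <- stats::setNames(2 * prof2$mat_mean + rnorm(80, 0, 1),
                       prof2$species_id)
  sel <- stepwise_climate(y, prof2)
  expect_lte(sum(c("mat_mean", "tmax_warm_mean") %in% sel), 1)
})

test_that("adjusted R-squared follows its formula", {
  set.seed(59)
  n <- 25
  X <- matrix(rnorm(n * 3), n)
  y <- X %*% c(1, -1, 0.5) + rnorm(n)
  got <- adjusted_r2(y, X)
  expect_equal(got, summary(stats::lm(y ~ X))$adj.r.squared,
               tolerance = 1e-12)
  # perfect fit
  expect_equal(adjusted_r2(as.numeric(X %*% c(1, 2, 3)), X), 1)
  # intercept-only
  expect_equal(adjusted_r2(y, NULL), 0)
  expect_error(adjusted_r2(y[1:4], X[1:4, ]), "too few")
})

test_that("the partition identity holds exactly, including edge cases", {
  set.seed(60)
  for (i in 1:25) {
    n <- sample(15:40, 1)
    y <- rnorm(n)
    cx <- if (i %% 4 == 0) NULL else matrix(rnorm(n * sample(1:3, 1)), n)
    px <- if (i %% 5 == 0) NULL else matrix(rnorm(n * sample(1:3, 1)), n)
    pa <- pvr_partition(y, cx, px)
    expect_equal(pa$P1 + pa$P2 + pa$P3, pa$r2adj_full, tolerance = 1e-12)
    expect_equal(pa$P1, pa$r2adj_full - pa$r2adj_climate, tolerance = 1e-12)
    expect_equal(pa$P2, pa$r2adj_full - pa$r2adj_phylo, tolerance = 1e-12)
  }
  # empty phylogeny block: P1 = P3 = 0, P2 = climate R2adj
  y <- rnorm(20); cx <- matrix(rnorm(40), 20)
  pa <- pvr_partition(y, cx, NULL)
  expect_equal(pa$P1, 0)
  expect_equal(pa$P3, 0)
  expect_equal(pa$P2, pa$r2adj_climate)
})

test_that("regional partition averages per region and keeps the identity", {
  sr <- data.frame(site_id = c("a", "b", "c"),
                   r2adj_climate = c(0.2, 0.4, 0.1),
                   r2adj_phylo = c(0.1, 0.2, 0.3),
                   r2adj_full = c(0.4, 0.6, 0.5),
                   P1 = c(0.1, 0.3, 0.2), P2 = c(0.3, 0.2, 0.4),
                   P3 = c(0, 0.1, -0.1))
  rm <- data.frame(site_id = c("a", "b", "c"),
                   region = c("n", "n", "s"))
  out <- regional_partition(sr, rm)
  expect_equal(out$P1[out$region == "n"], 0.2)
  expect_equal(out$P1[out$region == "s"], 0.2)
  expect_equal(out$P1 + out$P2 + out$P3, out$r2adj_full, tolerance = 1e-12)
  expect_error(regional_partition(sr, rm[1:2, ]), "missing from region map")
})
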