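# Phylogenetic eigenvector regression and the exclusive/shared
# adjusted-R^2 variance partition.

#' Patristic distance matrix of a phylogeny
#'
#' `D[i, j]` is the sum of branch lengths on the path between tips i and
#' j; the diagonal is zero.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return Symmetric matrix with tip labels as dimnames.
#' @export
patristic_distances <- function(tree) {
  validate_tree(tree)
  D <- ape::cophenetic.phylo(tree)
  D[tree$tip.label, tree$tip.label]
}

#' Principal coordinate analysis of a distance matrix
#'
#' Eigendecomposition of the Gower-centered matrix
#' `B = -1/2 J D^2 J` (J the centering matrix). Axes with eigenvalue at or
#' below `tolerance * max(eigenvalue)` are dropped; columns are scaled so
#' each squared column norm equals its eigenvalue, hence pairwise
#' Euclidean distances between rows reproduce `D` when `D` is Euclidean
#' (patristic distances are). A warning is raised if a negative eigenvalue
#' exceeds 1% of the leading one in magnitude, which for tree distances
#' indicates a malformed input.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param tolerance relative eigenvalue cutoff (default 1e-8).
#' @return List of class `pcoa_result`: `values` (retained eigenvalues,
#'   descending) and `vectors` (n x n_axes matrix, rows named as `D`).
#' @export
pcoa_axes <- function(D, tolerance = 1e-8) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stopf("D must be a square matrix")
  if (max(abs(D - t(D))) > 1e-8) stopf("D must be symmetric")
  n <- nrow(D)
  D2 <- D^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D2 %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  lam_max <- max(e$values, 0)
  if (lam_max > 0 && min(e$values) < -0.01 * lam_max)
    warnf("large negative PCoA eigenvalue (%.3g); distances are far from Euclidean",
          min(e$values))
  keep <- which(e$values > tolerance * max(lam_max, .Machine$double.eps))
  vec <- e$vectors[, keep, drop = FALSE]
  if (length(keep))
    vec <- sweep(vec, 2, sqrt(e$values[keep]), `*`)
  rownames(vec) <- rownames(D)
  colnames(vec) <- if (length(keep)) paste0("V", seq_along(keep))
                   else character()
  structure(list(values = e$values[keep], vectors = vec),
            class = "pcoa_result")
}

# inverse-patristic-distance weights, row-standardized
inverse_distance_weights <- function(D) {
  off <- D[upper.tri(D)]
  if (any(off == 0))
    stopf("zero off-diagonal distance: identical tips")
  W <- 1 / D
  diag(W) <- 0
  W / rowSums(W)
}

#' Moran's I autocorrelation with inverse-distance weights
#'
#' `I = (n / S0) (z' W z) / (z' z)` with `z` the centered values, `W` the
#' row-standardized inverse-distance weights derived from `D`, and
#' `S0 = sum(W)`. The p-value is two-sided from the normal approximation
#' under the randomization null, for which `E[I] = -1/(n-1)`.
#'
#' @param values numeric vector (n >= 3, nonconstant), ordered as `D`.
#' @param D distance matrix (e.g. [patristic_distances()]).
#' @param alternative `"two.sided"` (default) or `"greater"` (positive
#'   autocorrelation only, the alternative relevant to phylogenetic
#'   signal).
#' @return List of class `moran_result`: `I`, `expected_I`, `sd`,
#'   `p_value`.
#' @export
morans_i <- function(values, D, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  n <- length(values)
  if (n < 3) stopf("Moran's I needs n >= 3")
  if (stats::sd(values) == 0) stopf("constant values: Moran's I undefined")
  if (nrow(D) != n) stopf("values and D have mismatched sizes")
  W <- inverse_distance_weights(D)
  m <- ape::Moran.I(values, W, alternative = alternative)
  structure(list(I = m$observed, expected_I = m$expected, sd = m$sd,
                 p_value = m$p.value),
            class = "moran_result")
}

#' Select phylogenetic eigenvectors for a trait
#'
#' Two stages. First, Moran's I of the (centered) response under
#' inverse-patristic-distance weights gates the selection: if the trait
#' shows no significant positive phylogenetic autocorrelation (one-sided
#' test, p >= `alpha`; any autocorrelation counts as nonsignificant when
#' `alpha >= 1`), no eigenvector is selected. Second, among traits that pass the gate, the
#' default `"aic"` method runs bidirectional stepwise regression (AIC) of
#' the trait on the leading `max_axes` PCoA axes, mirroring the stepwise
#' selection used for the native-climate predictors. The `"moran"` method
#' instead repeats the classic residual-whitening search: greedily add the
#' axis leaving residual Moran's I closest to its null expectation and
#' stop as soon as the residual autocorrelation is nonsignificant. The
#' whitening search detects autocorrelation structure with very few axes
#' and therefore tends to understate the variance attributable to
#' phylogeny in a partition; `"aic"` is the default for that reason (see
#' the package vignette).
#'
#' @param response named numeric vector (tip order of `pcoa$vectors`).
#' @param pcoa a [pcoa_axes()] result.
#' @param D the distance matrix the axes came from.
#' @param alpha significance threshold for the Moran's I gate and, for
#'   `method = "moran"`, the residual stopping rule (default 0.05).
#' @param max_axes cap on the candidate/selected axes (default n/2,
#'   silently capped at the number of retained axes).
#' @param method `"aic"` (default) or `"moran"`.
#' @return Integer vector of selected axis indices (possibly empty), with
#'   attribute `trait_moran` (the gating [morans_i()] result, or `NULL`
#'   when `alpha >= 1`).
#' @export
select_eigenvectors <- function(response, pcoa, D, alpha = 0.05,
                                max_axes = NULL,
                                method = c("aic", "moran")) {
  method <- match.arg(method)
  stopifnot(inherits(pcoa, "pcoa_result"))
  V <- pcoa$vectors
  n <- nrow(V)
  y <- align_trait(response, rownames(V))
  if (is.null(max_axes)) max_axes <- floor(n / 2)
  max_axes <- max(0L, min(max_axes, ncol(V)))
  empty <- function(m) structure(integer(), trait_moran = m)
  if (alpha >= 1 || max_axes == 0L) return(empty(NULL))
  m0 <- morans_i(y - mean(y), D, alternative = "greater")
  if (m0$p_value >= alpha) return(empty(m0))
  if (method == "aic") {
    cand <- colnames(V)[seq_len(max_axes)]
    df <- as.data.frame(V[, cand, drop = FALSE])
    df$.y <- y
    fit <- stats::step(stats::lm(.y ~ 1, data = df),
                       scope = stats::reformulate(cand, response = ".y"),
                       direction = "both", trace = 0)
    sel <- which(colnames(V) %in% setdiff(names(stats::coef(fit)),
                                          "(Intercept)"))
  } else {
    sel <- integer()
    resid <- y - mean(y)
    repeat {
      m <- morans_i(resid, D, alternative = "greater")
      if (m$p_value >= alpha || length(sel) >= max_axes) break
      cand <- setdiff(seq_len(ncol(V)), sel)
      if (!length(cand)) break
      dev <- vapply(cand, function(j) {
        r <- stats::lm.fit(cbind(1, V[, c(sel, j), drop = FALSE]),
                           y)$residuals
        if (stats::sd(r) == 0) return(0)
        mi <- morans_i(r, D)
        abs(mi$I - mi$expected_I)
      }, numeric(1))
      sel <- c(sel, cand[which.min(dev)])
      r <- stats::lm.fit(cbind(1, V[, sel, drop = FALSE]), y)$residuals
      if (stats::sd(r) == 0) break
      resid <- r
    }
  }
  structure(sort(sel), trait_moran = m0)
}

#' Stepwise selection of native-climate predictors
#'
#' Bidirectional stepwise regression (AIC criterion) of the response on
#' the ten native-climate predictors, starting from the intercept-only
#' model. With 12 or fewer species the procedure falls back to
#' forward-only selection capped at n/5 predictors, with a warning.
#'
#' @param response named numeric vector (names = species ids).
#' @param profiles data frame from [build_profiles()].
#' @return Character vector of selected predictor column names (possibly
#'   empty).
#' @export
stepwise_climate <- function(response, profiles) {
  preds <- profile_predictors()
  assert_cols(profiles, c("species_id", preds), "profile table")
  sp <- profiles$species_id
  y <- align_trait(response, sp)
  df <- profiles[, preds, drop = FALSE]
  # constant columns carry no information and upset step()
  usable <- preds[vapply(df, function(v) stats::sd(v) > 0, logical(1))]
  if (!length(usable)) return(character())
  df <- df[, usable, drop = FALSE]
  df$.y <- y
  n <- length(y)
  scope <- stats::reformulate(usable, response = ".y")
  base <- stats::lm(.y ~ 1, data = df)
  if (n <= 12) {
    warnf("only %d species: forward-only stepwise capped at %d predictor(s)",
          n, max(1, floor(n / 5)))
    fit <- stats::step(base, scope = scope, direction = "forward",
                       steps = max(1, floor(n / 5)), trace = 0)
  } else {
    fit <- stats::step(base, scope = scope, direction = "both", trace = 0)
  }
  setdiff(names(stats::coef(fit)), "(Intercept)")
}

#' Adjusted R-squared of a least-squares fit
#'
#' `R2_adj = 1 - (1 - R2) (n - 1) / (n - p - 1)`, with `p` the number of
#' predictor columns (intercept excluded). An empty predictor matrix gives
#' 0.
#'
#' @param y response vector.
#' @param X predictor matrix (or `NULL` for intercept-only).
#' @return Adjusted R-squared (fraction; can be negative).
#' @export
adjusted_r2 <- function(y, X = NULL) {
  n <- length(y)
  p <- if (is.null(X)) 0L else ncol(as.matrix(X))
  if (p == 0L) return(0)
  X <- as.matrix(X)
  if (nrow(X) != n) stopf("rows of X must match length of y")
  if (n - p - 1 <= 0) stopf("too few observations for %d predictor(s)", p)
  fit <- stats::lm.fit(cbind(1, X), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stopf("constant response")
  r2 <- 1 - rss / tss
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Partition trait variance into exclusive and shared components
#'
#' Fits three regressions of the trait: on the selected native-climate
#' predictors, on the selected phylogenetic eigenvectors, and on both.
#' With their adjusted R-squared values `R1` (climate), `R2` (phylogeny)
#' and `R3` (full), the components are
#' `P1 = R3 - R1` (exclusive phylogeny), `P2 = R3 - R2` (exclusive
#' climate) and `P3 = R2 - (R3 - R1)` (shared), so that
#' `P1 + P2 + P3 = R3` identically. Adjusted R-squared can make individual
#' components slightly negative; they are reported unclamped, since
#' clamping would silently break the sum identity.
#'
#' @param trait named numeric response (one value per species).
#' @param climate_X matrix (or `NULL`) of selected climate predictors.
#' @param phylo_X matrix (or `NULL`) of selected eigenvectors.
#' @return List of class `partition_result`: `r2adj_climate`,
#'   `r2adj_phylo`, `r2adj_full`, `P1`, `P2`, `P3`, `n_species`,
#'   `n_climate`, `n_phylo`.
#' @export
pvr_partition <- function(trait, climate_X = NULL, phylo_X = NULL) {
  y <- as.numeric(trait)
  ncol0 <- function(X) if (is.null(X)) 0L else ncol(as.matrix(X))
  both <- if (is.null(climate_X) && is.null(phylo_X)) NULL
          else cbind(climate_X, phylo_X)
  r1 <- adjusted_r2(y, climate_X)
  r2 <- adjusted_r2(y, phylo_X)
  r3 <- adjusted_r2(y, both)
  structure(list(r2adj_climate = r1, r2adj_phylo = r2, r2adj_full = r3,
                 P1 = r3 - r1, P2 = r3 - r2, P3 = r2 - (r3 - r1),
                 n_species = length(y), n_climate = ncol0(climate_X),
                 n_phylo = ncol0(phylo_X)),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf(paste0("<partition_result> n = %d\n",
                     "  R2adj climate %.4f | phylo %.4f | full %.4f\n",
                     "  P1 (phylo excl.) %.4f  P2 (climate excl.) %.4f  ",
                     "P3 (shared) %.4f\n"),
              x$n_species, x$r2adj_climate, x$r2adj_phylo, x$r2adj_full,
              x$P1, x$P2, x$P3))
  invisible(x)
}

#' Average partition components over regions
#'
#' Unweighted arithmetic mean of P1, P2, P3 (and the three adjusted
#' R-squared values) over the sites of each region.
#'
#' @param site_results data frame with one row per site, columns
#'   `site_id`, `r2adj_climate`, `r2adj_phylo`, `r2adj_full`, `P1`, `P2`,
#'   `P3`.
#' @param region_map data frame with columns `site_id`, `region`.
#' @return Data frame with one row per region.
#' @export
regional_partition <- function(site_results, region_map) {
  assert_cols(site_results, c("site_id", "P1", "P2", "P3"),
              "partition table")
  assert_cols(region_map, c("site_id", "region"), "region map")
  m <- match(site_results$site_id, region_map$site_id)
  if (anyNA(m))
    stopf("site(s) missing from region map: %s",
          paste(unique(site_results$site_id[is.na(m)]), collapse = ", "))
  site_results$region <- region_map$region[m]
  grp <- split(site_results, site_results$region, drop = TRUE)
  if (!length(grp)) stopf("no sites to average")
  num <- intersect(c("r2adj_climate", "r2adj_phylo", "r2adj_full",
                     "P1", "P2", "P3"), names(site_results))
  out <- do.call(rbind, lapply(grp, function(g) {
    row <- as.data.frame(as.list(colMeans(g[, num, drop = FALSE])))
    cbind(data.frame(region = g$region[1], n_sites = nrow(g),
                     stringsAsFactors = FALSE), row)
  }))
  rownames(out) <- NULL
  out
}
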