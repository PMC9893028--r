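#' Phylogenetic variance-covariance matrix
#'
#' `C[i, j]` is the branch length shared from the root to the most recent
#' common ancestor of tips i and j; the diagonal holds root-to-tip
#' distances. Up to a rate constant this is the tip covariance implied by
#' Brownian-motion evolution on the tree.
#'
#' @param tree an [ape::phylo] tree with nonnegative branch lengths.
#' @return Symmetric numeric matrix with tip labels as dimnames.
#' @export
phylo_vcv <- function(tree) {
  validate_tree(tree)
  C <- ape::vcv.phylo(tree)
  C[tree$tip.label, tree$tip.label]
}

# core K statistic given a trait vector and a Cholesky-solved covariance;
# split out so the permutation test can reuse one factorization
blomberg_k_core <- function(x, C, Cinv, expected_ratio) {
  n <- length(x)
  s_inv <- sum(Cinv)
  ahat <- sum(Cinv %*% x) / s_inv
  r <- x - ahat
  mse0 <- sum(r^2) / (n - 1)
  mse <- as.numeric(crossprod(r, Cinv %*% r)) / (n - 1)
  (mse0 / mse) / expected_ratio
}

k_setup <- function(tree) {
  C <- phylo_vcv(tree)
  n <- nrow(C)
  L <- tryCatch(chol(C), error = function(e)
    stopf("phylogenetic covariance is singular"))
  Cinv <- chol2inv(L)
  expected_ratio <- (sum(diag(C)) - n / sum(Cinv)) / (n - 1)
  list(C = C, Cinv = Cinv, expected_ratio = expected_ratio, n = n)
}

#' Blomberg's K phylogenetic-signal statistic
#'
#' Compares the observed tip variance of a trait with the variance
#' expected under Brownian motion on the tree:
#' \deqn{K = \frac{MSE_0 / MSE}{E_{BM}[MSE_0 / MSE]}}
#' where `MSE0` is the mean squared deviation of the trait from its
#' phylogenetically weighted mean `a = (1' C^{-1} x)/(1' C^{-1} 1)`, `MSE`
#' is the covariance-standardized counterpart
#' `(x - a)' C^{-1} (x - a)/(n - 1)`, and the Brownian-motion expectation
#' of the ratio is `(tr C - n / (1' C^{-1} 1)) / (n - 1)`. K is
#' nonnegative, dimensionless, and invariant to affine transforms of the
#' trait; values near 1 are consistent with Brownian motion, values near 0
#' with phylogenetic independence.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param trait named numeric vector with one value per tip.
#' @return K (numeric scalar).
#' @export
blomberg_k <- function(tree, trait) {
  s <- k_setup(tree)
  x <- align_trait(trait, rownames(s$C))
  if (stats::sd(x) == 0) stopf("trait is constant; K is undefined")
  blomberg_k_core(x, s$C, s$Cinv, s$expected_ratio)
}

align_trait <- function(trait, tips) {
  if (is.null(names(trait))) {
    if (length(trait) != length(tips))
      stopf("trait length does not match tip count")
    return(as.numeric(trait))
  }
  miss <- setdiff(tips, names(trait))
  if (length(miss))
    stopf("trait missing for tip(s): %s", paste(miss, collapse = ", "))
  as.numeric(trait[tips])
}

#' Permutation test for Blomberg's K
#'
#' Shuffles trait values across tips `n_permutations` times and compares
#' the observed K with the permutation distribution (one-sided: signal
#' means larger-than-random K). The p-value uses the add-one rule
#' `p = (1 + #\{K_perm >= K_obs\}) / (1 + n_permutations)`, so it is never
#' exactly zero. Under the conventional decision rule, `p > 0.05` means no
#' evidence of phylogenetic conservatism.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param trait named numeric vector with one value per tip.
#' @param n_permutations number of label permutations (default 1000).
#' @param seed integer random seed (for reproducible permutations).
#' @return List of class `k_result`: `K`, `p_value`, `n_permutations`,
#'   `seed`, `n_tips`.
#' @export
k_permutation_test <- function(tree, trait, n_permutations = 1000,
                               seed = 1) {
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 1) stopf("n_permutations must be >= 1")
  s <- k_setup(tree)
  x <- align_trait(trait, rownames(s$C))
  if (stats::sd(x) == 0) stopf("trait is constant; K is undefined")
  k_obs <- blomberg_k_core(x, s$C, s$Cinv, s$expected_ratio)
  set.seed(as.integer(seed))
  P <- vapply(seq_len(n_permutations), function(i) x[sample.int(s$n)],
              numeric(s$n))
  # vectorized K over all permutations (shared C^{-1})
  s_inv <- sum(s$Cinv)
  ahat <- colSums(s$Cinv %*% P) / s_inv
  Rm <- sweep(P, 2, ahat)
  mse0 <- colSums(Rm^2)
  mse <- colSums(Rm * (s$Cinv %*% Rm))
  k_perm <- (mse0 / mse) / s$expected_ratio
  p <- (1 + sum(k_perm >= k_obs)) / (1 + n_permutations)
  structure(list(K = k_obs, p_value = p,
                 n_permutations = n_permutations, seed = seed,
                 n_tips = s$n),
            class = "k_result")
}

#' @export
print.k_result <- function(x, ...) {
  cat(sprintf("<k_result> K = %.4f, p = %.4f (%d tips, %d permutations)\n",
              x$K, x$p_value, x$n_tips, x$n_permutations))
  invisible(x)
}
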