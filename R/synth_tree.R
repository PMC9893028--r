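#' Simulate a Yule (pure-birth) phylogeny
#'
#' Forward simulation: starting from two lineages at the root, each of the
#' `k` extant lineages splits at total rate `k * birth_rate`; after the
#' n-th tip is born the tree grows for one further exponential waiting time
#' (rate `n * birth_rate`) so every terminal branch has positive length.
#' The expected root-to-tip depth is therefore
#' `sum_{k=2}^{n} 1 / (k * birth_rate)`.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate per lineage per unit time.
#' @param seed integer random seed.
#' @return A rooted binary [ape::phylo] tree with tips `sp1..spN`.
#' @export
#' @examples
#' tr <- gen_yule_tree(10, 1, seed = 42)
#' ape::is.binary(tr)
gen_yule_tree <- function(n_tips, birth_rate = 1, seed = 1) {
  n_tips <- as.integer(n_tips)
  if (n_tips < 2) stopf("n_tips must be >= 2")
  if (birth_rate <= 0) stopf("birth_rate must be > 0")
  set.seed(as.integer(seed))
  n_edge <- 2L * n_tips - 2L
  edge <- matrix(0L, n_edge, 2L)
  edge_len <- numeric(n_edge)
  n_nodes <- n_tips - 1L
  root <- n_tips + 1L
  # active lineages: parent node id and birth time
  par <- c(root, root)
  birth <- c(0, 0)
  next_internal <- root + 1L
  t_now <- 0
  ne <- 0L
  for (k in 2:n_tips) {
    t_now <- t_now + stats::rexp(1, rate = k * birth_rate)
    if (k < n_tips) {
      i <- sample.int(k, 1L)
      v <- next_internal
      next_internal <- next_internal + 1L
      ne <- ne + 1L
      edge[ne, ] <- c(par[i], v)
      edge_len[ne] <- t_now - birth[i]
      par <- c(par[-i], v, v)
      birth <- c(birth[-i], t_now, t_now)
    }
  }
  # close out extant lineages as tips at the present
  for (i in seq_along(par)) {
    ne <- ne + 1L
    edge[ne, ] <- c(par[i], i)
    edge_len[ne] <- t_now - birth[i]
  }
  tr <- structure(list(edge = edge, edge.length = edge_len,
                       tip.label = paste0("sp", seq_len(n_tips)),
                       Nnode = n_nodes),
                  class = "phylo", order = "postorder")
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

#' Specification for Brownian-motion trait simulation
#'
#' @param sigma2 trait variance accrued per unit branch length (> 0).
#' @param root_state trait value at the root.
#' @param seed integer random seed.
#' @return An object of class `bm_spec`.
#' @export
bm_spec <- function(sigma2 = 1, root_state = 0, seed = 1) {
  if (sigma2 <= 0) stopf("sigma2 must be > 0")
  structure(list(sigma2 = sigma2, root_state = root_state,
                 seed = as.integer(seed)),
            class = "bm_spec")
}

#' Simulate a Brownian-motion trait on a phylogeny
#'
#' Draws tip values from the multivariate normal with mean `root_state` and
#' covariance `sigma2 * C`, where `C` is the phylogenetic
#' variance-covariance matrix of the tree (shared root-to-MRCA branch
#' lengths, see [phylo_vcv()]).
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param spec a [bm_spec()].
#' @return Named numeric vector of tip trait values (names = tip labels).
#' @export
gen_bm_trait <- function(tree, spec = bm_spec()) {
  stopifnot(inherits(spec, "bm_spec"))
  C <- phylo_vcv(tree)
  # reject degenerate covariances (e.g. tips joined by zero-length cherries)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev))
    stopf("phylogenetic covariance is not positive definite")
  set.seed(spec$seed)
  x <- MASS::mvrnorm(1, mu = rep(spec$root_state, nrow(C)),
                     Sigma = spec$sigma2 * C)
  names(x) <- rownames(C)
  x
}
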