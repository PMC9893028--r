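#' Generate a species ensemble with known climate/phylogeny/noise shares
#'
#' Ground-truth generator for the species-level variance partition. Each
#' species receives a standardized mean leaf-coloring-date score
#' \deqn{z = \sqrt{w_c}\, c + \sqrt{w_p}\, u + \sqrt{w_n}\, e}
#' where `c` is a (standardized) linear function of the species'
#' native-climate optima, `u` is a standardized Brownian-motion trait
#' simulated on `tree`, and `e` is iid standard normal. Mean LCD is
#' `280 + 8 z` days. Occurrence-climate records are drawn around the
#' species-specific optima, so profile means computed by
#' [build_profiles()] recover `c` up to sampling error.
#'
#' @param tree an [ape::phylo] tree; its tips define the species set.
#' @param climate_weight,phylo_weight,noise_weight nonnegative variance
#'   shares; must sum to 1 (tolerance 1e-9).
#' @param n_occurrences occurrence records generated per species.
#' @param seed integer random seed.
#' @return A list with elements `mean_lcd` (named numeric vector, days),
#'   `occurrences` (data frame in the layout of [read_occurrences()]) and
#'   `truth` (the latent `c`, `u`, `e` components and species optima).
#' @export
gen_species_ensemble <- function(tree, climate_weight, phylo_weight,
                                 noise_weight, n_occurrences = 30,
                                 seed = 1) {
  w <- c(climate_weight, phylo_weight, noise_weight)
  if (any(w < 0)) stopf("weights must be nonnegative")
  if (abs(sum(w) - 1) > 1e-9) stopf("weights must sum to 1")
  validate_tree(tree)
  sp <- tree$tip.label
  n <- length(sp)
  set.seed(as.integer(seed))

  # species-specific native-climate optima
  mat_opt <- stats::runif(n, 2, 20)
  warm_gap <- stats::runif(n, 8, 15)
  cold_gap <- stats::runif(n, 8, 18)
  map_opt <- stats::runif(n, 300, 1600)
  srad_opt <- stats::runif(n, 3500, 6500)

  # latent climate score: cool, dry, low-radiation origins -> early LCD
  c_raw <- 0.7 * as.numeric(scale(mat_opt)) +
    0.5 * as.numeric(scale(map_opt)) +
    0.3 * as.numeric(scale(srad_opt))
  cc <- as.numeric(scale(c_raw))

  u_raw <- gen_bm_trait(tree, bm_spec(sigma2 = 1, seed = derive_seed(seed, "bm")))
  uu <- as.numeric(scale(u_raw))

  set.seed(derive_seed(seed, "noise"))
  ee <- as.numeric(scale(stats::rnorm(n)))

  z <- sqrt(w[1]) * cc + sqrt(w[2]) * uu + sqrt(w[3]) * ee
  mean_lcd <- stats::setNames(280 + 8 * z, sp)

  set.seed(derive_seed(seed, "occurrences"))
  m <- n_occurrences
  occ <- do.call(rbind, lapply(seq_len(n), function(i) {
    # a shared per-occurrence thermal anomaly keeps the ordering
    # tmin_cold <= mat <= tmax_warm intact
    anom <- stats::rnorm(m, 0, 1.5)
    data.frame(species_id = sp[i],
               lon = round(stats::runif(m, 70, 135), 4),
               lat = round(stats::runif(m, 18, 53), 4),
               mat = mat_opt[i] + anom,
               tmax_warm = mat_opt[i] + warm_gap[i] + anom +
                 stats::rnorm(m, 0, 0.5),
               tmin_cold = mat_opt[i] - cold_gap[i] + anom +
                 stats::rnorm(m, 0, 0.5),
               map = pmax(0, map_opt[i] + stats::rnorm(m, 0, 100)),
               srad = srad_opt[i] + stats::rnorm(m, 0, 200),
               stringsAsFactors = FALSE)
  }))
  occ$tmax_warm <- pmax(occ$tmax_warm, occ$mat)
  occ$tmin_cold <- pmin(occ$tmin_cold, occ$mat)

  list(mean_lcd = mean_lcd, occurrences = occ,
       truth = list(climate_score = stats::setNames(cc, sp),
                    phylo_score = stats::setNames(uu, sp),
                    noise_score = stats::setNames(ee, sp),
                    optima = data.frame(species_id = sp, mat = mat_opt,
                                        map = map_opt, srad = srad_opt),
                    weights = w))
}

#' Simulate a complete multi-site study dataset
#'
#' Bundles the individual generators into a small end-to-end dataset
#' exercising the full pipeline: daily climate, LCD and FLD series with a
#' common driver structure, one Yule tree per site, occurrence-climate
#' records, and a site-to-region map.
#'
#' @param n_sites number of sites.
#' @param n_species species per site.
#' @param n_years years of daily climate and phenology.
#' @param seed master seed; all stage seeds derive from it.
#' @param beta,fld_coeff,noise_sd,trend response parameters shared by all
#'   species (passed to [response_spec()]).
#' @return A list with `phenology` (data frame), `climate` (data frame),
#'   `trees` (named list of [ape::phylo], one per site), `occurrences`
#'   (data frame) and `region_map` (data frame `site_id`, `region`).
#' @export
gen_study_dataset <- function(n_sites = 2, n_species = 8, n_years = 40,
                              seed = 1,
                              beta = c(tmax = 1, tmin = 1, pre = 0.5,
                                       ins = -0.8, win = 0),
                              fld_coeff = 0.3, noise_sd = 3, trend = 0.3) {
  sites <- paste0("site", seq_len(n_sites))
  regions <- paste0("region", rep(seq_len(max(1, n_sites %/% 2)),
                                  each = 2, length.out = n_sites))
  climate <- do.call(rbind, lapply(seq_len(n_sites), function(s) {
    gen_climate(climate_gen_spec(n_years = n_years,
                                 seed = derive_seed(seed, paste0("climate", s))),
                site_id = sites[s])
  }))
  class(climate) <- c("climate_table", "data.frame")
  pheno <- list()
  occs <- list()
  trees <- list()
  for (s in seq_len(n_sites)) {
    cl <- climate[climate$site_id == sites[s], ]
    tr <- gen_yule_tree(n_species, 1,
                        seed = derive_seed(seed, paste0("tree", s)))
    ens <- gen_species_ensemble(
      tr, climate_weight = 0.5, phylo_weight = 0.3, noise_weight = 0.2,
      seed = derive_seed(seed, paste0("ensemble", s)))
    trees[[sites[s]]] <- tr
    occs[[s]] <- ens$occurrences
    for (i in seq_len(n_species)) {
      spid <- paste0("sp", i)
      sd_i <- derive_seed(seed, paste(sites[s], spid))
      fld <- gen_fld(cl, noise_sd = noise_sd, seed = sd_i,
                     species_id = spid)
      spec <- response_spec(base_doy = round(ens$mean_lcd[[spid]]),
                            beta = beta, fld_coeff = fld_coeff,
                            noise_sd = noise_sd, trend = trend,
                            seed = sd_i + 1L)
      lcd <- gen_phenology(cl, spec, event = "LCD", fld = fld,
                           species_id = spid)
      pheno[[length(pheno) + 1L]] <- data.frame(
        species_id = spid, site_id = sites[s],
        event = c(rep("FLD", length(fld$year)), rep("LCD", length(lcd$year))),
        year = c(fld$year, lcd$year), doy = c(fld$doy, lcd$doy),
        stringsAsFactors = FALSE)
    }
  }
  occ <- do.call(rbind, occs)
  occ <- occ[!duplicated(paste(occ$species_id, occ$lon, occ$lat)), ]
  list(phenology = do.call(rbind, pheno), climate = climate, trees = trees,
       occurrences = occ,
       region_map = data.frame(site_id = sites, region = regions,
                               stringsAsFactors = FALSE))
}
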