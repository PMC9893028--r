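#' Pipeline run configuration
#'
#' Collects the thresholds and constants shared by both analysis arms.
#'
#' @param alpha significance level for all reported tests.
#' @param max_preseason longest candidate preseason window, days.
#' @param min_years minimum series length retained by quality control and
#'   required of complete-case attribution.
#' @param mad_k MAD multiplier of the outlier screen.
#' @param mad_fld apply the MAD screen to FLD series too.
#' @param n_permutations permutations for the phylogenetic-signal test.
#' @param seed master seed; per-stage seeds derive from it
#'   deterministically, so stages are independently reproducible.
#' @param criterion preseason optimality criterion (`"abs"` or `"max"`).
#' @return List of class `run_config`.
#' @export
run_config <- function(alpha = 0.05, max_preseason = 150, min_years = 15,
                       mad_k = 2, mad_fld = TRUE, n_permutations = 1000,
                       seed = 1, criterion = "abs") {
  stopifnot(alpha > 0, max_preseason > 0, min_years > 0, mad_k > 0,
            n_permutations > 0)
  structure(list(alpha = alpha, max_preseason = as.integer(max_preseason),
                 min_years = as.integer(min_years), mad_k = mad_k,
                 mad_fld = isTRUE(mad_fld),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), criterion = criterion),
            class = "run_config")
}

load_table <- function(x, reader) if (is.character(x)) reader(x) else x

#' Interannual analysis arm: trends and driver attribution
#'
#' Quality control, per-species linear LCD trends, optimal-preseason
#' determination, six-predictor partial-correlation attribution, and
#' regional summaries, in that order. Species that cannot be attributed
#' (too few complete-case years, degenerate series) are recorded in the
#' skip table with a reason rather than aborting the run.
#'
#' @param phenology phenology table (data frame or CSV path; see
#'   [read_phenology()]).
#' @param climate climate table (data frame or CSV path).
#' @param region_map data frame (`site_id`, `region`) or CSV path.
#' @param out_dir output directory; created if missing. `NULL` suppresses
#'   file output.
#' @param config a [run_config()].
#' @return Invisibly, a list with `trends`, `trend_summary`, `preseason`,
#'   `attribution` (long and wide), `regional_summary`, `qc_report`,
#'   `skipped`.
#' @export
run_interannual <- function(phenology, climate, region_map,
                            out_dir = NULL, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  pheno <- load_table(phenology, read_phenology)
  climate <- load_table(climate, read_climate)
  region_map <- load_table(region_map, read_result_table)
  assert_cols(region_map, c("site_id", "region"), "region map")
  miss <- setdiff(unique(pheno$site_id), region_map$site_id)
  if (length(miss))
    stopf("site(s) missing from region map: %s", paste(miss, collapse = ", "))

  qc <- qc_filter(pheno_split(pheno), mad_k = config$mad_k,
                  mad_fld = config$mad_fld, min_years = config$min_years)
  if (nrow(qc$retained) == 0)
    stopf("no species survive quality control")
  lcd <- Filter(function(s) s$event == "LCD", qc$series)
  fld <- Filter(function(s) s$event == "FLD", qc$series)
  fld_key <- vapply(fld, function(s) paste(s$species_id, s$site_id),
                    character(1))

  trends <- do.call(rbind, lapply(lcd, fit_trend))
  overall <- summarize_trends(trends, alpha = config$alpha, region = "all")
  reg <- region_map$region[match(trends$site_id, region_map$site_id)]
  by_region <- do.call(rbind, lapply(split(trends, reg), function(g)
    summarize_trends(g, alpha = config$alpha, region =
                       region_map$region[match(g$site_id[1],
                                               region_map$site_id)])))
  trend_summary <- rbind(overall, by_region)
  rownames(trend_summary) <- NULL

  attr_rows <- list()
  pres_rows <- list()
  skipped <- list()
  for (s in lcd) {
    key <- paste(s$species_id, s$site_id)
    f <- fld[match(key, fld_key)][[1]]
    res <- tryCatch(
      attribute_drivers(s, f, climate, max_preseason = config$max_preseason,
                        min_years = config$min_years,
                        criterion = config$criterion),
      error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(species_id = s$species_id, site_id = s$site_id,
                   stage = "attribution", reason = conditionMessage(res),
                   stringsAsFactors = FALSE)
      next
    }
    attr_rows[[length(attr_rows) + 1L]] <- res$table
    pres_rows[[length(pres_rows) + 1L]] <- do.call(rbind, lapply(
      res$preseasons, function(p)
        data.frame(species_id = s$species_id, site_id = s$site_id,
                   variable = p$variable, length_days = p$length_days,
                   anchor_doy = p$anchor_doy, pearson_r = p$pearson_r,
                   n_years = p$n_years, stringsAsFactors = FALSE)))
  }
  attribution <- if (length(attr_rows)) do.call(rbind, attr_rows) else NULL
  preseason <- if (length(pres_rows)) do.call(rbind, pres_rows) else NULL
  skipped <- if (length(skipped)) do.call(rbind, skipped)
             else data.frame(species_id = character(), site_id = character(),
                             stage = character(), reason = character())
  regional <- if (!is.null(attribution))
    summarize_region(attribution, region_map, alpha = config$alpha)
  else NULL

  out <- list(trends = trends, trend_summary = trend_summary,
              preseason = preseason, attribution = attribution,
              attribution_wide = if (!is.null(attribution))
                attribution_wide(attribution) else NULL,
              regional_summary = regional, qc_report = qc$report,
              skipped = skipped)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_result_table(trends, file.path(out_dir, "trends.csv"))
    write_result_table(trend_summary,
                       file.path(out_dir, "trend_summary.csv"))
    if (!is.null(preseason))
      write_result_table(preseason, file.path(out_dir, "preseason.csv"))
    if (!is.null(out$attribution_wide))
      write_result_table(out$attribution_wide,
                         file.path(out_dir, "attribution.csv"))
    if (!is.null(regional))
      write_result_table(regional,
                         file.path(out_dir, "regional_summary.csv"))
    write_result_table(qc$report, file.path(out_dir, "qc_report.csv"))
    write_result_table(skipped, file.path(out_dir, "skipped.csv"))
  }
  invisible(out)
}

# long attribution table -> one row per species: 6 x (R, p) + preseasons
attribution_wide <- function(attribution) {
  keys <- unique(attribution[, c("species_id", "site_id")])
  preds <- c("tmax", "tmin", "pre", "ins", "win", "fld")
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    g <- attribution[attribution$species_id == keys$species_id[i] &
                       attribution$site_id == keys$site_id[i], ]
    row <- list(species_id = keys$species_id[i],
                site_id = keys$site_id[i], n_years = g$n_years[1])
    for (p in preds) {
      gp <- g[g$predictor == p, ]
      row[[paste0("R_", p)]] <- gp$R
      row[[paste0("p_", p)]] <- gp$p
      if (p != "fld") row[[paste0("preseason_", p)]] <- gp$preseason_length
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Species-level analysis arm: phylogenetic signal and variance partition
#'
#' Per site: multi-year mean LCD per species (from the quality-filtered
#' series), Blomberg's K with its permutation test, native-climate profile
#' construction, eigenvector and climate predictor selection, and the
#' exclusive/shared adjusted-R^2 partition; regional averaging last.
#' Sites with fewer than `min_species` species are skipped with a warning
#' (the partition needs residual degrees of freedom).
#'
#' @param phenology phenology table (data frame or CSV path).
#' @param trees named list of [ape::phylo] trees (one per site; a single
#'   unnamed tree is reused for every site), or a Newick file path.
#' @param occurrences occurrence-climate table (data frame or CSV path).
#' @param region_map data frame (`site_id`, `region`) or CSV path.
#' @param out_dir output directory, or `NULL` for no file output.
#' @param config a [run_config()].
#' @param min_species minimum species per site (default 4).
#' @return Invisibly, a list with `phylosignal`, `profiles`, `partition`,
#'   `regional_partition`, `mean_lcd`, `skipped_sites`.
#' @export
run_species_level <- function(phenology, trees, occurrences, region_map,
                              out_dir = NULL, config = run_config(),
                              min_species = 4) {
  stopifnot(inherits(config, "run_config"))
  pheno <- load_table(phenology, read_phenology)
  occurrences <- load_table(occurrences, read_occurrences)
  region_map <- load_table(region_map, read_result_table)
  if (is.character(trees)) trees <- read_tree(trees)
  if (inherits(trees, "phylo")) {
    trees <- stats::setNames(rep(list(trees),
                                 length(unique(pheno$site_id))),
                             unique(pheno$site_id))
  }

  qc <- qc_filter(pheno_split(pheno), mad_k = config$mad_k,
                  mad_fld = config$mad_fld, min_years = config$min_years)
  lcd <- Filter(function(s) s$event == "LCD", qc$series)
  if (!length(lcd)) stopf("no species survive quality control")

  occ <- dedup_occurrences(occurrences)
  profiles <- build_profiles(occ)

  sites <- unique(vapply(lcd, function(s) s$site_id, character(1)))
  sig_rows <- list()
  part_rows <- list()
  skipped <- character()
  mean_lcd_rows <- list()
  for (st in sites) {
    ser <- Filter(function(s) s$site_id == st, lcd)
    mlcd <- stats::setNames(vapply(ser, function(s) mean(s$doy), numeric(1)),
                            vapply(ser, function(s) s$species_id,
                                   character(1)))
    mean_lcd_rows[[st]] <- data.frame(site_id = st,
                                      species_id = names(mlcd),
                                      mean_lcd = unname(mlcd),
                                      stringsAsFactors = FALSE)
    if (length(mlcd) < min_species) {
      warnf("site %s has %d species (< %d); skipped", st, length(mlcd),
            min_species)
      skipped <- c(skipped, st)
      next
    }
    tr <- trees[[st]]
    if (is.null(tr)) stopf("no tree supplied for site %s", st)
    mism <- c(setdiff(names(mlcd), tr$tip.label),
              setdiff(tr$tip.label, names(mlcd)))
    if (length(mism))
      stopf("site %s: tree tips and species table disagree on: %s", st,
            paste(mism, collapse = ", "))
    kt <- k_permutation_test(tr, mlcd,
                             n_permutations = config$n_permutations,
                             seed = derive_seed(config$seed,
                                                paste0("ksig-", st)))
    sig_rows[[st]] <- data.frame(site_id = st, n_species = length(mlcd),
                                 K = kt$K, p_value = kt$p_value,
                                 n_permutations = kt$n_permutations,
                                 seed = kt$seed, stringsAsFactors = FALSE)
    prof <- profiles[match(names(mlcd), profiles$species_id), ]
    if (anyNA(prof$species_id))
      stopf("site %s: no occurrence profile for species: %s", st,
            paste(names(mlcd)[is.na(prof$species_id)], collapse = ", "))
    climate_sel <- stepwise_climate(mlcd, prof)
    D <- patristic_distances(tr)[names(mlcd), names(mlcd)]
    pc <- pcoa_axes(D)
    eig_sel <- select_eigenvectors(mlcd, pc, D, alpha = config$alpha)
    part <- pvr_partition(
      mlcd,
      if (length(climate_sel))
        as.matrix(prof[, climate_sel, drop = FALSE]) else NULL,
      if (length(eig_sel))
        pc$vectors[names(mlcd), eig_sel, drop = FALSE] else NULL)
    part_rows[[st]] <- data.frame(
      site_id = st, n_species = part$n_species,
      r2adj_climate = part$r2adj_climate, r2adj_phylo = part$r2adj_phylo,
      r2adj_full = part$r2adj_full, P1 = part$P1, P2 = part$P2,
      P3 = part$P3,
      climate_predictors = paste(climate_sel, collapse = ";"),
      eigenvectors = paste(eig_sel, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  phylosignal <- if (length(sig_rows)) do.call(rbind, sig_rows) else NULL
  partition <- if (length(part_rows)) do.call(rbind, part_rows) else NULL
  regional <- if (!is.null(partition))
    regional_partition(partition, region_map) else NULL
  out <- list(phylosignal = phylosignal, profiles = profiles,
              partition = partition, regional_partition = regional,
              mean_lcd = do.call(rbind, mean_lcd_rows),
              skipped_sites = skipped)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(phylosignal))
      write_result_table(phylosignal,
                         file.path(out_dir, "phylosignal.csv"))
    write_result_table(profiles,
                       file.path(out_dir, "native_profiles.csv"))
    if (!is.null(partition))
      write_result_table(partition, file.path(out_dir, "partition.csv"))
    if (!is.null(regional))
      write_result_table(regional,
                         file.path(out_dir, "regional_partition.csv"))
  }
  invisible(out)
}
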