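#' Remove coordinate duplicates from occurrence records
#'
#' Within each species, occurrence records sharing the same coordinates
#' (after rounding to 4 decimal places, about 11 m) collapse to the first
#' occurrence. Identical coordinates in different species are kept. The
#' operation is idempotent and order-stable.
#'
#' @param records occurrence data frame (see [read_occurrences()]).
#' @param digits coordinate rounding applied before comparison.
#' @return The deduplicated data frame.
#' @export
dedup_occurrences <- function(records, digits = 4) {
  assert_cols(records, c("species_id", "lon", "lat"), "occurrence table")
  key <- paste(records$species_id, round(records$lon, digits),
               round(records$lat, digits))
  records[!duplicated(key), , drop = FALSE]
}

#' Native-climate profiles: mean and range per species
#'
#' For each species, computes the arithmetic mean and the range
#' (max - min) of the five occurrence-climate variables across its
#' (deduplicated) occurrence points — ten predictors per species.
#'
#' @param records occurrence data frame, ideally after
#'   [dedup_occurrences()].
#' @return Data frame with one row per species: `species_id`,
#'   `<var>_mean` and `<var>_range` for `mat`, `tmax_warm`, `tmin_cold`,
#'   `map`, `srad`, plus `n_occurrences`.
#' @export
#' @examples
#' occ <- data.frame(species_id = "sp1", lon = 1:3, lat = 1:3,
#'                   mat = c(10, 12, 14), tmax_warm = c(25, 26, 27),
#'                   tmin_cold = c(-5, -4, -3), map = c(500, 600, 700),
#'                   srad = c(4000, 4100, 4200))
#' build_profiles(occ)  # mat_mean 12, mat_range 4
build_profiles <- function(records) {
  vars <- c("mat", "tmax_warm", "tmin_cold", "map", "srad")
  assert_cols(records, c("species_id", vars), "occurrence table")
  if (nrow(records) == 0) stopf("no occurrence records")
  sp <- unique(records$species_id)
  out <- do.call(rbind, lapply(sp, function(s) {
    g <- records[records$species_id == s, , drop = FALSE]
    row <- list(species_id = s)
    for (v in vars) {
      row[[paste0(v, "_mean")]] <- mean(g[[v]])
      row[[paste0(v, "_range")]] <- max(g[[v]]) - min(g[[v]])
    }
    row$n_occurrences <- nrow(g)
    as.data.frame(row, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# the ten predictor column names, in canonical order
profile_predictors <- function() {
  vars <- c("mat", "tmax_warm", "tmin_cold", "map", "srad")
  c(paste0(vars, "_mean"), paste0(vars, "_range"))
}
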