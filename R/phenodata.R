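#' Phenological time series for one species, site and event
#'
#' Lightweight container for a single species x site x event series of
#' day-of-year (DOY) observations, one value per year. Years are kept
#' strictly increasing; duplicate years are an error.
#'
#' @param species_id character scalar, species identifier.
#' @param site_id character scalar, site identifier.
#' @param event `"FLD"` (first leaf date) or `"LCD"` (leaf coloring date).
#' @param year integer vector of observation years.
#' @param doy integer vector of 1-based day-of-year values (1..366),
#'   parallel to `year`.
#'
#' @return An object of class `pheno_series`: a list with elements
#'   `species_id`, `site_id`, `event`, `year`, `doy`.
#' @export
#' @examples
#' pheno_series("sp1", "Beijing", "LCD", 1990:1994, c(281, 282, 280, 283, 285))
pheno_series <- function(species_id, site_id, event, year, doy) {
  event <- match.arg(event, c("FLD", "LCD"))
  if (length(year) != length(doy))
    stopf("year and doy must have equal length")
  year <- as.integer(year)
  doy <- as.numeric(doy)
  if (anyDuplicated(year))
    stopf("duplicate year(s) in series %s/%s/%s: %s", species_id, site_id,
          event, paste(unique(year[duplicated(year)]), collapse = ", "))
  if (length(doy) && (any(doy < 1) || any(doy > 366)))
    stopf("doy values must lie in [1, 366]")
  o <- order(year)
  structure(list(species_id = as.character(species_id),
                 site_id = as.character(site_id),
                 event = event,
                 year = year[o], doy = doy[o]),
            class = "pheno_series")
}

#' @export
print.pheno_series <- function(x, ...) {
  cat(sprintf("<pheno_series> %s @ %s [%s], %d years (%s-%s)\n",
              x$species_id, x$site_id, x$event, length(x$year),
              if (length(x$year)) min(x$year) else NA,
              if (length(x$year)) max(x$year) else NA))
  invisible(x)
}

#' @export
length.pheno_series <- function(x) length(x$year)

#' Read a phenological observation table
#'
#' Parses a CSV with columns `species_id`, `site_id`, `event`, `year` and a
#' date column that is either an ISO-8601 calendar date (`date`) or an
#' integer day-of-year (`doy`). Calendar dates are converted to 1-based DOY
#' (Feb 29 = 60 in leap years). Duplicate (species, site, event, year) keys
#' are rejected.
#'
#' @param path path to a CSV file with a header row.
#' @return A data frame with columns `species_id`, `site_id`, `event`,
#'   `year`, `doy`.
#' @seealso [pheno_split()] to explode the table into `pheno_series`.
#' @export
read_phenology <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_cols(df, c("species_id", "site_id", "event", "year"),
              "phenology table")
  if (!("date" %in% names(df)) && !("doy" %in% names(df)))
    stopf("phenology table needs a 'date' (ISO-8601) or 'doy' column")
  n <- nrow(df)
  if (n == 0L)
    return(data.frame(species_id = character(), site_id = character(),
                      event = character(), year = integer(),
                      doy = integer()))
  yr <- suppressWarnings(as.integer(df$year))
  bad <- which(is.na(yr))
  if (length(bad))
    stopf("phenology: unparsable year at data line(s) %s",
          paste(bad + 1L, collapse = ", "))
  if ("date" %in% names(df)) {
    raw <- as.character(df$date)
    iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", raw)
    doy <- rep(NA_integer_, n)
    if (any(iso)) {
      d <- as.Date(raw[iso], format = "%Y-%m-%d")
      if (anyNA(d))
        stopf("phenology: invalid calendar date at data line(s) %s",
              paste(which(iso)[is.na(d)] + 1L, collapse = ", "))
      if (any(year_of(d) != yr[iso]))
        stopf("phenology: date/year mismatch at data line(s) %s",
              paste(which(iso)[year_of(d) != yr[iso]] + 1L, collapse = ", "))
      doy[iso] <- doy_of(d)
    }
    doy[!iso] <- suppressWarnings(as.integer(raw[!iso]))
  } else {
    doy <- suppressWarnings(as.integer(df$doy))
  }
  bad <- which(is.na(doy) | doy < 1L | doy > 366L)
  if (length(bad))
    stopf("phenology: unparsable or out-of-range date/doy at data line(s) %s",
          paste(bad + 1L, collapse = ", "))
  ev <- as.character(df$event)
  bad <- which(!(ev %in% c("FLD", "LCD")))
  if (length(bad))
    stopf("phenology: event must be FLD or LCD at data line(s) %s",
          paste(bad + 1L, collapse = ", "))
  key <- paste(df$species_id, df$site_id, ev, yr, sep = "\r")
  if (anyDuplicated(key)) {
    d <- unique(key[duplicated(key)])
    stopf("phenology: duplicate (species, site, event, year) record(s): %s",
          paste(gsub("\r", "/", d), collapse = "; "))
  }
  data.frame(species_id = as.character(df$species_id),
             site_id = as.character(df$site_id),
             event = ev, year = yr, doy = doy,
             stringsAsFactors = FALSE)
}

#' Split a phenology table into per-series objects
#'
#' @param df data frame as returned by [read_phenology()].
#' @return A named list of [pheno_series] objects, keyed
#'   `"species/site/event"`, in order of first appearance.
#' @export
pheno_split <- function(df) {
  assert_cols(df, c("species_id", "site_id", "event", "year", "doy"),
              "phenology table")
  key <- paste(df$species_id, df$site_id, df$event, sep = "/")
  idx <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
  lapply(idx, function(i)
    pheno_series(df$species_id[i[1]], df$site_id[i[1]], df$event[i[1]],
                 df$year[i], df$doy[i]))
}

#' Read a daily site climate table
#'
#' Expects CSV columns `site_id`, `date` (ISO-8601), `tmax`, `tmin` (deg C),
#' `pre` (mm/day), `ins` (MJ m-2 day-1), `win` (m/s). Rows violating
#' physical constraints (tmin > tmax, negative precipitation/insolation/
#' wind) are an error; gaps in per-site date coverage are reported as a
#' warning and left to downstream window aggregation to handle.
#'
#' @param path path to a CSV file.
#' @return A data frame (class `climate_table`) keyed by (`site_id`, `date`).
#' @export
read_climate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_cols(df, c("site_id", "date", "tmax", "tmin", "pre", "ins", "win"),
              "climate table")
  df$date <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(df$date))
    stopf("climate: invalid date at data line(s) %s",
          paste(which(is.na(df$date)) + 1L, collapse = ", "))
  for (v in c("tmax", "tmin", "pre", "ins", "win"))
    df[[v]] <- as.numeric(df[[v]])
  bad <- which(df$tmin > df$tmax)
  if (length(bad))
    stopf("climate: tmin > tmax at data line(s) %s",
          paste(bad + 1L, collapse = ", "))
  for (v in c("pre", "ins", "win")) {
    bad <- which(df[[v]] < 0)
    if (length(bad))
      stopf("climate: negative %s at data line(s) %s", v,
            paste(bad + 1L, collapse = ", "))
  }
  key <- paste(df$site_id, df$date)
  if (anyDuplicated(key))
    stopf("climate: duplicate (site, date) rows")
  for (s in unique(df$site_id)) {
    d <- sort(df$date[df$site_id == s])
    if (length(d) > 1) {
      full <- seq(d[1], d[length(d)], by = "day")
      ngap <- length(full) - length(d)
      if (ngap > 0)
        warnf("climate: site %s has %d missing day(s) between %s and %s",
              s, ngap, d[1], d[length(d)])
    }
  }
  class(df) <- c("climate_table", "data.frame")
  df
}

#' Read a per-species occurrence-climate table
#'
#' Expects CSV columns `species_id`, `lon`, `lat`, `mat` (mean annual
#' temperature, deg C), `tmax_warm` (max temperature of the warmest month),
#' `tmin_cold` (min temperature of the coldest month), `map` (mean annual
#' precipitation, mm), `srad` (mean annual solar radiation).
#'
#' @param path path to a CSV file.
#' @return Data frame of occurrence records.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_cols(df, c("species_id", "lon", "lat", "mat", "tmax_warm",
                    "tmin_cold", "map", "srad"), "occurrence table")
  for (v in c("lon", "lat", "mat", "tmax_warm", "tmin_cold", "map", "srad"))
    df[[v]] <- as.numeric(df[[v]])
  bad <- which(!(df$tmin_cold <= df$mat & df$mat <= df$tmax_warm))
  if (length(bad))
    stopf("occurrences: tmin_cold <= mat <= tmax_warm violated at line(s) %s",
          paste(bad + 1L, collapse = ", "))
  bad <- which(df$map < 0)
  if (length(bad))
    stopf("occurrences: negative map at line(s) %s",
          paste(bad + 1L, collapse = ", "))
  df
}

#' Read a phylogeny from a Newick file
#'
#' Wraps [ape::read.tree()] with the validation required downstream:
#' unique tip labels and branch lengths present and nonnegative (patristic
#' distances and the Brownian-motion covariance are undefined otherwise).
#'
#' @param path path to a file containing a single Newick string.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stopf("could not parse a Newick tree from %s", path)
  if (inherits(tr, "multiPhylo"))
    stopf("expected a single Newick tree, found %d", length(tr))
  validate_tree(tr)
  tr
}

# shared tree validation (also applied to trees passed in directly)
validate_tree <- function(tr) {
  if (!inherits(tr, "phylo")) stopf("not a phylo object")
  if (anyDuplicated(tr$tip.label))
    stopf("duplicate tip label(s): %s",
          paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                collapse = ", "))
  if (is.null(tr$edge.length) || anyNA(tr$edge.length))
    stopf("tree has missing branch lengths; distances are undefined")
  if (any(tr$edge.length < 0))
    stopf("tree has negative branch length(s)")
  invisible(tr)
}

#' Write a phylogeny to a Newick file
#'
#' @param tree an [ape::phylo] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  validate_tree(tree)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write / read a result table
#'
#' Plain UTF-8 comma-separated output with a header row and full numeric
#' precision (round trips are the identity to at least 12 significant
#' digits).
#'
#' @param df data frame to write.
#' @param path file path.
#' @return `path` (writer) or the data frame (reader).
#' @export
write_result_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
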