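# Shared fixtures, built in code.

tree3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

star_tree <- function(n, t = 1) {
  tr <- ape::stree(n, "star")
  tr$edge.length <- rep(t, n)
  tr$tip.label <- paste0("sp", seq_len(n))
  tr
}

# deterministic climate table: tmax = doy/10, other variables constant
linear_climate <- function(years = 1990:1994, site_id = "s1") {
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  doy <- as.integer(strftime(dates, "%j"))
  df <- data.frame(site_id = site_id, date = dates, tmax = doy / 10,
                   tmin = doy / 10 - 5, pre = 1, ins = 10, win = 2,
                   stringsAsFactors = FALSE)
  class(df) <- c("climate_table", "data.frame")
  df
}

write_lines_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# literal transcription of the Blomberg's K formula, independent of the
# package implementation (explicit solve(), no shared code paths)
k_oracle <- function(tree, x) {
  C <- ape::vcv.phylo(tree)
  x <- x[rownames(C)]
  n <- length(x)
  Cinv <- solve(C)
  one <- rep(1, n)
  ahat <- as.numeric(t(one) %*% Cinv %*% x) / as.numeric(t(one) %*% Cinv %*% one)
  r <- x - ahat
  mse0 <- sum(r^2) / (n - 1)
  mse <- as.numeric(t(r) %*% Cinv %*% r) / (n - 1)
  expected <- (sum(diag(C)) - n / as.numeric(t(one) %*% Cinv %*% one)) / (n - 1)
  (mse0 / mse) / expected
}
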