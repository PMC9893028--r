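# Internal helpers shared across modules.

# day-of-year, 1-based (Feb 29 = 60 in leap years)
doy_of <- function(date) as.integer(strftime(date, "%j"))

year_of <- function(date) as.integer(format(date, "%Y"))

# Deterministic 31-bit stage seed derived from a master seed and a stage
# label, so pipeline stages are independently reproducible.
derive_seed <- function(master, stage) {
  cp <- utf8ToInt(stage)
  h <- sum(cp * seq_along(cp))
  as.integer((as.numeric(master) %% 44488 * 48271 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stopf("%s is missing required column(s): %s", what,
          paste(miss, collapse = ", "))
}
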