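## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(msg, ...) stop(sprintf(msg, ...), call. = FALSE)

#' @noRd
assert_that <- function(ok, msg, ...) {
  if (!isTRUE(ok)) stop_field(msg, ...)
  invisible(TRUE)
}

## Inner-join two (year, value) tables, reporting dropped years.
join_years <- function(x, y, quiet = TRUE) {
  common <- intersect(x$year, y$year)
  dropped <- length(unique(c(x$year, y$year))) - length(common)
  if (dropped > 0L && !quiet) {
    message(sprintf("join_years(): dropped %d non-overlapping year(s)", dropped))
  }
  out <- merge(x, y, by = "year")
  out[order(out$year), , drop = FALSE]
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= 0
}

## Contiguity check for (year, value) long data; returns offending years or NULL.
find_year_gaps <- function(years) {
  years <- sort(unique(years))
  if (length(years) < 2L) return(NULL)
  d <- diff(years)
  if (all(d == 1L)) return(NULL)
  years[which(d != 1L)]
}
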