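## Standard-format I/O: Tucson .rwl decadal files (0.01 mm and 0.001 mm
## dialects), long CSV proxy tables, monthly climate CSV and JSON reports.

#' Read a Tucson (.rwl) decadal ring-width file
#'
#' Auto-detects the measurement dialect from the terminal stop marker:
#' series ending in `-9999` are 0.001 mm units, series ending in `999` are
#' 0.01 mm (an interior `999` in a 0.001 mm series is read as a 0.999 mm
#' datum).  Malformed decade lines and non-monotonic years are rejected with
#' the offending line number.
#'
#' @param path file path.
#' @return data frame of widths in mm, rownames = years, one column per
#'   series.
#' @export
read_rwl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  series <- list()
  for (ln in seq_along(lines)) {
    toks <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(toks) < 3L) stop_field("read_rwl(): malformed line %d", ln)
    id <- toks[1]
    decade <- suppressWarnings(as.integer(toks[2]))
    vals <- suppressWarnings(as.numeric(toks[-(1:2)]))
    if (is.na(decade) || anyNA(vals)) {
      stop_field("read_rwl(): malformed decade line %d", ln)
    }
    if (is.null(series[[id]])) {
      series[[id]] <- list(years = integer(), raw = numeric(), last = -Inf)
    }
    s <- series[[id]]
    if (decade <= s$last) {
      stop_field("read_rwl(): non-monotonic years for series '%s' at line %d", id, ln)
    }
    s$years <- c(s$years, decade + seq_along(vals) - 1L)
    s$raw <- c(s$raw, vals)
    s$last <- decade
    series[[id]] <- s
  }
  assert_that(length(series) > 0, "read_rwl(): no series found in '%s'", path)
  ## dialect from the trailing stop marker: -9999 ends a 0.001 mm series,
  ## 999 a 0.01 mm series (999 elsewhere is a valid 0.999 mm datum)
  for (id in names(series)) {
    s <- series[[id]]
    tail_val <- s$raw[length(s$raw)]
    if (tail_val == -9999) {
      s$unit <- 0.001
    } else if (tail_val == 999) {
      s$unit <- 0.01
    } else {
      stop_field("read_rwl(): series '%s' has no terminal stop marker", id)
    }
    s$years <- s$years[-length(s$years)]
    s$raw <- s$raw[-length(s$raw)]
    series[[id]] <- s
  }
  all_years <- range(unlist(lapply(series, `[[`, "years")))
  years <- seq.int(all_years[1], all_years[2])
  out <- as.data.frame(matrix(NA_real_, length(years), length(series)))
  names(out) <- names(series)
  rownames(out) <- years
  for (id in names(series)) {
    s <- series[[id]]
    gaps <- find_year_gaps(s$years)
    if (!is.null(gaps)) {
      stop_field("read_rwl(): series '%s' has a gap after year %d", id, gaps[1])
    }
    out[match(s$years, years), id] <- s$raw * s$unit
  }
  out
}

#' Write a Tucson (.rwl) decadal ring-width file
#'
#' @param rwl data frame of widths in mm (rownames = years).
#' @param path output path.
#' @param units `0.001` (stop marker -9999, the default for modern precision)
#'   or `0.01` mm (stop marker 999).
#' @export
write_rwl <- function(rwl, path, units = 0.001) {
  assert_that(units %in% c(0.001, 0.01), "write_rwl(): units must be 0.001 or 0.01")
  years <- as.integer(rownames(rwl))
  con <- file(path, "w")
  on.exit(close(con))
  marker <- if (units == 0.001) -9999 else 999
  for (id in names(rwl)) {
    v <- rwl[[id]]
    present <- which(!is.na(v))
    yrs <- years[present]
    vals <- round(v[present] / units)
    seq_years <- c(yrs, yrs[length(yrs)] + 1L)      # trailing stop marker year
    seq_vals <- c(vals, marker)
    while (length(seq_vals)) {
      y0 <- seq_years[1]
      n_in_decade <- min(10L - (y0 %% 10L), length(seq_vals))
      chunk <- seq_len(n_in_decade)
      writeLines(sprintf("%-8s%4d%s", substr(id, 1, 8), y0,
                         paste(sprintf("%6d", seq_vals[chunk]), collapse = "")),
                 con)
      seq_years <- seq_years[-chunk]
      seq_vals <- seq_vals[-chunk]
    }
  }
  invisible(path)
}

#' Read/write long-format ring-width CSV
#'
#' Columns `tree_id`, `core_id`, `year`, `width_mm`; per-core years must be
#' contiguous.
#' @param path file path.
#' @return wide data frame as from [read_rwl()] (columns = core ids).
#' @export
read_ring_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tree_id", "core_id", "year", "width_mm")
  assert_that(all(need %in% names(df)), "read_ring_csv(): columns %s required",
              paste(need, collapse = ", "))
  for (cid in unique(df$core_id)) {
    sub <- df[df$core_id == cid, ]
    gaps <- find_year_gaps(sub$year)
    if (!is.null(gaps)) {
      stop_field("read_ring_csv(): tree %s core %s has a gap after year %d",
                 sub$tree_id[1], cid, gaps[1])
    }
  }
  years <- seq.int(min(df$year), max(df$year))
  ids <- unique(df$core_id)
  out <- as.data.frame(matrix(NA_real_, length(years), length(ids)))
  names(out) <- ids
  rownames(out) <- years
  for (cid in ids) {
    sub <- df[df$core_id == cid, ]
    out[match(sub$year, years), cid] <- sub$width_mm
  }
  out
}

#' @rdname read_ring_csv
#' @param rwl wide ring-width data frame.
#' @param tree_of optional function mapping a core id to its tree id
#'   (default: strip a trailing letter).
#' @export
write_ring_csv <- function(rwl, path, tree_of = function(id) sub("[A-Za-z]$", "", id)) {
  years <- as.integer(rownames(rwl))
  rows <- lapply(names(rwl), function(id) {
    ok <- !is.na(rwl[[id]])
    data.frame(tree_id = tree_of(id), core_id = id, year = years[ok],
               width_mm = rwl[[id]][ok])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read/write the monthly climate CSV
#'
#' Columns `year`, `month`, `tmax_c`, `tmean_c`, `rh_pct`, `precip_mm`; one
#' row per year-month with no interior gaps.
#' @param path file path.
#' @export
read_climate_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("year", "month", "tmax_c", "tmean_c", "rh_pct", "precip_mm")
  assert_that(all(need %in% names(df)), "read_climate_csv(): columns %s required",
              paste(need, collapse = ", "))
  df <- df[order(df$year, df$month), ]
  expected <- 12L * length(unique(df$year))
  assert_that(nrow(df) == expected && !anyNA(df),
              "read_climate_csv(): gaps or missing values inside the monthly span")
  df
}

#' Write a JSON report (models, validation, manifest entries)
#' @param x a list or model object.
#' @param path output path.
#' @export
write_report_json <- function(x, path) {
  if (inherits(x, c("transfer_model", "validation_report", "elevation_model"))) {
    x <- unclass(x)
    x$data <- NULL
  }
  ## named atomic vectors serialize as JSON objects, not nameless arrays
  x <- lapply(x, function(v) {
    if (is.atomic(v) && !is.null(names(v))) as.list(v) else v
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}
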