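## Superposed epoch analysis of the ring-width chronology around drought years.

#' Superposed epoch analysis with a Monte-Carlo null
#'
#' Composites the chronology at lags `-window..+window` around the event
#' years, standardizes the composite means against the whole-record mean and
#' SD of the chronology, and assesses significance against `n_mc` random
#' event sets of the same size drawn without replacement from all eligible
#' years (events included by default, the common SEA convention; switchable).
#'
#' @param chronology data frame `year`, `index` (a `"crn"` object's `$crn`
#'   table also works) -- or any `year`/second-column pair.
#' @param event_years integer years of the events (lag 0).  Events whose full
#'   window falls outside the record are dropped with a message.
#' @param window half-width of the lag window in years (default 3).
#' @param n_mc Monte-Carlo iterations (default 1000).
#' @param seed integer seed for the null draws.
#' @param conf confidence level of the null band (default 0.95).
#' @param exclude_events if `TRUE`, null sets are drawn from non-event years
#'   only.
#' @return class `"sea_result"`: data frame `lag`, `mean_anomaly`,
#'   `ci_lower`, `ci_upper`, `significant` with attributes `n_events`,
#'   `n_mc`, `seed`, `window`, `record_mean`, `record_sd`.
#' @export
superposed_epoch <- function(chronology, event_years, window = 3L,
                             n_mc = 1000L, seed = 42L, conf = 0.95,
                             exclude_events = FALSE) {
  if (inherits(chronology, "crn") && !is.data.frame(chronology)) {
    chronology <- chronology$crn
  }
  years <- chronology$year
  values <- chronology[[2]]
  assert_that(!anyNA(values), "superposed_epoch(): chronology has missing values")
  rec_mean <- mean(values)
  rec_sd <- stats::sd(values)
  assert_that(rec_sd > 0, "superposed_epoch(): constant chronology; anomalies undefined (SD = 0)")

  n <- length(years)
  eligible_idx <- seq.int(window + 1L, n - window)
  assert_that(length(eligible_idx) >= 1L, "superposed_epoch(): record shorter than the window")
  ev_idx <- match(event_years, years)
  bad <- is.na(ev_idx) | ev_idx < min(eligible_idx) | ev_idx > max(eligible_idx)
  if (any(bad)) {
    message(sprintf("superposed_epoch(): dropped %d event(s) too close to the record edges",
                    sum(bad)))
  }
  ev_idx <- ev_idx[!bad]
  n_ev <- length(ev_idx)
  assert_that(n_ev >= 1L, "superposed_epoch(): no eligible event years")
  if (n_ev < 3L) warning("superposed_epoch(): fewer than 3 events; composite is fragile")

  lags <- seq.int(-window, window)
  composite <- vapply(lags, function(L) mean(values[ev_idx + L]), numeric(1))
  anomaly <- (composite - rec_mean) / rec_sd

  pool <- if (exclude_events) setdiff(eligible_idx, ev_idx) else eligible_idx
  assert_that(length(pool) >= n_ev,
              "superposed_epoch(): null pool smaller than the event count")
  set.seed(seed)
  draws <- vapply(seq_len(n_mc), function(i) sample(pool, n_ev), integer(n_ev))
  draws <- matrix(draws, nrow = n_ev)
  null_anom <- vapply(lags, function(L) {
    (colMeans(matrix(values[draws + L], nrow = n_ev)) - rec_mean) / rec_sd
  }, numeric(n_mc))
  alpha <- (1 - conf) / 2
  ci <- apply(null_anom, 2L, stats::quantile, probs = c(alpha, 1 - alpha))
  out <- data.frame(lag = lags, mean_anomaly = anomaly,
                    ci_lower = ci[1, ], ci_upper = ci[2, ],
                    significant = anomaly < ci[1, ] | anomaly > ci[2, ])
  structure(out, n_events = n_ev, n_mc = n_mc, seed = seed, window = window,
            record_mean = rec_mean, record_sd = rec_sd, conf = conf,
            normalization = "whole-record mean/SD of the chronology",
            class = c("sea_result", "data.frame"))
}

#' SEA per drought-classification scheme
#'
#' Runs [superposed_epoch()] once per scheme with the severe (`D`) years of
#' each classification as events, and assembles a comparison table of lag-0
#' anomalies and post-event recovery lags (first lag >= +1 whose anomaly
#' falls inside the null band).
#'
#' @param chronology as in [superposed_epoch()].
#' @param classifications named list of `"drought_classification"` objects
#'   (e.g. `list(SPEI = ..., VPD = ..., COMB = ...)`).
#' @param ... passed to [superposed_epoch()].
#' @return list with `results` (one `"sea_result"` per scheme; schemes with
#'   zero severe years are skipped with a warning) and `comparison` (data
#'   frame `scheme`, `n_events`, `lag0_anomaly`, `lag0_significant`,
#'   `recovery_lag`).
#' @export
sea_by_type <- function(chronology, classifications, ...) {
  results <- list()
  rows <- list()
  for (nm in names(classifications)) {
    cls <- classifications[[nm]]
    ev <- cls$year[cls$label == "D"]
    if (!length(ev)) {
      warning(sprintf("sea_by_type(): scheme '%s' has no severe years; skipped", nm))
      next
    }
    res <- superposed_epoch(chronology, ev, ...)
    results[[nm]] <- res
    post <- res[res$lag >= 1L, ]
    rec <- post$lag[!post$significant]
    rows[[nm]] <- data.frame(
      scheme = nm,
      n_events = attr(res, "n_events"),
      lag0_anomaly = res$mean_anomaly[res$lag == 0L],
      lag0_significant = res$significant[res$lag == 0L],
      recovery_lag = if (length(rec)) min(rec) else NA_integer_)
  }
  list(results = results, comparison = do.call(rbind, rows))
}
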