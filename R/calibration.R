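## Proxy-climate screening and transfer-function calibration/validation.

#' Spearman correlation with bootstrapped significance
#'
#' Rank correlation between two annual series (inner-joined on year), with a
#' two-sided bootstrap p-value: pairs are resampled with replacement and the
#' p-value is twice the smaller tail fraction of the resampled correlation
#' distribution around zero (percentile construction, declared in the output
#' rather than assumed to match any particular screening tool).
#'
#' @param x,y data frames `year`, `value` (or plain numeric vectors of equal
#'   length, taken as already aligned).
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed integer seed for the resampling.
#' @param min_overlap minimum common years.
#' @return list `rho`, `p_boot`, `n`, `n_boot`.
#' @export
spearman_bootstrap <- function(x, y, n_boot = 1000L, seed = 1L, min_overlap = 10L) {
  if (is.data.frame(x)) {
    xy <- join_years(x, y)
    xv <- xy[[2]]; yv <- xy[[3]]
  } else {
    assert_that(length(x) == length(y), "spearman_bootstrap(): unequal lengths")
    ok <- is.finite(x) & is.finite(y)
    xv <- x[ok]; yv <- y[ok]
  }
  n <- length(xv)
  assert_that(n >= min_overlap, "spearman_bootstrap(): overlap %d < %d years", n, min_overlap)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    warning("spearman_bootstrap(): constant series; rho undefined")
    return(list(rho = NA_real_, p_boot = NA_real_, n = n, n_boot = n_boot))
  }
  rho <- stats::cor(xv, yv, method = "spearman")
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    suppressWarnings(stats::cor(xv[idx], yv[idx], method = "spearman"))
  }, numeric(1))
  boot <- boot[is.finite(boot)]
  p <- 2 * min(mean(boot <= 0), mean(boot >= 0))
  p <- min(max(p, 1 / length(boot)), 1)
  list(rho = rho, p_boot = p, n = n, n_boot = n_boot)
}

#' Month-by-accumulation correlation grid
#'
#' Screens a proxy against the standardized moisture index for every
#' (target month, accumulation k) cell, or against windowed VPD means (window
#' of k months ending in the row month), mirroring the usual climate-response
#' heat maps.
#'
#' @param proxy annual data frame `year`, `value`.
#' @param climate monthly climate table.
#' @param index_spec `"smi"` or `"vpd"`.
#' @param k_range accumulation periods / window lengths (columns).
#' @param months target months (rows).
#' @param n_boot,seed bootstrap controls passed to [spearman_bootstrap()].
#' @param lat_deg latitude for PET when `index_spec = "smi"`.
#' @return class `"correlation_grid"` data frame `month`, `k`, `rho`,
#'   `p_boot`, `n`.
#' @export
correlation_grid <- function(proxy, climate, index_spec = c("smi", "vpd"),
                             k_range = 1:7, months = 1:12,
                             n_boot = 1000L, seed = 1L, lat_deg = 37) {
  index_spec <- match.arg(index_spec)
  assert_that(nrow(join_years(proxy, data.frame(year = unique(climate$year), value = 0))) >= 10,
              "correlation_grid(): proxy does not overlap the climate span by >= 10 years")
  if (index_spec == "vpd") climate <- climate_vpd(climate)
  cells <- expand.grid(k = k_range, month = months)[, c("month", "k")]
  res <- lapply(seq_len(nrow(cells)), function(i) {
    m <- cells$month[i]; k <- cells$k[i]
    idx <- if (index_spec == "smi") {
      standardized_moisture_index(climate, k, m, lat_deg = lat_deg)
    } else {
      vpd_window_mean(climate, k, m)
    }
    sb <- spearman_bootstrap(proxy, idx, n_boot = n_boot, seed = seed + i)
    data.frame(month = m, k = k, rho = sb$rho, p_boot = sb$p_boot, n = sb$n)
  })
  out <- do.call(rbind, res)
  class(out) <- c("correlation_grid", "data.frame")
  out
}

## Mean VPD over the k months ending in `month` (window clipped to one
## calendar year: windows reaching before January use the available months of
## the same year -- the pipeline's seasonal targets never cross years).
vpd_window_mean <- function(climate, k, month) {
  start <- max(1L, month - k + 1L)
  seasonal_mean(climate, "vpd_kpa", start, month)
}

#' Fit a linear transfer function with diagnostics
#'
#' OLS of a seasonal climate target on one or two annual proxy series over
#' their common (calibration) years, reporting R2, adjusted R2, residual SE,
#' Durbin-Watson, per-predictor variance inflation factors and a Shapiro-Wilk
#' residual-normality p-value.  Diagnostics are reported, never used to
#' refuse a fit; only perfect collinearity rejects.
#'
#' @param target data frame `year`, `value` (the climate index).
#' @param predictors named list of 1 or 2 data frames `year`, `value`
#'   (e.g. `list(d18o = ..., rwi = ...)`).
#' @param calibration_span optional length-2 year range.
#' @return class `"transfer_model"` with `coefficients` (intercept first),
#'   `predictors`, `r2`, `adj_r2`, `rse`, `dw`, `vif`, `shapiro_p`, `n`,
#'   `calibration_years`, `data` (the model frame, kept for validation).
#' @export
fit_transfer <- function(target, predictors, calibration_span = NULL) {
  assert_that(is.list(predictors) && length(predictors) %in% 1:2,
              "fit_transfer(): 1 or 2 predictors required (model space is deliberately small)")
  assert_that(!is.null(names(predictors)) && all(nzchar(names(predictors))),
              "fit_transfer(): predictors must be named")
  df <- target
  names(df)[2] <- "target"
  for (nm in names(predictors)) {
    p <- predictors[[nm]]
    names(p)[2] <- nm
    df <- join_years(df, p)
  }
  if (!is.null(calibration_span)) {
    df <- df[df$year >= calibration_span[1] & df$year <= calibration_span[2], ]
  }
  df <- df[stats::complete.cases(df), ]
  p <- length(predictors)
  assert_that(nrow(df) >= 3 + p,
              "fit_transfer(): %d complete years < %d required", nrow(df), 3 + p)
  if (p == 2) {
    r12 <- stats::cor(df[[names(predictors)[1]]], df[[names(predictors)[2]]])
    assert_that(abs(r12) < 1 - 1e-12,
                "fit_transfer(): predictors perfectly collinear (VIF = infinity)")
    vif <- rep(1 / (1 - r12^2), 2)
  } else {
    vif <- 1
  }
  names(vif) <- names(predictors)
  fml <- stats::as.formula(paste("target ~", paste(names(predictors), collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  sm <- summary(fit)
  res <- stats::residuals(fit)
  structure(list(coefficients = stats::coef(fit),
                 predictors = names(predictors),
                 r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
                 rse = sm$sigma,
                 dw = durbin_watson(res),
                 vif = vif,
                 shapiro_p = tryCatch(stats::shapiro.test(res)$p.value,
                                      error = function(e) NA_real_),
                 n = nrow(df),
                 calibration_years = range(df$year),
                 data = df),
            class = "transfer_model")
}

#' @export
print.transfer_model <- function(x, ...) {
  eq <- paste(sprintf("%.3f", x$coefficients[1]),
              paste(sprintf("%+.3f*%s", x$coefficients[-1], x$predictors),
                    collapse = " "))
  cat(sprintf("Transfer model: target = %s\n", eq))
  cat(sprintf("  n = %d (%d-%d)  R2 = %.3f  adj R2 = %.3f  rse = %.3f  DW = %.2f\n",
              x$n, x$calibration_years[1], x$calibration_years[2],
              x$r2, x$adj_r2, x$rse, x$dw))
  cat(sprintf("  VIF: %s   Shapiro-Wilk p = %.3f\n",
              paste(sprintf("%s=%.3f", names(x$vif), x$vif), collapse = ", "),
              x$shapiro_p))
  invisible(x)
}

#' Durbin-Watson statistic of a residual series
#'
#' \eqn{\sum_t (e_t - e_{t-1})^2 / \sum_t e_t^2}; near 2 for white noise,
#' below 2 under positive autocorrelation.
#'
#' @param residuals numeric vector (time-ordered), length >= 3.
#' @return statistic in \[0, 4\]; `NA` with a warning for an all-zero series.
#' @export
durbin_watson <- function(residuals) {
  assert_that(length(residuals) >= 3, "durbin_watson(): at least 3 residuals required")
  denom <- sum(residuals^2)
  if (denom == 0) {
    warning("durbin_watson(): all residuals zero; statistic undefined")
    return(NA_real_)
  }
  sum(diff(residuals)^2) / denom
}

#' Reduction of error against the calibration-mean null
#'
#' RE = 1 - SSE(prediction) / SSE(null), the null predicting the calibration
#' mean every year.  Positive values indicate skill over climatology; RE <= 1
#' always.
#'
#' @param obs,pred observed and predicted values.
#' @param calibration_mean the null prediction (defaults to `mean(obs)`).
#' @export
reduction_of_error <- function(obs, pred, calibration_mean = mean(obs)) {
  sse <- sum((obs - pred)^2)
  ssn <- sum((obs - calibration_mean)^2)
  if (ssn == 0) return(if (sse == 0) 1 else -Inf)
  1 - sse / ssn
}

#' Leave-one-out cross-validation of a transfer model
#'
#' Each year is withheld in turn, the model refitted on the remaining years
#' and the withheld year predicted; the assembled predictions give RMSE, MAE,
#' cross-validated R2 (both the squared-correlation and the skill-score
#' definitions are reported) and the reduction of error against the all-years
#' calibration mean.
#'
#' @inheritParams fit_transfer
#' @return class `"validation_report"`: `rmse`, `mae`, `r2_cv` (squared
#'   Pearson correlation of predicted vs observed), `r2_sse` (1 - SSE/SST),
#'   `re`, `n`, `n_skipped`, `predicted` (data frame `year`, `obs`, `pred`).
#' @export
loocv <- function(target, predictors, calibration_span = NULL) {
  model <- fit_transfer(target, predictors, calibration_span)
  df <- model$data
  n <- nrow(df)
  assert_that(n >= 5, "loocv(): at least 5 calibration years required")
  X <- cbind(1, as.matrix(df[, model$predictors, drop = FALSE]))
  y <- df$target
  pred <- rep(NA_real_, n)
  skipped <- 0L
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    if (qr(Xi)$rank < ncol(Xi)) { skipped <- skipped + 1L; next }
    beta <- stats::lm.fit(Xi, y[-i])$coefficients
    pred[i] <- drop(X[i, ] %*% beta)
  }
  ok <- !is.na(pred)
  err <- y[ok] - pred[ok]
  structure(list(rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
                 r2_cv = suppressWarnings(stats::cor(y[ok], pred[ok]))^2,
                 r2_sse = 1 - sum(err^2) / sum((y[ok] - mean(y[ok]))^2),
                 re = reduction_of_error(y[ok], pred[ok], mean(y)),
                 n = n, n_skipped = skipped,
                 predicted = data.frame(year = df$year[ok], obs = y[ok], pred = pred[ok]),
                 re_null = "calibration-period mean (classical dendro RE)"),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("LOOCV: RMSE = %.3f  MAE = %.3f  R2cv = %.3f  RE = %.3f  (n = %d, %d fold(s) skipped)\n",
              x$rmse, x$mae, x$r2_cv, x$re, x$n, x$n_skipped))
  cat(sprintf("  RE null model: %s\n", x$re_null))
  invisible(x)
}
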