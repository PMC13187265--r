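## Applying transfer models over the full proxy period and low-pass smoothing.

#' Apply a transfer model over the full proxy period
#'
#' `value_t = intercept + sum(coef * proxy_t)` for every year with all
#' predictors present; the error band is the constant calibration residual
#' standard error (no time-varying prediction interval).
#'
#' @param model a `"transfer_model"` from [fit_transfer()].
#' @param proxies named list of full-period data frames `year`, `value`;
#'   names must match the model's predictors.
#' @param cutoff_years optional low-pass cutoff; when given, a `smoothed`
#'   column from [fft_lowpass()] is included.
#' @return class `"reconstruction"` data frame `year`, `value`, `lower`,
#'   `upper` (and `smoothed`).
#' @export
apply_transfer <- function(model, proxies, cutoff_years = NULL) {
  assert_that(inherits(model, "transfer_model"),
              "apply_transfer(): model must come from fit_transfer()")
  assert_that(setequal(names(proxies), model$predictors),
              "apply_transfer(): proxy names (%s) do not match model predictors (%s)",
              paste(names(proxies), collapse = ","), paste(model$predictors, collapse = ","))
  df <- NULL
  for (nm in model$predictors) {
    p <- proxies[[nm]]
    names(p)[2] <- nm
    df <- if (is.null(df)) p else join_years(df, p)
  }
  df <- df[stats::complete.cases(df), ]
  X <- cbind(1, as.matrix(df[, model$predictors, drop = FALSE]))
  val <- drop(X %*% model$coefficients)
  out <- data.frame(year = df$year, value = val,
                    lower = val - model$rse, upper = val + model$rse)
  if (!is.null(cutoff_years)) out$smoothed <- fft_lowpass(out$value, cutoff_years)
  attr(out, "band_halfwidth") <- model$rse
  class(out) <- c("reconstruction", "data.frame")
  out
}

#' FFT low-pass filter
#'
#' Removes variability at periods shorter than `cutoff_years`: the mean is
#' removed, the series is reflection-padded on both sides to limit wrap-around
#' leakage, Fourier coefficients above the cutoff frequency are zeroed with a
#' one-bin cosine taper, and the series mean is restored exactly.
#'
#' @param x numeric series (annual, no interior `NA`).
#' @param cutoff_years cutoff period in years (default 10).
#' @return smoothed series, same length; mean identical to `mean(x)`.
#' @export
fft_lowpass <- function(x, cutoff_years = 10) {
  n <- length(x)
  assert_that(n >= 2 * cutoff_years,
              "fft_lowpass(): series length %d < 2 * cutoff (%g)", n, 2 * cutoff_years)
  assert_that(!anyNA(x), "fft_lowpass(): missing interior values; gap-fill or omit upstream")
  mu <- mean(x)
  z <- x - mu
  pad <- c(rev(z), z, rev(z))
  N <- length(pad)
  f <- pmin(seq_len(N) - 1L, N - (seq_len(N) - 1L)) / N   # |frequency|, cycles/step
  fc <- 1 / cutoff_years
  bin <- 1 / N
  w <- ifelse(f <= fc, 1,
              ifelse(f <= fc + bin, 0.5 * (1 + cos(pi * (f - fc) / bin)), 0))
  sm <- Re(stats::fft(stats::fft(pad) * w, inverse = TRUE)) / N
  out <- sm[(n + 1):(2 * n)]
  out - mean(out) + mu
}
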