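## Chronology construction: growth-curve fitting, signal-free detrending,
## robust chronology averaging and the classical chronology quality statistics.

#' Tukey biweight robust mean
#'
#' Location estimate used when averaging detrended ring-width indices across
#' series into a chronology.  Observations are weighted by
#' \eqn{w(u) = (1-u^2)^2} for \eqn{|u|<1}, where \eqn{u} is the deviation from
#' the current center scaled by `c` times the median absolute deviation (MAD),
#' and the center is re-estimated until the relative change falls below `tol`.
#'
#' Falls back to the median when the MAD is zero (more than half the values
#' tied), and to the arithmetic mean for one or two values, where robust
#' weighting is undefined in any useful sense.
#'
#' @param x numeric vector; non-finite values are dropped.
#' @param c tuning constant on the MAD scale (default 9, the dendro standard).
#' @param tol relative convergence tolerance for the center.
#' @param max_iter iteration cap.
#' @return the biweight location estimate (length-1 numeric).
#' @examples
#' biweight_mean(c(1, 1, 1, 1, 100))  # ~1, the outlier is down-weighted
#' @export
biweight_mean <- function(x, c = 9, tol = 1e-6, max_iter = 100L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop_field("biweight_mean(): no finite values supplied")
  if (length(x) <= 2L) return(mean(x))
  m <- stats::median(x)
  s <- stats::median(abs(x - m))
  if (s == 0) return(m)
  for (i in seq_len(max_iter)) {
    u <- (x - m) / (c * s)
    w <- (1 - u^2)^2
    w[abs(u) >= 1] <- 0
    if (all(w == 0)) return(m)
    m_new <- sum(w * x) / sum(w)
    if (abs(m_new - m) <= tol * (abs(m) + tol)) return(m_new)
    m <- m_new
  }
  m
}

## ---- growth-curve fitters ---------------------------------------------------

## Modified negative exponential w = a*exp(-b*age) + k, the classical
## conservative fit for open-grown conifers.  Parameters are optimized on the
## log scale (guaranteeing a, b, k > 0 and a monotone non-increasing curve)
## with a deterministic Nelder-Mead search, so repeated fits inside the
## signal-free loop are smooth functions of the data; series the curve cannot
## describe fall back to a non-increasing straight line, then to the
## horizontal mean, mirroring standard practice.
## `state` carries the previous iteration's branch and parameters so repeated
## fits inside the signal-free loop warm-start smoothly and never jump
## between fitting families mid-iteration.
fit_negexp_state <- function(y, age, state = NULL) {
  n <- length(y)
  if (n < 5L) return(list(fitted = rep(mean(y), n), branch = "mean", par = NULL))
  branch <- state$branch %||% NA_character_
  if (identical(branch, "negexp") || is.na(branch)) {
    k0 <- max(0.9 * min(y), 1e-4)
    a0 <- max(mean(y[seq_len(max(3L, n %/% 10))]) - k0, 1e-4)
    start <- state$par %||% log(c(a0, 5 / n, k0))
    sse <- function(p) {
      f <- exp(p[1]) * exp(-exp(p[2]) * age) + exp(p[3])
      sum((y - f)^2)
    }
    opt <- tryCatch(
      stats::optim(start, sse, method = "Nelder-Mead",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(opt) && all(is.finite(opt$par))) {
      a <- exp(opt$par[1]); b <- exp(opt$par[2]); k <- exp(opt$par[3])
      ## polish to machine precision where Gauss-Newton converges cleanly
      pol <- tryCatch(
        stats::nls(y ~ a * exp(-b * age) + k,
                   start = list(a = a, b = b, k = k),
                   lower = c(a = 1e-10, b = 1e-10, k = 0),
                   algorithm = "port",
                   control = stats::nls.control(maxiter = 100)),
        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(pol)) {
        cf <- stats::coef(pol)
        if (all(is.finite(cf)) && cf[["b"]] > 0 && cf[["a"]] > 0) {
          a <- cf[["a"]]; b <- cf[["b"]]; k <- max(cf[["k"]], 1e-10)
        }
      }
      f <- a * exp(-b * age) + k
      ok <- all(f > 0) && b * n > 1e-3 &&
        sum((y - f)^2) < sum((y - mean(y))^2) * (1 - 1e-10)
      if (ok || identical(branch, "negexp")) {
        return(list(fitted = f, branch = "negexp", par = log(c(a, b, k))))
      }
    } else if (identical(branch, "negexp")) {
      ## keep the family: refuse to jump branches mid-iteration
      f <- exp(start[1]) * exp(-exp(start[2]) * age) + exp(start[3])
      return(list(fitted = f, branch = "negexp", par = start))
    }
  }
  if (identical(branch, "line") || is.na(branch)) {
    lf <- stats::lm.fit(cbind(1, age), y)
    if (lf$coefficients[2L] < 0) {
      f <- drop(cbind(1, age) %*% lf$coefficients)
      if (all(f > 0) || identical(branch, "line")) {
        return(list(fitted = pmax(f, 1e-6), branch = "line", par = NULL))
      }
    } else if (identical(branch, "line")) {
      return(list(fitted = rep(mean(y), n), branch = "line", par = NULL))
    }
  }
  list(fitted = rep(mean(y), n), branch = "mean", par = NULL)
}

## One-shot interface (first-iteration behavior).
fit_negexp <- function(y, age) fit_negexp_state(y, age)$fitted

## Discrete cubic smoothing spline (Whittaker form, second-difference penalty)
## with the smoothing weight chosen so the frequency response is 0.5 at
## wavelength `cutoff` years.  `cutoff` may vary along the series, giving the
## age-dependent spline: stiffness grows with cambial age.
whittaker_mu <- function(cutoff) {
  f <- 1 / pmax(cutoff, 2.01)
  1 / (16 * sin(pi * f)^4)
}

fit_spline_cutoff <- function(y, cutoff) {
  n <- length(y)
  if (n < 5L) return(rep(mean(y), n))
  mu <- whittaker_mu(if (length(cutoff) == 1L) rep(cutoff, n) else cutoff)
  ## interior second-difference operator rows i = 2..n-1
  D <- matrix(0, n - 2L, n)
  idx <- seq_len(n - 2L)
  D[cbind(idx, idx)] <- 1
  D[cbind(idx, idx + 1L)] <- -2
  D[cbind(idx, idx + 2L)] <- 1
  M <- diag(mu[idx + 1L], n - 2L)
  A <- diag(n) + crossprod(D, M %*% D)
  drop(solve(A, y))
}

fit_growth_curve <- function(y, age, method, stiffness, state = NULL) {
  switch(method,
    negexp = fit_negexp_state(y, age, state),
    ads    = list(fitted = pmax(fit_spline_cutoff(y, age + stiffness), 1e-6),
                  branch = "ads", par = NULL),
    spline = list(fitted = pmax(fit_spline_cutoff(y, max(ceiling(0.67 * length(y)), 10L)), 1e-6),
                  branch = "spline", par = NULL),
    stop_field("unknown growth-curve method '%s'", method))
}

## ---- signal-free detrending -------------------------------------------------

#' Signal-free detrending of ring-width series
#'
#' Iteratively removes the common (climate) signal from the measurements
#' before refitting per-series growth curves, which reduces the trend
#' distortion of conventional one-pass detrending:
#' \enumerate{
#'   \item fit a growth curve to each (signal-free) series,
#'   \item index = measured width / fitted curve,
#'   \item chronology = biweight robust mean of indices per year,
#'   \item signal-free measurements = measured width / chronology value,
#'   \item refit the growth curves to the signal-free measurements,
#' }
#' repeating (2)–(5) until the maximum absolute change of the chronology is
#' below `tol` or `max_iter` is reached.
#'
#' The product of growth curves and chronology is only weakly identified
#' when the growth-curve fitter is a flexible smoother: on multi-century
#' series the spline variants can drift slowly at low frequency instead of
#' contracting, so the iteration additionally stops (with `converged =
#' FALSE` and a warning) when the chronology change stalls.  The rigid
#' modified negative exponential is contractive and is therefore the
#' default.
#'
#' @param rwl data frame of ring widths (mm), rows = calendar years (as
#'   `rownames`), one column per measurement series, `NA` outside each
#'   series' span.  The layout written by [generate_proxies()] and
#'   [read_rwl()].
#' @param method growth-curve fitter: `"negexp"` (modified negative
#'   exponential with linear/mean fallback, the default), `"ads"`
#'   (age-dependent smoothing spline, 50% frequency cutoff at cambial age +
#'   `stiffness` years) or `"spline"` (fixed 67%-of-length cutoff).
#' @param stiffness base stiffness in years for the age-dependent spline.
#' @param max_iter,tol signal-free iteration controls.
#' @param min_depth years with fewer series than this are dropped from the
#'   chronology (depth-1 years are retained but flagged).
#' @return an object of class `"crn"`: a list with `crn` (data frame:
#'   `year`, `index`, `sample_depth`, `flag_depth1`), `series_indices`
#'   (year-by-series data frame of detrended indices), `converged`,
#'   `n_iter`, and `stats` (see [chronology_stats()], filled in when at
#'   least two series overlap).
#' @export
detrend_signal_free <- function(rwl, method = c("negexp", "ads", "spline"),
                                stiffness = 50, max_iter = 20L, tol = 1e-4,
                                min_depth = 1L) {
  method <- match.arg(method)
  assert_that(tol > 0, "detrend_signal_free(): tol must be > 0")
  assert_that(is.data.frame(rwl) && ncol(rwl) >= 1L,
              "detrend_signal_free(): at least one series required")
  years <- as.integer(rownames(rwl))
  W <- as.matrix(rwl)
  ## missing rings coded as width 0: treat as 0.001 mm for ratio indices
  zero_flag <- !is.na(W) & W == 0
  if (any(zero_flag)) {
    warning(sprintf("%d zero-width (missing) ring(s) set to 0.001 mm", sum(zero_flag)))
    W[zero_flag] <- 0.001
  }
  assert_that(all(W > 0, na.rm = TRUE),
              "detrend_signal_free(): negative ring widths found")
  depth <- rowSums(!is.na(W))
  if (ncol(W) > 1L && max(depth) < 2L) {
    stop_field("detrend_signal_free(): series never overlap; no common years anywhere")
  }

  span <- lapply(seq_len(ncol(W)), function(j) which(!is.na(W[, j])))
  ages <- lapply(span, function(s) seq_along(s))
  SF <- W
  chron <- rep(1, nrow(W))
  converged <- FALSE
  n_iter <- 0L
  idx_mat <- W
  prev_delta <- Inf
  stalled <- FALSE
  state <- vector("list", ncol(W))
  for (it in seq_len(max_iter)) {
    n_iter <- it
    for (j in seq_len(ncol(W))) {
      s <- span[[j]]
      fit <- fit_growth_curve(SF[s, j], ages[[j]], method, stiffness, state[[j]])
      state[[j]] <- fit[c("branch", "par")]
      idx_mat[s, j] <- W[s, j] / fit$fitted
    }
    new_chron <- apply(idx_mat, 1L, function(v) {
      v <- v[is.finite(v)]
      if (length(v)) biweight_mean(v) else NA_real_
    })
    ## rescale to the RWI ~ 1 baseline so the signal-free division cannot
    ## drift the overall level between iterations
    new_chron <- new_chron / mean(new_chron, na.rm = TRUE)
    delta <- max(abs(new_chron - chron), na.rm = TRUE)
    chron <- new_chron
    ## divide the common signal back out of the measurements
    for (j in seq_len(ncol(W))) {
      s <- span[[j]]
      SF[s, j] <- W[s, j] / pmax(chron[s], 0.05)
    }
    if (delta < tol) { converged <- TRUE; break }
    ## drift guard: a change that stops shrinking while still well above the
    ## tolerance signals the weakly identified low-frequency mode
    if (it > 2L && delta >= prev_delta && delta > 10 * tol) { stalled <- TRUE; break }
    prev_delta <- delta
  }
  if (!converged) {
    warning(if (stalled)
      sprintf("signal-free iteration stalled after %d iterations (change %.2g)", n_iter, prev_delta)
    else
      sprintf("signal-free iteration did not converge in %d iterations", max_iter))
  }

  keep <- depth >= max(1L, min_depth)
  crn <- data.frame(year = years[keep],
                    index = chron[keep],
                    sample_depth = depth[keep],
                    flag_depth1 = depth[keep] == 1L)
  series_indices <- as.data.frame(idx_mat)
  rownames(series_indices) <- rownames(rwl)
  st <- tryCatch(chronology_stats(series_indices), error = function(e) NULL)
  structure(list(crn = crn, series_indices = series_indices,
                 converged = converged, n_iter = n_iter,
                 final_delta = delta,
                 method = method, stats = st),
            class = "crn")
}

#' @export
print.crn <- function(x, ...) {
  cat(sprintf("Tree-ring chronology: %d years (%d-%d), %d series, method '%s'%s\n",
              nrow(x$crn), min(x$crn$year), max(x$crn$year),
              ncol(x$series_indices), x$method,
              if (x$converged) "" else " [NOT converged]"))
  if (!is.null(x$stats)) print(x$stats)
  invisible(x)
}

## ---- chronology quality statistics ------------------------------------------

#' Chronology signal-strength statistics
#'
#' Computes the classical chronology quality statistics from a year-by-series
#' table of detrended indices:
#' \describe{
#'   \item{rbar}{mean pairwise Pearson correlation over common years,}
#'   \item{eps}{expressed population signal \eqn{n\bar r/(1+(n-1)\bar r)},}
#'   \item{snr}{signal-to-noise ratio \eqn{n\bar r/(1-\bar r)},}
#'   \item{sss}{per-year subsample signal strength
#'     \eqn{n'(1+(n-1)\bar r)/(n(1+(n'-1)\bar r))} with \eqn{n'} the actual
#'     sample depth of the year,}
#'   \item{ac1}{lag-1 autocorrelation of the (biweight) chronology.}
#' }
#' `n` is the time-averaged sample depth over the analysis window, because a
#' single whole-period value is reported.
#'
#' @param indices data frame, rows = years (rownames), columns = series.
#' @param window optional integer vector of years restricting the analysis.
#' @param min_overlap minimum pairwise overlap (years) for a pair to enter rbar.
#' @return object of class `"chronology_stats"`; fields `rbar`, `eps`, `snr`,
#'   `ac1`, `n_eff`, `sss` (data frame `year`, `depth`, `sss`).  Fields are
#'   `NA` (not zero) when fewer than two series overlap.
#' @export
chronology_stats <- function(indices, window = NULL, min_overlap = 10L) {
  M <- as.matrix(indices)
  years <- as.integer(rownames(indices))
  if (!is.null(window)) {
    keep <- years %in% window
    M <- M[keep, , drop = FALSE]
    years <- years[keep]
  }
  depth <- rowSums(!is.na(M))
  in_span <- depth >= 1L
  M <- M[in_span, , drop = FALSE]
  years <- years[in_span]
  depth <- depth[in_span]

  ns <- ncol(M)
  cors <- c()
  if (ns >= 2L) {
    for (i in seq_len(ns - 1L)) {
      for (j in seq(i + 1L, ns)) {
        ok <- stats::complete.cases(M[, i], M[, j])
        if (sum(ok) >= min_overlap) {
          r <- suppressWarnings(stats::cor(M[ok, i], M[ok, j]))
          if (is.finite(r)) cors <- c(cors, r)
        }
      }
    }
  }
  if (!length(cors)) {
    warning("chronology_stats(): fewer than 2 sufficiently overlapping series; statistics undefined")
    rbar <- eps <- snr <- NA_real_
    n_eff <- mean(depth)
    sss <- data.frame(year = years, depth = depth, sss = NA_real_)
  } else {
    rbar <- mean(cors)
    n_eff <- mean(depth)
    eps <- eps_stat(rbar, n_eff)
    snr <- snr_stat(rbar, n_eff)
    sss <- data.frame(year = years, depth = depth,
                      sss = sss_stat(rbar, n_eff, depth))
  }
  chron <- apply(M, 1L, function(v) {
    v <- v[is.finite(v)]
    if (length(v)) biweight_mean(v) else NA_real_
  })
  ac1 <- if (sum(is.finite(chron)) >= 3L) {
    stats::cor(chron[-1L], chron[-length(chron)], use = "complete.obs")
  } else NA_real_
  structure(list(rbar = rbar, eps = eps, snr = snr, ac1 = ac1,
                 n_eff = n_eff, n_pairs = length(cors), sss = sss),
            class = "chronology_stats")
}

#' Expressed population signal from rbar and replication
#' @param rbar mean inter-series correlation.
#' @param n (effective) number of series.
#' @export
eps_stat <- function(rbar, n) n * rbar / (1 + (n - 1) * rbar)

#' Signal-to-noise ratio from rbar and replication
#' @inheritParams eps_stat
#' @export
snr_stat <- function(rbar, n) n * rbar / (1 - rbar)

#' Subsample signal strength for reduced replication n'
#' @inheritParams eps_stat
#' @param n_sub reduced replication (may be a vector).
#' @export
sss_stat <- function(rbar, n, n_sub) {
  n_sub * (1 + (n - 1) * rbar) / (n * (1 + (n_sub - 1) * rbar))
}

#' @export
print.chronology_stats <- function(x, ...) {
  cat(sprintf("  rbar = %.3f  EPS = %.3f  SNR = %.3f  AC1 = %.3f  (n_eff = %.1f, %d pairs)\n",
              x$rbar, x$eps, x$snr, x$ac1, x$n_eff, x$n_pairs))
  invisible(x)
}

#' Gleichlaeufigkeit (sign-agreement) between two series
#'
#' Fraction of overlapping first-difference pairs whose signs agree; a pair in
#' which exactly one difference is zero counts one half.  The classical
#' cross-dating agreement statistic.
#'
#' @param a,b numeric vectors on the same year axis (`NA` where absent).
#' @return fraction in \[0, 1\].
#' @export
glk <- function(a, b) {
  assert_that(length(a) == length(b), "glk(): series must share a year axis")
  ok <- is.finite(a) & is.finite(b)
  run <- which(ok)
  da <- diff(a[run])
  db <- diff(b[run])
  keep <- diff(run) == 1L   # only differences between consecutive years
  da <- da[keep]; db <- db[keep]
  assert_that(length(da) >= 1L, "glk(): overlap of at least 2 years required")
  sa <- sign(da); sb <- sign(db)
  score <- ifelse(sa == sb, 1, ifelse(sa == -sb & sa != 0, 0, 0.5))
  mean(score)
}
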