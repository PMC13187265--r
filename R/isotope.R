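## Elevation normalization of tree-ring d18O and the mean isotope chronology.

#' Fit the d18O-elevation lapse model
#'
#' Ordinary least squares of each tree's period-mean d18O on its sampling
#' elevation.  The slope is the isotopic lapse rate used to normalize all
#' trees to a common reference elevation.
#'
#' @param iso long data frame `tree_id`, `elevation_m`, `year`, `d18o_permil`.
#' @param window optional year range (length-2) restricting the period means.
#' @param elevation_limits plausible elevation range; values outside reject
#'   the input.
#' @return class `"elevation_model"`: `beta0` (permil), `beta1` (permil/m),
#'   `slope_per_100m`, `r`, `r2`, `p_value`, `n_trees`, `tree_means`.
#' @export
fit_elevation_model <- function(iso, window = NULL,
                                elevation_limits = c(500, 5000)) {
  need <- c("tree_id", "elevation_m", "year", "d18o_permil")
  assert_that(all(need %in% names(iso)),
              "fit_elevation_model(): columns %s required", paste(need, collapse = ", "))
  assert_that(all(is.finite(iso$d18o_permil)), "fit_elevation_model(): non-finite d18o values")
  assert_that(all(iso$elevation_m >= elevation_limits[1] & iso$elevation_m <= elevation_limits[2]),
              "fit_elevation_model(): elevations outside plausible range %g-%g m",
              elevation_limits[1], elevation_limits[2])
  if (!is.null(window)) {
    iso <- iso[iso$year >= window[1] & iso$year <= window[2], ]
  }
  tm <- stats::aggregate(d18o_permil ~ tree_id + elevation_m, data = iso, FUN = mean)
  assert_that(nrow(tm) >= 3, "fit_elevation_model(): at least 3 trees required")
  assert_that(length(unique(tm$elevation_m)) >= 2,
              "fit_elevation_model(): all elevations equal; no gradient identifiable")
  if (length(unique(tm$elevation_m)) == 2) {
    warning("fit_elevation_model(): only two distinct elevations; high-leverage design")
  }
  fit <- stats::lm(d18o_permil ~ elevation_m, data = tm)
  sm <- summary(fit)
  beta <- stats::coef(fit)
  r2 <- sm$r.squared
  r <- sign(beta[[2]]) * sqrt(r2)
  p <- if (nrow(tm) > 2) sm$coefficients[2, 4] else NA_real_
  structure(list(beta0 = beta[[1]], beta1 = beta[[2]],
                 slope_per_100m = beta[[2]] * 100,
                 r = r, r2 = r2, p_value = p, n_trees = nrow(tm),
                 tree_means = tm),
            class = "elevation_model")
}

#' @export
print.elevation_model <- function(x, ...) {
  cat(sprintf("d18O-elevation model: %.3f permil/100 m (r = %.2f, R2 = %.3f, p = %.3g, n = %d trees)\n",
              x$slope_per_100m, x$r, x$r2, x$p_value, x$n_trees))
  invisible(x)
}

#' Normalize d18O series to a reference elevation
#'
#' Adds `beta1 * (reference - elevation)` to every value of each tree, a
#' constant per-tree shift that leaves all interannual anomalies (and hence
#' every temporal correlation) untouched.
#'
#' @param iso long isotope data frame (see [fit_elevation_model()]).
#' @param model fitted `"elevation_model"`.
#' @param reference_m reference elevation in m (default 2000).
#' @return the input data frame with corrected `d18o_permil` (and the shift
#'   recorded in column `elev_correction`).
#' @export
correct_to_reference <- function(iso, model, reference_m = 2000) {
  assert_that(inherits(model, "elevation_model"),
              "correct_to_reference(): model must come from fit_elevation_model()")
  shift <- model$beta1 * (reference_m - iso$elevation_m)
  iso$d18o_permil <- iso$d18o_permil + shift
  iso$elev_correction <- shift
  iso
}

#' Mean isotope chronology with confidence band
#'
#' Annual arithmetic mean of the (corrected) tree series; years below the
#' minimum replication are excluded (never interpolated).  The band is
#' mean +/- t(0.975, n-1) * SE.  Arithmetic rather than biweight averaging is
#' used because isotope replication (~5-8 trees) is too low for robust
#' weighting; switchable via `average`.
#'
#' @param iso long isotope data frame.
#' @param min_replication minimum trees per year (default 5).
#' @param conf confidence level for the band.
#' @param average `"mean"` or `"biweight"`.
#' @return class `"iso_crn"`: data frame `year`, `d18o`, `lower`, `upper`,
#'   `n_trees` plus attribute `stats` ([chronology_stats()] across trees).
#' @export
build_isotope_chronology <- function(iso, min_replication = 5L, conf = 0.95,
                                     average = c("mean", "biweight")) {
  average <- match.arg(average)
  wide <- stats::reshape(iso[, c("tree_id", "year", "d18o_permil")],
                         idvar = "year", timevar = "tree_id", direction = "wide")
  wide <- wide[order(wide$year), ]
  M <- as.matrix(wide[, -1, drop = FALSE])
  rownames(M) <- wide$year
  depth <- rowSums(!is.na(M))
  keep <- depth >= min_replication
  if (any(!keep)) {
    message(sprintf("build_isotope_chronology(): excluded %d year(s) below replication %d",
                    sum(!keep), min_replication))
  }
  M2 <- M[keep, , drop = FALSE]
  depth2 <- depth[keep]
  avg <- if (average == "mean") rowMeans(M2, na.rm = TRUE) else
    apply(M2, 1L, biweight_mean)
  se <- apply(M2, 1L, function(v) stats::sd(v, na.rm = TRUE)) / sqrt(depth2)
  tq <- stats::qt(1 - (1 - conf) / 2, depth2 - 1L)
  out <- data.frame(year = as.integer(rownames(M2)), d18o = avg,
                    lower = avg - tq * se, upper = avg + tq * se,
                    n_trees = depth2)
  rownames(out) <- NULL
  st <- tryCatch(chronology_stats(as.data.frame(M2)), error = function(e) NULL)
  structure(out, stats = st, class = c("iso_crn", "data.frame"))
}
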