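## Climate indices: vapor pressure deficit, seasonal window aggregates, and a
## standardized multi-month moisture index (climatic water balance with
## Thornthwaite PET, normal-score standardized).

#' Monthly vapor pressure deficit
#'
#' VPD = es(T) * (1 - RH/100), with saturation vapor pressure from the Magnus
#' form es(T) = 0.6108 * exp(17.27 T / (T + 237.3)) kPa (FAO-56-compatible
#' constants, configurable).
#'
#' @param t_c air temperature in deg C (use the monthly maximum for the
#'   atmospheric-demand reading; monthly mean is a configurable alternative).
#' @param rh_pct relative humidity in percent, in (0, 100].
#' @param magnus named numeric vector `c(a=, b=, c=)` of Magnus constants.
#' @return VPD in kPa (vectorized, >= 0).
#' @examples
#' vpd_monthly(25, 50)   # ~1.584 kPa
#' @export
vpd_monthly <- function(t_c, rh_pct, magnus = c(a = 0.6108, b = 17.27, c = 237.3)) {
  assert_that(all(is.finite(t_c)) && all(is.finite(rh_pct)),
              "vpd_monthly(): non-finite inputs")
  assert_that(all(rh_pct > 0 & rh_pct <= 100),
              "vpd_monthly(): rh_pct must lie in (0, 100]")
  assert_that(all(t_c > -magnus[["c"]]),
              "vpd_monthly(): temperature at or below the Magnus pole (%g degC)",
              -magnus[["c"]])
  es <- magnus[["a"]] * exp(magnus[["b"]] * t_c / (t_c + magnus[["c"]]))
  es * (1 - rh_pct / 100)
}

## Add a vpd column to a monthly climate table.
climate_vpd <- function(climate, temperature = c("tmax", "tmean"),
                        magnus = c(a = 0.6108, b = 17.27, c = 237.3)) {
  temperature <- match.arg(temperature)
  tcol <- if (temperature == "tmax") climate$tmax_c else climate$tmean_c
  climate$vpd_kpa <- vpd_monthly(tcol, climate$rh_pct, magnus)
  climate
}

#' Seasonal aggregate of a monthly series
#'
#' One value per calendar year: the mean (or sum) of `var` over months
#' `start_month..end_month`.  Years missing any month of the window are
#' dropped (and reported), never silently filled.
#'
#' @param climate monthly climate table (`year`, `month`, plus `var`).
#' @param var column to aggregate.
#' @param start_month,end_month window within one calendar year
#'   (`start_month <= end_month`).
#' @param statistic `"mean"` or `"sum"`.
#' @return data frame `year`, `value`, with attribute `label` describing the
#'   window; class `"seasonal_series"`.
#' @export
seasonal_mean <- function(climate, var, start_month, end_month,
                          statistic = c("mean", "sum")) {
  statistic <- match.arg(statistic)
  assert_that(start_month %in% 1:12 && end_month %in% 1:12 && start_month <= end_month,
              "seasonal_mean(): invalid month window %s..%s", start_month, end_month)
  assert_that(var %in% names(climate), "seasonal_mean(): no column '%s'", var)
  months <- start_month:end_month
  sub <- climate[climate$month %in% months, c("year", "month", var)]
  counts <- table(sub$year)
  complete <- as.integer(names(counts)[counts == length(months)])
  dropped <- setdiff(unique(sub$year), complete)
  if (length(dropped)) {
    message(sprintf("seasonal_mean(): dropped %d year(s) with incomplete windows", length(dropped)))
  }
  sub <- sub[sub$year %in% complete, ]
  agg <- stats::aggregate(sub[[var]], by = list(year = sub$year),
                          FUN = if (statistic == "mean") mean else sum)
  out <- data.frame(year = agg$year, value = agg$x)
  out <- out[order(out$year), ]
  rownames(out) <- NULL
  attr(out, "label") <- sprintf("%s(%s, months %d-%d)", statistic, var,
                                start_month, end_month)
  class(out) <- c("seasonal_series", "data.frame")
  out
}

#' Thornthwaite monthly potential evapotranspiration
#'
#' Classical temperature-based PET with the latitude/daylength correction:
#' zero whenever the monthly mean temperature is at or below 0 deg C.
#'
#' @param tmean_c monthly mean temperatures, one value per row of the climate
#'   table (deg C).
#' @param month month numbers 1..12 aligned with `tmean_c`.
#' @param year years aligned with `tmean_c` (heat index is computed per year).
#' @param lat_deg site latitude in decimal degrees (default 37 N).
#' @return PET in mm/month.
#' @export
thornthwaite_pet <- function(tmean_c, month, year, lat_deg = 37) {
  tpos <- pmax(tmean_c, 0)
  ## annual heat index per year
  hi <- tapply((tpos / 5)^1.514, year, sum)
  I <- hi[as.character(year)]
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  pet <- ifelse(I > 0, 16 * (10 * tpos / pmax(I, 1e-9))^a, 0)
  ## daylength correction: mean daylength of month / 12 * days / 30
  dl <- daylength_hours(month, lat_deg)
  days <- c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[month]
  pet <- pet * (dl / 12) * (days / 30)
  unname(ifelse(tmean_c <= 0, 0, pet))
}

## Mean daylength (hours) at mid-month from standard solar declination.
daylength_hours <- function(month, lat_deg) {
  jday <- c(15, 45, 74, 105, 135, 166, 196, 227, 258, 288, 319, 349)[month]
  decl <- 0.409 * sin(2 * pi * jday / 365 - 1.39)
  phi <- lat_deg * pi / 180
  x <- pmin(pmax(-tan(phi) * tan(decl), -1), 1)
  ws <- acos(x)
  24 / pi * ws
}

#' Standardized multi-month moisture index
#'
#' A standardized index with the structure of the SPEI family: the monthly
#' climatic water balance D = P - PET (Thornthwaite PET) is accumulated over
#' `accumulation_k` months ending in `target_month`, and the resulting annual
#' series is standardized by an empirical normal-score transform (ties broken
#' by average rank), rescaled to mean 0 / SD 1 over the reference years.
#' A constant accumulation series is defined as all-zero by convention.
#'
#' @param climate monthly climate table (`year`, `month`, `tmean_c`,
#'   `precip_mm`, contiguous).
#' @param accumulation_k accumulation period in months (1..7 in this pipeline).
#' @param target_month calendar month the accumulation ends in.
#' @param lat_deg latitude for the PET daylength correction.
#' @param ref_years optional reference years for the standardization
#'   (default: all years with a defined accumulation).
#' @return class `"seasonal_series"` data frame `year`, `value`; years whose
#'   accumulation window reaches before the record start are dropped.
#' @export
standardized_moisture_index <- function(climate, accumulation_k, target_month,
                                        lat_deg = 37, ref_years = NULL) {
  assert_that(accumulation_k >= 1 && accumulation_k == round(accumulation_k),
              "standardized_moisture_index(): accumulation_k must be a positive integer")
  assert_that(target_month %in% 1:12,
              "standardized_moisture_index(): target_month must be 1..12")
  climate <- climate[order(climate$year, climate$month), ]
  assert_that(length(unique(climate$year)) >= 20,
              "standardized_moisture_index(): at least 20 years required for standardization")
  pet <- thornthwaite_pet(climate$tmean_c, climate$month, climate$year, lat_deg)
  D <- climate$precip_mm - pet
  ## windowed sums (not cumsum differences): identical windows must give
  ## bit-identical sums so that a constant water balance stays exactly tied
  acc <- as.numeric(stats::filter(D, rep(1, accumulation_k), sides = 1))
  sel <- climate$month == target_month & !is.na(acc)
  years <- climate$year[sel]
  vals <- acc[sel]
  if (is.null(ref_years)) ref_years <- years
  ## empirical normal-score transform over all years jointly
  if (length(unique(vals)) <= 1L) {
    z <- rep(0, length(vals))
  } else {
    r <- rank(vals, ties.method = "average")
    q <- stats::qnorm((r - 0.5) / length(vals))
    in_ref <- years %in% ref_years
    assert_that(sum(in_ref) >= 2L,
                "standardized_moisture_index(): reference period too short")
    mu <- mean(q[in_ref]); sdv <- stats::sd(q[in_ref])
    z <- if (sdv > 0) (q - mu) / sdv else rep(0, length(q))
  }
  out <- data.frame(year = years, value = z)
  rownames(out) <- NULL
  attr(out, "label") <- sprintf("smi(k=%d, month=%d)", accumulation_k, target_month)
  class(out) <- c("seasonal_series", "data.frame")
  out
}
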