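## Synthetic-data generator: monthly climate and multi-tree proxy series with
## known transfer functions, elevation gradient and noise levels, exposing
## ground truth for parameter-recovery tests.

## Monthly climatology of the semi-arid mountain site the generator emulates:
## continental seasonality, winter/spring precipitation maximum (March), a
## nearly rain-free August, ~213 mm/yr and a 16.9 degC annual mean.
site_climatology <- function() {
  data.frame(
    month  = 1:12,
    tmean  = c(3.8, 6.2, 10.6, 16.2, 21.8, 26.4, 28.3, 28.4, 24.8, 18.2, 11.6, 6.9),
    tmax   = c(3.8, 6.2, 10.6, 16.2, 21.8, 26.4, 28.3, 28.4, 24.8, 18.2, 11.6, 6.9) + 7.5,
    rh     = c(68, 65, 60, 52, 42, 30, 24, 22, 26, 42, 56, 66),
    precip = c(24, 32, 48.7, 40, 26, 6, 1.5, 0.19, 1.6, 7, 12, 14))
}

#' Configuration for the synthetic dual-proxy dataset
#'
#' Defaults encode the study conditions the pipeline is designed around:
#' 47 trees between 2000 and 2656 m a.s.l., 200-year records (1821--2020)
#' with a 37-year calibration window (1984--2020), a -0.339 permil/100 m
#' oxygen-isotope lapse, the printed transfer functions
#' VPD = -4.643 + 0.218 d18O (residual SD 0.22 kPa) and
#' SMI = 14.371 - 0.491 d18O + 2.537 RWI (residual SD 0.78), a 0.56 permil
#' between-tree isotope spread, and a modified negative-exponential juvenile
#' growth trend.
#'
#' @param ... overrides for any default field (see Details in the methods
#'   vignette).  All noise SDs must be >= 0; `n_trees >= 2`; the elevation
#'   range and spans must be non-empty.
#' @return validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(...) {
  cfg <- list(
    n_trees = 47L,
    cores_per_tree = 2L,
    n_iso_trees = NULL,              # NULL = isotopes measured on every tree
    elevation_range = c(2000, 2656), # m a.s.l.
    reference_elevation = 2000,      # m
    span = c(1821L, 2020L),
    calibration_span = c(1984L, 2020L),
    elevation_slope = -0.00339,      # permil per m
    vpd_transfer = c(intercept = -4.643, slope = 0.218),          # kPa per permil
    spei_transfer = c(intercept = 14.371, iso = -0.491, rwi = 2.537),
    vpd_months = c(3L, 9L),          # March-September seasonal window
    smi_k = 7L, smi_month = 9L,      # 7-month accumulation ending September
    noise_sd_iso = 1.6,              # permil, per tree and year
    noise_sd_tree = 0.56,            # permil, between-tree offset
    noise_sd_vpd = 0.22,             # kPa, transfer residual
    noise_sd_spei = 0.78,            # dimensionless, transfer residual
    noise_sd_rwi = 0.6,              # per core and year, ring-index units
    growth_curve = c(amplitude = 0.8, decay = 0.02, asymptote = 0.25),  # mm
    stand_age_spread = 150,          # yr: germination dates extend this far
                                     # before the span (multi-century stand)
    climate_noise = c(temp = 1.2, rh = 4, logprecip = 0.4),
    wet_coupling = c(rh = 6, logprecip = 0.35, ar1 = 0.3),
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  assert_that(length(unknown) == 0L,
              "synthetic_config(): unknown field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  assert_that(is_count(cfg$n_trees) && cfg$n_trees >= 2, "n_trees must be a count >= 2")
  assert_that(is_count(cfg$cores_per_tree) && cfg$cores_per_tree >= 1,
              "cores_per_tree must be a count >= 1")
  assert_that(cfg$span[1] <= cfg$span[2], "span is empty (first year > last year)")
  assert_that(cfg$calibration_span[1] <= cfg$calibration_span[2],
              "calibration_span is empty (first year > last year)")
  assert_that(cfg$elevation_range[1] < cfg$elevation_range[2],
              "elevation_range low must be < high")
  for (f in c("noise_sd_iso", "noise_sd_tree", "noise_sd_vpd", "noise_sd_spei",
              "noise_sd_rwi")) {
    assert_that(cfg[[f]] >= 0, "%s must be >= 0", f)
  }
  assert_that(all(cfg$climate_noise >= 0), "climate_noise SDs must be >= 0")
  assert_that(cfg$stand_age_spread >= 0, "stand_age_spread must be >= 0")
  assert_that(is.numeric(cfg$seed) && length(cfg$seed) == 1L, "seed must be one integer")
  invisible(cfg)
}

#' A fully deterministic variant of a synthetic configuration
#'
#' Sets every noise SD to zero while keeping the latent interannual wet-year
#' factor (the climate signal itself), so downstream transfer-function
#' round-trips are exact.
#' @param cfg a [synthetic_config()].
#' @export
zero_noise_config <- function(cfg = synthetic_config()) {
  cfg$noise_sd_iso <- cfg$noise_sd_tree <- cfg$noise_sd_vpd <- 0
  cfg$noise_sd_spei <- cfg$noise_sd_rwi <- 0
  cfg$climate_noise[] <- 0
  validate_synthetic_config(cfg)
  cfg
}

#' Generate a monthly climate table
#'
#' Sinusoidal-seasonality-free construction: each month draws around a fixed
#' site climatology (so long-run monthly means match it), with a latent AR(1)
#' wet-year factor that raises relative humidity and precipitation together in
#' wet years -- the source of the negative VPD/moisture-index dependence the
#' analysis expects.  Precipitation noise is lognormal and mean-corrected.
#'
#' @param config a [synthetic_config()].
#' @return monthly data frame `year`, `month`, `tmax_c`, `tmean_c`, `rh_pct`,
#'   `precip_mm` over the configured span; the latent wet-year factor is
#'   attached as attribute `"wet_factor"`.
#' @export
generate_climate <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config") || is.list(config))
  assert_that(config$span[1] <= config$span[2], "span is empty (first year > last year)")
  years <- seq.int(config$span[1], config$span[2])
  n <- length(years)
  clim <- site_climatology()
  set.seed(config$seed)
  phi <- config$wet_coupling[["ar1"]]
  u <- numeric(n)
  u[1] <- stats::rnorm(1)
  if (n > 1) {
    innov <- stats::rnorm(n - 1, sd = sqrt(1 - phi^2))
    for (t in 2:n) u[t] <- phi * u[t - 1] + innov[t - 1]
  }
  sd_t <- config$climate_noise[["temp"]]
  sd_rh <- config$climate_noise[["rh"]]
  sd_lp <- config$climate_noise[["logprecip"]]
  lam_rh <- config$wet_coupling[["rh"]]
  lam_p <- config$wet_coupling[["logprecip"]]

  grid <- expand.grid(month = 1:12, year = years)[, c("year", "month")]
  m <- grid$month
  uy <- u[match(grid$year, years)]
  tmean <- clim$tmean[m] + stats::rnorm(nrow(grid), sd = sd_t)
  tmax <- tmean + (clim$tmax[m] - clim$tmean[m])
  rh <- clim$rh[m] + lam_rh * uy + stats::rnorm(nrow(grid), sd = sd_rh)
  rh <- pmin(pmax(rh, 2), 100)
  lp <- lam_p * uy - lam_p^2 / 2 +
    stats::rnorm(nrow(grid), sd = sd_lp) - sd_lp^2 / 2
  precip <- clim$precip[m] * exp(lp)
  out <- data.frame(year = grid$year, month = m, tmax_c = tmax, tmean_c = tmean,
                    rh_pct = rh, precip_mm = precip)
  attr(out, "wet_factor") <- data.frame(year = years, u = u)
  out
}

#' Generate multi-tree proxy series with known ground truth
#'
#' The latent annual drivers are taken from the supplied climate table with
#' the same operators the analysis pipeline uses: latent VPD is the seasonal
#' (default March--September) table VPD and the latent moisture index is the
#' standardized k-month water-balance index.  Tree-ring d18O follows the
#' inverse atmospheric transfer d18O = (VPD - a)/b plus the elevation term
#' beta1 (elev - reference), a between-tree offset and measurement noise; the
#' latent ring-width index follows the inverse soil-moisture transfer given
#' the moisture index and d18O (rescaled to a mean-1 RWI baseline, scale kept
#' in the truth object), and raw widths are the modified negative-exponential
#' growth curve times per-core noisy indices.  Germination years are staggered
#' uniformly over the first 20% of the span so sample depth varies.
#'
#' @param config a [synthetic_config()].
#' @param climate a monthly climate table spanning the configured years
#'   (typically from [generate_climate()]).
#' @return list with `rwl` (year-by-core ring widths, mm, 0.001 precision),
#'   `iso` (long data frame `tree_id`, `elevation_m`, `year`, `d18o_permil`),
#'   and `truth` (class `"synthetic_truth"`: latent VPD, moisture index,
#'   latent d18O and RWI series, elevations, offsets, germination years,
#'   the RWI scale factor and the generating config).
#' @export
generate_proxies <- function(config = synthetic_config(), climate = generate_climate(config)) {
  a <- config$vpd_transfer[["intercept"]]
  b <- config$vpd_transfer[["slope"]]
  assert_that(b != 0, "generate_proxies(): vpd_transfer slope must be non-zero (non-invertible)")
  c0 <- config$spei_transfer[["intercept"]]
  c1 <- config$spei_transfer[["iso"]]
  c2 <- config$spei_transfer[["rwi"]]
  assert_that(c2 != 0, "generate_proxies(): spei_transfer rwi coefficient must be non-zero")

  years <- seq.int(config$span[1], config$span[2])
  assert_that(all(years %in% climate$year),
              "generate_proxies(): climate table does not span the configured years")

  vpd <- seasonal_mean(climate_vpd(climate), "vpd_kpa",
                       config$vpd_months[1], config$vpd_months[2])
  smi <- standardized_moisture_index(climate, config$smi_k, config$smi_month)
  assert_that(all(years %in% vpd$year) && all(years %in% smi$year),
              "generate_proxies(): latent drivers incomplete over the span")
  vpd_t <- vpd$value[match(years, vpd$year)]
  smi_t <- smi$value[match(years, smi$year)]
  n <- length(years)

  set.seed(config$seed + 1L)
  eps_vpd <- stats::rnorm(n, sd = config$noise_sd_vpd)
  eps_spei <- stats::rnorm(n, sd = config$noise_sd_spei)
  ## the transfer residual makes d18O an imperfect recorder of seasonal VPD;
  ## calibrating proxy against climate on such data shows the classical
  ## (real-world) regression attenuation, vanishing at zero noise
  delta_lat <- (vpd_t - a - eps_vpd) / b
  q <- (smi_t + eps_spei - c0 - c1 * delta_lat) / c2
  rwi_scale <- mean(q)
  assert_that(rwi_scale > 0,
              "generate_proxies(): latent ring index non-positive on average; check transfer settings")
  rwi_lat <- q / rwi_scale

  nt <- config$n_trees
  elev <- stats::runif(nt, config$elevation_range[1], config$elevation_range[2])
  offs <- stats::rnorm(nt, sd = config$noise_sd_tree)
  ## germination dates span a multi-century stand: most trees predate the
  ## analysis window (their juvenile decay lies before it), a minority
  ## germinate inside its first 20% so sample depth still varies.  A pure
  ## within-window cohort would confound cambial age with calendar year and
  ## make the growth-curve/chronology decomposition unidentifiable.
  stagger <- max(1L, floor(0.2 * n))
  first_years <- sample(seq.int(config$span[1] - round(config$stand_age_spread),
                                config$span[1] + stagger - 1L),
                        nt, replace = TRUE)

  gc <- config$growth_curve
  n_iso <- config$n_iso_trees %||% nt
  assert_that(n_iso >= 2 && n_iso <= nt, "n_iso_trees must be in 2..n_trees")

  rwl <- matrix(NA_real_, n, nt * config$cores_per_tree)
  cn <- character(ncol(rwl))
  iso_list <- vector("list", n_iso)
  col <- 0L
  for (i in seq_len(nt)) {
    rows <- which(years >= first_years[i])
    age <- years[rows] - first_years[i] + 1L   # cambial age from germination
    curve <- gc[["amplitude"]] * exp(-gc[["decay"]] * age) + gc[["asymptote"]]
    for (cc in seq_len(config$cores_per_tree)) {
      col <- col + 1L
      r_core <- pmax(rwi_lat[rows] + stats::rnorm(length(rows), sd = config$noise_sd_rwi),
                     0.05)
      rwl[rows, col] <- pmax(round(curve * r_core, 3), 0.001)
      cn[col] <- sprintf("T%02d%s", i, LETTERS[cc])
    }
    if (i <= n_iso) {
      ## isotope series cover the whole span: the sampling protocol demands
      ## full-period replication, so isotope trees are the full-length ones
      d18o <- delta_lat +
        config$elevation_slope * (elev[i] - config$reference_elevation) +
        offs[i] + stats::rnorm(n, sd = config$noise_sd_iso)
      iso_list[[i]] <- data.frame(tree_id = sprintf("T%02d", i),
                                  elevation_m = elev[i],
                                  year = years,
                                  d18o_permil = d18o)
    }
  }
  rwl <- as.data.frame(rwl)
  names(rwl) <- cn
  rownames(rwl) <- years

  truth <- structure(list(
    years = years, vpd = vpd_t, smi = smi_t,
    delta_latent = delta_lat, rwi_latent = rwi_lat, rwi_scale = rwi_scale,
    elevations = elev, tree_offsets = offs, first_years = first_years,
    config = config), class = "synthetic_truth")
  list(rwl = rwl, iso = do.call(rbind, iso_list), truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic truth: %d years (%d-%d), %d trees, elevations %.0f-%.0f m\n",
              length(x$years), min(x$years), max(x$years),
              length(x$elevations), min(x$elevations), max(x$elevations)))
  cat(sprintf("  latent VPD mean %.3f kPa (sd %.3f); RWI scale %.4f\n",
              mean(x$vpd), stats::sd(x$vpd), x$rwi_scale))
  invisible(x)
}
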