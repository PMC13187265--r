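## End-to-end orchestration: simulate/load -> chronologies -> indices ->
## calibrate -> reconstruct -> classify -> SEA, with standard-format outputs
## and a reproducibility manifest.

#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()].  By
#' default the pipeline runs on a synthetic dataset from [synthetic_config()];
#' supply `inputs` (paths to an `.rwl`/ring CSV, an isotope CSV and a climate
#' CSV) to run on measured data instead.
#'
#' @param synthetic list of overrides for [synthetic_config()] (ignored when
#'   `inputs` is given).
#' @param inputs optional named list `rwl` or `ring_csv`, `iso`, `climate`.
#' @param calibration_span,vpd_months length-2 integer vectors.
#' @param smi_k,smi_month moisture-index accumulation and target month.
#' @param reference_elevation m a.s.l. for the isotope normalization.
#' @param detrend_method,detrend_stiffness growth-curve fitter settings.
#' @param min_replication minimum trees per isotope-chronology year.
#' @param cluster_seed,cluster_n_init,sea_window,sea_n_mc,sea_seed
#'   classification and SEA controls.
#' @param cutoff_years low-pass cutoff for the smoothed reconstructions.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(synthetic = list(),
                            inputs = NULL,
                            calibration_span = c(1984L, 2020L),
                            vpd_months = c(3L, 9L),
                            smi_k = 7L, smi_month = 9L,
                            reference_elevation = 2000,
                            detrend_method = "negexp", detrend_stiffness = 50,
                            min_replication = 5L,
                            cluster_seed = 42L, cluster_n_init = 25L,
                            sea_window = 3L, sea_n_mc = 1000L, sea_seed = 42L,
                            cutoff_years = 10) {
  assert_that(calibration_span[1] <= calibration_span[2],
              "pipeline_config(): calibration_span is empty")
  cfg <- list(synthetic = synthetic, inputs = inputs,
              calibration_span = calibration_span, vpd_months = vpd_months,
              smi_k = smi_k, smi_month = smi_month,
              reference_elevation = reference_elevation,
              detrend_method = detrend_method,
              detrend_stiffness = detrend_stiffness,
              min_replication = min_replication,
              cluster_seed = cluster_seed, cluster_n_init = cluster_n_init,
              sea_window = sea_window, sea_n_mc = sea_n_mc, sea_seed = sea_seed,
              cutoff_years = cutoff_years)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror the [pipeline_config()] arguments.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full dual-proxy drought-reconstruction pipeline
#'
#' Executes, in order: data simulation (or loading), signal-free ring-width
#' chronology, isotope elevation correction and chronology, climate-index
#' targets (seasonal VPD and the standardized moisture index), transfer
#' calibration with leave-one-out validation, full-period reconstruction with
#' low-pass smoothing, k-means drought typology (VPD / SPEI / combined), and
#' superposed epoch analysis of the severe years of each scheme.  Every
#' intermediate artifact is written to `out_dir`, and a manifest records
#' stage completion, seeds, switches, file checksums and the package version.
#' A stage failure halts with the stage name; artifacts already written are
#' retained.
#'
#' @param config a [pipeline_config()] (or path to its YAML form).
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with all stage objects plus `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  assert_that(inherits(config, "pipeline_config"),
              "run_pipeline(): config must come from pipeline_config()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character()
  res <- list(config = config)
  run_stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      stop_field("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    stages <<- c(stages, name)
    out
  }
  p <- function(f) file.path(out_dir, f)

  ## 1 -- simulate or load ----------------------------------------------------
  res$data <- run_stage("simulate", {
    if (is.null(config$inputs)) {
      scfg <- do.call(synthetic_config, config$synthetic)
      climate <- generate_climate(scfg)
      prox <- generate_proxies(scfg, climate)
      utils::write.csv(climate, p("climate.csv"), row.names = FALSE)
      write_rwl(prox$rwl, p("ringwidths.rwl"))
      write_ring_csv(prox$rwl, p("ringwidths.csv"))
      utils::write.csv(prox$iso, p("isotopes.csv"), row.names = FALSE)
      write_report_json(unclass(scfg), p("generator_params.json"))
      list(climate = climate, rwl = prox$rwl, iso = prox$iso,
           truth = prox$truth, synthetic = TRUE)
    } else {
      rwl <- if (!is.null(config$inputs$rwl)) read_rwl(config$inputs$rwl)
             else read_ring_csv(config$inputs$ring_csv)
      list(climate = read_climate_csv(config$inputs$climate),
           rwl = rwl,
           iso = utils::read.csv(config$inputs$iso, stringsAsFactors = FALSE),
           truth = NULL, synthetic = FALSE)
    }
  })

  ## 2 -- ring-width chronology ----------------------------------------------
  res$trw <- run_stage("chronology", {
    crn <- detrend_signal_free(res$data$rwl, method = config$detrend_method,
                               stiffness = config$detrend_stiffness)
    utils::write.csv(crn$crn, p("trw_chronology.csv"), row.names = FALSE)
    if (!is.null(crn$stats)) {
      write_report_json(list(rbar = crn$stats$rbar, eps = crn$stats$eps,
                             snr = crn$stats$snr, ac1 = crn$stats$ac1,
                             n_eff = crn$stats$n_eff),
                        p("trw_stats.json"))
    }
    crn
  })

  ## 3 -- isotope elevation correction and chronology -------------------------
  res$iso <- run_stage("isotope", {
    model <- fit_elevation_model(res$data$iso)
    corrected <- correct_to_reference(res$data$iso, model,
                                      config$reference_elevation)
    crn <- build_isotope_chronology(corrected,
                                    min_replication = config$min_replication)
    write_report_json(model, p("elevation_model.json"))
    utils::write.csv(as.data.frame(crn), p("iso_chronology.csv"), row.names = FALSE)
    list(model = model, corrected = corrected, crn = crn)
  })

  ## 4 -- climate-index targets ----------------------------------------------
  res$indices <- run_stage("indices", {
    vpd <- seasonal_mean(climate_vpd(res$data$climate), "vpd_kpa",
                         config$vpd_months[1], config$vpd_months[2])
    smi <- standardized_moisture_index(res$data$climate, config$smi_k,
                                       config$smi_month)
    utils::write.csv(vpd, p("vpd_target.csv"), row.names = FALSE)
    utils::write.csv(smi, p("smi_target.csv"), row.names = FALSE)
    list(vpd = vpd, smi = smi)
  })

  ## 5 -- calibration ----------------------------------------------------------
  res$calibration <- run_stage("calibrate", {
    d18o <- data.frame(year = res$iso$crn$year, value = res$iso$crn$d18o)
    rwi <- data.frame(year = res$trw$crn$year, value = res$trw$crn$index)
    vpd_model <- fit_transfer(res$indices$vpd, list(d18o = d18o),
                              config$calibration_span)
    vpd_cv <- loocv(res$indices$vpd, list(d18o = d18o), config$calibration_span)
    spei_model <- fit_transfer(res$indices$smi, list(d18o = d18o, rwi = rwi),
                               config$calibration_span)
    spei_cv <- loocv(res$indices$smi, list(d18o = d18o, rwi = rwi),
                     config$calibration_span)
    write_report_json(vpd_model, p("vpd_model.json"))
    write_report_json(vpd_cv[c("rmse", "mae", "r2_cv", "r2_sse", "re", "n", "re_null")],
                      p("vpd_loocv.json"))
    write_report_json(spei_model, p("spei_model.json"))
    write_report_json(spei_cv[c("rmse", "mae", "r2_cv", "r2_sse", "re", "n", "re_null")],
                      p("spei_loocv.json"))
    list(d18o = d18o, rwi = rwi, vpd_model = vpd_model, vpd_cv = vpd_cv,
         spei_model = spei_model, spei_cv = spei_cv)
  })

  ## 6 -- full-period reconstruction -------------------------------------------
  res$reconstruction <- run_stage("reconstruct", {
    vpd_rec <- apply_transfer(res$calibration$vpd_model,
                              list(d18o = res$calibration$d18o),
                              cutoff_years = config$cutoff_years)
    spei_rec <- apply_transfer(res$calibration$spei_model,
                               list(d18o = res$calibration$d18o,
                                    rwi = res$calibration$rwi),
                               cutoff_years = config$cutoff_years)
    utils::write.csv(vpd_rec, p("vpd_reconstruction.csv"), row.names = FALSE)
    utils::write.csv(spei_rec, p("spei_reconstruction.csv"), row.names = FALSE)
    list(vpd = vpd_rec, spei = spei_rec)
  })

  ## 7 -- drought typology ------------------------------------------------------
  res$typology <- run_stage("classify", {
    vr <- res$reconstruction$vpd[, c("year", "value")]
    sr <- res$reconstruction$spei[, c("year", "value")]
    common <- intersect(vr$year, sr$year)
    vr <- vr[vr$year %in% common, ]; sr <- sr[sr$year %in% common, ]
    comb <- data.frame(year = vr$year, vpd = vr$value,
                       spei = sr$value[match(vr$year, sr$year)])
    vpd_cls <- kmeans_classify(vr, "VPD", seed = config$cluster_seed,
                               n_init = config$cluster_n_init)
    spei_cls <- kmeans_classify(sr, "SPEI", seed = config$cluster_seed,
                                n_init = config$cluster_n_init)
    comb_cls <- kmeans_classify(comb, "COMB", seed = config$cluster_seed,
                                n_init = config$cluster_n_init)
    labels <- data.frame(year = vr$year, vpd_label = vpd_cls$label,
                         spei_label = spei_cls$label, comb_label = comb_cls$label)
    utils::write.csv(labels, p("labels.csv"), row.names = FALSE)
    rwi <- data.frame(year = res$trw$crn$year, value = res$trw$crn$index)
    series <- list(spei = sr, vpd = vr, rwi = rwi)
    summaries <- do.call(rbind, lapply(list(SPEI = spei_cls, VPD = vpd_cls,
                                            COMB = comb_cls), function(cls) {
      s <- cluster_summary(cls, series)
      s$scheme <- attr(cls, "scheme")
      s$drought_fraction_pct <- 100 * attr(s, "drought_fraction")
      s
    }))
    utils::write.csv(summaries, p("cluster_summary.csv"), row.names = FALSE)
    comp <- composition_analysis(vpd_cls, spei_cls, comb_cls)
    utils::write.csv(comp, p("composition.csv"), row.names = FALSE)
    trends <- do.call(rbind, lapply(list(SPEI = spei_cls, VPD = vpd_cls,
                                         COMB = comb_cls), function(cls) {
      tr <- period_trends(cls)
      tr$scheme <- attr(cls, "scheme")
      tr
    }))
    utils::write.csv(trends, p("period_trends.csv"), row.names = FALSE)
    list(vpd = vpd_cls, spei = spei_cls, comb = comb_cls,
         summary = summaries, composition = comp, trends = trends)
  })

  ## 8 -- superposed epoch analysis ---------------------------------------------
  res$sea <- run_stage("sea", {
    sea <- sea_by_type(res$trw$crn,
                       list(SPEI = res$typology$spei, VPD = res$typology$vpd,
                            COMB = res$typology$comb),
                       window = config$sea_window, n_mc = config$sea_n_mc,
                       seed = config$sea_seed)
    for (nm in names(sea$results)) {
      utils::write.csv(as.data.frame(sea$results[[nm]]),
                       p(sprintf("sea_%s.csv", tolower(nm))), row.names = FALSE)
    }
    utils::write.csv(sea$comparison, p("sea_comparison.csv"), row.names = FALSE)
    sea
  })

  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    package = "dendrodrought",
    version = as.character(utils::packageVersion("dendrodrought")),
    stages_completed = stages,
    seeds = list(synthetic = if (res$data$synthetic)
                   do.call(synthetic_config, config$synthetic)$seed else NULL,
                 clustering = config$cluster_seed, sea = config$sea_seed),
    switches = list(detrend_method = config$detrend_method,
                    detrend_stiffness = config$detrend_stiffness,
                    comb_scaling = "z-score per variable before clustering",
                    sea_normalization = "whole-record mean/SD",
                    re_null = "calibration-period mean",
                    magnus = c(a = 0.6108, b = 17.27, c = 237.3),
                    vpd_temperature = "tmax"),
    config = unclass(config),
    checksums = as.list(tools::md5sum(file.path(out_dir, files))))
  write_report_json(manifest, file.path(out_dir, "manifest.json"))
  res$manifest <- manifest
  invisible(res)
}
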