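## Drought-year typology: k-means classification of reconstructed indices,
## cluster summaries, composition and 50-year period trends.

#' Classify years into drought types by k-means
#'
#' k = 3 clusters on one reconstructed index (schemes `"VPD"`, `"SPEI"`) or on
#' the combined two-column matrix (scheme `"COMB"`, both variables z-scored
#' first so neither unit dominates).  Cluster labels are assigned by a fixed
#' severity ordering, so they are invariant to the arbitrary cluster
#' numbering of the k-means run:
#' \itemize{
#'   \item SPEI scheme: lowest cluster-mean index = severe drought `D`;
#'   \item VPD scheme: highest cluster-mean index = `D`;
#'   \item COMB scheme: clusters ranked by mean z(VPD) - z(SPEI), highest =
#'     `D` (highest atmospheric demand with lowest moisture), ties broken by
#'     the lower mean SPEI.
#' }
#'
#' @param values data frame `year`, `value` for single-index schemes, or
#'   `year`, `vpd`, `spei` for `"COMB"`.
#' @param scheme `"VPD"`, `"SPEI"` or `"COMB"`.
#' @param seed integer seed for the k-means restarts.
#' @param n_init random restarts (best within-cluster SS kept).
#' @param k number of clusters (3: severe, moderate, non-drought).
#' @return class `"drought_classification"`: data frame `year`, `label`
#'   (factor D/M/ND) with attributes `cluster_means`, `cluster_sizes`,
#'   `scheme`, `k`, `seed`.
#' @export
kmeans_classify <- function(values, scheme = c("VPD", "SPEI", "COMB"),
                            seed = 42L, n_init = 25L, k = 3L) {
  scheme <- match.arg(scheme)
  if (scheme == "COMB") {
    assert_that(all(c("year", "vpd", "spei") %in% names(values)),
                "kmeans_classify(): COMB scheme needs columns year, vpd, spei")
    values <- values[stats::complete.cases(values), ]
    X <- scale(as.matrix(values[, c("vpd", "spei")]))
  } else {
    values <- values[stats::complete.cases(values), ]
    X <- as.matrix(values[, 2, drop = FALSE])
  }
  n <- nrow(X)
  assert_that(n >= k, "kmeans_classify(): need at least %d years, got %d", k, n)
  if (n < 3 * k) {
    warning(sprintf("kmeans_classify(): only %d years for %d clusters; labels will be fragile",
                    n, k))
  }
  assert_that(any(apply(X, 2, stats::sd) > 0),
              "kmeans_classify(): identical values for all years; no clusters")
  set.seed(seed)
  km <- stats::kmeans(X, centers = k, nstart = n_init, iter.max = 300L)
  ## severity ordering -> labels independent of cluster numbering
  sev <- switch(scheme,
    SPEI = -km$centers[, 1],                       # lowest SPEI most severe
    VPD  = km$centers[, 1],                        # highest VPD most severe
    COMB = km$centers[, "vpd"] - km$centers[, "spei"])
  tie <- if (scheme == "COMB") km$centers[, "spei"] else seq_len(k)
  ord <- order(-sev, tie)                          # most severe first
  lab_levels <- c("D", "M", "ND")
  lab_map <- character(k)
  lab_map[ord] <- lab_levels[seq_len(k)]
  labels <- factor(lab_map[km$cluster], levels = lab_levels)

  means <- if (scheme == "COMB") {
    agg <- stats::aggregate(values[, c("vpd", "spei")], by = list(label = labels), mean)
    agg[match(lab_levels, agg$label), ]
  } else {
    agg <- stats::aggregate(values[, 2, drop = FALSE], by = list(label = labels), mean)
    names(agg)[2] <- "value"
    agg[match(lab_levels, agg$label), ]
  }
  means$label <- as.character(means$label)
  rownames(means) <- NULL
  sizes <- table(labels)
  out <- data.frame(year = values$year, label = labels)
  structure(out, cluster_means = means, cluster_sizes = sizes,
            scheme = scheme, k = k, seed = seed,
            class = c("drought_classification", "data.frame"))
}

#' Per-cluster summary table
#'
#' Mean SPEI, VPD and RWI and year counts per drought class of one
#' classification, plus the drought-year fraction (D + M)/total as an
#' attribute.
#'
#' @param classification a `"drought_classification"`.
#' @param series named list of aligned annual data frames `year`, `value`
#'   (typically `list(spei = ..., vpd = ..., rwi = ...)`).
#' @return data frame `label`, `n_years`, then `mean_<name>` per series;
#'   attribute `drought_fraction`.  Empty clusters appear with `n_years = 0`
#'   and `NA` means.
#' @export
cluster_summary <- function(classification, series) {
  labs <- levels(classification$label)
  out <- data.frame(label = labs,
                    n_years = as.integer(table(classification$label)[labs]))
  for (nm in names(series)) {
    s <- series[[nm]]
    names(s)[2] <- "value"
    m <- merge(classification, s, by = "year")
    agg <- tapply(m$value, factor(m$label, levels = labs), mean)
    out[[paste0("mean_", nm)]] <- as.numeric(agg)
  }
  frac <- sum(out$n_years[out$label %in% c("D", "M")]) / sum(out$n_years)
  structure(out, drought_fraction = frac)
}

#' Drought-year fraction from cluster sizes
#'
#' (n_D + n_M) / n_total, as a percentage.
#' @param sizes named vector or table with elements `D`, `M`, `ND`.
#' @export
drought_year_fraction <- function(sizes) {
  sizes <- sizes[c("D", "M", "ND")]
  100 * sum(sizes[c("D", "M")]) / sum(sizes)
}

#' Composition of combined clusters by single-index labels
#'
#' Cross-tabulates the (VPD label, SPEI label) combination of every year
#' within each combined-scheme cluster.
#'
#' @param vpd_cls,spei_cls,comb_cls three `"drought_classification"` objects
#'   over identical years.
#' @return data frame `comb_label`, `vpd_label`, `spei_label`, `n`, `prop`
#'   (proportion within the combined cluster); only non-empty combinations.
#' @export
composition_analysis <- function(vpd_cls, spei_cls, comb_cls) {
  assert_that(identical(vpd_cls$year, spei_cls$year) &&
              identical(vpd_cls$year, comb_cls$year),
              "composition_analysis(): classifications cover different years")
  tab <- table(comb = comb_cls$label, vpd = vpd_cls$label, spei = spei_cls$label)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("comb_label", "vpd_label", "spei_label", "n")
  df <- df[df$n > 0, ]
  totals <- tapply(df$n, df$comb_label, sum)
  df$prop <- df$n / as.numeric(totals[df$comb_label])
  df <- df[order(df$comb_label, -df$n), ]
  rownames(df) <- NULL
  stopifnot(sum(df$n) == nrow(comb_cls))
  df
}

#' Severity trend over fixed-length blocks
#'
#' Splits the classified span into consecutive blocks (default 50 years) and
#' reports, per block, the proportion of severe years among drought years,
#' n_D / (n_D + n_M).
#'
#' @param classification a `"drought_classification"`.
#' @param block_length block length in years.
#' @return data frame `block_start`, `block_end`, `n_D`, `n_M`, `n_ND`,
#'   `severe_prop` (`NA` when a block has no drought years), `short_block`.
#' @export
period_trends <- function(classification, block_length = 50L) {
  yrs <- classification$year
  span <- range(yrs)
  starts <- seq.int(span[1], span[2], by = block_length)
  assert_that(length(starts) >= 2,
              "period_trends(): span shorter than two blocks of %d years", block_length)
  out <- lapply(starts, function(s) {
    e <- min(s + block_length - 1L, span[2])
    lab <- classification$label[yrs >= s & yrs <= e]
    nD <- sum(lab == "D"); nM <- sum(lab == "M"); nND <- sum(lab == "ND")
    data.frame(block_start = s, block_end = e, n_D = nD, n_M = nM, n_ND = nND,
               severe_prop = if (nD + nM > 0) nD / (nD + nM) else NA_real_,
               short_block = (e - s + 1L) < block_length)
  })
  do.call(rbind, out)
}
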