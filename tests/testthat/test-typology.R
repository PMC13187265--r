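## Brute-force 1-D k-means oracle: optimal clusters are contiguous in sorted
## order, so enumerate all ordered 3-partitions and minimize within-cluster SS.
kmeans1d_oracle <- function(x, k = 3) {
  xs <- sort(x)
  n <- length(xs)
  best <- NULL; best_ss <- Inf
  for (i in 1:(n - k + 1)) {
    for (j in (i + 1):(n - k + 2)) {
      parts <- list(xs[1:i], xs[(i + 1):j], xs[(j + 1):n])
      ss <- sum(vapply(parts, function(p) sum((p - mean(p))^2), numeric(1)))
      if (ss < best_ss) { best_ss <- ss; best <- parts }
    }
  }
  list(ss = best_ss, means = vapply(best, mean, numeric(1)),
       sizes = lengths(best))
}

test_that("k-means partition matches the exhaustive 1-D oracle", {
  x <- c(-1.6, -1.5, 0.0, 0.1, 1.4, 1.5)
  oracle <- kmeans1d_oracle(x)
  expect_equal(oracle$sizes, c(2L, 2L, 2L))
  expect_equal(oracle$means, c(-1.55, 0.05, 1.45))
  cls <- suppressWarnings(
    kmeans_classify(data.frame(year = 2001:2006, value = x), "SPEI", seed = 1))
  cm <- attr(cls, "cluster_means")
  expect_equal(sort(cm$value), oracle$means)
  expect_equal(unname(as.integer(attr(cls, "cluster_sizes"))), c(2L, 2L, 2L))
  ## severity ordering: the lowest-SPEI pair is labeled D
  expect_equal(as.character(cls$label[x <= -1.5]), c("D", "D"))
  expect_equal(as.character(cls$label[x >= 1.4]), c("ND", "ND"))
})

test_that("VPD scheme labels the highest cluster severe and ordering is monotone", {
  set.seed(10)
  x <- c(rnorm(30, 2.7, 0.05), rnorm(30, 3.0, 0.05), rnorm(30, 3.3, 0.05))
  cls <- kmeans_classify(data.frame(year = 1901:1990, value = x), "VPD", seed = 3)
  cm <- attr(cls, "cluster_means")
  expect_equal(cm$label, c("D", "M", "ND"))
  expect_true(cm$value[1] > cm$value[2] && cm$value[2] > cm$value[3])
  ## SPEI ordering on the same values is reversed
  cls2 <- kmeans_classify(data.frame(year = 1901:1990, value = x), "SPEI", seed = 3)
  cm2 <- attr(cls2, "cluster_means")
  expect_true(cm2$value[1] < cm2$value[2] && cm2$value[2] < cm2$value[3])
})

test_that("labels are invariant to the k-means seed when clusters are separated", {
  set.seed(20)
  vals <- data.frame(year = 1901:1990,
                     value = c(rnorm(30, -2, 0.1), rnorm(30, 0, 0.1), rnorm(30, 2, 0.1)))
  ref <- kmeans_classify(vals, "SPEI", seed = 1)
  for (s in 2:10) {
    expect_identical(kmeans_classify(vals, "SPEI", seed = s)$label, ref$label)
  }
})

test_that("COMB scheme z-scores inputs and ranks by joint severity", {
  set.seed(30)
  n <- 40
  comb <- data.frame(
    year = 1901:(1900 + 3 * n),
    vpd = c(rnorm(n, 3.3, 0.05), rnorm(n, 3.0, 0.05), rnorm(n, 2.8, 0.05)),
    spei = c(rnorm(n, -1.5, 0.1), rnorm(n, -0.4, 0.1), rnorm(n, 0.4, 0.1)))
  cls <- kmeans_classify(comb, "COMB", seed = 5)
  cm <- attr(cls, "cluster_means")
  expect_equal(cm$label, c("D", "M", "ND"))
  expect_lt(cm$spei[1], cm$spei[3])   # D has the driest soils
  expect_gt(cm$vpd[1], cm$vpd[3])     # and the highest atmospheric demand
  expect_equal(as.character(cls$label[1:n]), rep("D", n))
})

test_that("degenerate clustering inputs are rejected", {
  expect_error(kmeans_classify(data.frame(year = 1:20, value = rep(1, 20)), "SPEI"),
               "identical values")
  expect_error(kmeans_classify(data.frame(year = 1:2, value = rnorm(2)), "SPEI"),
               "at least 3 years")
  expect_warning(kmeans_classify(data.frame(year = 1:8, value = c(1:8) + rnorm(8)), "SPEI"),
                 "fragile")
})

test_that("cluster summaries partition the years and rank growth sensibly", {
  set.seed(40)
  n <- 60
  spei <- data.frame(year = 1901:(1900 + n),
                     value = c(rnorm(n / 3, -1.5, 0.2), rnorm(n / 3, 0, 0.2),
                               rnorm(n / 3, 1.2, 0.2)))
  ## growth suppressed in planted severe years
  rwi <- data.frame(year = spei$year, value = 1 + 0.25 * spei$value + rnorm(n, sd = 0.05))
  vpd <- data.frame(year = spei$year, value = 3 - 0.1 * spei$value)
  cls <- kmeans_classify(spei, "SPEI", seed = 2)
  sm <- cluster_summary(cls, list(spei = spei, vpd = vpd, rwi = rwi))
  expect_equal(sum(sm$n_years), n)
  expect_lt(sm$mean_rwi[sm$label == "D"], sm$mean_rwi[sm$label == "ND"])
  expect_true(attr(sm, "drought_fraction") >= 0 && attr(sm, "drought_fraction") <= 1)
})

test_that("drought-year fraction arithmetic on printed-style counts", {
  expect_equal(drought_year_fraction(c(D = 32, M = 97, ND = 71)), 64.5)
})

test_that("composition is diagonal for identical labels and collapses for all-ND", {
  labs <- factor(rep(c("D", "M", "ND"), times = c(10, 20, 15)),
                 levels = c("D", "M", "ND"))
  yrs <- seq_along(labs) + 1900
  cls <- data.frame(year = yrs, label = labs)
  comp <- composition_analysis(cls, cls, cls)
  expect_true(all(comp$vpd_label == comp$spei_label &
                  comp$vpd_label == comp$comb_label))
  expect_equal(sum(comp$n), length(labs))
  all_nd <- data.frame(year = yrs, label = factor(rep("ND", length(yrs)),
                                                  levels = c("D", "M", "ND")))
  comp_nd <- composition_analysis(all_nd, all_nd, all_nd)
  expect_equal(nrow(comp_nd), 1L)
  expect_equal(comp_nd$prop, 1)
  expect_error(composition_analysis(cls, cls, cls[-1, ]), "different years")
})

test_that("mixed-driver years concentrate where the dominant driver points", {
  ## soil-drought-dominated combined classification: SPEI-D + VPD-M years
  ## carry extreme spei, middling vpd -> they cluster into COMB-D
  set.seed(50)
  n <- 30
  spei <- data.frame(year = 1901:(1900 + 3 * n),
                     value = c(rnorm(n, -1.6, 0.1), rnorm(n, -0.4, 0.1), rnorm(n, 0.5, 0.1)))
  vpd <- data.frame(year = spei$year,
                    value = c(rnorm(n, 3.05, 0.03), rnorm(n, 3.0, 0.03), rnorm(n, 2.8, 0.03)))
  spei_cls <- kmeans_classify(spei, "SPEI", seed = 2)
  vpd_cls <- kmeans_classify(vpd, "VPD", seed = 2)
  comb_cls <- kmeans_classify(data.frame(year = spei$year, vpd = vpd$value,
                                         spei = spei$value), "COMB", seed = 2)
  comp <- composition_analysis(vpd_cls, spei_cls, comb_cls)
  in_d <- comp[comp$comb_label == "D" & comp$spei_label == "D", ]
  expect_gt(sum(in_d$n), 0)
  expect_gt(sum(in_d$prop), 0.5)
})

test_that("period trends split blocks correctly and track planted severity shifts", {
  labs <- rep(c("D", "M", "ND"), length.out = 200)
  cls <- data.frame(year = 1821:2020, label = factor(labs, levels = c("D", "M", "ND")))
  tr <- period_trends(cls, 50)
  expect_equal(nrow(tr), 4L)
  expect_false(any(tr$short_block))
  expect_equal(tr$severe_prop, rep(0.5, 4), tolerance = 0.05)
  ## severity concentrated in the final block
  labs2 <- c(rep(c("M", "ND"), 75), rep(c("D", "M"), 25))
  cls2 <- data.frame(year = 1821:2020, label = factor(labs2, levels = c("D", "M", "ND")))
  tr2 <- period_trends(cls2, 50)
  expect_equal(which.max(tr2$severe_prop), 4L)
  ## a trailing short block is flagged
  tr3 <- period_trends(cls[1:120, ], 50)
  expect_true(tr3$short_block[3])
})
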