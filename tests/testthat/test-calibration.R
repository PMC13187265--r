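test_that("Spearman correlation matches the rank formula and handles edge cases", {
  x <- data.frame(year = 2001:2005, value = c(1, 2, 3, 4, 5))
  y <- data.frame(year = 2001:2005, value = c(2, 1, 4, 3, 5))
  sb <- spearman_bootstrap(x, y, n_boot = 50, min_overlap = 5)
  expect_equal(sb$rho, 0.8)   # 1 - 6*4/(5*24)
  ## monotone transform gives rho exactly 1
  xv <- data.frame(year = 1981:2010, value = rnorm(30))
  yv <- data.frame(year = 1981:2010, value = exp(2 * xv$value))
  expect_equal(spearman_bootstrap(xv, yv, n_boot = 50)$rho, 1)
  const <- data.frame(year = 1981:2010, value = 1)
  expect_warning(sc <- spearman_bootstrap(xv, const, n_boot = 50), "constant")
  expect_true(is.na(sc$rho))
  expect_error(spearman_bootstrap(x, y, n_boot = 50), "overlap")
})

test_that("bootstrap significance has roughly nominal type-I error", {
  set.seed(99)
  hits <- 0L
  n_sim <- 200L
  for (i in seq_len(n_sim)) {
    x <- rnorm(30); y <- rnorm(30)
    p <- spearman_bootstrap(x, y, n_boot = 199, seed = 1000 + i)$p_boot
    hits <- hits + (p < 0.05)
  }
  rate <- hits / n_sim
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.12)
})

test_that("transfer fits report exact diagnostics on constructed designs", {
  yrs <- 1984:2020
  x1 <- sin(seq_along(yrs)); x2 <- cos(seq_along(yrs))
  x1 <- (x1 - mean(x1)); x2 <- resid(lm(x2 ~ x1))    # exactly orthogonal
  tgt <- data.frame(year = yrs, value = 2 + 0.5 * x1 - 0.3 * x2)
  m <- fit_transfer(tgt, list(a = data.frame(year = yrs, value = x1),
                              b = data.frame(year = yrs, value = x2)))
  expect_equal(m$r2, 1, tolerance = 1e-9)
  expect_lt(m$rse, 1e-9)
  expect_equal(unname(m$vif), c(1, 1), tolerance = 1e-9)
  ## predictors correlated at exactly r = -0.28: VIF = 1/(1-0.28^2)
  set.seed(5)
  z1 <- scale(rnorm(37)); z2 <- scale(resid(lm(rnorm(37) ~ z1)))
  xc <- -0.28 * z1 + sqrt(1 - 0.28^2) * z2
  m2 <- fit_transfer(data.frame(year = yrs, value = rnorm(37)),
                     list(a = data.frame(year = yrs, value = as.numeric(z1)),
                          b = data.frame(year = yrs, value = as.numeric(xc))))
  expect_equal(unname(m2$vif), rep(1 / (1 - 0.28^2), 2), tolerance = 1e-9)
  expect_equal(unname(m2$vif)[1], 1.085, tolerance = 1e-3)
  ## single predictor: VIF exactly 1; collinear pair rejected
  m1 <- fit_transfer(tgt, list(a = data.frame(year = yrs, value = x1)))
  expect_identical(unname(m1$vif), 1)
  expect_lte(m1$adj_r2, m1$r2)
  expect_error(fit_transfer(tgt, list(a = data.frame(year = yrs, value = x1),
                                      b = data.frame(year = yrs, value = 2 * x1))),
               "collinear")
  expect_error(fit_transfer(tgt, list(data.frame(year = yrs, value = x1))), "named")
  expect_error(fit_transfer(tgt, list(a = data.frame(year = yrs, value = x1),
                                      b = data.frame(year = yrs, value = x2),
                                      c = data.frame(year = yrs, value = x1 + x2))),
               "1 or 2 predictors")
})

test_that("Durbin-Watson matches hand computations and the asymptotic value", {
  expect_equal(durbin_watson(c(1, -1, 1, -1, 1)), 16 / 5)
  expect_equal(durbin_watson(c(1, 1, 1, 1)), 0)
  expect_warning(dw0 <- durbin_watson(c(0, 0, 0)), "undefined")
  expect_true(is.na(dw0))
  set.seed(8)
  expect_equal(durbin_watson(rnorm(1000)), 2, tolerance = 0.15 / 2)
})

test_that("Durbin-Watson agrees with the lmtest oracle on a fitted model", {
  set.seed(13)
  x <- rnorm(40); y <- 1 + 0.5 * x + as.numeric(arima.sim(list(ar = 0.5), 40))
  fit <- lm(y ~ x)
  expect_equal(durbin_watson(resid(fit)),
               unname(lmtest::dwtest(fit)$statistic), tolerance = 1e-9)
})

test_that("reduction of error matches its definition", {
  expect_equal(reduction_of_error(c(1, 2, 3), c(2, 2, 2)), 0)
  obs <- c(4, 6, 5, 7)
  expect_equal(reduction_of_error(obs, rep(mean(obs), 4)), 0)
  expect_equal(reduction_of_error(obs, obs), 1)
  expect_lt(reduction_of_error(obs, rev(obs) * 3), 0)
})

test_that("LOOCV is exact on noise-free data and bounded in general", {
  yrs <- 1984:2020
  x <- rnorm(37, 31, 1)
  tgt <- data.frame(year = yrs, value = -4.643 + 0.218 * x)
  pred <- list(d18o = data.frame(year = yrs, value = x))
  cv <- loocv(tgt, pred)
  expect_lt(cv$rmse, 1e-8)
  expect_equal(cv$re, 1, tolerance = 1e-8)
  expect_equal(cv$n_skipped, 0L)
  ## RE <= 1 and r2_cv in [0,1] across random data
  set.seed(31)
  for (i in 1:10) {
    t2 <- data.frame(year = yrs, value = rnorm(37))
    p2 <- list(a = data.frame(year = yrs, value = rnorm(37)))
    cv2 <- loocv(t2, p2)
    expect_lte(cv2$re, 1)
    expect_gte(cv2$r2_cv, 0); expect_lte(cv2$r2_cv, 1)
    expect_lte(cv2$r2_sse, cv2$re + 1e-12)  # same SSE, null uses full mean
  }
  expect_error(loocv(tgt[1:4, ], list(d18o = pred$d18o[1:4, ])), "5 calibration years")
})

test_that("calibration on transfer-generated data recovers the coefficients", {
  set.seed(77)
  sl <- numeric(100)
  yrs <- 1984:2020
  for (i in 1:100) {
    x <- rnorm(37, 31, 1.08)
    y <- -4.643 + 0.218 * x + rnorm(37, sd = 0.22)
    m <- fit_transfer(data.frame(year = yrs, value = y),
                      list(d18o = data.frame(year = yrs, value = x)))
    sl[i] <- m$coefficients[["d18o"]]
  }
  se_mc <- sd(sl) / sqrt(100)
  expect_lt(abs(mean(sl) - 0.218), 3 * se_mc + 1e-3)
})

test_that("a dual-proxy model beats either single proxy when both drive the target", {
  set.seed(55)
  yrs <- 1984:2020
  x1 <- rnorm(37); x2 <- rnorm(37)
  tgt <- data.frame(year = yrs, value = 0.7 * x1 - 0.6 * x2 + rnorm(37, sd = 0.5))
  p1 <- list(a = data.frame(year = yrs, value = x1))
  p2 <- list(b = data.frame(year = yrs, value = x2))
  both <- c(p1, p2)
  r2_both <- fit_transfer(tgt, both)$r2
  expect_gt(r2_both, fit_transfer(tgt, p1)$r2)
  expect_gt(r2_both, fit_transfer(tgt, p2)$r2)
})

test_that("the correlation grid has the right shape and finds planted windows", {
  cl <- default_climate()
  smi79 <- standardized_moisture_index(cl, 7, 9)
  ## proxy equal to the index itself: that cell correlates perfectly
  grid <- correlation_grid(smi79, cl, "smi", k_range = 6:7, months = 8:9,
                           n_boot = 99)
  expect_equal(nrow(grid), 4L)
  cell <- grid[grid$month == 9 & grid$k == 7, ]
  expect_equal(cell$rho, 1)
  ## noisy proxies generated from the k=7/September index still peak there
  set.seed(3)
  for (i in 1:3) {
    prox <- data.frame(year = smi79$year, value = smi79$value + rnorm(nrow(smi79), sd = 0.3))
    g <- correlation_grid(prox, cl, "smi", k_range = 1:7, months = c(3, 6, 9),
                          n_boot = 49)
    expect_equal(nrow(g), 21L)
    top <- g[which.max(abs(g$rho)), ]
    expect_equal(c(top$month, top$k), c(9, 7))
  }
})
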