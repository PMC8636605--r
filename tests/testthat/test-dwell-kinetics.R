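test_that("dwells are classified by flanking step signs and filtered by dead time", {
  st <- make_steps(c(3, 2.5, -3), 0.1, atp = 1)
  st$dwell_after <- c(0.5, 0.4, 0.6)
  dw <- classify_and_filter_dwells(st)
  expect_equal(dw$class, c("+/+", "+/-"))
  expect_equal(dw$d, c(2.5, -3))
  # 15 ms dwell: excluded at 1 uM, kept at 10 uM
  st$dwell_after <- c(0.015, 0.4, 0.6)
  expect_equal(nrow(classify_and_filter_dwells(st, atp = 1)), 1)
  expect_equal(nrow(classify_and_filter_dwells(st, atp = 10)), 2)
})

test_that("generator dwells are dominated by processive classes", {
  set.seed(41)
  recs <- lapply(1:6, function(i) {
    sim <- simulate_trace(generator_config(), 0.5, 25, seed = 410 + i)
    extract_steps(detect_steps(sim$trace))
  })
  st <- structure(do.call(rbind, lapply(recs, as.data.frame)),
                  class = c("step_records", "data.frame"))
  dw <- classify_and_filter_dwells(st)
  frac_pp <- mean(dw$class == "+/+")
  expect_gt(frac_pp, 0.7)
  expect_lt(mean(dw$class %in% c("+/-", "-/+")), 0.3)
})

test_that("boxcar curves reproduce flat and identity relations", {
  dw <- structure(data.frame(t = rep(0.4, 60), class = "+/+",
                             d = runif(60, 1, 5), atp = 1, force = 12,
                             trace_id = "x"),
                  class = c("dwell_records", "data.frame"))
  cv <- dwell_vs_step(dw, "+/+", window = 25)
  expect_true(all(abs(cv$t_mean - 0.4) < 1e-12))
  expect_true(all(cv$t_se < 1e-12))
  dw2 <- dw; dw2$t <- dw2$d
  cv2 <- dwell_vs_step(dw2, "+/+", window = 25)
  expect_equal(cv2$t_mean, cv2$d, tolerance = 1e-12)
  expect_error(dwell_vs_step(dw[1:10, ], "+/+", 25), "need >=")
})

test_that("trendline fits recover printed parameters exactly on clean points", {
  d <- seq(1, 6, by = 0.5)
  for (p in list(c(0.16, 2.6), c(-0.11, 5.1), c(0.22, 2.4), c(-0.29, 1.2))) {
    fit <- fit_trendline(d, p[1] * (d + p[2]))
    expect_equal(fit$kappa, p[1], tolerance = 1e-6)
    expect_equal(fit$d0, p[2], tolerance = 1e-6)
    expect_false(fit$degenerate)
  }
  flat <- fit_trendline(d, rep(2, length(d)))
  expect_true(flat$degenerate)
  expect_true(is.na(flat$d0))
})

test_that("trendline interval estimates cover the truth", {
  set.seed(42)
  cover <- replicate(60, {
    d <- seq(1, 6, length.out = 30)
    y <- 0.16 * (d + 2.6) + rnorm(30, 0, 0.05)
    f <- fit_trendline(d, y, se = rep(0.05, 30))
    abs(f$kappa - 0.16) <= 2 * f$kappa_se
  })
  expect_gte(mean(cover), 0.85)
})

test_that("n_min follows the moment formula and its analytic oracles", {
  a <- 1 / sqrt(2)
  r <- n_min(rep(c(1 - a, 1 + a), 10))
  expect_equal(r$t_mean, 1)
  expect_equal(r$t2_mean, 1.5)
  expect_equal(r$n_min, 2, tolerance = 1e-12)
  set.seed(43)
  expect_equal(n_min(rexp(1e4))$n_min, 1.0, tolerance = 0.05)
  expect_equal(n_min(rgamma(1e4, shape = 2, rate = 2))$n_min, 2.0,
               tolerance = 0.1)
  expect_equal(n_min(rgamma(1e4, shape = 3, rate = 3))$n_min, 3.0,
               tolerance = 0.15)
  # scale invariance
  t <- rgamma(500, 2, 2)
  expect_equal(n_min(t)$n_min, n_min(37.5 * t)$n_min, tolerance = 1e-12)
  # zero variance flagged
  z <- n_min(rep(1, 20))
  expect_true(z$degenerate)
  expect_true(is.infinite(z$n_min))
  expect_error(n_min(1:5), ">= 10")
})

test_that("heterogeneous rates depress n_min below the event count", {
  set.seed(44)
  t <- rexp(1e4, 1) + rexp(1e4, 10)   # two events, very different rates
  r <- n_min(t)
  expect_lt(r$n_min, 1.5)
  expect_gt(r$n_min, 1.0)
})

test_that("bootstrap outlier scan is specific on clean data and flags a gross outlier", {
  set.seed(45)
  clean <- rgamma(100, 2, 2)
  res <- nmin_outlier_scan(clean, n_boot = 800, seed = 450)
  expect_length(res$outliers, 0)
  spiked <- c(clean, 20 * mean(clean))
  res2 <- nmin_outlier_scan(spiked, n_boot = 800, seed = 451)
  expect_equal(res2$outliers, length(spiked))
  expect_length(res2$outliers, 1)
  expect_gt(res2$result$n_min, res2$result_raw$n_min)
  expect_error(nmin_outlier_scan(rexp(10)), ">= 30")
})

test_that("speed estimators match hand values and the kinetic closed form", {
  st <- make_steps(rep(3, 20), 0.1)
  dw <- structure(data.frame(t = rep(0.5, 20), class = "+/+", d = 3,
                             atp = 0.5, force = 12, trace_id = "x"),
                  class = c("dwell_records", "data.frame"))
  v <- speeds(st, dw, "unwinding")
  expect_equal(v$speed, 6)
  # noise-free ramp: line fit returns the slope
  tr <- make_trace(45 * seq(0, 2, by = 0.01), rate = 100)
  vl <- speeds(method = "line_fit", trace = tr,
               intervals = list(c(0, 2)))
  expect_equal(vl$speed, 45, tolerance = 1e-9)
  # auto-selected monotone runs pick up the ramp too
  vla <- speeds(method = "line_fit", trace = tr)
  expect_equal(vla$speed, 45, tolerance = 1)
  # generator at 10 uM: step-over-dwell speed matches Vmax * 10 / (KM + 10)
  set.seed(46)
  cfg <- generator_config(sample_rate = 267)
  recs <- lapply(1:8, function(i)
    extract_steps(detect_steps(
      simulate_trace(cfg, 10, 6, seed = 460 + i)$trace)))
  st10 <- structure(do.call(rbind, lapply(recs, as.data.frame)),
                    class = c("step_records", "data.frame"))
  dw10 <- classify_and_filter_dwells(st10)
  v10 <- speeds(st10, dw10, "unwinding")
  expect_equal(v10$speed, 220 * 10 / 49, tolerance = 0.25 * 220 * 10 / 49)
})

test_that("Michaelis-Menten fit is exact on clean curves and flags saturation", {
  atp <- c(0.5, 1, 2.5, 5, 10, 100, 250, 500, 1000)
  v <- 220 * atp / (39 + atp)
  fit <- fit_michaelis_menten(atp, v)
  expect_equal(fit$Vmax, 220, tolerance = 1e-5)
  expect_equal(fit$KM, 39, tolerance = 1e-5)
  # negative speeds keep their sign
  fitn <- fit_michaelis_menten(atp, -v)
  expect_equal(fitn$Vmax, -220, tolerance = 1e-4)
  flat <- fit_michaelis_menten(atp, rep(100, 9))
  expect_true(flat$saturated)
  expect_error(fit_michaelis_menten(c(1, 1, 1), c(1, 2, 3)), ">= 3")
})

test_that("Michaelis-Menten interval estimates cover the truth", {
  set.seed(47)
  atp <- c(0.5, 1, 2.5, 5, 10, 100, 250, 500, 1000)
  v0 <- 220 * atp / (39 + atp)
  cover <- replicate(60, {
    v <- v0 * (1 + rnorm(9, 0, 0.05))
    f <- fit_michaelis_menten(atp, v, se = 0.05 * v0)
    abs(f$Vmax - 220) <= 2 * f$Vmax_se && abs(f$KM - 39) <= 2.5 * f$KM_se
  })
  expect_gte(mean(cover), 0.8)
})

test_that("normalized dwell-vs-step trendlines collapse across ATP", {
  set.seed(48)
  curves <- lapply(c(0.5, 2.5), function(a) {
    recs <- lapply(1:10, function(i)
      extract_steps(detect_steps(
        simulate_trace(generator_config(), a, if (a < 1) 30 else 10,
                       seed = round(1000 * a) + i)$trace)))
    st <- structure(do.call(rbind, lapply(recs, as.data.frame)),
                    class = c("step_records", "data.frame"))
    dw <- classify_and_filter_dwells(st)
    cv <- dwell_vs_step(dw, "+/+", window = 25)
    cv$t_norm <- cv$t_mean / mean(dw$t[dw$class == "+/+"])
    cv
  })
  f1 <- fit_trendline(curves[[1]]$d, curves[[1]]$t_norm)
  f2 <- fit_trendline(curves[[2]]$d, curves[[2]]$t_norm)
  # dwell time grows with succeeding step size at both concentrations,
  # with comparable normalized slopes
  expect_gt(f1$kappa, 0)
  expect_gt(f2$kappa, 0)
  expect_lt(abs(f1$kappa - f2$kappa), 0.15)
})
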