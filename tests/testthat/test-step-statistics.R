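test_that("error-weighted KDE integrates to one and weights kernels by precision", {
  k1 <- step_size_kde(make_steps(3.0, 0.2))
  expect_equal(trapz_test(k1$grid, k1$density), 1, tolerance = 1e-6)
  expect_equal(k1$grid[which.max(k1$density)], 3.0, tolerance = 0.011)
  # two well-separated kernels give two resolvable peaks
  k2 <- step_size_kde(make_steps(c(2.5, 3.0), 0.1))
  d <- k2$density
  pk <- k2$grid[which(d[2:(length(d) - 1)] > d[1:(length(d) - 2)] &
                        d[2:(length(d) - 1)] >= d[3:length(d)]) + 1]
  expect_true(any(abs(pk - 2.5) < 0.05) && any(abs(pk - 3.0) < 0.05))
  # a precise kernel dominates a diffuse one at the shared center:
  # kernel heights scale as 1/sigma, so the 0.1-bp kernel contributes
  # 10x more than the 1.0-bp kernel at the peak
  k3 <- step_size_kde(make_steps(c(3, 3), c(0.1, 1.0)))
  at3 <- k3$density[which.min(abs(k3$grid - 3))]
  expect_gt(at3, 4 * dnorm(0, 0, 1) / 2)
  empty <- data.frame(s = numeric(0), sigma_s = numeric(0))
  expect_error(step_size_kde(empty), "no steps")
})

test_that("re-zipping KDE grid spans the negative axis", {
  k <- step_size_kde(make_steps(c(-3, -2.5), 0.1))
  expect_equal(k$side, "rezipping")
  expect_lte(max(k$grid), 0)
  expect_lte(min(k$grid), -3 - 3 * 0.1 + 0.011)
})

test_that("bootstrap band is zero for identical steps and reproducible", {
  k <- step_size_kde(make_steps(rep(3, 20), 0.1))
  b1 <- bootstrap_kde(k, n_boot = 200, seed = 31)
  expect_true(all(b1$se < 1e-6))
  set.seed(1); kk <- step_size_kde(make_steps(rnorm(40, 3, 0.8), 0.1))
  b2 <- bootstrap_kde(kk, n_boot = 300, seed = 7)
  b3 <- bootstrap_kde(kk, n_boot = 300, seed = 7)
  expect_identical(b2$se, b3$se)
  # band center stays near the plain KDE
  expect_true(all(abs(b2$boot_mean - kk$density) <= 2 * b2$se + 1e-8))
})

test_that("bootstrap band width shrinks like one over root n", {
  set.seed(32)
  widths <- vapply(c(50, 200, 800), function(n) {
    st <- make_steps(rnorm(n, 3, 0.5), 0.1)
    k <- bootstrap_kde(step_size_kde(st), n_boot = 400, seed = n)
    k$se[which.min(abs(k$grid - 3))]
  }, numeric(1))
  slope <- coef(lm(log(widths) ~ log(c(50, 200, 800))))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.15)
})

test_that("KDE periodicity reflects the half-integer step lattice", {
  # clean lattice: kernels at half-integer positions
  s <- rep(c(2, 2.5, 3, 3.5, 4), times = c(10, 25, 40, 25, 10))
  k <- bootstrap_kde(step_size_kde(make_steps(s, 0.05)), n_boot = 300,
                     seed = 33)
  per <- kde_periodicity(k)
  expect_equal(per$spacing, 0.5, tolerance = 0.02)
  # even-only nucleotide totals give integer (1.0 bp) spacing
  s2 <- rep(c(2, 3, 4), times = c(25, 50, 25))
  k2 <- bootstrap_kde(step_size_kde(make_steps(s2, 0.05)), n_boot = 300,
                      seed = 34)
  expect_equal(kde_periodicity(k2)$spacing, 1.0, tolerance = 0.02)
})

test_that("double-Gaussian EM recovers simulated mixtures", {
  set.seed(35)
  s <- rnorm(500, 3, 1)
  g1 <- fit_double_gaussian(s)
  expect_equal(g1$means[1], 3.0, tolerance = 0.2)
  expect_gte(g1$weights[1], 0.9)
  s2 <- c(rnorm(750, 3, 1), rnorm(250, 6, 0.8))
  g2 <- fit_double_gaussian(s2)
  expect_equal(g2$means[1], 3, tolerance = 0.3)
  expect_equal(g2$means[2], 6, tolerance = 0.3)
  expect_error(fit_double_gaussian(rnorm(19)), ">= 20")
})

test_that("EM agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  set.seed(36)
  s <- c(rnorm(600, 3, 0.9), rnorm(200, 6, 0.9))
  ours <- fit_double_gaussian(s)
  mc <- mclust::Mclust(s, G = 2, modelNames = "E", verbose = FALSE)
  expect_equal(sort(ours$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.1)
})

test_that("pairwise distances enumerate signed ordered pairs", {
  pd <- pairwise_distance_distribution(c(0, 0, 3, 3), bin = 0.5)
  nz <- rep(pd$mids, pd$counts)
  nz <- nz[abs(nz) > 0.25]
  expect_true(all(abs(nz - 3) < 0.3))
  # staircase of +3 steps: peaks at 3, 6, 9 and periodicity 3
  x <- rep(c(0, 3, 6, 9), each = 25)
  pd2 <- pairwise_distance_distribution(x)
  expect_equal(pd2$periodicity, 3, tolerance = 0.1)
  expect_error(pairwise_distance_distribution(1), ">= 2")
})

test_that("generator traces show 3-4 bp pairwise periodicity", {
  set.seed(37)
  sim <- simulate_trace(generator_config(), 0.5, 30, seed = 370)
  pd <- pairwise_distance_distribution(sim$trace$position)
  expect_gte(pd$periodicity, 2.5)
  expect_lte(pd$periodicity, 4.5)
})

test_that("covariate independence test behaves under null and alternative", {
  set.seed(38)
  st <- make_steps(rnorm(60, 3, 0.8), 0.1)
  st$force <- runif(60, 9, 15)
  null <- covariate_independence(st, "force", n_perm = 2000, seed = 1)
  expect_lt(abs(null$r), 0.35)
  expect_gt(null$p, 0.01)
  # exact dependence
  st2 <- make_steps(seq(1, 5, length.out = 30), 0.1)
  st2$force <- st2$s
  dep <- covariate_independence(st2, "force", n_perm = 10000, seed = 2)
  expect_equal(dep$r, 1, tolerance = 1e-12)
  expect_lte(dep$p, 1e-4 + 1e-6)
  st2$force <- rep(12, 30)
  expect_error(covariate_independence(st2, "force"), "constant")
})

test_that("step sizes from the generator are force independent", {
  set.seed(39)
  recs <- list()
  for (i in seq_along(ff <- c(9, 10.5, 12, 13.5, 15))) {
    sim <- simulate_trace(generator_config(), 0.5, 20, force = ff[i],
                          seed = 390 + i)
    recs[[i]] <- extract_steps(detect_steps(sim$trace))
  }
  st <- do.call(rbind, lapply(recs, as.data.frame))
  st <- structure(st[st$s > 0, ], class = c("step_records", "data.frame"))
  res <- covariate_independence(st, "force", n_perm = 2000, seed = 3)
  expect_gt(res$p, 0.01)
})
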