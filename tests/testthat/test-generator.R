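test_that("generator config validates pmfs and rates", {
  expect_error(generator_config(k_cat = -1), "positive")
  expect_error(generator_config(cycles_per_release = c(0.5, 0.6)), "sum to 1")
  expect_error(generator_config(noise_sd = -0.1), ">= 0")
  expect_error(generator_config(backstep_prob = 1), "\\[0, 1\\)")
  cfg <- generator_config()
  expect_s3_class(cfg, "gen_config")
  expect_equal(sum(cfg$cycles_per_release), 1)
  expect_equal(sum(seq_along(cfg$cycles_per_release) *
                     cfg$cycles_per_release), 3)
})

test_that("degenerate pmfs force constant steps on the half-integer lattice", {
  d3 <- release_distribution("3p", 3, 1)
  d5 <- release_distribution("5p", 3, 1)
  cfg <- generator_config(cycles_per_release = c(0, 0, 1), release_3p = d3,
                          release_5p = d5, noise_sd = 0, backstep_prob = 0)
  sim <- simulate_trace(cfg, atp = 5, duration = 5, seed = 1)
  jumps <- sim$events$events$dx_bp
  expect_true(length(jumps) > 3)
  expect_true(all(jumps == 3.0))
  # odd total nucleotides give half-integer steps
  # a large cap isolates the convolution arithmetic from cap enlargement
  cfg2 <- generator_config(cycles_per_release = c(0, 0, 1),
                           release_3p = release_distribution("3p", 2, 1),
                           release_5p = release_distribution("5p", 3, 1),
                           noise_sd = 0, backstep_prob = 0, loop_cap = 100)
  sim2 <- simulate_trace(cfg2, atp = 5, duration = 5, seed = 2)
  expect_true(all(sim2$events$events$dx_bp == 2.5))
})

test_that("zero-noise observed steps lie exactly on the 0.5-bp lattice", {
  cfg <- generator_config(noise_sd = 0)
  sim <- simulate_trace(cfg, atp = 2, duration = 20, seed = 3)
  dx <- sim$events$events$dx_bp
  expect_true(all(abs(2 * dx - round(2 * dx)) < 1e-12))
  pos <- unique(sim$trace$position)
  expect_true(all(abs(2 * pos - round(2 * pos)) < 1e-9))
})

test_that("nucleotide conservation holds at every event in all modes", {
  for (sd in 1:5) {
    cfg <- generator_config()
    sim <- simulate_trace(cfg, atp = 1, duration = 30, seed = sd)
    expect_invisible(check_conservation(sim$events))
    ev <- sim$events$events
    expect_true(all(ev$L3 >= 0 & ev$L5 >= 0))
    expect_true(all(ev$L3 <= cfg$loop_cap + length(cfg$cycles_per_release)))
    rel <- ev[ev$type == "release", ]
    expect_equal(rel$cum_released_nt, 2 * rel$h_bp - (rel$L3 + rel$L5))
  }
  simr <- simulate_trace(generator_config(), 1, 30, mode = "rezipping",
                         seed = 9)
  expect_invisible(check_conservation(simr$events))
  expect_true(all(simr$events$events$L3 >= 0))
})

test_that("steady-state mean observed step equals the mean cycles per release", {
  cfg <- generator_config(noise_sd = 0, backstep_prob = 0)
  sim <- simulate_trace(cfg, atp = 1000, duration = 140, seed = 5)
  ev <- sim$events$events
  expect_gt(nrow(ev), 9000)
  expect_lt(abs(mean(ev$dx_bp) - 3.0) / 3.0, 0.02)
  # waiting-cycle bookkeeping: cycle counts per event match pmf support
  expect_true(all(ev$cycles %in% seq_along(cfg$cycles_per_release)))
})

test_that("theoretical mean speed follows Michaelis-Menten identities", {
  cfg <- generator_config(k_cat = 220, k_on = 220 / 39)
  expect_error(mean_speed_theoretical(cfg, 0), "positive")
  # saturation limit and half-saturation identity
  expect_equal(mean_speed_theoretical(cfg, 1e9), 220, tolerance = 1e-6)
  expect_equal(mean_speed_theoretical(cfg, 39), 110, tolerance = 1e-12)
  # Monte-Carlo mean cycle rate matches the closed form
  set.seed(42)
  w <- simulate_cycle_times(cfg, 10, 1e5)
  mc <- 1 / mean(w)
  se <- mc^2 * sd(w) / sqrt(length(w))
  expect_lt(abs(mc - mean_speed_theoretical(cfg, 10)), 3 * se)
})

test_that("backsteps are rare, sign-flipped, and outside the loop bookkeeping", {
  cfg <- generator_config(noise_sd = 0)
  sim <- simulate_trace(cfg, atp = 1000, duration = 60, seed = 7)
  ev <- sim$events$events
  bs <- ev[ev$type == "backstep", ]
  expect_gt(nrow(bs), 0)
  expect_lt(nrow(bs) / nrow(ev), 0.12)
  expect_true(all(bs$dx_bp < 0))
  # released-nt tally unchanged across a backstep row
  i <- match(rownames(bs), rownames(ev))
  prev <- ifelse(i > 1, ev$cum_released_nt[i - 1], 0)
  expect_equal(bs$cum_released_nt, prev)
})

test_that("alternating mode switches direction with finite bursts", {
  cfg <- generator_config(noise_sd = 0)
  sim <- simulate_trace(cfg, atp = 100, duration = 30, mode = "alternating",
                        seed = 11)
  dh <- sim$events$cycles$dh
  expect_true(any(dh == 1) && any(dh == -1))
})

test_that("fixture sets are reproducible byte for byte and mirror the design", {
  cfg <- generator_config()
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  atp <- c(0.5, 1, 2.5, 5, 10)
  n <- c(3, 2, 1, 1, 1)  # scaled-down copy of the 25/16/12/12/12 design
  m1 <- make_fixture_set(cfg, atp, n, d1, seed = 5, duration = 2)
  m2 <- make_fixture_set(cfg, atp, n, d2, seed = 5, duration = 2)
  expect_equal(length(m1$traces), sum(n))
  expect_equal(vapply(m1$traces, `[[`, numeric(1), "atp"),
               rep(atp, times = n))
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  for (f in setdiff(f1, "manifest.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # empty design is allowed
  d3 <- file.path(tempdir(), "fx3")
  m3 <- make_fixture_set(cfg, numeric(0), integer(0), d3, seed = 1)
  expect_length(m3$traces, 0)
  expect_true(file.exists(file.path(d3, "manifest.json")))
})

test_that("simulate_trace rejects invalid inputs", {
  cfg <- generator_config()
  expect_error(simulate_trace(cfg, 1, -2), "positive")
  expect_error(simulate_trace(cfg, 0, 2), "positive")
})

test_that("unresolved-event merging sums jumps within the dead time", {
  cfg <- generator_config(sample_rate = 267)
  sim <- simulate_trace(cfg, 10, 5, seed = 13)
  ev <- sim$events$events
  rel <- ev[ev$dx_bp > 0, ]
  merged <- merge_unresolved_events(sim$events, dead_time = 0.015)
  expect_lte(length(merged), nrow(rel))
  expect_equal(sum(merged), sum(rel$dx_bp))
  # with a zero dead time nothing merges
  expect_equal(merge_unresolved_events(sim$events, 0), rel$dx_bp)
})
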