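# Construct a noise-free square-wave trace with known levels
square_trace <- function(voltage, i_open, n_cycles = 25, half = 100, fs = 5000) {
  cur <- rep(c(rep(0, half), rep(i_open, half)), n_cycles)
  structure(list(voltage = voltage, fs = fs, current = cur,
                 state = rep(c(rep(0L, half), rep(1L, half)), n_cycles),
                 open_level = i_open, config = NULL),
            class = "channel_trace")
}

test_that("simulate_trace honors length, levels and rate positivity", {
  m <- gating_model(k0_open = 20, k0_close = 20, gamma_pS = 100)
  cfg <- sim_config(fs = 5000, duration = 2, noise_sd = 0, filter_corner = NULL,
                    seed = 7)
  tr <- simulate_trace(m, 100, cfg)
  expect_length(tr$current, 10000L)
  expect_equal(tr$open_level, 10)  # 100 pS * 100 mV = 10 pA
  expect_setequal(unique(tr$current), c(0, 10))
  expect_equal(as.integer(tr$current > 5), tr$state)
  # k_oc effectively 0 -> all samples at the open level
  m2 <- gating_model(k0_open = 1000, k0_close = 1e-9, gamma_pS = 100)
  tr2 <- simulate_trace(m2, 100, cfg)
  expect_true(all(tr2$current == 10))
  expect_error(sim_config(fs = 1500, duration = 2, filter_corner = 1000), "corner")
})

test_that("dwell times are exponential with the stated means", {
  m <- gating_model(k0_open = 50, k0_close = 25, gamma_pS = 100)
  cfg <- sim_config(fs = 20000, duration = 20, noise_sd = 0, filter_corner = NULL,
                    seed = 8)
  tr <- simulate_trace(m, 80, cfg)
  r <- rle(tr$state)
  open_dwell <- r$lengths[r$values == 1L] / cfg$fs
  closed_dwell <- r$lengths[r$values == 0L] / cfg$fs
  # drop censored first/last dwells
  open_dwell <- open_dwell[2:(length(open_dwell) - 1)]
  closed_dwell <- closed_dwell[2:(length(closed_dwell) - 1)]
  se_o <- mean(open_dwell) / sqrt(length(open_dwell))
  se_c <- mean(closed_dwell) / sqrt(length(closed_dwell))
  expect_lt(abs(mean(open_dwell) - 1 / 25), 3 * se_o + 1 / cfg$fs)
  expect_lt(abs(mean(closed_dwell) - 1 / 50), 3 * se_c + 1 / cfg$fs)
})

test_that("idealize recovers exact boundaries of a noise-free square wave", {
  tr <- square_trace(100, 8)
  id <- idealize(tr)
  expect_equal(id$open_level, 8)
  expect_equal(id$closed_level, 0)
  expect_equal(id$state, tr$state)
  expect_equal(sum(id$segments$n_samples), length(tr$current))
  expect_equal(open_probability(id), 0.5)
  # states strictly alternate
  expect_true(all(id$segments$state[-1] != head(id$segments$state, -1)))
})

test_that("idealize single-level and degenerate contracts", {
  flat_open <- structure(list(voltage = 100, fs = 5000, current = rep(8, 2000)),
                         class = "channel_trace")
  id <- idealize(flat_open, single_level = TRUE)
  expect_equal(nrow(id$segments), 1L)
  expect_equal(id$segments$state, "open")
  expect_equal(open_probability(id), 1)
  flat_zero <- structure(list(voltage = 0, fs = 5000, current = rep(0, 2000)),
                         class = "channel_trace")
  id0 <- idealize(flat_zero, single_level = TRUE)
  expect_equal(open_probability(id0), 0)
  expect_error(idealize(flat_open), "degenerate")
})

test_that("idealize misassigns < 1% of samples at noise <= 20% of the open level", {
  m <- gating_model(k0_open = 20, k0_close = 20, gamma_pS = 100)
  for (seed in 1:3) {
    cfg <- sim_config(fs = 5000, duration = 10, noise_sd = 1.5,
                      filter_corner = NULL, seed = seed)
    tr <- simulate_trace(m, 100, cfg)  # open level 10 pA, noise 15%
    id <- idealize(tr)
    expect_lt(mean(id$state != tr$state), 0.01)
    expect_equal(sum(id$segments$n_samples), length(tr$current))
  }
})

test_that("Po matches the two-state stationary distribution within 3 s.e.", {
  for (case in list(c(20, 20), c(60, 20), c(10, 40))) {
    m <- gating_model(k0_open = case[1], k0_close = case[2], gamma_pS = 87)
    cfg <- sim_config(duration = 10, seed = 90 + case[1])
    tr <- simulate_trace(m, 80, cfg)
    id <- idealize(tr)
    po_hat <- open_probability(id)
    po <- case[1] / sum(case)
    n_events <- nrow(id$segments)
    se <- sqrt(po * (1 - po) / n_events)
    expect_lt(abs(po_hat - po), 3 * se)
    expect_true(po_hat >= 0 && po_hat <= 1)
  }
})

test_that("iv_and_conductance recovers exact arithmetic and guards fit_range", {
  traces <- lapply(c(40, 80, 120), function(V) square_trace(V, 0.1 * V))
  est <- iv_and_conductance(traces)
  expect_equal(est$gamma_pS, 100)
  expect_equal(est$iv$i, c(4, 8, 12))
  expect_error(iv_and_conductance(traces, fit_range = 40), "at least 2")
  expect_error(iv_and_conductance(traces, fit_range = c(40, 999)), "missing")
})

test_that("flicker artifact: fast gating depresses the negative branch only", {
  models <- flicker_reference_models(gamma_pS = 87)
  chk <- flicker_artifact_check(models$fast, models$slow, sim_config(seed = 12),
                                voltages = c(-120, -80, 80, 120))
  expect_true(chk$artifact_fast)
  expect_true(chk$no_artifact_slow)
  expect_lt(chk$ratio_fast, chk$ratio_slow)
  # with the filter off and high bandwidth, the artifact shrinks
  cfg_wide <- sim_config(fs = 50000, duration = 1, filter_corner = NULL, seed = 12)
  chk2 <- flicker_artifact_check(models$fast, models$slow, cfg_wide,
                                 voltages = c(-120, -80, 80, 120))
  expect_gt(chk2$ratio_fast, chk$ratio_fast)
})

test_that("traces and estimates round-trip through their text formats", {
  m <- gating_model(k0_open = 20, k0_close = 20, gamma_pS = 87)
  tr <- simulate_trace(m, 80, sim_config(duration = 0.5, seed = 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$voltage, 80)
  expect_equal(back$fs, 5000)
  expect_equal(back$current, tr$current, tolerance = 1e-4)
  est <- iv_and_conductance(lapply(c(40, 80, 120), function(V) square_trace(V, 0.1 * V)))
  stem <- withr::local_tempfile()
  write_channel_estimate(est, stem)
  js <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(js$gamma_pS, 100)
})
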