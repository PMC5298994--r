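test_that("junctional conductance implements the dual voltage-clamp formula", {
  # worked case: 40 pA over a 40 mV transjunctional difference -> 1 nS
  expect_equal(junctional_conductance(I_b = 40, V_a = -100, V_b = -60), 1.0)
  # uncoupled cells: zero current at every step -> zero conductance
  steps <- setdiff(seq(-100, 0, by = 20), -60)
  expect_equal(junctional_conductance(rep(0, length(steps)), steps, -60),
               rep(0, 5))
  # linearity in the current
  expect_equal(junctional_conductance(80, -100, -60),
               2 * junctional_conductance(40, -100, -60))
  # role swap with negated current gives the same conductance
  expect_equal(junctional_conductance(-40, -60, -100),
               junctional_conductance(40, -100, -60))
  expect_error(junctional_conductance(10, -60, -60), "undefined")
})

test_that("noiseless square waves idealize exactly", {
  # 4.5 pA openings with 100 ms dwells at 5 kHz
  rate <- 5000
  dwell <- 0.1
  cycle <- c(rep(0, dwell * rate), rep(4.5, dwell * rate))
  tr <- channel_trace(rep(cycle, 10), sampling_rate = rate)
  ev <- detect_events(tr)
  open <- ev[ev$state == "open", ]
  expect_equal(nrow(open), 10L)
  expect_equal(open$amplitude, rep(4.5, 10))
  expect_equal(open$end - open$start, rep(dwell, 10), tolerance = 1e-9)
  # dwell starts reproduce the generator grid to one sample
  expect_equal(open$start, dwell + 2 * dwell * (0:9), tolerance = 1 / rate)
  # transitions are instantaneous: 10-90% time within one sample
  expect_true(all(open$rise_ms <= 1000 / rate + 1e-9))
  # constant zero trace -> no events
  flat <- channel_trace(rep(0, 1000), sampling_rate = rate)
  expect_equal(nrow(detect_events(flat)), 0L)
})

test_that("noisy square waves recover amplitude within tolerance", {
  rate <- 5000
  cycle <- c(rep(0, 500), rep(4.5, 500))
  clean <- rep(cycle, 10)
  noisy <- withr::with_seed(9L, clean + stats::rnorm(length(clean), 0, 0.5))
  ev <- detect_events(channel_trace(noisy, sampling_rate = rate))
  open <- ev[ev$state == "open", ]
  expect_gte(nrow(open), 9L)
  expect_lt(abs(mean(open$amplitude) - 4.5), 0.15)
})

test_that("conductance and open probability are estimated from events", {
  rate <- 5000
  # single 4.5 pA event at +60 mV -> 75 pS
  tr <- channel_trace(c(rep(0, 1000), rep(4.5, 500), rep(0, 1000)),
                      sampling_rate = rate)
  est <- conductance_estimate(detect_events(tr), V = 60)
  expect_equal(est$modal_conductance, 75)
  expect_equal(est$open_probability, 500 / 2500)
  expect_equal(est$n_open_events, 1L)
  # always-open trace -> P_o = 1
  open_tr <- gen_channel_trace(g = 75, P_o = 1, V = 60, noise_sd = 0.5,
                               duration_s = 2, seed = 5)
  est1 <- conductance_estimate(detect_events(open_tr), V = 60)
  expect_equal(est1$open_probability, 1.0)
  # parameter recovery on a seeded 75 pS simulation
  sim <- gen_channel_trace(g = 75, P_o = 0.5, V = 60, noise_sd = 0.5,
                           duration_s = 20, seed = 11)
  est2 <- conductance_estimate(detect_events(sim), V = 60)
  expect_lte(abs(est2$modal_conductance - 75), 5)
  expect_error(conductance_estimate(detect_events(tr), V = 0), "V_rev")
  # histogram counts sum to the number of open events
  expect_equal(sum(est2$histogram$count), est2$n_open_events)
})

test_that("uptake slopes are recovered per phase with fold change and block", {
  phases <- data.frame(label = c("control", "DCFS", "DCFS+La"),
                       slope = c(2.4, 9.3, 0.5),
                       duration = c(5, 8, 5))
  tr <- gen_uptake_trace(phases, noise_sd = 0)
  rates <- uptake_rate(tr)
  expect_equal(rates$slope, phases$slope, tolerance = 1e-10)
  expect_equal(rates$fold_vs_first[2], 9.3 / 2.4, tolerance = 1e-10)
  expect_equal(attr(rates, "percent_block"), 100 * (1 - 0.5 / 9.3),
               tolerance = 1e-8)
  # noisy recovery within 10%
  trn <- gen_uptake_trace(phases, noise_sd = 0.5, seed = 21)
  rn <- uptake_rate(trn)
  expect_true(all(abs(rn$slope[1:2] - phases$slope[1:2]) /
                    phases$slope[1:2] < 0.10))
  # constant fluorescence -> slope 0
  const <- uptake_trace(seq(0, 5, 0.5), rep(3, 11),
                        data.frame(label = "a", t_start = 0, t_end = 5.1))
  expect_equal(uptake_rate(const)$slope, 0)
  # short phases are skipped with a warning
  short <- uptake_trace(c(0, 1, 2, 3), c(0, 1, 2, 3),
                        data.frame(label = c("tiny", "main"),
                                   t_start = c(0, 0.9), t_end = c(0.5, 3.5)))
  expect_warning(rs <- uptake_rate(short), "fewer than 3")
  expect_equal(rs$label, "main")
})

test_that("the calcium ratio is elementwise and gain-invariant", {
  expect_equal(ca_ratio(c(1, 2, 3), c(1, 2, 3)), c(1, 1, 1))
  expect_equal(ca_ratio(c(2, 4), c(1, 2)), c(2, 2))
  f340 <- c(1.2, 3.4, 0.7); f380 <- c(0.9, 1.1, 2.2)
  expect_equal(ca_ratio(5 * f340, 5 * f380), ca_ratio(f340, f380))
  expect_error(ca_ratio(c(1, 2), c(1, 0)), "positive")
  expect_error(ca_ratio(c(1, 2), c(1, 2, 3)), "equal lengths")
})
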