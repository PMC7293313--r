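test_that("white-noise traces reproduce the RMSSD closed form s*sqrt(2)", {
  s <- 15
  vals <- vapply(1:10, function(k) {
    sim <- simulate_ibi_trace(ibi_sim_params(noise_sd = s, duration = 1500,
                                             seed = 100 + k))
    rmssd(sim$trace$beats$ibi_ms)
  }, numeric(1))
  expect_equal(mean(vals), s * sqrt(2), tolerance = 0.03)
})

test_that("zero noise gives identical IBIs and RMSSD 0", {
  sim <- simulate_ibi_trace(ibi_sim_params(noise_sd = 0, duration = 300,
                                           seed = 1))
  expect_true(all(sim$trace$beats$ibi_ms == sim$trace$beats$ibi_ms[1L]))
  expect_identical(rmssd(sim$trace$beats$ibi_ms), 0)
})

test_that("AR(1) noise reduces RMSSD by sqrt(1 - phi) as predicted", {
  phi <- 0.6
  sim <- simulate_ibi_trace(ibi_sim_params(noise_sd = 15, noise_model = "ar1",
                                           ar1_coef = phi, duration = 3000,
                                           seed = 5))
  expect_equal(sim$truth$true_rmssd, 15 * sqrt(2 * (1 - phi)))
  expect_equal(rmssd(sim$trace$beats$ibi_ms), sim$truth$true_rmssd,
               tolerance = 0.06)
})

test_that("same params and seed give byte-identical outputs", {
  p <- ibi_sim_params(noise_sd = 12, duration = 600, seed = 77)
  a <- simulate_ibi_trace(p)
  b <- simulate_ibi_trace(p)
  expect_identical(a, b)
  cp <- colony_sim_params(seed = 42)
  expect_identical(simulate_colony(cp), simulate_colony(cp))
})

test_that("trace duration approximately matches the requested duration and the behaviour log partitions it", {
  p <- ibi_sim_params(duration = 900, seed = 3)
  sim <- simulate_ibi_trace(p)
  expect_lte(trace_duration(sim$trace), 900)
  expect_gt(trace_duration(sim$trace), 900 - 3 * p$mean_ibi / 1000)
  log <- sim$behaviour
  expect_equal(log$start_s[1L], 0)
  expect_equal(log$end_s[nrow(log)], 900)
  # contiguous intervals, alternating Resting
  expect_equal(log$start_s[-1L], log$end_s[-nrow(log)])
  expect_true(all(diff(log$state == "Resting") != 0))
})

test_that("parameter validation rejects invalid generator settings", {
  expect_error(ibi_sim_params(mean_ibi = -1), "mean_ibi")
  expect_error(ibi_sim_params(noise_sd = -2), "noise_sd")
  expect_error(ibi_sim_params(ar1_coef = 1), "ar1_coef")
  expect_error(artefact_spec(p_missed_beat = 1.5), "probabilities")
  expect_error(artefact_spec(flat_len = 1), "run lengths")
})

test_that("missed/extra beat injection conserves total duration to the millisecond", {
  sim <- simulate_ibi_trace(ibi_sim_params(duration = 1200, seed = 8))
  art <- inject_artefacts(sim$trace,
                          artefact_spec(p_missed_beat = 0.02,
                                        p_extra_beat = 0.02, seed = 4))
  expect_gt(nrow(art$ledger), 0L)
  expect_equal(sum(art$trace$beats$ibi_ms), sum(sim$trace$beats$ibi_ms),
               tolerance = 1e-9)
})

test_that("zero-rate artefact spec returns the input unchanged with empty ledger", {
  sim <- simulate_ibi_trace(ibi_sim_params(duration = 600, seed = 2))
  art <- inject_artefacts(sim$trace, artefact_spec(seed = 1))
  expect_equal(art$trace$beats$ibi_ms, sim$trace$beats$ibi_ms)
  expect_identical(nrow(art$ledger), 0L)
})

test_that("an injected extra beat splits one IBI into two parts summing to the original", {
  tr <- flat_trace(800, 50)
  art <- inject_artefacts(tr, artefact_spec(p_extra_beat = 0.2, seed = 11))
  splits <- art$ledger[art$ledger$type == "extra_beat", ]
  expect_gt(nrow(splits), 0L)
  for (r in seq_len(nrow(splits))) {
    i <- splits$index[r]
    expect_equal(sum(art$trace$beats$ibi_ms[i:(i + 1L)]), 800)
  }
})

test_that("injected flats are found by the detector exactly at the ledger position", {
  sim <- simulate_ibi_trace(ibi_sim_params(duration = 1200, seed = 21))
  art <- inject_artefacts(sim$trace,
                          artefact_spec(n_flats = 1, flat_len = 5, seed = 13))
  led <- art$ledger[art$ledger$type == "flat", ]
  runs <- detect_flat_stair_runs(art$trace, cleaning_config())
  flats <- runs[runs$kind == "flat", ]
  expect_identical(nrow(flats), 1L)
  expect_identical(flats$start_index, led$index)
  expect_identical(flats$length, led$length)
})
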