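cfg <- cleaning_config()

test_that("a clean trace passes through correction untouched", {
  sim <- simulate_ibi_trace(ibi_sim_params(noise_sd = 10, duration = 600,
                                           seed = 14))
  out <- correct_artefacts(sim$trace, cfg)
  expect_equal(out$beats$ibi_ms, sim$trace$beats$ibi_ms)
  expect_identical(nrow(out$corrections), 0L)
})

test_that("a split extra-beat pair is merged back and duration conserved", {
  x <- c(rep(800, 5), 400, 400, rep(800, 5))
  out <- correct_artefacts(ibi_trace(x), cfg)
  expect_equal(out$beats$ibi_ms, rep(800, 11))
  expect_equal(sum(out$beats$ibi_ms), sum(x))
  expect_identical(out$corrections$kind, "merged_extra_beat")
})

test_that("a merged missed-beat IBI is interpolated into equal parts", {
  x <- c(rep(800, 5), 1600, rep(800, 5))
  out <- correct_artefacts(ibi_trace(x), cfg)
  expect_equal(out$beats$ibi_ms, rep(800, 12))
  expect_identical(out$corrections$kind, "interpolated_missed_beat")
  # a tripled IBI gets three parts: round(2400/800) = 3
  x3 <- c(rep(800, 5), 2400, rep(800, 5))
  out3 <- correct_artefacts(ibi_trace(x3), cfg)
  expect_equal(out3$beats$ibi_ms, rep(800, 13))
})

test_that("correction is idempotent", {
  sim <- simulate_ibi_trace(ibi_sim_params(duration = 900, seed = 31))
  art <- inject_artefacts(sim$trace,
                          artefact_spec(p_missed_beat = 0.02,
                                        p_extra_beat = 0.02, seed = 6))
  once <- correct_artefacts(art$trace, cfg)
  twice <- correct_artefacts(once, cfg)
  expect_equal(twice$beats$ibi_ms, once$beats$ibi_ms)
  expect_identical(nrow(twice$corrections), 0L)
})

test_that("traces shorter than the median window come back flagged, not corrected", {
  tr <- flat_trace(800, 5)
  expect_warning(out <- correct_artefacts(tr, cfg), "shorter")
  expect_true("too_short" %in% out$flags)
  expect_equal(out$beats$ibi_ms, tr$beats$ibi_ms)
})

test_that("flat and stair detection finds canonical constructed runs", {
  runs <- detect_flat_stair_runs(ibi_trace(c(800, 800, 800, 800, 800, 810, 795)),
                                 cfg)
  expect_identical(nrow(runs), 1L)
  expect_identical(runs$kind, "flat")
  expect_identical(runs$start_index, 1L)
  expect_identical(runs$length, 5L)

  runs <- detect_flat_stair_runs(ibi_trace(c(700, 710, 720, 730)), cfg)
  expect_identical(runs$kind, "stair")
  expect_identical(runs$length, 4L)
})

test_that("run detection agrees with a brute-force oracle on random traces", {
  set.seed(99)
  for (rep in 1:30) {
    # coarse quantization makes flats/stairs common enough to exercise
    x <- 800 + 10 * sample(-2:2, 60, replace = TRUE)
    tr <- ibi_trace(x)
    got <- detect_flat_stair_runs(tr, cfg)
    flats <- got[got$kind == "flat", c("start_index", "length")]
    stairs <- got[got$kind == "stair", c("start_index", "length")]
    rownames(flats) <- rownames(stairs) <- NULL
    expect_equal(flats,
                 brute_force_runs(x, "flat", cfg$flat_min_run, cfg$flat_tol_ms),
                 ignore_attr = TRUE)
    expect_equal(stairs,
                 brute_force_runs(x, "stair", cfg$stair_min_run,
                                  cfg$stair_step_tol_ms),
                 ignore_attr = TRUE)
  }
})

test_that("white-noise traces contain almost no flat/stair beats", {
  sim <- simulate_ibi_trace(ibi_sim_params(noise_sd = 20, duration = 3000,
                                           seed = 55))
  res <- process_trace(sim$trace, whole_span_log(3000))
  frac <- res$windows$flatstair_fraction
  expect_gte(mean(frac < 0.01), 0.95)
})

test_that("windowing follows the half-open 300-s convention", {
  # 1000 s of exact 1000-ms beats -> 3 complete windows, final 100 s dropped
  tr <- ibi_trace(rep(1000, 1000))
  w <- segment_windows(tr, cfg)
  expect_identical(nrow(w), 3L)
  expect_equal(w$start_s, c(0, 300, 600))
  # beat ending exactly at 300.0 s belongs to the second window
  idx300 <- which(abs(tr$beats$end_time_s - 300) < 1e-9)
  expect_true(idx300 %in% w$beat_idx[[2L]])
  expect_false(idx300 %in% w$beat_idx[[1L]])
  # 299 s -> no window
  expect_identical(nrow(segment_windows(ibi_trace(rep(1000, 299)), cfg)), 0L)
})

test_that("beat-time gaps split the trace into independently windowed segments", {
  x <- rep(1000, 700)
  tr <- ibi_trace(x)
  tr$beats$end_time_s[351:700] <- tr$beats$end_time_s[351:700] + 60  # 60 s dropout
  w <- segment_windows(tr, cfg)
  expect_identical(unique(w$segment), c(1L, 2L))
  expect_identical(nrow(w), 2L)  # 350 s per segment -> one window each
})

test_that("retention filters drop windows for the documented reasons", {
  n <- 300
  tr <- ibi_trace(rep(1000, n))
  w <- segment_windows(tr, cfg)

  # 100% resting -> retained
  a <- annotate_and_filter(w, tr, whole_span_log(300), empty_runs(), cfg)
  expect_true(a$retained[1L])

  # 94% resting (quiet non-rest remainder) -> dropped as low_resting
  log94 <- behaviour_log(c(0, 282), c(282, 300), c("Resting", "Alert"))
  a <- annotate_and_filter(w, tr, log94, empty_runs(), cfg)
  expect_false(a$retained[1L])
  expect_identical(a$drop_reason[1L], "low_resting")

  # 96% resting but the rest is locomotion -> dropped as disqualifying
  log96 <- behaviour_log(c(0, 288), c(288, 300), c("Resting", "Locomotion"))
  a <- annotate_and_filter(w, tr, log96, empty_runs(), cfg)
  expect_false(a$retained[1L])
  expect_identical(a$drop_reason[1L], "disqualifying_state")

  # > 5% of beats inside a flat run -> dropped as flatstair
  runs <- data.frame(kind = "flat", start_index = 1L, length = 20L)
  a <- annotate_and_filter(w, tr, whole_span_log(300), runs, cfg)
  expect_false(a$retained[1L])
  expect_identical(a$drop_reason[1L], "flatstair")

  # empty behaviour log -> all Unknown, dropped with its own reason code
  a <- annotate_and_filter(w, tr, behaviour_log(numeric(0), numeric(0),
                                                character(0)),
                           empty_runs(), cfg)
  expect_false(a$retained[1L])
  expect_identical(a$drop_reason[1L], "no_behaviour")
})

test_that("tightening thresholds never increases the retained-window count", {
  sim <- simulate_ibi_trace(ibi_sim_params(duration = 3000,
                                           rest_bout_mean = 200,
                                           active_bout_mean = 100, seed = 9))
  res <- process_trace(sim$trace, sim$behaviour, cfg)
  base_kept <- sum(res$windows$retained)
  for (rmin in c(0.90, 0.95, 0.99, 1.0)) {
    cfg2 <- cleaning_config(resting_min_fraction = rmin)
    r2 <- process_trace(sim$trace, sim$behaviour, cfg2)
    if (rmin <= cfg$resting_min_fraction) {
      expect_gte(sum(r2$windows$retained), base_kept)
    } else {
      expect_lte(sum(r2$windows$retained), base_kept)
    }
  }
  cfg3 <- cleaning_config(flatstair_max_fraction = 0)
  r3 <- process_trace(sim$trace, sim$behaviour, cfg3)
  expect_lte(sum(r3$windows$retained), base_kept)
})
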