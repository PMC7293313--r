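## Simulation-study drivers: each function runs one parameter-recovery study
## under the generator's study conditions and returns the measured
## quantities. The test suite and the acceptance script assert on these
## measurements; the functions themselves only measure.

#' White-noise RMSSD recovery study
#'
#' Simulates `n_traces` white-noise IBI traces and compares the mean
#' per-window RMSSD against the closed form `noise_sd * sqrt(2)`.
#'
#' @param n_traces number of traces.
#' @param noise_sd white-noise SD, ms.
#' @param duration trace duration, s.
#' @param seed integer seed.
#' @return list: `mean_rmssd`, `expected`, `rel_err` (|mean/expected - 1|),
#'   `n_windows`.
#' @export
measure_rmssd_recovery <- function(n_traces = 50L, noise_sd = 15,
                                   duration = 1500, seed = 1L) {
  cfg <- cleaning_config()
  vals <- unlist(lapply(seq_len(n_traces), function(k) {
    sim <- simulate_ibi_trace(ibi_sim_params(
      noise_sd = noise_sd, duration = duration,
      seed = derive_seed(seed, paste0("rmssd", k))))
    w <- segment_windows(sim$trace, cfg)
    vapply(w$beat_idx, function(idx) rmssd(sim$trace$beats$ibi_ms[idx]),
           numeric(1))
  }))
  expected <- noise_sd * sqrt(2)
  list(mean_rmssd = mean(vals), expected = expected,
       rel_err = abs(mean(vals) / expected - 1), n_windows = length(vals))
}

#' Artefact round-trip study
#'
#' Corrupts clean traces with 1% missed and 1% extra beats, then measures
#' how far the mean window RMSSD of the uncorrected and corrected traces
#' sits from the clean trace's value.
#'
#' @param n_traces number of traces.
#' @param p_missed,p_extra per-beat artefact probabilities.
#' @param noise_sd,duration trace generator settings.
#' @param seed integer seed.
#' @return list: `clean_rmssd`, `uncorrected_rel_err`, `corrected_rel_err`
#'   (relative deviations of the mean window RMSSD from clean).
#' @export
measure_artefact_roundtrip <- function(n_traces = 10L, p_missed = 0.01,
                                       p_extra = 0.01, noise_sd = 15,
                                       duration = 3000, seed = 1L) {
  cfg <- cleaning_config()
  win_rmssd <- function(trace) {
    w <- segment_windows(trace, cfg)
    mean(vapply(w$beat_idx, function(idx) rmssd(trace$beats$ibi_ms[idx]),
                numeric(1)))
  }
  res <- vapply(seq_len(n_traces), function(k) {
    sim <- simulate_ibi_trace(ibi_sim_params(
      noise_sd = noise_sd, duration = duration,
      seed = derive_seed(seed, paste0("rt", k))))
    art <- inject_artefacts(sim$trace, artefact_spec(
      p_missed_beat = p_missed, p_extra_beat = p_extra,
      seed = derive_seed(seed, paste0("rtart", k))))
    corr <- correct_artefacts(art$trace, cfg)
    c(clean = win_rmssd(sim$trace), raw = win_rmssd(art$trace),
      corrected = win_rmssd(corr))
  }, numeric(3))
  clean <- mean(res["clean", ])
  list(clean_rmssd = clean,
       uncorrected_rel_err = abs(mean(res["raw", ]) / clean - 1),
       corrected_rel_err = abs(mean(res["corrected", ]) / clean - 1))
}

#' Deterministic filter fixture
#'
#' Builds a three-window trace in which window 1 is clean and fully
#' Resting, window 2 contains a 20-beat flat run (a 6.7% flat fraction),
#' and window 3 is 94% Resting, then runs annotation and filtering.
#'
#' @return the annotated window table (3 rows) with an `rmssd_ms` column.
#' @export
filter_determinism_fixture <- function() {
  cfg <- cleaning_config()
  ## alternating 980/1020 ms beats: no flats, no stairs, mean 1 beat/s
  x <- rep(c(980, 1020), 450)
  x[320:339] <- 1000  # flat run entirely inside window 2
  trace <- ibi_trace(x)
  log <- behaviour_log(c(0, 600, 618), c(600, 618, 901),
                       c("Resting", "Alert", "Resting"))
  runs <- detect_flat_stair_runs(trace, cfg)
  w <- segment_windows(trace, cfg)
  annotate_and_filter(w, trace, log, runs, cfg)
}

#' Repeatability recovery study
#'
#' Simulates `n_datasets` colonies at the study size (57 mothers, ~95
#' mother-year rows, true repeatability 0.63 by construction), estimates R
#' with a parametric bootstrap CI on each, and summarises bias and CI
#' coverage.
#'
#' @param n_datasets number of simulated colonies.
#' @param n_boot bootstrap replicates per dataset.
#' @param seed integer seed.
#' @param params colony parameters (defaults are the study conditions).
#' @return list: `true_R`, `mean_R`, `bias`, `coverage` (fraction of CIs
#'   covering the truth), `R_values`.
#' @export
measure_repeatability_recovery <- function(n_datasets = 100L, n_boot = 200L,
                                           seed = 1L,
                                           params = colony_sim_params()) {
  true_R <- NA_real_
  res <- vapply(seq_len(n_datasets), function(k) {
    p <- params
    p$seed <- derive_seed(seed, paste0("colony", k))
    col <- simulate_colony(p)
    true_R <<- col$truth$true_repeatability
    r <- estimate_repeatability(col$hrv, n_boot = n_boot,
                                seed = derive_seed(seed, paste0("boot", k)))
    c(R = r$R, lo = r$ci[1], hi = r$ci[2])
  }, numeric(3))
  list(true_R = true_R, mean_R = mean(res["R", ]),
       bias = mean(res["R", ]) - true_R,
       coverage = mean(res["lo", ] <= true_R & true_R <= res["hi", ]),
       R_values = unname(res["R", ]))
}

#' Heteroscedasticity recovery study
#'
#' For each replicate a colony is simulated, the analysis table built, and
#' the deviance-modulus models for maternal daily mass loss and pup daily
#' mass gain (`dev ~ HRV + birthdate + (1|id)`, the retained structure)
#' fitted by REML. A replicate scores a detection when the HRV coefficient
#' is positive with p < 0.05 in both models.
#'
#' @param n_reps replicates.
#' @param slope residual-SD log-linear HRV slope of the generator (the
#'   default study condition for the signal arm; 0 gives the null arm).
#' @param seed integer seed.
#' @param joint if `TRUE` (default) a detection requires both responses;
#'   otherwise either.
#' @return list: `rate` (detections / n_reps), `per_response` rates,
#'   `slope`.
#' @export
measure_heteroscedasticity_recovery <- function(n_reps = 100L,
                                                slope = NULL, seed = 1L,
                                                joint = TRUE) {
  base <- colony_sim_params()
  if (is.null(slope)) slope <- base$resid_log_sd_hrv_slope
  hits <- vapply(seq_len(n_reps), function(k) {
    p <- colony_sim_params(resid_log_sd_hrv_slope = slope,
                           seed = derive_seed(seed, paste0("het", k)))
    col <- simulate_colony(p)
    tab <- build_analysis_table(col$captures, col$hrv)
    vapply(c("z_dev_mdml", "z_dev_pdmg"), function(resp) {
      f <- fit_lmm(resp, c("hrv", "birthdate"), tab, REML = TRUE)
      ct <- f$coef_table[f$coef_table$term == "hrv", ]
      ct$estimate > 0 && ct$p < 0.05
    }, logical(1))
  }, logical(2))
  per <- rowMeans(hits)
  rate <- if (joint) mean(hits[1, ] & hits[2, ]) else mean(hits[1, ] | hits[2, ])
  list(rate = rate,
       per_response = c(dev_MDML = unname(per[1]), dev_PDMG = unname(per[2])),
       slope = slope, joint = joint)
}
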