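## Time-domain HRV: RMSSD per window, aggregated to seal-season and
## across-year resting-HRV estimates. Low resting HRV marks proactive
## (sympathetically dominated) copers, high resting HRV reactive
## (parasympathetically dominated) ones.

#' Root mean square of successive differences
#'
#' `sqrt(mean(diff(ibis)^2))` over the n - 1 successive differences within a
#' window. Differences never span window boundaries; callers pass only the
#' IBIs of one window.
#'
#' @param ibis ordered numeric vector of IBIs (ms), length >= 2, all > 0.
#' @return RMSSD in ms.
#' @examples
#' rmssd(c(800, 810, 800, 810, 800))  # 10
#' @export
rmssd <- function(ibis) {
  check_that(length(ibis) >= 2L, "RMSSD needs at least 2 IBIs")
  check_that(all(ibis > 0), "IBIs must be positive")
  sqrt(mean(diff(ibis)^2))
}

#' Seal-season resting HRV
#'
#' The median RMSSD over all retained 300-s windows of one seal-season.
#' Seasons with fewer than `min_windows` windows are kept but flagged
#' insufficient (the field minimum observed was three windows).
#'
#' @param window_rmssd numeric vector of per-window RMSSD values (ms).
#' @param seal_id,year identifiers.
#' @param min_windows flag threshold (default 3).
#' @return a one-row data.frame: `id`, `year`, `resting_hrv_ms`,
#'   `n_windows`, `insufficient`.
#' @export
season_resting_hrv <- function(window_rmssd, seal_id = "S1", year = 1L,
                               min_windows = 3L) {
  window_rmssd <- window_rmssd[!is.na(window_rmssd)]
  check_that(length(window_rmssd) >= 1L,
             "no retained windows for seal %s year %s", seal_id, year)
  data.frame(id = seal_id, year = year,
             resting_hrv_ms = stats::median(window_rmssd),
             n_windows = length(window_rmssd),
             insufficient = length(window_rmssd) < min_windows,
             stringsAsFactors = FALSE)
}

#' Across-year individual resting HRV
#'
#' The median of an individual's seasonal resting-HRV values across all
#' observed years. This is the coping-style covariate used in the
#' performance models (keeping the ID random effect distinct from the
#' highly individual HRV measure).
#'
#' @param seasonal data.frame with columns `id`, `resting_hrv_ms` (one row
#'   per season).
#' @return data.frame: `id`, `hrv_ms`, `n_years`.
#' @export
across_year_hrv <- function(seasonal) {
  check_that(nrow(seasonal) >= 1L, "need at least one season")
  agg <- stats::aggregate(resting_hrv_ms ~ id, data = seasonal,
                          FUN = stats::median)
  cnt <- stats::aggregate(resting_hrv_ms ~ id, data = seasonal, FUN = length)
  out <- data.frame(id = agg$id, hrv_ms = agg$resting_hrv_ms,
                    n_years = cnt$resting_hrv_ms, stringsAsFactors = FALSE)
  out[order(out$id), , drop = FALSE]
}
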