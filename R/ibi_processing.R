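## IBI cleaning and window-level quality control.
##
## Raw beat-to-beat series from field telemetry carry artefacts: spurious
## extra beats (extreme short IBIs), missed beats (extreme long IBIs), and
## uncorrectable device failure runs -- flats (invariable IBIs) and stairs
## (monotone ramps). Correction uses a local-median filter: an IBI outside
## [short_factor, long_factor] times its local running median is either
## merged with a neighbour (extra-beat deletion) or split into equal
## sub-intervals (missed-beat interpolation); both operations conserve the
## total recording duration. Traces are then cut into non-overlapping 300-s
## windows, each IBI is labelled with the behavioural state active at the
## R-peak that ends it, and windows are retained only when >= 95% of IBIs
## are Resting, no high-energy states occur, and <= 5% of IBIs sit in
## flat/stair runs.

#' Cleaning and retention configuration
#'
#' @param ibi_min_ms,ibi_max_ms absolute physiological bounds, ms.
#' @param local_window running-median window, beats (odd).
#' @param short_factor,long_factor multiples of the local median delimiting
#'   acceptable IBIs.
#' @param flat_min_run minimum beats for a flat run.
#' @param flat_tol_ms equality tolerance within a flat (0 = exact at device
#'   precision).
#' @param stair_min_run minimum beats for a stair run.
#' @param stair_step_tol_ms tolerance on equality of successive stair steps
#'   (0 = exact: device-generated stairs interpolate with identical
#'   1-ms-quantized increments, and a looser tolerance flags too many
#'   chance monotone runs in genuinely noisy traces).
#' @param max_corrected_fraction window-level cap on corrected beats.
#' @param resting_min_fraction minimum fraction of Resting IBIs per window.
#' @param flatstair_max_fraction maximum fraction of IBIs in flat/stair runs.
#' @param disqualifying_states high-energy states that disqualify a window
#'   outright.
#' @param window_s analysis window length, seconds.
#' @param gap_split_s beat-time gaps longer than this split the trace into
#'   independently windowed segments.
#' @return a `cleaning_config` list.
#' @export
cleaning_config <- function(ibi_min_ms = 250, ibi_max_ms = 3000,
                            local_window = 11L,
                            short_factor = 0.7, long_factor = 1.3,
                            flat_min_run = 3L, flat_tol_ms = 0,
                            stair_min_run = 4L, stair_step_tol_ms = 0,
                            max_corrected_fraction = 0.05,
                            resting_min_fraction = 0.95,
                            flatstair_max_fraction = 0.05,
                            disqualifying_states = c("Locomotion",
                                                     "Aggression"),
                            window_s = 300, gap_split_s = 5) {
  check_that(short_factor > 0 && short_factor < 1 && long_factor > 1,
             "need 0 < short_factor < 1 < long_factor")
  check_that(local_window %% 2L == 1L && local_window >= 3L,
             "local_window must be odd and >= 3")
  check_that(resting_min_fraction >= 0 && resting_min_fraction <= 1 &&
             flatstair_max_fraction >= 0 && flatstair_max_fraction <= 1 &&
             max_corrected_fraction >= 0 && max_corrected_fraction <= 1,
             "fractions must be in [0, 1]")
  check_that(flat_min_run >= 2L && stair_min_run >= 2L,
             "minimum run lengths must be >= 2")
  structure(list(ibi_min_ms = ibi_min_ms, ibi_max_ms = ibi_max_ms,
                 local_window = as.integer(local_window),
                 short_factor = short_factor, long_factor = long_factor,
                 flat_min_run = as.integer(flat_min_run),
                 flat_tol_ms = flat_tol_ms,
                 stair_min_run = as.integer(stair_min_run),
                 stair_step_tol_ms = stair_step_tol_ms,
                 max_corrected_fraction = max_corrected_fraction,
                 resting_min_fraction = resting_min_fraction,
                 flatstair_max_fraction = flatstair_max_fraction,
                 disqualifying_states = disqualifying_states,
                 window_s = window_s, gap_split_s = gap_split_s),
            class = "cleaning_config")
}

#' Correct missed/extra-beat artefacts with a local-median filter
#'
#' Each IBI is compared against its running local median m. Extreme long
#' IBIs (missed beats) are replaced by `round(ibi / m)` equal sub-intervals;
#' extreme short IBIs (spurious extra beats) are merged with the following
#' (preferred) or preceding IBI when the sum falls back inside
#' `[short_factor * m, long_factor * m]`. Corrections conserve total
#' duration exactly and are listed in the trace's ledger (positions index
#' the corrected trace).
#'
#' @param trace an `ibi_trace`.
#' @param cfg a [cleaning_config()].
#' @return the corrected `ibi_trace`; `$flags` gains `"too_short"` when the
#'   trace is shorter than the median window (returned uncorrected) and
#'   `"overcorrected"` when the corrected-beat fraction exceeds
#'   `max_corrected_fraction`.
#' @export
correct_artefacts <- function(trace, cfg = cleaning_config()) {
  stopifnot(inherits(trace, "ibi_trace"), inherits(cfg, "cleaning_config"))
  x <- trace$beats$ibi_ms
  n <- length(x)
  start_s <- trace$beats$end_time_s[1L] - x[1L] / 1000
  if (n < cfg$local_window) {
    trace$flags <- union(trace$flags, "too_short")
    warning("trace shorter than local median window; returned uncorrected")
    return(trace)
  }
  m <- stats::runmed(x, cfg$local_window, endrule = "median")
  lo <- pmax(cfg$short_factor * m, cfg$ibi_min_ms)
  hi <- pmin(cfg$long_factor * m, cfg$ibi_max_ms)

  out <- numeric(0); corr <- logical(0)
  ledger <- empty_correction_ledger()
  add_event <- function(idx, kind, orig) {
    ledger <<- rbind(ledger, data.frame(index = idx, kind = kind,
                                        original_ms = orig,
                                        stringsAsFactors = FALSE))
  }
  i <- 1L
  while (i <= n) {
    xi <- x[i]
    if (xi > hi[i]) {
      k <- max(2L, as.integer(round(xi / m[i])))
      add_event(length(out) + 1L, "interpolated_missed_beat", xi)
      out <- c(out, rep(xi / k, k))
      corr <- c(corr, rep(TRUE, k))
      i <- i + 1L
    } else if (xi < lo[i]) {
      if (i < n && (xi + x[i + 1L]) >= lo[i] && (xi + x[i + 1L]) <= hi[i]) {
        add_event(length(out) + 1L, "merged_extra_beat", xi)
        out <- c(out, xi + x[i + 1L])
        corr <- c(corr, TRUE)
        i <- i + 2L
      } else if (length(out) > 0L &&
                 (out[length(out)] + xi) >= lo[i] &&
                 (out[length(out)] + xi) <= hi[i]) {
        add_event(length(out), "merged_extra_beat", xi)
        out[length(out)] <- out[length(out)] + xi
        corr[length(corr)] <- TRUE
        i <- i + 1L
      } else {
        ## uncorrectable short beat; leave in place
        out <- c(out, xi); corr <- c(corr, FALSE)
        i <- i + 1L
      }
    } else {
      out <- c(out, xi); corr <- c(corr, FALSE)
      i <- i + 1L
    }
  }
  res <- ibi_trace(out, seal_id = trace$seal_id, year = trace$year,
                   start_s = start_s, corrected = corr)
  res$corrections <- ledger
  if (nrow(ledger) / n > cfg$max_corrected_fraction) {
    res$flags <- union(res$flags, "overcorrected")
  }
  res
}

## all maximal intervals [i, j] (1-based, inclusive) satisfying a hereditary
## predicate ok(i, j), with run length >= min_len. ok must stay TRUE on any
## subinterval of a TRUE interval, which makes the two-pointer scan exact.
maximal_runs <- function(n, ok, min_len) {
  starts <- integer(0); ends <- integer(0)
  j <- 0L; j_hi <- 0L
  for (i in seq_len(n)) {
    if (j < i) j <- i
    while (j < n && ok(i, j + 1L)) j <- j + 1L
    if (j - i + 1L >= min_len && j > j_hi) {
      starts <- c(starts, i); ends <- c(ends, j)
      j_hi <- j
    }
  }
  data.frame(start_index = starts, length = ends - starts + 1L)
}

#' Detect flat and stair artefact runs
#'
#' Flats are maximal runs of IBIs equal within `flat_tol_ms` (range of the
#' run at most the tolerance) of length >= `flat_min_run`. Stairs are
#' maximal strictly monotone runs of length >= `stair_min_run` whose
#' successive differences agree within `stair_step_tol_ms`. These artefact
#' shapes cannot be corrected and are only flagged for window-level
#' filtering.
#'
#' @inheritParams correct_artefacts
#' @return data.frame with columns `kind` (`"flat"`/`"stair"`),
#'   `start_index`, `length`.
#' @export
detect_flat_stair_runs <- function(trace, cfg = cleaning_config()) {
  x <- trace$beats$ibi_ms
  n <- length(x)
  flat_ok <- function(i, j) {
    v <- x[i:j]
    max(v) - min(v) <= cfg$flat_tol_ms + 1e-9
  }
  stair_ok <- function(i, j) {
    d <- diff(x[i:j])
    (all(d > 0) || all(d < 0)) &&
      (max(d) - min(d) <= cfg$stair_step_tol_ms + 1e-9)
  }
  flats <- maximal_runs(n, flat_ok, cfg$flat_min_run)
  stairs <- maximal_runs(n, stair_ok, cfg$stair_min_run)
  out <- rbind(
    if (nrow(flats)) cbind(kind = "flat", flats),
    if (nrow(stairs)) cbind(kind = "stair", stairs))
  if (is.null(out)) {
    out <- data.frame(kind = character(0), start_index = integer(0),
                      length = integer(0), stringsAsFactors = FALSE)
  }
  out[order(out$start_index, out$kind), , drop = FALSE]
}

#' Segment a trace into non-overlapping analysis windows
#'
#' Windows are half-open `[k * window_s, (k + 1) * window_s)` in trace time;
#' an IBI belongs to the window containing the R-peak that ends it (an end
#' time exactly on a boundary starts the next window). The trailing partial
#' window is discarded. Gaps in beat times longer than `gap_split_s` split
#' the trace into segments whose windowing restarts at the segment origin.
#'
#' @inheritParams correct_artefacts
#' @return data.frame with one row per complete window: `window_index`,
#'   `segment`, `start_s`, `end_s`, `n_beats`, and a list-column `beat_idx`
#'   of member beat indices. Zero rows when no complete window fits.
#' @export
segment_windows <- function(trace, cfg = cleaning_config()) {
  e <- trace$beats$end_time_s
  x <- trace$beats$ibi_ms
  n <- length(x)
  w <- cfg$window_s
  gap <- c(0, diff(e)) - x / 1000
  seg_id <- cumsum(c(1L, as.integer(gap[-1L] > cfg$gap_split_s)))

  out <- list(); widx <- 0L
  for (s in unique(seg_id)) {
    sel <- which(seg_id == s)
    origin <- e[sel[1L]] - x[sel[1L]] / 1000
    rel_end <- e[sel] - origin
    seg_len <- rel_end[length(rel_end)]
    n_complete <- floor(seg_len / w + 1e-9)
    if (n_complete < 1L) next
    k <- floor(rel_end / w + 1e-9)  # window id per beat (end-time convention)
    ## a beat ending exactly at (k+1)*w belongs to window k+1: floor handles
    ## this because the interval is half-open on the right in *start* time
    for (kk in 0:(n_complete - 1L)) {
      beats <- sel[k == kk]
      widx <- widx + 1L
      out[[widx]] <- list(window_index = widx, segment = s,
                          start_s = origin + kk * w,
                          end_s = origin + (kk + 1L) * w,
                          n_beats = length(beats), beat_idx = beats)
    }
  }
  if (!length(out)) {
    return(data.frame(window_index = integer(0), segment = integer(0),
                      start_s = numeric(0), end_s = numeric(0),
                      n_beats = integer(0),
                      beat_idx = I(list())))
  }
  data.frame(
    window_index = vapply(out, `[[`, integer(1), "window_index"),
    segment = vapply(out, `[[`, integer(1), "segment"),
    start_s = vapply(out, `[[`, numeric(1), "start_s"),
    end_s = vapply(out, `[[`, numeric(1), "end_s"),
    n_beats = vapply(out, `[[`, integer(1), "n_beats"),
    beat_idx = I(lapply(out, `[[`, "beat_idx")))
}

#' Annotate windows with behaviour/artefact fractions and apply retention
#' filters
#'
#' Each member IBI is labelled with the behavioural state active at its end
#' time (uncovered times are `Unknown`). A window is retained iff its
#' Resting fraction is at least `resting_min_fraction`, no IBI carries a
#' disqualifying high-energy state, its flat/stair fraction is at most
#' `flatstair_max_fraction`, and its corrected-beat fraction is at most
#' `max_corrected_fraction`. Dropped windows carry `;`-joined reason codes
#' (`low_resting`, `disqualifying_state`, `flatstair`, `overcorrected`,
#' `no_behaviour`, `empty`).
#'
#' @param windows output of [segment_windows()].
#' @param trace the corrected `ibi_trace` the windows were cut from.
#' @param log a `behaviour_log` covering the trace span.
#' @param runs output of [detect_flat_stair_runs()] on the same trace.
#' @param cfg a [cleaning_config()].
#' @return `windows` augmented with `resting_fraction`,
#'   `disqualifying_fraction`, `flatstair_fraction`, `corrected_fraction`,
#'   `retained`, `drop_reason`.
#' @export
annotate_and_filter <- function(windows, trace, log, runs,
                                cfg = cleaning_config()) {
  n_beats_total <- nrow(trace$beats)
  states <- state_at(log, trace$beats$end_time_s)
  in_run <- rep(FALSE, n_beats_total)
  if (nrow(runs)) {
    for (r in seq_len(nrow(runs))) {
      in_run[runs$start_index[r]:(runs$start_index[r] + runs$length[r] - 1L)] <- TRUE
    }
  }
  corrected <- trace$beats$corrected

  k <- nrow(windows)
  resting <- disq <- fs <- cf <- numeric(k)
  retained <- logical(k); reason <- character(k)
  for (w in seq_len(k)) {
    idx <- windows$beat_idx[[w]]
    if (!length(idx)) {
      resting[w] <- disq[w] <- fs[w] <- cf[w] <- NA_real_
      retained[w] <- FALSE; reason[w] <- "empty"
      next
    }
    st <- states[idx]
    resting[w] <- mean(st == "Resting")
    disq[w] <- mean(st %in% cfg$disqualifying_states)
    fs[w] <- mean(in_run[idx])
    cf[w] <- mean(corrected[idx])
    why <- character(0)
    if (all(st == "Unknown")) why <- c(why, "no_behaviour")
    else if (resting[w] < cfg$resting_min_fraction) why <- c(why, "low_resting")
    if (disq[w] > 0) why <- c(why, "disqualifying_state")
    if (fs[w] > cfg$flatstair_max_fraction) why <- c(why, "flatstair")
    if (cf[w] > cfg$max_corrected_fraction) why <- c(why, "overcorrected")
    retained[w] <- length(why) == 0L
    reason[w] <- paste(why, collapse = ";")
  }
  windows$resting_fraction <- resting
  windows$disqualifying_fraction <- disq
  windows$flatstair_fraction <- fs
  windows$corrected_fraction <- cf
  windows$retained <- retained
  windows$drop_reason <- reason
  windows
}

#' Process one raw trace end to end
#'
#' Convenience wrapper: artefact correction, flat/stair detection,
#' windowing, behavioural annotation/filtering, and per-window RMSSD.
#'
#' @param trace a raw `ibi_trace`.
#' @param log a `behaviour_log`.
#' @param cfg a [cleaning_config()].
#' @return list with `trace` (corrected), `runs`, and `windows` (the QC
#'   table, including an `rmssd_ms` column; NA where a window has < 2 beats).
#' @export
process_trace <- function(trace, log, cfg = cleaning_config()) {
  corrected <- correct_artefacts(trace, cfg)
  runs <- detect_flat_stair_runs(corrected, cfg)
  windows <- segment_windows(corrected, cfg)
  windows <- annotate_and_filter(windows, corrected, log, runs, cfg)
  windows$rmssd_ms <- vapply(windows$beat_idx, function(idx) {
    if (length(idx) < 2L) return(NA_real_)
    rmssd(corrected$beats$ibi_ms[idx])
  }, numeric(1))
  list(trace = corrected, runs = runs, windows = windows)
}
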