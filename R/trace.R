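## Core containers: IBI traces and behavioural ethogram logs.

#' Construct an inter-beat-interval trace
#'
#' An `ibi_trace` holds one seal-season sequence of inter-beat intervals
#' (IBIs, milliseconds) as recorded by an on-animal heart-rate monitor.
#' Beat end times are cumulative seconds from the start of the recording;
#' by construction `diff(end_time_s)` equals `ibi_ms / 1000`.
#'
#' @param ibi_ms numeric vector of positive IBI durations in milliseconds.
#' @param seal_id identifier of the animal.
#' @param year season label.
#' @param start_s recording start offset in seconds (default 0).
#' @param corrected optional logical vector flagging beats touched by
#'   artefact correction.
#' @return an object of class `ibi_trace` with elements `seal_id`, `year`,
#'   `beats` (data.frame: `end_time_s`, `ibi_ms`, `corrected`),
#'   `corrections` (ledger data.frame) and `flags` (character).
#' @export
ibi_trace <- function(ibi_ms, seal_id = "S1", year = 1L, start_s = 0,
                      corrected = NULL) {
  check_that(length(ibi_ms) > 0L, "ibi_ms must be non-empty")
  check_that(all(is.finite(ibi_ms)) && all(ibi_ms > 0),
             "all IBIs must be finite and > 0")
  if (is.null(corrected)) corrected <- rep(FALSE, length(ibi_ms))
  check_that(length(corrected) == length(ibi_ms),
             "corrected flag length mismatch")
  beats <- data.frame(
    end_time_s = start_s + cumsum(as.numeric(ibi_ms)) / 1000,
    ibi_ms = as.numeric(ibi_ms),
    corrected = corrected
  )
  structure(
    list(seal_id = seal_id, year = year, beats = beats,
         corrections = empty_correction_ledger(), flags = character(0)),
    class = "ibi_trace"
  )
}

empty_correction_ledger <- function() {
  data.frame(index = integer(0), kind = character(0),
             original_ms = numeric(0), stringsAsFactors = FALSE)
}

#' @export
print.ibi_trace <- function(x, ...) {
  cat(sprintf("ibi_trace: seal %s, season %s, %d beats, %.1f s, %d corrections\n",
              x$seal_id, x$year, nrow(x$beats), trace_duration(x),
              nrow(x$corrections)))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Total duration of a trace in seconds
#' @param trace an `ibi_trace`.
#' @return seconds spanned by the beats.
#' @export
trace_duration <- function(trace) {
  sum(trace$beats$ibi_ms) / 1000
}

#' Construct a behavioural ethogram log
#'
#' Ordered, non-overlapping state intervals (seconds) from decoded video
#' ethograms. `Resting` is the state of interest for resting-HRV windows.
#'
#' @param start_s,end_s interval bounds in seconds.
#' @param state character state labels.
#' @return a `behaviour_log` (data.frame subclass).
#' @export
behaviour_log <- function(start_s, end_s, state) {
  check_that(length(start_s) == length(end_s) &&
             length(end_s) == length(state), "unequal column lengths")
  log <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                    state = as.character(state), stringsAsFactors = FALSE)
  log <- log[order(log$start_s), , drop = FALSE]
  if (nrow(log)) {
    check_that(all(log$end_s > log$start_s), "intervals must have start < end")
    if (nrow(log) > 1L) {
      check_that(all(log$start_s[-1L] >= log$end_s[-nrow(log)] - 1e-9),
                 "behaviour intervals must not overlap")
    }
  }
  class(log) <- c("behaviour_log", "data.frame")
  log
}

#' State active at given times
#'
#' Each query time is matched to the interval containing it; times not
#' covered by the log are labelled `"Unknown"`.
#'
#' @param log a `behaviour_log`.
#' @param times numeric vector of seconds.
#' @return character vector of state labels.
#' @export
state_at <- function(log, times) {
  if (nrow(log) == 0L) return(rep("Unknown", length(times)))
  idx <- findInterval(times, log$start_s)
  out <- rep("Unknown", length(times))
  hit <- idx >= 1L
  ok <- hit & times < log$end_s[pmax(idx, 1L)] + 1e-9
  out[ok] <- log$state[idx[ok]]
  out
}

#' Write / read IBI trace CSV
#'
#' Columns `time_s` (cumulative seconds) and `ibi_ms`. A `#`-prefixed header
#' comment records provenance (seed, config hash) when supplied.
#'
#' @param trace an `ibi_trace`.
#' @param file path.
#' @param header_comment optional character vector of comment lines.
#' @export
write_ibi_csv <- function(trace, file, header_comment = NULL) {
  df <- data.frame(time_s = trace$beats$end_time_s, ibi_ms = trace$beats$ibi_ms)
  write_csv_commented(df, file, header_comment)
}

#' @rdname write_ibi_csv
#' @param seal_id,year identifiers attached to the trace read back.
#' @export
read_ibi_csv <- function(file, seal_id = "S1", year = 1L) {
  df <- utils::read.csv(file, comment.char = "#")
  check_that(all(c("time_s", "ibi_ms") %in% names(df)),
             "IBI CSV needs columns time_s, ibi_ms")
  start_s <- df$time_s[1L] - df$ibi_ms[1L] / 1000
  ibi_trace(df$ibi_ms, seal_id = seal_id, year = year, start_s = start_s)
}

#' Write / read behaviour log CSV (columns start_s, end_s, state)
#' @inheritParams write_ibi_csv
#' @param log a `behaviour_log`.
#' @export
write_behaviour_csv <- function(log, file, header_comment = NULL) {
  write_csv_commented(as.data.frame(log), file, header_comment)
}

#' @rdname write_behaviour_csv
#' @export
read_behaviour_csv <- function(file) {
  df <- utils::read.csv(file, comment.char = "#")
  behaviour_log(df$start_s, df$end_s, df$state)
}

write_csv_commented <- function(df, file, header_comment = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(file)
}
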