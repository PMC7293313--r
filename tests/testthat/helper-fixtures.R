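# shared fixtures: tiny constructed traces and logs used across test files

# trace of n identical beats (ms)
flat_trace <- function(ibi = 800, n = 12, ...) {
  ibi_trace(rep(ibi, n), ...)
}

# behaviour log marking the whole span as one state
whole_span_log <- function(duration_s, state = "Resting") {
  behaviour_log(0, duration_s, state)
}

empty_runs <- function() {
  data.frame(kind = character(0), start_index = integer(0),
             length = integer(0))
}

# brute-force O(n^2) oracle for maximal flat/stair runs; definition mirrors
# the documented contract, implementation is independent (direct enumeration)
brute_force_runs <- function(x, kind, min_run, tol) {
  n <- length(x)
  pred <- function(i, j) {
    if (kind == "flat") {
      max(x[i:j]) - min(x[i:j]) <= tol + 1e-9
    } else {
      d <- diff(x[i:j])
      (all(d > 0) || all(d < 0)) && (max(d) - min(d) <= tol + 1e-9)
    }
  }
  out <- data.frame(start_index = integer(0), length = integer(0))
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1L < min_run) next
      if (!pred(i, j)) next
      left_max <- i == 1L || !pred(i - 1L, j)
      right_max <- j == n || !pred(i, j + 1L)
      if (left_max && right_max) {
        out <- rbind(out, data.frame(start_index = i, length = j - i + 1L))
      }
    }
  }
  out <- out[order(out$start_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# independent brute-force enumerator: loops over all term subsets and keeps
# those whose interactions have both parents present
oracle_candidates <- function(terms) {
  out <- list(character(0))
  for (size in seq_along(terms)) {
    for (idx in utils::combn(length(terms), size, simplify = FALSE)) {
      sel <- terms[idx]
      ints <- sel[grepl(":", sel)]
      ok <- all(vapply(ints, function(tt)
        all(strsplit(tt, ":")[[1]] %in% sel), logical(1)))
      if (ok) out <- c(out, list(sel))
    }
  }
  out
}

canon <- function(sets) {
  sort(vapply(sets, function(s) paste(sort(s), collapse = "+"), character(1)))
}

# balanced one-way ANOVA method-of-moments variance components
# (independent oracle for REML on balanced designs)
anova_varcomp <- function(values, ids) {
  k <- length(unique(ids))
  n_per <- as.numeric(table(ids))
  stopifnot(length(unique(n_per)) == 1L)
  n0 <- n_per[1L]
  fit <- stats::aov(values ~ factor(ids))
  ms <- summary(fit)[[1L]]$`Mean Sq`
  s2e <- ms[2L]
  s2a <- max(0, (ms[1L] - ms[2L]) / n0)
  c(s2a = s2a, s2e = s2e)
}
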