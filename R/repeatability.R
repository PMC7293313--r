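## Across-year repeatability of resting HRV.
##
## Population repeatability R is the fraction of phenotypic variance
## attributable to differences among individuals:
## R = sigma2_alpha / (sigma2_alpha + sigma2_eps), estimated from a Gaussian
## random-intercept model (REML) with the number of measures per individual
## as a fixed covariate. Uncertainty comes from a parametric bootstrap
## (simulate from the fitted model, refit, recompute R); significance from a
## likelihood-ratio test of the ID variance against its boundary, using the
## 50:50 mixture of a point mass at zero and chi-square(1) (i.e. p / 2).
## Per-individual repeatability Ri divides sigma2_alpha by
## sigma2_alpha + s2_i, where s2_i is the sample variance of individual i's
## conditional residuals.

#' Estimate across-year repeatability of a seal-season trait
#'
#' @param table data.frame with one row per seal-season.
#' @param value_col,id_col column names of the response and the individual
#'   identifier.
#' @param min_seasons individuals with fewer rows are dropped before
#'   fitting (default 2; singletons carry no repeatability information).
#' @param n_boot parametric bootstrap replicates for the CI (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param ci_level confidence level (default 0.95).
#' @return an object of class `repeatability_result`: `R`, `se`, `ci`,
#'   `lrt_p`, `n_boot`, `boot_R`, `vc` (sigma2_alpha, sigma2_eps, fixed
#'   coefficients), `Ri` (named vector), `n_ids`, `n_obs`, `boundary`
#'   (TRUE when sigma2_alpha collapsed to 0), and the fitted lme4 model.
#' @export
estimate_repeatability <- function(table, value_col = "resting_hrv_ms",
                                   id_col = "id", min_seasons = 2L,
                                   n_boot = 1000L, seed = 1L,
                                   ci_level = 0.95) {
  check_that(all(c(value_col, id_col) %in% names(table)),
             "table lacks required columns")
  d <- data.frame(y = table[[value_col]], id = as.character(table[[id_col]]),
                  stringsAsFactors = FALSE)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  counts <- table(d$id)
  keep <- names(counts)[counts >= min_seasons]
  check_that(length(keep) >= 2L,
             "need >= 2 individuals with >= %d seasons", min_seasons)
  d <- d[d$id %in% keep, , drop = FALSE]
  d$n_measures <- as.numeric(counts[d$id])

  ## n_measures can be constant (balanced designs): lme4 then drops the
  ## aliased column and the model reduces to the one-way layout
  fit <- suppressMessages(
    lme4::lmer(y ~ n_measures + (1 | id), data = d, REML = TRUE))
  R_of <- function(f) {
    vc <- as.data.frame(lme4::VarCorr(f))
    s2a <- vc$vcov[vc$grp == "id"]
    s2e <- vc$vcov[vc$grp == "Residual"]
    c(R = s2a / (s2a + s2e), s2a = s2a, s2e = s2e)
  }
  est <- R_of(fit)
  boundary <- est[["s2a"]] < 1e-10
  if (boundary) est[["R"]] <- 0

  boot_R <- numeric(0); se <- NA_real_; ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    ysim <- with_seed(derive_seed(seed, "rpt_boot"),
                      stats::simulate(fit, nsim = n_boot))
    boot_R <- vapply(seq_len(n_boot), function(b) {
      fb <- tryCatch(suppressWarnings(suppressMessages(
        lme4::refit(fit, ysim[[b]]))), error = function(e) NULL)
      if (is.null(fb)) return(NA_real_)
      unname(R_of(fb)[["R"]])
    }, numeric(1))
    boot_R <- boot_R[!is.na(boot_R)]
    se <- stats::sd(boot_R)
    a <- (1 - ci_level) / 2
    ci <- unname(stats::quantile(boot_R, c(a, 1 - a)))
  }

  ## boundary-mixture LRT on ML fits (lm is the sigma2_alpha = 0 null)
  m1 <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ n_measures + (1 | id), data = d, REML = FALSE)))
  m0 <- stats::lm(y ~ n_measures, data = d)
  D <- max(0, 2 * (as.numeric(stats::logLik(m1)) -
                     as.numeric(stats::logLik(m0))))
  lrt_p <- 0.5 * stats::pchisq(D, df = 1L, lower.tail = FALSE)

  Ri <- individual_Ri(est[["s2a"]], split(stats::residuals(fit), d$id))

  structure(list(R = unname(est[["R"]]), se = se, ci = ci, lrt_p = lrt_p,
                 n_boot = length(boot_R), boot_R = boot_R,
                 vc = list(sigma2_alpha = unname(est[["s2a"]]),
                           sigma2_eps = unname(est[["s2e"]]),
                           fixed_coefs = lme4::fixef(fit)),
                 Ri = Ri, n_ids = length(unique(d$id)), n_obs = nrow(d),
                 boundary = boundary, fit = fit),
            class = "repeatability_result")
}

#' Per-individual repeatability
#'
#' `Ri = sigma2_alpha / (sigma2_alpha + s2_i)` with `s2_i` the sample
#' variance of individual i's conditional (BLUP-adjusted) residuals.
#' Individuals with a single residual are excluded.
#'
#' @param sigma2_alpha between-individual variance.
#' @param resid_by_id named list of residual vectors, one per individual.
#' @return named numeric vector of Ri values in [0, 1].
#' @export
individual_Ri <- function(sigma2_alpha, resid_by_id) {
  check_that(sigma2_alpha >= 0, "sigma2_alpha must be >= 0")
  keep <- vapply(resid_by_id, length, integer(1)) >= 2L
  vapply(resid_by_id[keep], function(r) {
    s2i <- stats::var(r)
    if (sigma2_alpha == 0) return(0)
    if (s2i == 0) return(1)
    sigma2_alpha / (sigma2_alpha + s2i)
  }, numeric(1))
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("Repeatability R = %.3f +/- %.3f (95%% CI %.3f-%.3f), LRT p %s\n",
              x$R, x$se, x$ci[1], x$ci[2],
              format.pval(x$lrt_p, digits = 3)))
  cat(sprintf("  %d individuals, %d observations, %d bootstrap draws\n",
              x$n_ids, x$n_obs, x$n_boot))
  if (length(x$Ri)) {
    q <- stats::quantile(x$Ri, c(0, 0.25, 0.5, 0.75, 1))
    cat(sprintf("  Ri: range %.3f-%.3f, median %.3f (LQ %.3f, UQ %.3f)\n",
                q[1], q[5], q[3], q[2], q[4]))
  }
  invisible(x)
}
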