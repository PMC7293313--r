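## Mixed-model inference for the performance metrics.
##
## For each of the eight responses (four mass proxies and their annual
## deviance moduli) a global Gaussian random-intercept model is dredged:
## every subset of the global fixed terms respecting marginality is fitted
## by ML, ranked by AICc (k counts fixed coefficients plus the two variance
## components), and the confidence set keeps models within delta AICc <= 6
## of the best, then discards any model that fails to beat a simpler model
## nested within it (Richards' rule). The best model is refitted by REML
## for reported coefficients, Nakagawa marginal/conditional R2, the ID
## variance share, and Wald-F semipartial R2 per term with parametric
## bootstrap CIs.

MODEL_TERMS <- c("hrv", "birthdate", "pup_sex", "year", "device", "mppm_z",
                 "hrv:year")

#' Enumerate the candidate model set
#'
#' All subsets of the global fixed terms that respect marginality (an
#' interaction `a:b` requires both `a` and `b`), always including the
#' intercept-only null model, in deterministic order (by number of terms,
#' then lexicographically).
#'
#' @param global_terms character vector of fixed-effect terms; interactions
#'   written `"a:b"`.
#' @return list of character vectors (the null model is `character(0)`).
#' @export
build_candidate_set <- function(global_terms) {
  k <- length(global_terms)
  check_that(k == length(unique(global_terms)), "duplicate terms")
  subsets <- list(character(0))
  if (k > 0L) {
    for (mask in seq_len(2^k - 1L)) {
      sel <- global_terms[bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L]
      if (respects_marginality(sel)) subsets <- c(subsets, list(sel))
    }
  }
  ord <- order(vapply(subsets, length, integer(1)),
               vapply(subsets, function(s) paste(sort(s), collapse = "+"),
                      character(1)))
  subsets[ord]
}

respects_marginality <- function(terms) {
  ints <- terms[grepl(":", terms, fixed = TRUE)]
  if (!length(ints)) return(TRUE)
  all(vapply(ints, function(tt) {
    all(strsplit(tt, ":", fixed = TRUE)[[1L]] %in% terms)
  }, logical(1)))
}

#' Fit a Gaussian random-intercept mixed model
#'
#' @param response column name of the (standardized) response.
#' @param terms character vector of fixed terms (empty = null model).
#' @param data modelling table containing the response, the terms and `id`.
#' @param REML criterion; ML for cross-model AICc comparison, REML for
#'   reported coefficients.
#' @return a `coping_lmm_fit`: lme4 model plus coefficient table (Wald z
#'   p-values), variance components, log-likelihood, `n_obs`, `k_params`
#'   (fixed coefficients + 2 variance components), `aicc`, `singular` and
#'   `converged` flags.
#' @export
fit_lmm <- function(response, terms, data, REML = FALSE) {
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fml <- stats::as.formula(paste(response, "~", rhs, "+ (1 | id)"))
  fixed_fml <- stats::as.formula(paste(response, "~", rhs))
  use <- stats::complete.cases(
    data[, unique(c(response, all.vars(fixed_fml), "id")), drop = FALSE])
  d <- droplevels(data[use, , drop = FALSE])
  check_that(length(unique(d$id)) >= 2L, "need >= 2 individuals")

  converged <- TRUE
  fit <- suppressMessages(withCallingHandlers(
    lme4::lmer(fml, data = d, REML = REML,
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    }))

  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(V))
  zval <- beta / se
  coef_table <- data.frame(term = names(beta), estimate = unname(beta),
                           se = unname(se), z = unname(zval),
                           p = 2 * stats::pnorm(-abs(unname(zval))),
                           stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2a <- vc$vcov[vc$grp == "id"]
  s2e <- vc$vcov[vc$grp == "Residual"]
  n <- nrow(d)
  k <- length(beta) + 2L
  ll <- as.numeric(stats::logLik(fit))

  ## align the fixed design with the coefficients actually estimated:
  ## aliased columns (e.g. device fully confounded with year) are dropped
  ## by lme4, and the assign map must follow
  mm <- stats::model.matrix(fixed_fml, d)
  kept <- match(names(beta), colnames(mm))
  asgn <- attr(mm, "assign")[kept]
  mm <- mm[, kept, drop = FALSE]
  structure(list(
    response = response, terms = terms, model = fit, data = d,
    coef_table = coef_table, sigma2_alpha = s2a, sigma2_eps = s2e,
    log_likelihood = ll, criterion = if (REML) "REML" else "ML",
    n_obs = n, k_params = k, aicc = aicc(ll, k, n),
    model_matrix = mm, term_assign = asgn,
    term_labels = attr(stats::terms(fixed_fml), "term.labels"),
    singular = lme4::isSingular(fit), converged = converged),
    class = "coping_lmm_fit")
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 * ll + 2k + 2k(k + 1) / (n - k - 1)`, with k counting all
#' estimated parameters (fixed coefficients, the ID intercept variance and
#' the residual variance).
#'
#' @param log_likelihood model log-likelihood (ML for cross-model use).
#' @param k_params parameter count.
#' @param n_obs number of observations.
#' @return the AICc value.
#' @export
aicc <- function(log_likelihood, k_params, n_obs) {
  check_that(k_params < n_obs - 1L,
             "AICc undefined: k = %d >= n - 1 = %d", k_params, n_obs - 1L)
  -2 * log_likelihood + 2 * k_params +
    2 * k_params * (k_params + 1) / (n_obs - k_params - 1)
}

#' Richards confidence set with nested-model pruning
#'
#' Step 1 keeps every model within `delta_max` AICc of the best. Step 2
#' (default `direction = "richards"`) removes any model for which some
#' preliminary-set model nested within it (strict subset of its fixed
#' terms) has an AICc at least as low -- discarding overly complex models
#' that fail to beat their simpler nested versions. The literal alternative
#' (`direction = "literal"`) instead removes models that are not better
#' than every more complex preliminary-set model containing them. Pruning
#' decisions are made against the fixed preliminary set, so the result is
#' independent of processing order.
#'
#' @param fits list of `coping_lmm_fit` (ML).
#' @param delta_max retention window (default 6).
#' @param direction `"richards"` or `"literal"`.
#' @return list with `table` (model, df, logLik, AICc, delta, weight over
#'   the full candidate set, in_preliminary, retained, pruned_by) and
#'   `retained` (the retained fits, ordered by AICc).
#' @export
confidence_set <- function(fits, delta_max = 6,
                           direction = c("richards", "literal")) {
  direction <- match.arg(direction)
  fits <- fits[vapply(fits, function(f) isTRUE(f$converged), logical(1))]
  check_that(length(fits) >= 1L, "no converged fits")
  aiccs <- vapply(fits, `[[`, numeric(1), "aicc")
  ks <- vapply(fits, `[[`, integer(1), "k_params")
  labels <- vapply(fits, function(f) model_label(f$terms), character(1))
  ## deterministic ordering: AICc, then fewer parameters, then label
  ord <- order(aiccs, ks, labels)
  fits <- fits[ord]; aiccs <- aiccs[ord]; ks <- ks[ord]; labels <- labels[ord]

  delta <- aiccs - aiccs[1L]
  prelim <- delta <= delta_max + 1e-12
  term_sets <- lapply(fits, `[[`, "terms")
  nested_in <- function(a, b) {  # a strictly nested in b
    length(a) < length(b) && all(a %in% b)
  }
  pruned_by <- rep(NA_character_, length(fits))
  retained <- prelim
  for (m in which(prelim)) {
    for (m2 in which(prelim)) {
      if (m == m2) next
      if (direction == "richards") {
        ## drop complex m beaten (or tied) by a nested simpler m2
        if (nested_in(term_sets[[m2]], term_sets[[m]]) &&
            aiccs[m2] <= aiccs[m]) {
          retained[m] <- FALSE
          pruned_by[m] <- labels[m2]
          break
        }
      } else {
        ## literal reading: m must have lower AICc than every more complex
        ## model containing it
        if (nested_in(term_sets[[m]], term_sets[[m2]]) &&
            aiccs[m] >= aiccs[m2]) {
          retained[m] <- FALSE
          pruned_by[m] <- labels[m2]
          break
        }
      }
    }
  }
  w <- exp(-0.5 * delta)
  w <- w / sum(w)
  tab <- data.frame(model = labels, df = ks,
                    logLik = vapply(fits, `[[`, numeric(1), "log_likelihood"),
                    AICc = aiccs, delta = delta, weight = w,
                    in_preliminary = prelim, retained = retained,
                    pruned_by = pruned_by, stringsAsFactors = FALSE)
  list(table = tab, retained = fits[retained])
}

model_label <- function(terms) {
  if (!length(terms)) "Null" else paste(terms, collapse = " + ")
}

#' Variance-explained decomposition of a fitted mixed model
#'
#' Nakagawa-style coefficients of determination:
#' `R2_marginal = s2_f / (s2_f + s2_alpha + s2_eps)` with `s2_f` the
#' variance of the fixed-effect linear predictor, and
#' `R2_conditional = (s2_f + s2_alpha) / (s2_f + s2_alpha + s2_eps)`.
#' `id_variance_share` is `s2_alpha / (s2_alpha + s2_eps)` as a percentage
#' (the share of stochastic variation attributed to ID). Per-term
#' semipartial R2 uses the Wald-F formulation
#' `R2_t = df1 * F / (df1 * F + df2)` with `df2 = n - k_fixed`, an
#' approximation of the adjusted-denominator method; CIs come from a
#' parametric bootstrap (simulate from the fit, refit, recompute).
#'
#' @param fit a REML `coping_lmm_fit`.
#' @param n_boot bootstrap replicates for the term CIs (0 skips them).
#' @param seed integer seed.
#' @param ci_level confidence level.
#' @return list: `r2_marginal`, `r2_conditional`, `id_variance_share`,
#'   `terms` (data.frame term, df1, F, R2, lower, upper).
#' @export
r2_decomposition <- function(fit, n_boot = 1000L, seed = 1L,
                             ci_level = 0.95) {
  stopifnot(inherits(fit, "coping_lmm_fit"))
  point <- r2_point(fit)
  term_tab <- point$terms
  if (n_boot > 0L && nrow(term_tab)) {
    ysim <- with_seed(derive_seed(seed, "r2_boot"),
                      stats::simulate(fit$model, nsim = n_boot))
    boot <- matrix(NA_real_, n_boot, nrow(term_tab))
    for (b in seq_len(n_boot)) {
      fb <- tryCatch(suppressWarnings(suppressMessages(
        lme4::refit(fit$model, ysim[[b]]))), error = function(e) NULL)
      if (is.null(fb)) next
      tb <- term_r2_from_model(fb, fit$term_assign, fit$n_obs)
      boot[b, ] <- tb$R2[tb$assign > 0L]
    }
    a <- (1 - ci_level) / 2
    qs <- apply(boot, 2L, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
    term_tab$lower <- qs[1L, ]
    term_tab$upper <- qs[2L, ]
  } else if (nrow(term_tab)) {
    term_tab$lower <- NA_real_
    term_tab$upper <- NA_real_
  }
  list(r2_marginal = point$r2_marginal,
       r2_conditional = point$r2_conditional,
       id_variance_share = point$id_variance_share,
       terms = term_tab)
}

r2_point <- function(fit) {
  beta <- lme4::fixef(fit$model)
  eta <- as.vector(fit$model_matrix %*% beta)
  s2f <- if (length(fit$terms)) stats::var(eta) else 0
  tot <- s2f + fit$sigma2_alpha + fit$sigma2_eps
  terms <- term_r2_from_model(fit$model, fit$term_assign, fit$n_obs)
  terms$term <- c("(Intercept)", fit$term_labels)[terms$assign + 1L]
  list(r2_marginal = s2f / tot,
       r2_conditional = (s2f + fit$sigma2_alpha) / tot,
       id_variance_share = 100 * fit$sigma2_alpha /
         (fit$sigma2_alpha + fit$sigma2_eps),
       terms = terms[terms$assign > 0L,
                     c("term", "df1", "F", "R2"), drop = FALSE])
}

## Wald-F semipartial R2 for every assign group of the fixed design
term_r2_from_model <- function(model, assign, n_obs) {
  beta <- lme4::fixef(model)
  V <- as.matrix(stats::vcov(model))
  k_fixed <- length(beta)
  df2 <- n_obs - k_fixed
  groups <- sort(unique(assign))
  res <- lapply(groups, function(g) {
    j <- which(assign == g)
    df1 <- length(j)
    Fval <- tryCatch(
      as.numeric(t(beta[j]) %*% solve(V[j, j, drop = FALSE], beta[j])) / df1,
      error = function(e) NA_real_)
    data.frame(assign = g, df1 = df1, F = Fval,
               R2 = df1 * Fval / (df1 * Fval + df2))
  })
  do.call(rbind, res)
}

#' Kruskal-Wallis rank-sum test (tie-corrected)
#'
#' Direct implementation of the rank-sum H statistic with the standard tie
#' correction, referred to a chi-square distribution with groups - 1
#' degrees of freedom.
#'
#' @param values numeric observations.
#' @param groups group labels.
#' @return list with `chi2`, `df`, `p`, `n`.
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  check_that(length(unique(groups)) >= 2L, "need >= 2 groups")
  check_that(stats::var(values) > 0, "all values identical")
  N <- length(values)
  r <- rank(values)
  Rj <- tapply(r, groups, sum)
  nj <- tapply(r, groups, length)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  ties <- table(values)
  tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- H / tie_corr
  df <- length(nj) - 1L
  list(chi2 = unname(H), df = df,
       p = stats::pchisq(H, df, lower.tail = FALSE), n = N)
}

RESPONSE_COLUMNS <- c(MPPM = "z_mppm", MDML = "z_mdml", PDMG = "z_pdmg",
                      MTE = "z_mte", dev_MPPM = "z_dev_mppm",
                      dev_MDML = "z_dev_mdml", dev_PDMG = "z_dev_pdmg",
                      dev_MTE = "z_dev_mte")

#' Run the full model-inference stage
#'
#' For every requested response: enumerate candidates from the global model
#' (HRV, birthdate, pup sex, year, device, post-partum mass except when it
#' is the response, and the HRV x year interaction), fit by ML, rank by
#' AICc, build the pruned confidence set, refit the best model by REML and
#' decompose its variance. Where HRV and birthdate co-occur in a
#' confidence-set model, the HRV x birthdate variant is fitted and compared
#' by AICc. Kruskal-Wallis year contrasts are run for the raw daily rates.
#'
#' @param table output of [build_analysis_table()].
#' @param responses subset of `names(RESPONSE_COLUMNS)`.
#' @param n_boot bootstrap replicates for semipartial R2 CIs.
#' @param seed integer seed.
#' @param delta_max AICc retention window.
#' @param direction pruning rule, see [confidence_set()].
#' @return list with one element per response (`candidates`, `set`,
#'   `best`, `best_reml`, `r2`, `null_fit`, `hrv_birthdate_check`) plus
#'   `kruskal_wallis` (MDML/PDMG by year) and `meta`. Responses whose
#'   fitting fails are reported with an `error` element rather than
#'   aborting the rest.
#' @export
run_analysis <- function(table, responses = names(RESPONSE_COLUMNS),
                         n_boot = 1000L, seed = 1L, delta_max = 6,
                         direction = "richards") {
  responses <- match.arg(responses, names(RESPONSE_COLUMNS),
                         several.ok = TRUE)
  out <- list()
  for (resp in responses) {
    col <- RESPONSE_COLUMNS[[resp]]
    out[[resp]] <- tryCatch(
      analyse_response(table, resp, col, n_boot = n_boot,
                       seed = derive_seed(seed, resp), delta_max = delta_max,
                       direction = direction),
      error = function(e) list(response = resp, error = conditionMessage(e)))
  }
  kw <- list()
  if (length(unique(table$year)) >= 2L) {
    kw$MDML <- kruskal_wallis(table$mdml, table$year)
    kw$PDMG <- kruskal_wallis(table$pdmg, table$year)
  }
  list(responses = out, kruskal_wallis = kw,
       meta = list(n_obs = nrow(table),
                   n_ids = length(unique(table$id)),
                   n_boot = n_boot, seed = seed, delta_max = delta_max,
                   direction = direction))
}

analyse_response <- function(table, resp, col, n_boot, seed, delta_max,
                             direction) {
  check_that(col %in% names(table) && !all(is.na(table[[col]])),
             "response %s unavailable", resp)
  global <- MODEL_TERMS
  if (resp %in% c("MPPM", "dev_MPPM")) {
    global <- setdiff(global, "mppm_z")
  }
  ## factors need >= 2 levels in the rows actually modelled
  use <- !is.na(table[[col]])
  for (f in c("pup_sex", "year", "device")) {
    if (length(unique(table[[f]][use])) < 2L) {
      global <- setdiff(global, c(f, paste0("hrv:", f)))
    }
  }
  candidates <- build_candidate_set(global)
  fits <- lapply(candidates, function(tt) fit_lmm(col, tt, table, REML = FALSE))
  cs <- confidence_set(fits, delta_max = delta_max, direction = direction)
  best <- cs$retained[[1L]]
  null_fit <- fits[[which(vapply(fits, function(f) length(f$terms) == 0L,
                                 logical(1)))[1L]]]
  best_reml <- fit_lmm(col, best$terms, table, REML = TRUE)
  r2 <- r2_decomposition(best_reml, n_boot = n_boot, seed = seed)

  ## alternative HRV x birthdate interaction check
  hb_check <- NULL
  with_both <- Filter(function(f) all(c("hrv", "birthdate") %in% f$terms),
                      cs$retained)
  if (length(with_both)) {
    hb_check <- lapply(with_both, function(f) {
      alt <- fit_lmm(col, c(f$terms, "hrv:birthdate"), table, REML = FALSE)
      data.frame(model = model_label(f$terms), aicc = f$aicc,
                 aicc_with_interaction = alt$aicc,
                 interaction_improves = alt$aicc < f$aicc,
                 stringsAsFactors = FALSE)
    })
    hb_check <- do.call(rbind, hb_check)
  }
  list(response = resp, column = col, global_terms = global,
       candidates = cs$table, set = cs,
       best = best, best_reml = best_reml, r2 = r2, null_fit = null_fit,
       hrv_birthdate_check = hb_check)
}
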