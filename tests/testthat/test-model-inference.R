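test_that("candidate enumeration matches brute force with marginality on all global models", {
  g1 <- c("A", "B", "A:B")
  got <- build_candidate_set(g1)
  expect_identical(length(got), 5L)
  expect_identical(canon(got), canon(oracle_candidates(g1)))

  expect_identical(length(build_candidate_set("A")), 2L)

  # the full 7-term global model used for the rate responses
  g7 <- c("hrv", "birthdate", "pup_sex", "year", "device", "mppm_z",
          "hrv:year")
  got7 <- build_candidate_set(g7)
  expect_identical(canon(got7), canon(oracle_candidates(g7)))
  expect_identical(length(got7), 80L)  # 2^6 + 2^4

  # post-partum mass as response: mppm_z excluded from the global model
  g6 <- setdiff(g7, "mppm_z")
  expect_identical(length(build_candidate_set(g6)), 40L)
  expect_false(any(vapply(build_candidate_set(g6),
                          function(s) "mppm_z" %in% s, logical(1))))
})

test_that("AICc arithmetic matches the closed form and its limits", {
  expect_equal(aicc(-20, 3, 10), 50)          # AIC 46 + 24/6
  # AICc -> AIC for large n
  expect_equal(aicc(-20, 3, 1e6), 46, tolerance = 1e-4)
  # identical likelihood, one extra parameter -> strictly larger AICc
  expect_gt(aicc(-20, 4, 30), aicc(-20, 3, 30))
  expect_error(aicc(-20, 10, 11), "undefined")
})

test_that("nested pruning keeps simple models that beat their complex supersets", {
  fits <- list(
    list(terms = c("A"), aicc = 100, k_params = 4L, log_likelihood = -45,
         converged = TRUE),
    list(terms = c("A", "B"), aicc = 100.5, k_params = 5L,
         log_likelihood = -44, converged = TRUE),
    list(terms = character(0), aicc = 103.33, k_params = 3L,
         log_likelihood = -48, converged = TRUE),
    list(terms = c("B"), aicc = 107.0, k_params = 4L, log_likelihood = -49,
         converged = TRUE))
  cs <- confidence_set(fits)
  tab <- cs$table
  # delta <= 6 keeps the first three; A+B is then pruned by nested A
  expect_identical(tab$model[tab$in_preliminary],
                   c("A", "A + B", "Null"))
  expect_identical(tab$model[tab$retained], c("A", "Null"))
  expect_identical(tab$pruned_by[tab$model == "A + B"], "A")
  # weights normalize over the full candidate set
  expect_equal(sum(tab$weight), 1)
})

test_that("pruning is order independent and keeps the best model", {
  set.seed(23)
  terms <- c("A", "B", "C")
  cands <- build_candidate_set(terms)
  for (rep in 1:25) {
    fits <- lapply(cands, function(tt) {
      list(terms = tt, aicc = 100 + runif(1, 0, 8),
           k_params = length(tt) + 3L, log_likelihood = -50,
           converged = TRUE)
    })
    ref <- confidence_set(fits)$table
    per <- confidence_set(sample(fits))$table
    expect_identical(ref$model, per$model)
    expect_identical(ref$retained, per$retained)
    best <- ref$model[which.min(ref$AICc)]
    expect_true(best %in% ref$model[ref$retained])
    expect_true(all(ref$delta[ref$retained] <= 6))
  }
})

test_that("a single candidate is retained as is", {
  fits <- list(list(terms = character(0), aicc = 50, k_params = 3L,
                    log_likelihood = -20, converged = TRUE))
  cs <- confidence_set(fits)
  expect_true(cs$table$retained)
})

sim_lmm_table <- function(n_ids = 30, n_per = 3, sd_id = 1, sd_eps = 1,
                          beta_x = 0.5, seed = 1) {
  set.seed(seed)
  id <- rep(sprintf("I%02d", 1:n_ids), each = n_per)
  x <- rnorm(n_ids * n_per)
  y <- beta_x * x + rep(rnorm(n_ids, 0, sd_id), each = n_per) +
    rnorm(n_ids * n_per, 0, sd_eps)
  data.frame(id = id, x = x, y = y)
}

test_that("with zero ID variance the mixed fit matches ordinary least squares", {
  d <- sim_lmm_table(sd_id = 0, seed = 4)
  f <- fit_lmm("y", "x", d, REML = FALSE)
  ols <- coef(lm(y ~ x, d))
  expect_equal(f$coef_table$estimate, unname(ols), tolerance = 1e-4)
  expect_true(f$singular || f$sigma2_alpha < 1e-6)
})

test_that("REML variance components match ANOVA moments on the balanced one-way layout", {
  d <- sim_lmm_table(n_ids = 15, n_per = 4, sd_id = 2, sd_eps = 1,
                     beta_x = 0, seed = 6)
  f <- fit_lmm("y", character(0), d, REML = TRUE)
  oracle <- anova_varcomp(d$y, d$id)
  expect_equal(f$sigma2_alpha, unname(oracle["s2a"]), tolerance = 1e-6)
  expect_equal(f$sigma2_eps, unname(oracle["s2e"]), tolerance = 1e-6)
})

test_that("refitting the same specification is deterministic", {
  d <- sim_lmm_table(seed = 3)
  f1 <- fit_lmm("y", "x", d, REML = FALSE)
  f2 <- fit_lmm("y", "x", d, REML = FALSE)
  expect_identical(f1$coef_table, f2$coef_table)
  expect_identical(f1$aicc, f2$aicc)
})

test_that("R2 decomposition reproduces the variance-share arithmetic of its own fit", {
  d <- sim_lmm_table(n_ids = 40, n_per = 3, sd_id = 1, sd_eps = sqrt(2),
                     beta_x = 1, seed = 21)
  f <- fit_lmm("y", "x", d, REML = TRUE)
  r2 <- r2_decomposition(f, n_boot = 0)
  s2f <- var(as.vector(f$model_matrix %*% lme4::fixef(f$model)))
  tot <- s2f + f$sigma2_alpha + f$sigma2_eps
  expect_equal(r2$r2_marginal, s2f / tot, tolerance = 1e-10)
  expect_equal(r2$r2_conditional, (s2f + f$sigma2_alpha) / tot,
               tolerance = 1e-10)
  expect_equal(r2$id_variance_share,
               100 * f$sigma2_alpha / (f$sigma2_alpha + f$sigma2_eps),
               tolerance = 1e-10)
  # generated at sigma2_f ~ 1, sigma2_a ~ 1, sigma2_e ~ 2: shares should
  # land near 0.25 / 0.50 / 33%
  expect_equal(r2$r2_marginal, 0.25, tolerance = 0.35)
  expect_equal(r2$r2_conditional, 0.50, tolerance = 0.30)
})

test_that("marginal R2 is zero for the null model and bounded by conditional R2", {
  d <- sim_lmm_table(seed = 9)
  f0 <- fit_lmm("y", character(0), d, REML = TRUE)
  r0 <- r2_decomposition(f0, n_boot = 0)
  expect_identical(r0$r2_marginal, 0)
  f1 <- fit_lmm("y", "x", d, REML = TRUE)
  r1 <- r2_decomposition(f1, n_boot = 0)
  expect_gte(r1$r2_conditional, r1$r2_marginal)
  expect_lte(r1$r2_conditional, 1)
})

test_that("semipartial R2 reduces to the squared correlation without grouping structure", {
  set.seed(11)
  n <- 120
  d <- data.frame(id = sprintf("I%02d", rep(1:40, each = 3)),
                  x = rnorm(n))
  d$y <- 0.6 * d$x + rnorm(n)
  f <- fit_lmm("y", "x", d, REML = TRUE)
  r2 <- r2_decomposition(f, n_boot = 0)
  expect_equal(r2$terms$R2[r2$terms$term == "x"],
               cor(d$x, d$y)^2, tolerance = 1e-2)
})

test_that("Kruskal-Wallis matches the hand-computed rank formula and stats::kruskal.test", {
  got <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(got$chi2, 27 / 7, tolerance = 1e-10)  # 12/42*(12+75)-21
  expect_identical(got$df, 1L)

  set.seed(13)
  for (k in 1:200) {
    n <- sample(8:25, 1)
    vals <- sample(1:10, n, replace = TRUE)  # heavy ties
    grp <- sample(letters[1:sample(2:4, 1)], n, replace = TRUE)
    if (length(unique(grp)) < 2 || var(vals) == 0) next
    if (any(table(grp) == 0)) next
    ref <- suppressWarnings(stats::kruskal.test(vals, factor(grp)))
    got <- kruskal_wallis(vals, grp)
    expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    expect_identical(got$df, unname(ref$parameter))
    # label permutation leaves H unchanged
    relab <- setNames(sample(LETTERS[1:4]), letters[1:4])
    expect_equal(kruskal_wallis(vals, relab[grp])$chi2, got$chi2)
  }
  expect_error(kruskal_wallis(rep(5, 6), rep(c("a", "b"), 3)), "identical")
})

test_that("run_analysis recovers a birthdate-only signal in the MPPM best model", {
  hits <- 0L
  for (k in 1:10) {
    col <- simulate_colony(colony_sim_params(
      n_ids = 40, mass_intercept_sd = 5, mppm_birthdate_slope = -8,
      mppm_resid_sd = 4, seed = 400 + k))
    tab <- build_analysis_table(col$captures, col$hrv)
    a <- run_analysis(tab, responses = "MPPM", n_boot = 0, seed = k)
    if ("birthdate" %in% a$responses$MPPM$best$terms) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("run_analysis produces a structurally complete report", {
  col <- simulate_colony(colony_sim_params(seed = 77))
  tab <- build_analysis_table(col$captures, col$hrv)
  a <- run_analysis(tab, responses = c("MDML", "dev_MDML"), n_boot = 10,
                    seed = 5)
  expect_identical(names(a$responses), c("MDML", "dev_MDML"))
  for (r in a$responses) {
    expect_null(r$error)
    expect_true("Null" %in% r$candidates$model)
    expect_true(any(r$candidates$retained))
    expect_true(all(r$candidates$delta[r$candidates$retained] <= 6))
    expect_identical(r$best_reml$criterion, "REML")
  }
  expect_identical(a$kruskal_wallis$MDML$df, 4L)
})
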