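toy_captures <- function() {
  data.frame(id = c("A", "B", "C"), year = c(1, 1, 1),
             birthdate_doy = c(310, 312, 315),
             cap1_date = c(313, 315, 318), cap2_date = c(324, 326, 329),
             cap1_mass_kg = c(180, 170, 160),
             cap2_mass_kg = c(147, 143.5, 138),
             pup1_mass_kg = c(15, 16, 14),
             pup2_mass_kg = c(31.5, 30.3, 27.2))
}

test_that("daily rates follow the two-capture arithmetic", {
  r <- daily_rates(toy_captures())
  expect_equal(r$mdml[1], 3.0)     # 33 kg over 11 days
  expect_equal(r$pdmg[1], 1.5)     # 16.5 kg over 11 days
  # no mass change -> zero rate
  cap <- toy_captures(); cap$cap2_mass_kg <- cap$cap1_mass_kg
  expect_equal(daily_rates(cap)$mdml, c(0, 0, 0))
  cap$cap2_date <- cap$cap1_date
  expect_error(daily_rates(cap), "after cap1")
})

test_that("post-partum mass extrapolates linearly back to the birthdate", {
  cap <- toy_captures()
  r <- daily_rates(cap)
  mppm <- maternal_postpartum_mass(cap, r$mdml)
  expect_equal(mppm[1], 180 + 3.0 * 3)  # day-3 capture at 3 kg/day
  # capture on the parturition day -> mppm equals the capture mass
  cap2 <- cap; cap2$cap1_date <- cap2$birthdate_doy
  expect_equal(maternal_postpartum_mass(cap2, r$mdml), cap2$cap1_mass_kg)
  # zero loss rate -> no extrapolation regardless of lag
  expect_equal(maternal_postpartum_mass(cap, rep(0, 3)), cap$cap1_mass_kg)
  cap3 <- cap; cap3$cap1_date <- cap3$birthdate_doy - 1
  expect_error(maternal_postpartum_mass(cap3, r$mdml), "precede")
})

test_that("mass transfer efficiency is the rate ratio, undefined for non-growing pups", {
  expect_equal(mass_transfer_efficiency(3, 1.5), 2)
  expect_equal(mass_transfer_efficiency(2.2, 2.2), 1)
  expect_true(is.na(mass_transfer_efficiency(3, 0)))
  # scale invariance under joint rescaling
  expect_equal(mass_transfer_efficiency(3 * 7, 1.5 * 7), 2)
})

test_that("annual deviance modulus measures distance from the year mean", {
  d <- annual_deviance_modulus(c(10, 12, 14), c(1, 1, 1))
  expect_equal(d$deviance, c(2, 0, 2))
  expect_false(any(d$degenerate))
  # singleton year -> modulus 0, degenerate flag
  d <- annual_deviance_modulus(c(10, 12, 99), c(1, 1, 2))
  expect_equal(d$deviance[3], 0)
  expect_true(d$degenerate[3])
})

test_that("within each year signed deviances sum to zero and moduli average to the MAD", {
  set.seed(8)
  vals <- rnorm(40, 5, 2)
  yrs <- sample(1:4, 40, replace = TRUE)
  d <- annual_deviance_modulus(vals, yrs)
  for (y in unique(yrs)) {
    sel <- yrs == y
    expect_equal(sum(vals[sel] - mean(vals[sel])), 0, tolerance = 1e-10)
    expect_equal(mean(d$deviance[sel]), mean(abs(vals[sel] - mean(vals[sel]))))
  }
})

test_that("z-transform uses the sample-sd convention; log variant handles zeros", {
  expect_equal(transform_response(c(1, 2, 3), "z"), c(-1, 0, 1))
  expect_error(transform_response(c(5, 5, 5), "z"), "zero variance")
  z <- transform_response(c(0, 1, 2), "log_then_z", eps = 0.01)
  expect_true(all(is.finite(z)))
  expect_error(transform_response(c(-1, 1, 2), "log_then_z"), ">= 0")
})

test_that("metrics round-trip the colony generator's ground-truth rates exactly", {
  col <- simulate_colony(colony_sim_params(n_ids = 20, seed = 31))
  perf <- performance_table(col$captures)
  truth <- col$truth$rates
  expect_equal(perf$mdml, truth$mdml, tolerance = 1e-10)
  expect_equal(perf$pdmg, truth$pdmg, tolerance = 1e-10)
  expect_equal(perf$mppm, truth$mppm, tolerance = 1e-10)
})

test_that("the analysis table carries standardized responses and covariates", {
  col <- simulate_colony(colony_sim_params(seed = 17))
  tab <- build_analysis_table(col$captures, col$hrv)
  expect_identical(nrow(tab), nrow(col$captures))
  for (cl in c("hrv", "birthdate", "z_mppm", "z_dev_mdml")) {
    expect_equal(mean(tab[[cl]]), 0, tolerance = 1e-10)
    expect_equal(sd(tab[[cl]]), 1, tolerance = 1e-10)
  }
  expect_s3_class(tab$year, "factor")
  expect_identical(levels(tab$device), c("Polar", "Firstbeat"))
})
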