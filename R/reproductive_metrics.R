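## Maternal reproductive-performance metrics and annual deviance moduli.
##
## Grey seal mothers are capital breeders: everything spent on the pup comes
## from reserves accumulated at sea, so four mass-based proxies summarise a
## breeding season: maternal post-partum mass (MPPM, kg; state on arrival),
## maternal daily mass loss rate (MDML, kg/day; expenditure), pup daily mass
## gain rate (PDMG, kg/day; short-term fitness outcome), and mass transfer
## efficiency (MTE = MDML / PDMG). The deviance modulus of each metric is
## the absolute difference between an individual's value and the sample mean
## of the mothers measured in the same year -- the quantity that separates
## "average" strategies from variable ones.

#' Daily maternal mass-loss and pup mass-gain rates
#'
#' Linear rates between the two lactation captures:
#' `mdml = (cap1_mass - cap2_mass) / (cap2_date - cap1_date)` and
#' `pdmg = (pup2_mass - pup1_mass) / (cap2_date - cap1_date)`.
#'
#' @param captures data.frame with columns `cap1_date`, `cap2_date`,
#'   `cap1_mass_kg`, `cap2_mass_kg`, `pup1_mass_kg`, `pup2_mass_kg`.
#' @return data.frame with columns `mdml`, `pdmg` (kg/day).
#' @export
daily_rates <- function(captures) {
  span <- captures$cap2_date - captures$cap1_date
  check_that(all(span > 0), "cap2_date must be after cap1_date")
  data.frame(
    mdml = (captures$cap1_mass_kg - captures$cap2_mass_kg) / span,
    pdmg = (captures$pup2_mass_kg - captures$pup1_mass_kg) / span)
}

#' Maternal post-partum mass
#'
#' Extrapolates the first-capture mass back to the parturition date using
#' the daily mass-loss rate: `mppm = cap1_mass + mdml * (cap1_date -
#' birthdate)`.
#'
#' @param captures data.frame with `cap1_date`, `cap1_mass_kg`,
#'   `birthdate_doy`.
#' @param mdml maternal daily mass loss rate, kg/day.
#' @return numeric vector of post-partum masses, kg.
#' @export
maternal_postpartum_mass <- function(captures, mdml) {
  lag <- captures$cap1_date - captures$birthdate_doy
  check_that(all(lag >= 0), "first capture cannot precede the birthdate")
  captures$cap1_mass_kg + mdml * lag
}

#' Mass transfer efficiency
#'
#' Ratio of maternal daily mass loss to pup daily mass gain. Undefined
#' (returned as `NA`) when the pup did not gain mass.
#'
#' @param mdml,pdmg daily rates, kg/day.
#' @return numeric vector; `NA` where `pdmg <= 0`.
#' @export
mass_transfer_efficiency <- function(mdml, pdmg) {
  out <- ifelse(pdmg > 0, mdml / pdmg, NA_real_)
  if (anyNA(out)) {
    attr(out, "missing_reason") <- "pdmg <= 0: efficiency undefined"
  }
  out
}

#' Annual deviance modulus
#'
#' `|x_i - mean(x of the same year)|`, the mean taken over the mothers
#' sampled in that year. Records in singleton years get modulus 0 and a
#' degenerate flag.
#'
#' @param values numeric metric values.
#' @param years year labels aligned with `values`.
#' @return data.frame with `deviance` and logical `degenerate`.
#' @export
annual_deviance_modulus <- function(values, years) {
  check_that(length(values) == length(years), "length mismatch")
  year_mean <- stats::ave(values, years, FUN = function(v) mean(v, na.rm = TRUE))
  n_in_year <- stats::ave(values, years,
                          FUN = function(v) sum(!is.na(v)))
  data.frame(deviance = abs(values - year_mean),
             degenerate = n_in_year <= 1)
}

#' Standardize a response or covariate
#'
#' `kind = "z"`: subtract the mean and divide by the sample (n - 1) SD over
#' the whole analysis table. `kind = "log_then_z"`: z-transform of
#' `log(x + eps)`; the offset guards deviance moduli that are exactly zero
#' (a record equal to its annual mean).
#'
#' @param values numeric vector (non-negative for the log variant).
#' @param kind `"z"` or `"log_then_z"`.
#' @param eps log offset in the metric's units (default 0.01).
#' @param base log base (default natural).
#' @return standardized numeric vector (NAs propagated).
#' @export
transform_response <- function(values, kind = c("z", "log_then_z"),
                               eps = 0.01, base = exp(1)) {
  kind <- match.arg(kind)
  x <- values
  if (kind == "log_then_z") {
    check_that(all(x >= 0, na.rm = TRUE), "log transform needs values >= 0")
    x <- log(x + eps, base = base)
  }
  s <- stats::sd(x, na.rm = TRUE)
  check_that(is.finite(s) && s > 0, "zero variance: cannot z-transform")
  (x - mean(x, na.rm = TRUE)) / s
}

#' Per-record performance metrics from a capture table
#'
#' Computes the four proxies and their annual deviance moduli for every
#' mother-year row.
#'
#' @param captures capture table (see [simulate_colony()] for the column
#'   layout).
#' @return data.frame: `id`, `year`, `mppm`, `mdml`, `pdmg`, `mte`,
#'   `dev_mppm`, `dev_mdml`, `dev_pdmg`, `dev_mte`, `degenerate_year`.
#' @export
performance_table <- function(captures) {
  rates <- daily_rates(captures)
  mppm <- maternal_postpartum_mass(captures, rates$mdml)
  mte <- mass_transfer_efficiency(rates$mdml, rates$pdmg)
  out <- data.frame(id = captures$id, year = captures$year,
                    mppm = mppm, mdml = rates$mdml, pdmg = rates$pdmg,
                    mte = as.numeric(mte), stringsAsFactors = FALSE)
  dev <- lapply(c(mppm = "mppm", mdml = "mdml", pdmg = "pdmg", mte = "mte"),
                function(col) annual_deviance_modulus(out[[col]], out$year))
  out$dev_mppm <- dev$mppm$deviance
  out$dev_mdml <- dev$mdml$deviance
  out$dev_pdmg <- dev$pdmg$deviance
  out$dev_mte <- dev$mte$deviance
  out$degenerate_year <- dev$mppm$degenerate
  out
}

#' Assemble the merged modelling table
#'
#' Joins per-record performance metrics, individual across-year resting HRV,
#' and capture covariates, then applies the modelling transforms: all eight
#' responses standardized (deviance moduli log-transformed first), all
#' continuous covariates z-transformed, year/pup sex/device as factors.
#'
#' @param captures capture table.
#' @param hrv_seasonal seal-season HRV table (`id`, `year`,
#'   `resting_hrv_ms`).
#' @param eps log offset for the deviance responses.
#' @return data.frame ready for [run_analysis()]: `id`, `year`, `pup_sex`,
#'   `device` (factors), `hrv`, `birthdate`, `mppm` (z-scored covariates),
#'   raw metric columns, and standardized responses `z_mppm`, `z_mdml`,
#'   `z_pdmg`, `z_mte`, `z_dev_mppm`, `z_dev_mdml`, `z_dev_pdmg`,
#'   `z_dev_mte`.
#' @export
build_analysis_table <- function(captures, hrv_seasonal, eps = 0.01) {
  perf <- performance_table(captures)
  ind <- across_year_hrv(hrv_seasonal)
  tab <- merge(perf, captures[, c("id", "year", "birthdate_doy", "pup_sex",
                                  "device")], by = c("id", "year"))
  tab <- merge(tab, ind[, c("id", "hrv_ms")], by = "id")
  tab <- tab[order(tab$id, tab$year), , drop = FALSE]
  rownames(tab) <- NULL

  tab$year <- factor(tab$year)
  tab$pup_sex <- factor(tab$pup_sex)
  tab$device <- factor(tab$device, levels = intersect(
    c("Polar", "Firstbeat"), unique(tab$device)))
  tab$hrv <- transform_response(tab$hrv_ms, "z")
  tab$birthdate <- transform_response(tab$birthdate_doy, "z")
  tab$mppm_z <- transform_response(tab$mppm, "z")

  tab$z_mppm <- transform_response(tab$mppm, "z")
  tab$z_mdml <- transform_response(tab$mdml, "z")
  tab$z_pdmg <- transform_response(tab$pdmg, "z")
  tab$z_mte <- if (all(is.na(tab$mte))) NA_real_ else
    transform_response(tab$mte, "z")
  tab$z_dev_mppm <- transform_response(tab$dev_mppm, "log_then_z", eps = eps)
  tab$z_dev_mdml <- transform_response(tab$dev_mdml, "log_then_z", eps = eps)
  tab$z_dev_pdmg <- transform_response(tab$dev_pdmg, "log_then_z", eps = eps)
  tab$z_dev_mte <- if (all(is.na(tab$dev_mte))) NA_real_ else
    transform_response(tab$dev_mte, "log_then_z", eps = eps)
  tab
}
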