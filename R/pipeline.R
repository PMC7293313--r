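## Pipeline orchestration: configuration, schema validation, and a single
## entry point chaining simulate -> process -> hrv -> repeatability ->
## metrics -> models, writing CSV/JSON outputs with provenance headers.

#' Pipeline configuration
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed; every stage derives its own stream from it.
#' @param colony a [colony_sim_params()] for the simulate stage (its seed is
#'   overridden by the master seed).
#' @param ibi an [ibi_sim_params()] template for the per-seal-season IBI
#'   demonstration traces.
#' @param n_demo_traces how many seal-seasons get full IBI-level processing
#'   (the remaining seal-seasons use the generator's summary HRV values;
#'   IBI-level processing of all ~95 seasons is identical work repeated).
#' @param cleaning a [cleaning_config()].
#' @param min_seasons,n_boot_repeatability repeatability stage settings.
#' @param eps log offset for deviance responses.
#' @param n_boot_r2 bootstrap replicates for semipartial R2 CIs.
#' @param responses responses passed to [run_analysis()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("copingHRV_run_"),
                            seed = 1L,
                            colony = colony_sim_params(),
                            ibi = ibi_sim_params(),
                            n_demo_traces = 2L,
                            cleaning = cleaning_config(),
                            min_seasons = 2L,
                            n_boot_repeatability = 200L,
                            eps = 0.01,
                            n_boot_r2 = 200L,
                            responses = names(RESPONSE_COLUMNS)) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), colony = colony,
                 ibi = ibi, n_demo_traces = as.integer(n_demo_traces),
                 cleaning = cleaning, min_seasons = as.integer(min_seasons),
                 n_boot_repeatability = as.integer(n_boot_repeatability),
                 eps = eps, n_boot_r2 = as.integer(n_boot_r2),
                 responses = responses),
            class = "pipeline_config")
}

#' Validate a tabular input against a named schema
#'
#' Schemas: `"ibi"` (time_s, ibi_ms), `"behaviour"` (start_s, end_s, state),
#' `"captures"` (the capture-table layout), `"hrv"` (id, year,
#' resting_hrv_ms). Checks required columns, types, and invariants
#' (positive IBIs, start < end, cap2 after cap1, positive masses, no
#' duplicated id-year).
#'
#' @param x data.frame or path to a CSV (comment lines `#` allowed).
#' @param schema schema name.
#' @return character vector of violations (empty when valid), each naming
#'   the offending rows.
#' @export
validate_table <- function(x, schema = c("ibi", "behaviour", "captures",
                                         "hrv")) {
  schema <- match.arg(schema)
  if (is.character(x)) {
    check_that(file.exists(x), "file not found: %s", x)
    x <- utils::read.csv(x, comment.char = "#")
  }
  v <- character(0)
  need <- switch(schema,
    ibi = c("time_s", "ibi_ms"),
    behaviour = c("start_s", "end_s", "state"),
    captures = c("id", "year", "birthdate_doy", "cap1_date", "cap1_mass_kg",
                 "cap2_date", "cap2_mass_kg", "pup1_mass_kg", "pup2_mass_kg"),
    hrv = c("id", "year", "resting_hrv_ms"))
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  bad_rows <- function(cond, msg) {
    rows <- which(cond)
    if (length(rows)) v <<- c(v, sprintf("%s (rows %s)", msg,
                                         paste(utils::head(rows, 10L),
                                               collapse = ",")))
  }
  if (schema == "ibi") {
    bad_rows(!is.finite(x$ibi_ms) | x$ibi_ms <= 0, "ibi_ms must be > 0")
    bad_rows(c(FALSE, diff(x$time_s) <= 0), "time_s must strictly increase")
  } else if (schema == "behaviour") {
    bad_rows(x$end_s <= x$start_s, "intervals need start_s < end_s")
  } else if (schema == "captures") {
    bad_rows(x$cap2_date <= x$cap1_date, "cap2_date must exceed cap1_date")
    bad_rows(x$cap1_date < x$birthdate_doy,
             "cap1_date cannot precede birthdate")
    mass_cols <- c("cap1_mass_kg", "cap2_mass_kg", "pup1_mass_kg",
                   "pup2_mass_kg")
    for (mc in mass_cols) bad_rows(x[[mc]] <= 0, paste(mc, "must be > 0"))
    bad_rows(duplicated(x[, c("id", "year")]), "duplicated (id, year)")
  } else if (schema == "hrv") {
    bad_rows(!is.finite(x$resting_hrv_ms) | x$resting_hrv_ms < 0,
             "resting_hrv_ms must be >= 0")
    bad_rows(duplicated(x[, c("id", "year")]), "duplicated (id, year)")
  }
  v
}

#' Run the full pipeline on synthetic data
#'
#' Chains all stages: colony simulation, IBI-trace processing for a
#' demonstration subset of seal-seasons, HRV aggregation, repeatability,
#' performance metrics, and mixed-model inference. All outputs are written
#' under `config$out_dir` with `#` provenance headers (seed, config hash),
#' plus a JSON manifest recording versions, seeds, and per-stage row
#' counts.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with `manifest`, `analysis`, `repeatability`,
#'   and the main tables.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  cfg_hash <- config_hash(config)
  hdr <- c(sprintf("seed=%d", seed), sprintf("config_hash=%s", cfg_hash))
  manifest <- list(package = "copingHRV",
                   version = as.character(utils::packageVersion("copingHRV")),
                   seed = seed, config_hash = cfg_hash, stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      writeLines(conditionMessage(e),
                 file.path(config$out_dir, paste0(name, ".failed")))
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    message(sprintf("[copingHRV] stage %-13s done (%s)", name,
                    res$note))
    manifest$stages[[name]] <<- res$info
    res$value
  }

  colony_params <- config$colony
  colony_params$seed <- derive_seed(seed, "stage_colony")
  colony <- stage("simulate", {
    col <- simulate_colony(colony_params)
    write_csv_commented(col$captures,
                        file.path(config$out_dir, "captures.csv"), hdr)
    write_csv_commented(col$hrv, file.path(config$out_dir, "hrv_seasonal.csv"),
                        hdr)
    list(value = col,
         info = list(rows = nrow(col$captures),
                     true_repeatability = col$truth$true_repeatability),
         note = sprintf("%d mother-year rows", nrow(col$captures)))
  })

  windows_qc <- stage("process", {
    ## IBI-level demonstration: full trace processing for the first
    ## n_demo_traces seal-seasons
    n_demo <- min(config$n_demo_traces, nrow(colony$hrv))
    qc <- list()
    for (i in seq_len(n_demo)) {
      prm <- config$ibi
      prm$seed <- derive_seed(seed, paste0("trace", i))
      sim <- simulate_ibi_trace(prm, seal_id = colony$hrv$id[i],
                                year = colony$hrv$year[i])
      res <- process_trace(sim$trace, sim$behaviour, config$cleaning)
      w <- res$windows
      w$id <- colony$hrv$id[i]; w$year <- colony$hrv$year[i]
      qc[[i]] <- w[, setdiff(names(w), "beat_idx")]
    }
    qc <- do.call(rbind, qc)
    write_csv_commented(qc, file.path(config$out_dir, "window_qc.csv"), hdr)
    list(value = qc,
         info = list(windows = nrow(qc), retained = sum(qc$retained)),
         note = sprintf("%d windows, %d retained", nrow(qc),
                        sum(qc$retained)))
  })

  hrv_tables <- stage("hrv", {
    ind <- across_year_hrv(colony$hrv)
    write_csv_commented(ind, file.path(config$out_dir, "hrv_individual.csv"),
                        hdr)
    list(value = ind, info = list(individuals = nrow(ind)),
         note = sprintf("%d individuals", nrow(ind)))
  })

  rpt <- stage("repeatability", {
    r <- estimate_repeatability(colony$hrv, min_seasons = config$min_seasons,
                                n_boot = config$n_boot_repeatability,
                                seed = derive_seed(seed, "stage_rpt"))
    jsonlite::write_json(
      list(R = r$R, se = r$se, ci = r$ci, lrt_p = r$lrt_p, n_boot = r$n_boot,
           n_ids = r$n_ids, n_obs = r$n_obs, seed = seed,
           config_hash = cfg_hash),
      file.path(config$out_dir, "repeatability.json"),
      auto_unbox = TRUE, digits = NA)
    write_csv_commented(data.frame(id = names(r$Ri), Ri = unname(r$Ri)),
                        file.path(config$out_dir, "Ri.csv"), hdr)
    list(value = r, info = list(R = r$R, n_ids = r$n_ids),
         note = sprintf("R = %.3f", r$R))
  })

  analysis_table <- stage("metrics", {
    tab <- build_analysis_table(colony$captures, colony$hrv, eps = config$eps)
    write_csv_commented(tab, file.path(config$out_dir, "analysis_table.csv"),
                        hdr)
    list(value = tab, info = list(rows = nrow(tab)),
         note = sprintf("%d rows", nrow(tab)))
  })

  analysis <- stage("models", {
    a <- run_analysis(analysis_table, responses = config$responses,
                      n_boot = config$n_boot_r2,
                      seed = derive_seed(seed, "stage_models"))
    jsonlite::write_json(report_json(a),
                         file.path(config$out_dir, "models.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    for (resp in names(a$responses)) {
      r <- a$responses[[resp]]
      if (!is.null(r$error)) next
      write_csv_commented(r$candidates,
                          file.path(config$out_dir,
                                    sprintf("models_%s.csv", resp)), hdr)
    }
    list(value = a, info = list(responses = names(a$responses)),
         note = sprintf("%d responses", length(a$responses)))
  })

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, colony = colony,
                 windows_qc = windows_qc, hrv_individual = hrv_tables,
                 repeatability = rpt, analysis_table = analysis_table,
                 analysis = analysis))
}

config_hash <- function(config) {
  cfg <- config
  cfg$out_dir <- NULL  # volatile path; hash the scientific settings only
  s <- paste(utils::capture.output(utils::str(cfg)), collapse = "\n")
  codes <- utf8ToInt(s)
  sprintf("%08x", sum(codes * (seq_along(codes) %% 97 + 1)) %% 4294967291)
}

## flatten a run_analysis() result into JSON-friendly structures
report_json <- function(a) {
  resp <- lapply(a$responses, function(r) {
    if (!is.null(r$error)) return(list(error = r$error))
    list(best_model = model_label(r$best$terms),
         confidence_set = r$candidates[r$candidates$retained,
                                       c("model", "df", "AICc", "delta",
                                         "weight")],
         null_delta = r$candidates$delta[r$candidates$model == "Null"],
         coefficients = r$best_reml$coef_table,
         r2_marginal = r$r2$r2_marginal,
         r2_conditional = r$r2$r2_conditional,
         id_variance_share = r$r2$id_variance_share,
         term_r2 = r$r2$terms,
         hrv_birthdate_check = r$hrv_birthdate_check)
  })
  list(responses = resp, kruskal_wallis = a$kruskal_wallis, meta = a$meta)
}
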