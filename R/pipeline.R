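# End-to-end orchestration: simulate or ingest a cohort, derive the marker
# panel, fit the sex-stratified age-adjusted models, apply the significance
# gate, assemble the benchmark-dose table, and write report artifacts
# (markers CSV, association-table report, BMD-table report, JSON manifest).

.all_endpoints <- c("crcl", "egfr", "ln_b2mg", "tr_below_95", "tr_below_90")

#' Build a pipeline run configuration
#'
#' @param input path to a cohort CSV (see [read_cohort_csv()]), or `NULL`
#'   to simulate.
#' @param simulate list of arguments for [cohort_config()] (used when
#'   `input` is `NULL`).
#' @param endpoints endpoints to analyse; default all five.
#' @param bmrs benchmark responses.
#' @param reference_age years.
#' @param bmdl_method,risk_type,p0_hybrid,confidence see [bmd_spec()].
#' @param seed integer seed recorded in every artifact (overrides the
#'   simulate block's seed).
#' @param out output directory or `NULL` to skip writing.
#' @return object of class `run_config`.
#' @export
run_config <- function(input = NULL, simulate = list(), endpoints = .all_endpoints,
                       bmrs = c(0.05, 0.10), reference_age = 70,
                       bmdl_method = "profile", risk_type = "additional",
                       p0_hybrid = 0.05, confidence = 0.95,
                       seed = 1L, out = NULL) {
  bad <- setdiff(endpoints, .all_endpoints)
  if (length(bad)) stop_domain("unknown endpoints: %s", paste(bad, collapse = ", "))
  structure(list(input = input, simulate = simulate, endpoints = endpoints,
                 bmrs = bmrs, reference_age = reference_age,
                 bmdl_method = bmdl_method, risk_type = risk_type,
                 p0_hybrid = p0_hybrid, confidence = confidence,
                 seed = as.integer(seed), out = out),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; a `simulate` block
#' holds [cohort_config()] arguments (`mode`, `scale`, `seed`, ...).
#'
#' @param path YAML file path.
#' @param ... overrides applied after reading (e.g. `seed`, `out`).
#' @return a `run_config`.
#' @export
read_run_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  do.call(run_config, raw)
}

#' Run the full benchmark-dose pipeline
#'
#' Simulate/ingest -> marker derivation -> sex-stratified age-adjusted fits
#' -> significance gate -> benchmark-dose table. When `config$out` is set,
#' writes `markers.csv`, `associations.csv`/`.txt`, `bmd.csv`/`.txt`, and
#' `manifest.json` (parameters, seed, package version, per-stage record
#' accounting; no timestamps, so identical configs give byte-identical
#' manifests).
#'
#' @param config a [run_config()].
#' @return list with `cohort`, `panel`, `fits`, `associations`, `bmd`,
#'   `manifest`, invisibly when writing.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- "ingest"
  counts <- list()
  tryCatch({
    if (!is.null(config$input)) {
      cohort <- read_cohort_csv(config$input)
      source_kind <- "file"
    } else {
      stage <- "simulate"
      sim_args <- config$simulate
      sim_args$seed <- sim_args$seed %||% config$seed
      cc <- do.call(cohort_config, sim_args)
      cohort <- sample_cohort(cc)
      source_kind <- paste0("simulated (", cc$mode, " mode)")
    }
    counts$cohort <- nrow(cohort)

    stage <- "derive_panel"
    analyte_mode <- all(c("s_cr_jaffe", "u_cr") %in% names(cohort))
    if (analyte_mode) {
      panel <- derive_panel(cohort)
      counts$panel_issues <- nrow(attr(panel, "issues"))
      model_data <- data.frame(
        subject_id = panel$subject_id,
        sex = cohort$sex, age = cohort$age, ucd = panel$u_cd,
        crcl = panel$crcl, egfr = panel$egfr, u_b2mg = panel$u_b2mg,
        tr_below_95 = panel$tr_below_95, tr_below_90 = panel$tr_below_90,
        stringsAsFactors = FALSE)
    } else {
      panel <- NULL
      model_data <- cohort
    }

    stage <- "fit"
    fits <- list()
    for (ep in config$endpoints) {
      for (sx in c("man", "woman")) {
        fit <- if (ep %in% .continuous_endpoints) {
          fit_linear_age_adjusted(model_data, ep, sx)
        } else {
          fit_logistic_age_adjusted(model_data, ep, sx)
        }
        fits[[paste(ep, sx, sep = ".")]] <- fit
      }
    }
    counts$fits <- lapply(fits, function(f) {
      list(n = f$n, excluded = f$n_excluded)
    })

    stage <- "bmd"
    table3 <- bmd_table(fits, bmrs = config$bmrs,
                        reference_age = config$reference_age,
                        bmdl_method = config$bmdl_method,
                        risk_type = config$risk_type,
                        p0_hybrid = config$p0_hybrid,
                        confidence = config$confidence)
    table2 <- association_table(fits)

    manifest <- list(
      package = "renalbmd",
      version = as.character(utils::packageVersion("renalbmd")),
      seed = config$seed,
      source = source_kind,
      parameters = list(
        endpoints = config$endpoints, bmrs = config$bmrs,
        reference_age = config$reference_age,
        bmdl_method = config$bmdl_method, risk_type = config$risk_type,
        p0_hybrid = config$p0_hybrid, confidence = config$confidence),
      records = counts)

    result <- list(cohort = cohort, panel = panel, fits = fits,
                   associations = table2, bmd = table3, manifest = manifest)
    if (!is.null(config$out)) {
      stage <- "write"
      write_reports(result, config$out)
      return(invisible(result))
    }
    result
  }, error = function(e) {
    stop_domain("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Association-model report table
#'
#' One row per endpoint x sex: estimate (regression coefficient B for
#' linear fits, odds ratio for logistic fits), 95% CI and p-value for the
#' dose term, plus the age term.
#'
#' @param fits list of fit objects.
#' @return data.frame.
#' @export
association_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    if (inherits(f, "linear_fit")) {
      data.frame(endpoint = f$endpoint, sex = f$sex, model = "linear",
                 term = c("ucd", "age"), estimate = unname(f$coef[c("ucd", "age")]),
                 lower = unname(f$ci[c("ucd", "age"), "lower"]),
                 upper = unname(f$ci[c("ucd", "age"), "upper"]),
                 p = unname(f$p[c("ucd", "age")]), n = f$n,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(endpoint = f$endpoint, sex = f$sex, model = "logistic",
                 term = c("ucd", "age"), estimate = unname(f$or[c("ucd", "age")]),
                 lower = unname(f$or_ci[c("ucd", "age"), "lower"]),
                 upper = unname(f$or_ci[c("ucd", "age"), "upper"]),
                 p = unname(f$p[c("ucd", "age")]), n = f$n,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format a "BMDL (BMD)" report cell
#'
#' Doses rounded half-up to one decimal, e.g. `1.8 (2.6) μg/g Cr`.
#'
#' @param bmdl,bmd doses in ug/g Cr.
#' @return character vector.
#' @export
format_bmdl_bmd <- function(bmdl, bmd) {
  ifelse(is.na(bmd), "skipped (p >= 0.05)",
         paste0(fmt_dose(bmdl), " (", fmt_dose(bmd), ") μg/g Cr"))
}

#' Write the pipeline report bundle
#'
#' @param result a [run_pipeline()] result list.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_reports <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ok <- dir.exists(out_dir) && file.access(out_dir, 2) == 0
  if (!ok) stop_domain("write_reports: cannot write to '%s'", out_dir)

  if (!is.null(result$panel)) {
    write_marker_csv(result$panel, file.path(out_dir, "markers.csv"))
  }
  utils::write.csv(result$associations, file.path(out_dir, "associations.csv"),
                   row.names = FALSE)

  bmd <- result$bmd
  bmd_report <- data.frame(
    endpoint = bmd$endpoint, sex = bmd$sex, model = bmd$model,
    p0 = ifelse(is.na(bmd$p0), "", sprintf("%.1f%%", 100 * bmd$p0)),
    cutoff = ifelse(is.na(bmd$cutoff), "", fmt_dose(bmd$cutoff)),
    bmr = sprintf("%.0f%%", 100 * bmd$bmr),
    bmdl_bmd = format_bmdl_bmd(bmd$bmdl, bmd$bmd),
    status = bmd$status, stringsAsFactors = FALSE)
  utils::write.csv(bmd_report, file.path(out_dir, "bmd.csv"), row.names = FALSE,
                   fileEncoding = "UTF-8")

  txt <- c("Age-adjusted association models",
           utils::capture.output(print(result$associations, digits = 4)),
           "", "Benchmark doses (BMDL (BMD))",
           utils::capture.output(print(bmd_report)))
  writeLines(txt, file.path(out_dir, "report.txt"), useBytes = TRUE)

  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
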