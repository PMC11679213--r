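# Cohort CSV i/o. One row per subject, header names matching the subject
# record fields; an optional "# units:" comment line is validated against
# the locked units rather than trusted.

.locked_units <- c(
  age = "years", s_cr_jaffe = "mg/dL", u_cr = "mg/mL",
  urine_volume_2h = "mL", u_cd_per_L = "ug/L", u_b2mg_per_L = "ug/L",
  s_b2mg = "ug/L", height = "cm", weight = "kg")

.subject_cols <- c("subject_id", "sex", "area", "age", "s_cr_jaffe", "u_cr",
                   "urine_volume_2h", "u_cd_per_L", "u_b2mg_per_L", "s_b2mg",
                   "height", "weight")

#' Read a subject-level cohort CSV
#'
#' Expects one row per subject with the subject-record column names. An
#' optional leading comment line of the form
#' `# units: age=years,s_cr_jaffe=mg/dL,...` is checked against the locked
#' unit declarations; a mismatch is an error (units are never rescaled).
#' Missing values are empty cells.
#'
#' @param path path to the CSV file.
#' @return data.frame of subject records.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_domain("cohort file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (grepl("^#\\s*units:", first)) {
    decl <- sub("^#\\s*units:\\s*", "", first)
    pairs <- strsplit(strsplit(decl, ",")[[1]], "=")
    for (p in pairs) {
      key <- trimws(p[1]); val <- trimws(p[2])
      if (key %in% names(.locked_units) && !identical(val, unname(.locked_units[key]))) {
        stop_domain("unit mismatch for '%s': file declares '%s', expected '%s'",
                    key, val, .locked_units[key])
      }
    }
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  missing_cols <- setdiff(.subject_cols, names(df))
  if (length(missing_cols)) {
    stop_domain("cohort CSV missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  df
}

#' Write a cohort CSV with the units comment line
#' @param records subject-record data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(records, path) {
  units_line <- paste0("# units: ", paste(names(.locked_units), .locked_units,
                                          sep = "=", collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(units_line, con)
  utils::write.csv(records, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a derived marker panel to CSV
#' @param panel output of [derive_panel()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_csv <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
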