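# Derived renal endpoints from raw analytes: body-surface-corrected 2-h
# creatinine clearance, eGFR (Japanese Society of Nephrology equation),
# creatinine-corrected urinary concentrations, and percent tubular
# reabsorption of beta2-microglobulin with its 95%/90% dichotomizations.
#
# Locked units: serum creatinine mg/dL (Jaffe), urinary creatinine mg/mL,
# beta2-microglobulin ug/L, urinary cadmium ug/L, urine volume mL per 2 h.

#' Body surface area by the Du Bois formula
#'
#' `BSA = 0.007184 * height^0.725 * weight^0.425`, strictly increasing in
#' both arguments.
#'
#' @param height height in cm, > 0.
#' @param weight weight in kg, > 0.
#' @return body surface area in m^2.
#' @examples
#' bsa_du_bois(160, 60) # 1.622
#' @export
bsa_du_bois <- function(height, weight) {
  if (any(!is.finite(height) | height <= 0) || any(!is.finite(weight) | weight <= 0)) {
    stop_domain("bsa_du_bois: height and weight must be positive and finite")
  }
  0.007184 * height^0.725 * weight^0.425
}

#' 2-h creatinine clearance normalized to 1.73 m^2
#'
#' CrCl (mL/min) = U-Cr (mg/mL) x UV (mL) / (S-Cr (mg/dL) x 0.01 x 2 h x
#' 60 min) x 1.73 / BSA. Serum creatinine is the measured (Jaffe) value;
#' the clearance uses it as printed, without the enzymatic offset.
#'
#' @param u_cr urinary creatinine, mg/mL (>= 0).
#' @param urine_volume_2h 2-h urine volume, mL (> 0).
#' @param s_cr_jaffe serum creatinine, mg/dL (> 0).
#' @param bsa body surface area, m^2 (> 0).
#' @return clearance in mL/min per 1.73 m^2.
#' @examples
#' crcl_2h(1.0, 120, 1.0, 1.73) # 100
#' @export
crcl_2h <- function(u_cr, urine_volume_2h, s_cr_jaffe, bsa) {
  if (any(!is.finite(s_cr_jaffe) | s_cr_jaffe <= 0)) {
    stop_domain("crcl_2h: s_cr_jaffe must be > 0")
  }
  if (any(!is.finite(bsa) | bsa <= 0)) stop_domain("crcl_2h: bsa must be > 0")
  if (any(!is.finite(urine_volume_2h) | urine_volume_2h <= 0)) {
    stop_domain("crcl_2h: urine_volume_2h must be > 0")
  }
  if (any(!is.finite(u_cr) | u_cr < 0)) stop_domain("crcl_2h: u_cr must be >= 0")
  (u_cr * urine_volume_2h) / (s_cr_jaffe * 0.01 * 2 * 60) * 1.73 / bsa
}

#' Convert Jaffe serum creatinine to the enzymatic scale
#'
#' The Jaffe colorimetric assay reads about 0.2 mg/dL above the enzymatic
#' method, so the eGFR equation (which expects enzymatic values) is fed
#' `s_cr_jaffe - 0.2`. Values that become non-positive are returned as `NA`
#' (record-level invalidation, not an error) so that callers can flag the
#' record.
#'
#' @param s_cr_jaffe serum creatinine by the Jaffe method, mg/dL.
#' @return enzymatic-scale serum creatinine, mg/dL, `NA` where the corrected
#'   value would be <= 0.
#' @export
jaffe_to_enzymatic <- function(s_cr_jaffe) {
  if (any(!is.finite(s_cr_jaffe) | s_cr_jaffe <= 0)) {
    stop_domain("jaffe_to_enzymatic: s_cr_jaffe must be > 0")
  }
  out <- s_cr_jaffe - 0.2
  out[out <= 0] <- NA_real_
  out
}

#' eGFR by the Japanese Society of Nephrology equation
#'
#' `eGFR = 194 * S-Cr^-1.094 * age^-0.287`, times 0.739 for women. Serum
#' creatinine must already be on the enzymatic scale
#' (see [jaffe_to_enzymatic()]).
#'
#' @param s_cr_enzymatic serum creatinine, mg/dL (> 0); `NA` propagates.
#' @param age age in years (> 0).
#' @param sex `"man"` or `"woman"` (vectorized).
#' @return eGFR in mL/min/1.73 m^2.
#' @examples
#' egfr_japanese(1.0, 70, "man") # 57.31
#' @export
egfr_japanese <- function(s_cr_enzymatic, age, sex) {
  sex <- match_sex(sex)
  ok <- is.na(s_cr_enzymatic) | (is.finite(s_cr_enzymatic) & s_cr_enzymatic > 0)
  if (!all(ok)) stop_domain("egfr_japanese: s_cr_enzymatic must be > 0 or NA")
  if (any(!is.finite(age) | age <= 0)) stop_domain("egfr_japanese: age must be > 0")
  out <- 194 * s_cr_enzymatic^(-1.094) * age^(-0.287)
  out * ifelse(sex == "woman", 0.739, 1)
}

#' Creatinine-correct a urinary concentration
#'
#' Divides a per-litre urinary concentration by urinary creatinine
#' (mg/mL is identically g/L, so ug/L divided by g/L is ug/g Cr).
#'
#' @param conc_per_L analyte concentration, ug/L (>= 0).
#' @param u_cr urinary creatinine, mg/mL (> 0).
#' @return concentration in ug/g creatinine.
#' @export
creatinine_correct <- function(conc_per_L, u_cr) {
  if (any(!is.finite(u_cr) | u_cr <= 0)) {
    stop_domain("creatinine_correct: u_cr must be > 0")
  }
  if (any(!is.finite(conc_per_L) | conc_per_L < 0)) {
    stop_domain("creatinine_correct: conc_per_L must be >= 0")
  }
  conc_per_L / u_cr
}

#' Percent tubular reabsorption of beta2-microglobulin
#'
#' `%TR = (1 - U-b2MG * S-Cr * 0.01 / (S-b2MG * U-Cr)) * 100`. Equals 100
#' exactly when urinary beta2-MG is zero; may be negative in severe tubular
#' failure and is deliberately not clamped (clamping would corrupt
#' dichotomization counts near extreme exposure).
#'
#' @param u_b2mg_per_L urinary beta2-microglobulin, ug/L (>= 0).
#' @param s_cr_jaffe serum creatinine, mg/dL (> 0).
#' @param s_b2mg serum beta2-microglobulin, ug/L (> 0).
#' @param u_cr urinary creatinine, mg/mL (> 0).
#' @return percent tubular reabsorption (<= 100, unbounded below).
#' @examples
#' tr_b2mg(0, 1.0, 2000, 1.0)    # 100
#' tr_b2mg(1000, 1.0, 2000, 1.0) # 99.5
#' @export
tr_b2mg <- function(u_b2mg_per_L, s_cr_jaffe, s_b2mg, u_cr) {
  if (any(!is.finite(s_b2mg) | s_b2mg <= 0)) stop_domain("tr_b2mg: s_b2mg must be > 0")
  if (any(!is.finite(u_cr) | u_cr <= 0)) stop_domain("tr_b2mg: u_cr must be > 0")
  if (any(!is.finite(s_cr_jaffe) | s_cr_jaffe <= 0)) {
    stop_domain("tr_b2mg: s_cr_jaffe must be > 0")
  }
  if (any(!is.finite(u_b2mg_per_L) | u_b2mg_per_L < 0)) {
    stop_domain("tr_b2mg: u_b2mg_per_L must be >= 0")
  }
  (1 - (u_b2mg_per_L * s_cr_jaffe * 0.01) / (s_b2mg * u_cr)) * 100
}

match_sex <- function(sex) {
  sex <- as.character(sex)
  bad <- !sex %in% c("man", "woman")
  if (any(bad)) stop_domain("sex must be 'man' or 'woman' (got '%s')", sex[bad][1])
  sex
}

#' Derive the full marker panel for a cohort of subject records
#'
#' Computes CrCl, eGFR, creatinine-corrected U-Cd and U-beta2-MG, percent
#' tubular reabsorption of beta2-MG, and the strict `< 95` / `< 90` percent
#' flags, per subject. Per-marker record-level problems (e.g. a Jaffe
#' creatinine at or below the 0.2 mg/dL offset, which invalidates eGFR) set
#' the affected marker to `NA` and are collected in the `issues` attribute
#' rather than aborting the run.
#'
#' @param records data.frame with columns `subject_id`, `sex`, `area`,
#'   `age`, `s_cr_jaffe`, `u_cr`, `urine_volume_2h`, `u_cd_per_L`,
#'   `u_b2mg_per_L`, `s_b2mg`, `height`, `weight` (locked units, see
#'   [read_cohort_csv()]).
#' @return data.frame with columns `subject_id`, `crcl`, `egfr`, `u_cd`,
#'   `u_b2mg`, `tr_b2mg`, `tr_below_95`, `tr_below_90`; attribute `issues`
#'   is a data.frame (`subject_id`, `marker`, `reason`) of invalidated
#'   markers.
#' @export
derive_panel <- function(records) {
  req <- c("subject_id", "sex", "age", "s_cr_jaffe", "u_cr", "urine_volume_2h",
           "u_cd_per_L", "u_b2mg_per_L", "s_b2mg", "height", "weight")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    stop_domain("derive_panel: missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(records)
  issues <- list()
  note <- function(id, marker, reason) {
    issues[[length(issues) + 1L]] <<- data.frame(
      subject_id = id, marker = marker, reason = reason,
      stringsAsFactors = FALSE)
  }

  with_guard <- function(marker, ids, f) {
    # evaluate per record so one bad record cannot take down the column
    vapply(seq_len(n), function(i) {
      val <- tryCatch(f(i), error = function(e) {
        note(ids[i], marker, conditionMessage(e))
        NA_real_
      })
      if (is.na(val)) val <- NA_real_
      val
    }, numeric(1))
  }

  ids <- as.character(records$subject_id)
  sex <- match_sex(records$sex)

  crcl <- with_guard("crcl", ids, function(i) {
    bsa <- bsa_du_bois(records$height[i], records$weight[i])
    crcl_2h(records$u_cr[i], records$urine_volume_2h[i], records$s_cr_jaffe[i], bsa)
  })
  egfr <- with_guard("egfr", ids, function(i) {
    s_enz <- jaffe_to_enzymatic(records$s_cr_jaffe[i])
    if (is.na(s_enz)) stop("corrected serum creatinine <= 0")
    egfr_japanese(s_enz, records$age[i], sex[i])
  })
  u_cd <- with_guard("u_cd", ids, function(i) {
    creatinine_correct(records$u_cd_per_L[i], records$u_cr[i])
  })
  u_b2mg <- with_guard("u_b2mg", ids, function(i) {
    creatinine_correct(records$u_b2mg_per_L[i], records$u_cr[i])
  })
  tr <- with_guard("tr_b2mg", ids, function(i) {
    tr_b2mg(records$u_b2mg_per_L[i], records$s_cr_jaffe[i],
            records$s_b2mg[i], records$u_cr[i])
  })

  out <- data.frame(
    subject_id = ids,
    crcl = crcl, egfr = egfr, u_cd = u_cd, u_b2mg = u_b2mg, tr_b2mg = tr,
    tr_below_95 = tr < 95,
    tr_below_90 = tr < 90,
    stringsAsFactors = FALSE)
  attr(out, "issues") <- if (length(issues)) {
    do.call(rbind, issues)
  } else {
    data.frame(subject_id = character(), marker = character(),
               reason = character(), stringsAsFactors = FALSE)
  }
  out
}
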