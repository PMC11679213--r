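# Benchmark-dose engine.
#
# Continuous endpoints use the hybrid approach: around the age-adjusted
# regression mean, residuals are normal with SD sigma, the background
# adverse probability P(0) (default 5%) fixes a cut-off in endpoint units,
# and the BMD is the dose at which the adverse-tail probability rises by
# the benchmark response. Under additional risk this has the closed form
#   BMD = (z(1 - p0) - z(1 - p0 - bmr)) * sigma / |beta_dose|.
# Dichotomous endpoints use the fitted logistic model with
#   BMD = (logit(p_target) - logit(p0)) / beta_dose,
# p0 estimated from the fit at the reference age. BMDLs (one-sided lower
# confidence limits) come from profile likelihood (default), the delta
# method on ln BMD, or a one-sided bound on the slope.

#' Benchmark-dose specification
#'
#' @param endpoint endpoint id.
#' @param model_kind `"hybrid_continuous"` or `"logistic"`.
#' @param bmr benchmark response (probability increment), default 0.05.
#' @param p0 background adverse probability; fixed at 0.05 for hybrid
#'   endpoints, `NA` (estimated from the fit) for logistic ones.
#' @param risk_type `"additional"` (P(d) - P(0) = BMR, the default) or
#'   `"extra"` ((P(d) - P(0)) / (1 - P(0)) = BMR).
#' @param adversity which tail is adverse; defaults by endpoint
#'   (low for CrCl/eGFR, high for ln beta2-MG).
#' @param reference_age age (years) at which age-adjusted quantities are
#'   evaluated; default 70.
#' @param bmdl_method `"profile"` (default, falls back to delta on
#'   bracketing failure), `"delta"`, or `"slope_bound"`.
#' @param confidence one-sided confidence level for the BMDL, default 0.95.
#' @return object of class `bmd_spec`.
#' @export
bmd_spec <- function(endpoint,
                     model_kind = c("hybrid_continuous", "logistic"),
                     bmr = 0.05,
                     p0 = if (match.arg(model_kind) == "hybrid_continuous") 0.05 else NA_real_,
                     risk_type = c("additional", "extra"),
                     adversity = NULL,
                     reference_age = 70,
                     bmdl_method = c("profile", "delta", "slope_bound"),
                     confidence = 0.95) {
  model_kind <- match.arg(model_kind)
  risk_type <- match.arg(risk_type)
  bmdl_method <- match.arg(bmdl_method)
  if (is.null(adversity)) {
    adversity <- switch(endpoint,
      crcl = "low_is_adverse", egfr = "low_is_adverse",
      ln_b2mg = "high_is_adverse",
      "low_is_adverse")
  }
  adversity <- match.arg(adversity, c("low_is_adverse", "high_is_adverse"))
  if (!(bmr > 0 && bmr < 1)) stop_domain("bmd_spec: bmr must be in (0, 1)")
  if (!is.na(p0) && !(p0 > 0 && p0 + bmr < 1)) {
    stop_domain("bmd_spec: need 0 < p0 and p0 + bmr < 1")
  }
  structure(list(endpoint = endpoint, model_kind = model_kind, bmr = bmr,
                 p0 = p0, risk_type = risk_type, adversity = adversity,
                 reference_age = reference_age, bmdl_method = bmdl_method,
                 confidence = confidence),
            class = "bmd_spec")
}

# probability that defines the BMD: additional risk targets p0 + bmr,
# extra risk targets p0 + bmr * (1 - p0)
target_prob <- function(p0, bmr, risk_type) {
  pt <- switch(risk_type,
               additional = p0 + bmr,
               extra = p0 + bmr * (1 - p0),
               stop_domain("unknown risk_type '%s'", risk_type))
  if (pt >= 1) stop_domain("target probability %.3f >= 1", pt)
  pt
}

adverse_sign <- function(adversity) {
  if (adversity == "low_is_adverse") -1 else 1
}

check_adverse_slope <- function(beta, spec, what) {
  s <- adverse_sign(spec$adversity)
  if (beta == 0 || sign(beta) != s) {
    stop_domain("%s: dose slope %.4g is not adverse-signed for %s (%s)",
                what, beta, spec$endpoint, spec$adversity)
  }
  invisible(s)
}

# ---- hybrid approach (continuous endpoints) --------------------------------

#' Hybrid-approach cut-off value
#'
#' The endpoint level whose background tail probability at dose zero (and
#' the reference age) equals P(0):
#' `mu0 -/+ z(1 - p0) * sigma` for low-/high-is-adverse. Returned on the
#' model scale; for ln-transformed endpoints exponentiate for reporting.
#'
#' @param fit a `linear_fit`.
#' @param spec a `bmd_spec` with `model_kind = "hybrid_continuous"`.
#' @return cut-off in (model-scale) endpoint units.
#' @export
hybrid_cutoff <- function(fit, spec) {
  stopifnot(inherits(fit, "linear_fit"), inherits(spec, "bmd_spec"))
  if (fit$sigma <= 0) stop_domain("hybrid_cutoff: residual SD must be > 0")
  mu0 <- unname(fit$coef["intercept"] + fit$coef["age"] * spec$reference_age)
  z <- stats::qnorm(1 - spec$p0)
  mu0 + adverse_sign(spec$adversity) * z * fit$sigma
}

hybrid_K <- function(spec) {
  pt <- target_prob(spec$p0, spec$bmr, spec$risk_type)
  stats::qnorm(1 - spec$p0) - stats::qnorm(1 - pt)
}

#' Hybrid-approach benchmark dose
#'
#' Closed form `K * sigma / |beta_dose|` with
#' `K = z(1 - p0) - z(1 - p_target)`; equals the root of
#' `P(adverse at dose d) - p0 = BMR` for additional risk.
#'
#' @inheritParams hybrid_cutoff
#' @return benchmark dose in ug/g Cr.
#' @export
hybrid_bmd <- function(fit, spec) {
  stopifnot(inherits(fit, "linear_fit"), inherits(spec, "bmd_spec"))
  beta <- unname(fit$coef["ucd"])
  check_adverse_slope(beta, spec, "hybrid_bmd")
  hybrid_K(spec) * fit$sigma / abs(beta)
}

#' Hybrid-approach BMDL (one-sided lower confidence limit)
#'
#' Methods:
#' * `profile`: smallest dose d0 at which the likelihood-ratio statistic of
#'   the constrained normal model (BMD held at d0, i.e. the dose slope tied
#'   to the residual SD) stays within the one-sided critical value
#'   `qchisq(2 * confidence - 1, 1)` (2.706 at 95%). Falls back to the
#'   delta method with a warning if the bracket fails.
#' * `delta`: `BMD * exp(-z * SE(ln BMD))` with
#'   `Var(ln BMD) = Var(beta)/beta^2 + 1/(2 * (n - 3))` (the second term is
#'   the ln-scale variance of sigma-hat).
#' * `slope_bound`: the closed form evaluated at the adverse-direction
#'   one-sided `confidence` bound of the dose slope (t distribution,
#'   n - 3 df).
#'
#' @inheritParams hybrid_cutoff
#' @return BMDL in ug/g Cr.
#' @export
hybrid_bmdl <- function(fit, spec) {
  bmd <- hybrid_bmd(fit, spec)
  switch(spec$bmdl_method,
    delta = hybrid_bmdl_delta(fit, spec, bmd),
    slope_bound = hybrid_bmdl_slope(fit, spec, bmd),
    profile = tryCatch(
      hybrid_bmdl_profile(fit, spec),
      bracket_failure = function(e) {
        warning("profile BMDL bracket failed (", conditionMessage(e),
                "); falling back to delta method", call. = FALSE)
        hybrid_bmdl_delta(fit, spec, bmd)
      }))
}

hybrid_bmdl_delta <- function(fit, spec, bmd) {
  beta <- unname(fit$coef["ucd"])
  v_ln <- fit$vcov["ucd", "ucd"] / beta^2 + 1 / (2 * fit$df)
  bmd * exp(-stats::qnorm(spec$confidence) * sqrt(v_ln))
}

hybrid_bmdl_slope <- function(fit, spec, bmd) {
  beta <- unname(fit$coef["ucd"])
  s <- adverse_sign(spec$adversity)
  beta_bound <- beta + s * stats::qt(spec$confidence, fit$df) * unname(fit$se["ucd"])
  hybrid_K(spec) * fit$sigma / abs(beta_bound)
}

hybrid_bmdl_profile <- function(fit, spec) {
  dat <- fit$data
  n <- nrow(dat)
  K <- hybrid_K(spec)
  s <- adverse_sign(spec$adversity)
  X0 <- cbind(1, dat$age)

  loglik <- function(b0, bage, beta, sigma) {
    res <- dat$y - b0 - beta * dat$ucd - bage * dat$age
    -n / 2 * log(2 * pi * sigma^2) - sum(res^2) / (2 * sigma^2)
  }
  # unconstrained ML (OLS coefficients, ML variance RSS/n)
  beta_hat <- unname(fit$coef["ucd"])
  res_full <- dat$y - cbind(1, dat$ucd, dat$age) %*%
    c(fit$coef["intercept"], beta_hat, fit$coef["age"])
  sigma_ml <- sqrt(sum(res_full^2) / n)
  ll_full <- loglik(unname(fit$coef["intercept"]), unname(fit$coef["age"]),
                    beta_hat, sigma_ml)
  bmd_ml <- K * sigma_ml / abs(beta_hat)

  nll_constrained <- function(par, d0) {
    sigma <- exp(par[3])
    beta <- s * K * sigma / d0
    -loglik(par[1], par[2], beta, sigma)
  }
  start <- c(unname(fit$coef["intercept"]), unname(fit$coef["age"]), log(sigma_ml))
  lr <- function(d0) {
    opt <- stats::optim(start, nll_constrained, d0 = d0, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    2 * (ll_full + opt$value)
  }
  crit <- stats::qchisq(2 * spec$confidence - 1, df = 1)

  lo <- bmd_ml / 2
  for (i in 1:12) {
    if (lr(lo) >= crit) break
    lo <- lo / 2
  }
  if (lr(lo) < crit) {
    stop(structure(class = c("bracket_failure", "error", "condition"),
                   list(message = "no lower bracket for the profile root",
                        call = NULL)))
  }
  stats::uniroot(function(d) lr(d) - crit, lower = lo, upper = bmd_ml,
                 tol = 1e-8 * bmd_ml)$root
}

# ---- logistic (dichotomous endpoints) --------------------------------------

#' Background prevalence from a logistic fit
#'
#' Inverse-logit of the linear predictor at dose zero and the reference
#' age: `plogis(intercept + beta_age * reference_age)`.
#'
#' @param fit a `logistic_fit`.
#' @param spec a `bmd_spec` with `model_kind = "logistic"`.
#' @return background probability P(0).
#' @export
logistic_background <- function(fit, spec) {
  stopifnot(inherits(fit, "logistic_fit"))
  stats::plogis(unname(fit$coef["intercept"] + fit$coef["age"] * spec$reference_age))
}

#' Closed-form logistic benchmark dose
#'
#' `BMD = (logit(p_target) - logit(p0)) / beta_dose` with
#' `p_target = p0 + bmr` (additional risk) or `p0 + bmr * (1 - p0)` (extra
#' risk). Independent of the age coefficient once p0 is given.
#'
#' @param beta_dose log-odds slope per ug/g Cr (> 0).
#' @param p0 background probability.
#' @param bmr benchmark response.
#' @param risk_type `"additional"` or `"extra"`.
#' @return benchmark dose in ug/g Cr.
#' @examples
#' logistic_bmd(log(1.17), 0.118, 0.05) # 2.62
#' @export
logistic_bmd <- function(beta_dose, p0, bmr, risk_type = "additional") {
  if (!is.finite(beta_dose) || beta_dose <= 0) {
    stop_domain("logistic_bmd: beta_dose must be > 0 (adverse direction)")
  }
  if (!(p0 > 0 && p0 < 1 && bmr > 0)) stop_domain("logistic_bmd: invalid p0/bmr")
  pt <- target_prob(p0, bmr, risk_type)
  (stats::qlogis(pt) - stats::qlogis(p0)) / beta_dose
}

logistic_bmd_from_fit <- function(fit, spec) {
  p0 <- if (is.na(spec$p0)) logistic_background(fit, spec) else spec$p0
  list(bmd = logistic_bmd(unname(fit$coef["ucd"]), p0, spec$bmr, spec$risk_type),
       p0 = p0)
}

#' Logistic BMDL (one-sided lower confidence limit)
#'
#' Methods as in [hybrid_bmdl()]: `profile` re-parameterizes the intercept
#' through the background prevalence and ties the dose slope to the BMD;
#' `delta` propagates the covariance of (intercept, dose, age) through
#' ln BMD; `slope_bound` evaluates the closed form at the one-sided upper
#' bound of the dose slope.
#'
#' @param fit a `logistic_fit`.
#' @param spec a `bmd_spec` with `model_kind = "logistic"`.
#' @return BMDL in ug/g Cr.
#' @export
logistic_bmdl <- function(fit, spec) {
  est <- logistic_bmd_from_fit(fit, spec)
  switch(spec$bmdl_method,
    delta = logistic_bmdl_delta(fit, spec, est),
    slope_bound = logistic_bmdl_slope(fit, spec, est),
    profile = tryCatch(
      logistic_bmdl_profile(fit, spec, est),
      bracket_failure = function(e) {
        warning("profile BMDL bracket failed (", conditionMessage(e),
                "); falling back to delta method", call. = FALSE)
        logistic_bmdl_delta(fit, spec, est)
      }))
}

logistic_bmdl_delta <- function(fit, spec, est) {
  A <- spec$reference_age
  ln_bmd <- function(theta) {
    p0 <- if (is.na(spec$p0)) stats::plogis(theta[1] + theta[3] * A) else spec$p0
    pt <- target_prob(p0, spec$bmr, spec$risk_type)
    log((stats::qlogis(pt) - stats::qlogis(p0)) / theta[2])
  }
  theta <- unname(fit$coef)
  g <- num_gradient(ln_bmd, theta)
  se <- sqrt(drop(t(g) %*% fit$vcov %*% g))
  est$bmd * exp(-stats::qnorm(spec$confidence) * se)
}

logistic_bmdl_slope <- function(fit, spec, est) {
  b1 <- unname(fit$coef["ucd"]) +
    stats::qnorm(spec$confidence) * unname(fit$se["ucd"])
  logistic_bmd(b1, est$p0, spec$bmr, spec$risk_type)
}

logistic_bmdl_profile <- function(fit, spec, est) {
  dat <- fit$data
  A <- spec$reference_age
  ll <- function(b0, b1, bage) {
    eta <- b0 + b1 * dat$ucd + bage * dat$age
    sum(dat$y * eta - log1p(exp(eta)))
  }
  ll_full <- ll(fit$coef["intercept"], fit$coef["ucd"], fit$coef["age"])

  nll_constrained <- function(par, d0) {
    p0 <- if (is.na(spec$p0)) stats::plogis(par[1] + par[2] * A) else spec$p0
    pt <- switch(spec$risk_type, additional = p0 + spec$bmr,
                 extra = p0 + spec$bmr * (1 - p0))
    # keep the optimizer out of the degenerate region p_target >= 1
    if (!is.finite(pt) || pt >= 1 || p0 <= 0 || p0 >= 1) return(1e10)
    b1 <- (stats::qlogis(pt) - stats::qlogis(p0)) / d0
    -ll(par[1], b1, par[2])
  }
  start <- c(unname(fit$coef["intercept"]), unname(fit$coef["age"]))
  lr <- function(d0) {
    opt <- stats::optim(start, nll_constrained, d0 = d0, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    2 * (ll_full + opt$value)
  }
  crit <- stats::qchisq(2 * spec$confidence - 1, df = 1)

  lo <- est$bmd / 2
  for (i in 1:12) {
    if (lr(lo) >= crit) break
    lo <- lo / 2
  }
  if (lr(lo) < crit) {
    stop(structure(class = c("bracket_failure", "error", "condition"),
                   list(message = "no lower bracket for the profile root",
                        call = NULL)))
  }
  stats::uniroot(function(d) lr(d) - crit, lower = lo, upper = est$bmd,
                 tol = 1e-8 * est$bmd)$root
}

# ---- table assembly --------------------------------------------------------

#' Assemble the benchmark-dose table
#'
#' One row per fitted endpoint x sex x BMR. Endpoints failing the
#' significance gate (dose p >= 0.05) appear as explicit skipped rows with
#' no doses. Cut-offs for ln-transformed endpoints are exponentiated to the
#' natural scale for reporting.
#'
#' @param fits list of `linear_fit` / `logistic_fit` objects.
#' @param bmrs benchmark responses, default `c(0.05, 0.10)`.
#' @param reference_age years, default 70.
#' @param bmdl_method passed to [bmd_spec()].
#' @param risk_type passed to [bmd_spec()].
#' @param p0_hybrid fixed background probability for hybrid endpoints.
#' @param confidence one-sided BMDL level.
#' @return data.frame with columns `endpoint`, `sex`, `model`, `p0`,
#'   `cutoff`, `bmr`, `bmd`, `bmdl`, `p_dose`, `status`.
#' @export
bmd_table <- function(fits, bmrs = c(0.05, 0.10), reference_age = 70,
                      bmdl_method = "profile", risk_type = "additional",
                      p0_hybrid = 0.05, confidence = 0.95) {
  rows <- list()
  for (fit in fits) {
    is_hybrid <- inherits(fit, "linear_fit")
    gate <- significance_gate(fit)
    for (bmr in bmrs) {
      spec <- bmd_spec(
        endpoint = fit$endpoint,
        model_kind = if (is_hybrid) "hybrid_continuous" else "logistic",
        bmr = bmr,
        p0 = if (is_hybrid) p0_hybrid else NA_real_,
        risk_type = risk_type, reference_age = reference_age,
        bmdl_method = bmdl_method, confidence = confidence)
      if (gate == "skip") {
        rows[[length(rows) + 1L]] <- data.frame(
          endpoint = fit$endpoint, sex = fit$sex,
          model = spec$model_kind, p0 = NA_real_, cutoff = NA_real_,
          bmr = bmr, bmd = NA_real_, bmdl = NA_real_,
          p_dose = unname(fit$p["ucd"]), status = "skipped (p >= 0.05)",
          stringsAsFactors = FALSE)
        next
      }
      if (is_hybrid) {
        cutoff <- hybrid_cutoff(fit, spec)
        if (fit$endpoint == "ln_b2mg") cutoff <- exp(cutoff)
        bmd <- hybrid_bmd(fit, spec)
        bmdl <- hybrid_bmdl(fit, spec)
        p0 <- spec$p0
      } else {
        est <- logistic_bmd_from_fit(fit, spec)
        bmd <- est$bmd
        p0 <- est$p0
        bmdl <- logistic_bmdl(fit, spec)
        cutoff <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        endpoint = fit$endpoint, sex = fit$sex, model = spec$model_kind,
        p0 = p0, cutoff = cutoff, bmr = bmr, bmd = bmd, bmdl = bmdl,
        p_dose = unname(fit$p["ucd"]), status = "ok",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
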