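# Independent numeric oracle for the hybrid benchmark dose: solves
# P(adverse at dose d) - p_target = 0 by root-finding on the normal tail
# probability, never touching the engine's closed form.

oracle_hybrid_bmd <- function(beta, sigma, p0, bmr, risk_type = "additional",
                              adversity = "low_is_adverse") {
  mu0 <- 100  # cut-off location cancels; any background mean works
  s <- if (adversity == "low_is_adverse") -1 else 1
  cutoff <- mu0 + s * qnorm(1 - p0) * sigma
  pt <- if (risk_type == "additional") p0 + bmr else p0 + bmr * (1 - p0)
  # adverse probability: low tail for low_is_adverse, upper tail otherwise
  prob <- function(d) {
    mu <- mu0 + beta * d
    if (s < 0) pnorm((cutoff - mu) / sigma) else pnorm((mu - cutoff) / sigma)
  }
  uniroot(function(d) prob(d) - pt, lower = 0, upper = 1e4 * sigma / abs(beta),
          tol = 1e-12)$root
}
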