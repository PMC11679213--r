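#' Round half away from zero at a given number of decimals
#'
#' Report tables round doses half-up at one decimal (4.65 -> "4.7"),
#' unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a dose to one decimal, half-up
#' @param x numeric scalar or vector.
#' @return character vector like "4.6".
#' @keywords internal
fmt_dose <- function(x) {
  sprintf("%.1f", round_half_up(x, 1))
}

# central-difference gradient; h scaled to parameter magnitude
num_gradient <- function(f, x, h = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    g[i] <- (f(xp) - f(xm)) / (2 * hi)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
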