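#' Exact binomial upper tail P(X >= r)
#'
#' Stable exact summation of binomial probabilities in log space, used by the
#' single-stage design search. `r` may range from 0 (full mass, returns 1) to
#' `n + 1` (empty event, returns 0).
#'
#' @param n number of trials.
#' @param r response threshold (success count).
#' @param p success probability.
#' @return `P(X >= r)` for `X ~ Binomial(n, p)`.
#' @export
binomial_tail <- function(n, r, p) {
  n <- as.integer(n); r <- as.integer(r)
  if (is.na(n) || n < 0L) stop("binomial_tail: n must be a non-negative integer")
  if (is.na(r) || r < 0L || r > n + 1L)
    stop("binomial_tail: r must lie in 0..(n+1)")
  if (is.na(p) || p < 0 || p > 1) stop("binomial_tail: p must lie in [0, 1]")
  if (r == 0L) return(1)
  if (r == n + 1L) return(0)
  if (p == 0) return(0)
  if (p == 1) return(1)
  k <- r:n
  lg <- lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)
  m <- max(lg)
  min(1, exp(m) * sum(exp(lg - m)))
}

#' Exact single-stage (A'Hern) phase II design
#'
#' Finds the smallest sample size `n` admitting a response threshold `r` such
#' that the exact binomial type-I error `P(X >= r | n, p0)` does not exceed
#' `alpha` and the exact power `P(X >= r | n, p1)` is at least `power`. The
#' study is declared positive when at least `r` responses are observed. At the
#' returned `n`, `r` is the smallest threshold meeting the alpha constraint
#' (which maximizes power among admissible thresholds).
#'
#' @param p0 unacceptable (null) response probability.
#' @param p1 target (alternative) response probability; must exceed `p0`.
#' @param alpha one-sided nominal type-I error.
#' @param power nominal power floor.
#' @param n_max search cap for the sample size.
#' @return an object of class `ahern_design` with fields `p0`, `p1`,
#'   `alpha_nominal`, `power_nominal`, `n`, `r`, `alpha_exact`, `power_exact`.
#' @examples
#' ahern_design(0.10, 0.30, 0.05, 0.85)
#' @export
ahern_design <- function(p0, p1, alpha = 0.05, power = 0.85, n_max = 1000L) {
  if (!(p0 > 0 && p1 < 1 && p0 < p1))
    stop("ahern_design: need 0 < p0 < p1 < 1 (no valid design otherwise)")
  if (!(alpha > 0 && alpha < 1 && power > 0 && power < 1))
    stop("ahern_design: alpha and power must lie in (0, 1)")
  for (n in seq_len(n_max)) {
    # smallest r meeting the one-sided alpha constraint at this n
    for (r in 0:(n + 1L)) {
      if (binomial_tail(n, r, p0) <= alpha) break
    }
    pw <- binomial_tail(n, r, p1)
    if (pw >= power) {
      return(structure(list(
        p0 = p0, p1 = p1,
        alpha_nominal = alpha, power_nominal = power,
        n = as.integer(n), r = as.integer(r),
        alpha_exact = binomial_tail(n, r, p0),
        power_exact = pw
      ), class = "ahern_design"))
    }
  }
  stop("ahern_design: no design found with n <= ", n_max,
       "; raise n_max or reconsider (p0, p1, alpha, power)")
}

#' @export
print.ahern_design <- function(x, ...) {
  cat(sprintf(
    paste0("Single-stage exact binomial design\n",
           "  H0: p <= %.3f vs H1: p >= %.3f\n",
           "  n = %d patients; positive if responses >= %d\n",
           "  exact one-sided alpha = %.4f (nominal %.3f)\n",
           "  exact power           = %.4f (nominal %.3f)\n"),
    x$p0, x$p1, x$n, x$r, x$alpha_exact, x$alpha_nominal,
    x$power_exact, x$power_nominal))
  invisible(x)
}

#' Binomial proportion endpoint with confidence interval
#'
#' Point estimate and two-sided confidence interval for a response-type
#' endpoint, on the percent scale. Three interval methods are provided:
#' Wald (normal approximation, clamped to \[0, 100\]), Wilson score, and
#' exact Clopper-Pearson.
#'
#' @param successes number of responders.
#' @param total number of evaluable patients.
#' @param method one of `"wald"`, `"wilson"`, `"clopper_pearson"`.
#' @param level confidence level in percent (default 95).
#' @return an object of class `endpoint_estimate` with fields `successes`,
#'   `total`, `proportion_percent`, `ci_method`, `ci_low_percent`,
#'   `ci_high_percent`, `level`.
#' @examples
#' endpoint_estimate(8, 27, "wald")   # ORR-style endpoint
#' @export
endpoint_estimate <- function(successes, total,
                              method = c("wald", "wilson", "clopper_pearson"),
                              level = 95) {
  method <- match.arg(method)
  successes <- as.integer(successes); total <- as.integer(total)
  if (total <= 0L) stop("endpoint_estimate: total must be positive")
  if (successes < 0L || successes > total)
    stop("endpoint_estimate: successes must lie in 0..total")
  if (level <= 0 || level >= 100)
    stop("endpoint_estimate: level is a percent in (0, 100)")
  phat <- successes / total
  conf <- level / 100
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- switch(method,
    wald = {
      se <- sqrt(phat * (1 - phat) / total)
      c(phat - z * se, phat + z * se)
    },
    wilson = {
      den <- 1 + z^2 / total
      ctr <- (phat + z^2 / (2 * total)) / den
      hw <- z * sqrt(phat * (1 - phat) / total + z^2 / (4 * total^2)) / den
      c(ctr - hw, ctr + hw)
    },
    clopper_pearson = {
      lo <- if (successes == 0L) 0 else
        stats::qbeta((1 - conf) / 2, successes, total - successes + 1)
      hi <- if (successes == total) 1 else
        stats::qbeta(1 - (1 - conf) / 2, successes + 1, total - successes)
      c(lo, hi)
    })
  ci <- pmin(pmax(ci, 0), 1)
  structure(list(
    successes = successes, total = total,
    proportion_percent = 100 * phat,
    ci_method = method,
    ci_low_percent = 100 * ci[1L],
    ci_high_percent = 100 * ci[2L],
    level = level
  ), class = "endpoint_estimate")
}

#' @export
print.endpoint_estimate <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (%d%% CI %.0f-%.0f%%, %s)\n",
              x$successes, x$total, x$proportion_percent, as.integer(x$level),
              .round_half_up(x$ci_low_percent), .round_half_up(x$ci_high_percent),
              x$ci_method))
  invisible(x)
}
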