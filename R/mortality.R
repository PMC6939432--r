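#' Decompose whole-population mortality into diabetic and non-diabetic rates
#'
#' National statistics report a single all-cause mortality rate `mu` for the
#' whole population. Given the diabetes prevalence `p` and the relative
#' mortality ratio `rr` of diabetic versus non-diabetic individuals, the
#' non-diabetic rate follows from mixing the two subpopulation rates back to
#' the total:
#' \deqn{\mu_{ND} = \frac{\mu}{1 - p + p \cdot RR}}
#' and the diabetic rate follows from the deaths accounting identity
#' \eqn{\mu b = \mu_{ND}(b - a) + \mu_D a} over a total population `b` with
#' `a` diabetic members:
#' \deqn{\mu_D = \frac{\mu b - \mu_{ND} (b - a)}{a}.}
#' When `a / b = p` exactly, `mu_diabetic()` equals `rr * mu_nondiabetic()`.
#'
#' @param mu All-cause mortality rate of the total population, per
#'   person-year, in (0, 1).
#' @param p Diabetes prevalence as a fraction in \[0, 1).
#' @param rr Relative mortality ratio (diabetic vs non-diabetic), > 0.
#' @param b Total population size (persons).
#' @param a Diabetic population size (persons), with 0 < a < b.
#' @param tol Relative tolerance for the optional consistency check between
#'   `a / b` and `p`; a mismatch beyond it raises a warning.
#' @return Mortality rate per person-year. `mu_diabetic()` warns and
#'   attaches attribute `flagged = TRUE` if the implied rate falls outside
#'   (0, 1), signalling inconsistent inputs.
#' @examples
#' mu_nondiabetic(0.007, p = 0.109, rr = 2)
#' mu_diabetic(0.007, p = 0.109, rr = 2, b = 1e6, a = 109000)
#' @export
mu_nondiabetic <- function(mu, p, rr) {
  check_mortality_inputs(mu, p, rr)
  denom <- 1 - p + p * rr
  if (denom <= 0) abort("mixing denominator 1 - p + p*rr must be positive")
  mu / denom
}

#' @rdname mu_nondiabetic
#' @export
mu_diabetic <- function(mu, p, rr, b, a, tol = 0.05) {
  check_mortality_inputs(mu, p, rr)
  if (!(a > 0 && a < b)) abort("`a` must satisfy 0 < a < b")
  if (p > 0 && abs(a / b - p) / p > tol) {
    warn(sprintf(
      "a/b = %.4f differs from prevalence p = %.4f by more than %.0f%%",
      a / b, p, 100 * tol
    ))
  }
  mu_nd <- mu_nondiabetic(mu, p, rr)
  mu_d <- (mu * b - mu_nd * (b - a)) / a
  if (mu_d <= 0 || mu_d >= 1) {
    warn(sprintf("implied diabetic mortality %.4g lies outside (0, 1); inputs look inconsistent", mu_d))
    attr(mu_d, "flagged") <- TRUE
  }
  mu_d
}

check_mortality_inputs <- function(mu, p, rr) {
  if (!(mu > 0 && mu < 1)) abort("`mu` must lie in (0, 1)")
  if (!(p >= 0 && p < 1)) abort("`p` must lie in [0, 1)")
  if (!(rr > 0)) abort("`rr` must be positive")
}

#' Age- and sex-averaged relative mortality ratio
#'
#' Published diabetic-mortality relative ratios come stratified by age band
#' and sex. For a cohort with a given female fraction, the single RR used in
#' the model is the per-sex unweighted mean over the age bands intersecting
#' the chosen window, combined as a weighted average by the cohort's sex
#' ratio.
#'
#' @param rr_table Data frame with columns `age_low`, `age_high`, `sex`
#'   (`"female"`/`"male"`), `rr`.
#' @param age_low,age_high Age window in years; a band is included when it
#'   overlaps the window.
#' @param female_fraction Female fraction of the modelled cohort, in
#'   \[0, 1\].
#' @return A single relative ratio.
#' @examples
#' tab <- tibble::tibble(
#'   age_low = c(40, 60, 40), age_high = c(59, 84, 84),
#'   sex = c("female", "female", "male"), rr = c(2.0, 3.0, 4.0)
#' )
#' weighted_rr(tab, 40, 84, female_fraction = 0.5)
#' @export
weighted_rr <- function(rr_table, age_low, age_high, female_fraction) {
  rr_table <- as_tibble(rr_table)
  req <- c("age_low", "age_high", "sex", "rr")
  if (!all(req %in% names(rr_table))) {
    abort(paste0("`rr_table` needs columns: ", paste(req, collapse = ", ")))
  }
  if (any(rr_table$rr <= 0)) abort("all RR values must be positive")
  if (female_fraction < 0 || female_fraction > 1) {
    abort("`female_fraction` must lie in [0, 1]")
  }

  hit <- rr_table %>%
    filter(.data$age_high >= .env$age_low, .data$age_low <= .env$age_high)
  sex_mean <- function(s) {
    v <- hit$rr[hit$sex == s]
    if (length(v) == 0) {
      abort(sprintf("no %s RR rows intersect ages [%g, %g]", s, age_low, age_high))
    }
    mean(v)
  }
  female_fraction * sex_mean("female") + (1 - female_fraction) * sex_mean("male")
}

#' Convert an annual rate to a per-cycle transition probability
#'
#' The source tables label their annual values as probabilities and the
#' model consumes them verbatim, so the default conversion is the identity
#' (capped at 1). The actuarial exponential conversion
#' \eqn{1 - e^{-rate \cdot cycle}} is available for sensitivity work.
#'
#' @param rate Nonnegative rate per person-year.
#' @param cycle Cycle length in years (default 1).
#' @param method `"identity"` (default) or `"exponential"`.
#' @return A probability in \[0, 1\].
#' @export
rate_to_probability <- function(rate, cycle = 1, method = c("identity", "exponential")) {
  method <- match.arg(method)
  if (any(rate < 0)) abort("`rate` must be nonnegative")
  if (cycle <= 0) abort("`cycle` must be positive")
  switch(method,
    identity = pmin(rate * cycle, 1),
    exponential = 1 - exp(-rate * cycle)
  )
}
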