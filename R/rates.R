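#' Convert between probabilities and constant rates
#'
#' A transition probability observed over a study window of `t` years is
#' converted to a constant annual rate by
#' \eqn{r = -\frac{1}{t}\ln(1-p)}, and a rate back to a 1-year probability
#' by \eqn{p_1 = 1 - e^{-r}}. `annualize_study_probability()` composes the
#' two steps, turning a multi-year study probability into an annual
#' transition probability under the constant-hazard assumption.
#'
#' @param p Probability (or vector of probabilities) in `[0, 1)`.
#' @param t Study window length in years, strictly positive.
#' @return `probability_to_rate()`: non-negative rate per year.
#' @examples
#' probability_to_rate(0.3069, t = 2)
#' rate_to_annual_probability(0.1833)
#' annualize_study_probability(0.3069, t = 2) # ~0.1675
#' @export
probability_to_rate <- function(p, t = 1) {
  stopifnot(is.numeric(p), is.numeric(t), length(t) == 1L)
  if (t <= 0) stop("study window 't' must be positive", call. = FALSE)
  if (any(p < 0)) stop("probability must be non-negative", call. = FALSE)
  if (any(p >= 1)) {
    stop("probability must be < 1 (a certain event has no finite rate)",
         call. = FALSE)
  }
  -(1 / t) * log1p(-p)
}

#' @rdname probability_to_rate
#' @param rate Non-negative rate per year.
#' @return `rate_to_annual_probability()`: probability in `[0, 1)`.
#' @export
rate_to_annual_probability <- function(rate) {
  stopifnot(is.numeric(rate))
  if (any(rate < 0)) stop("rate must be non-negative", call. = FALSE)
  -expm1(-rate)
}

#' @rdname probability_to_rate
#' @return `annualize_study_probability()`: the 1-year probability implied
#'   by observing `p` over `t` years.
#' @export
annualize_study_probability <- function(p, t) {
  rate_to_annual_probability(probability_to_rate(p, t))
}

#' Shorten an annual probability to a sub-year step
#'
#' Inverse companion of [annualize_study_probability()]: converts a 1-year
#' transition probability to the probability over a shorter (or longer)
#' step under the same constant-hazard assumption, so that composing
#' `1/step_years` steps recovers the annual probability. Used by the
#' synthetic-trial generator to drive bi-monthly state evolution from an
#' annual matrix.
#'
#' @param p_annual Annual probability in `[0, 1)`.
#' @param step_years Step length in years, strictly positive.
#' @return Probability over one step.
#' @examples
#' p2m <- annual_to_step_probability(0.1675, 1 / 6)
#' 1 - (1 - p2m)^6 # recovers 0.1675
#' @export
annual_to_step_probability <- function(p_annual, step_years) {
  stopifnot(is.numeric(p_annual), is.numeric(step_years),
            length(step_years) == 1L)
  if (step_years <= 0) stop("'step_years' must be positive", call. = FALSE)
  if (any(p_annual < 0)) stop("probability must be non-negative", call. = FALSE)
  if (any(p_annual >= 1)) stop("probability must be < 1", call. = FALSE)
  -expm1(step_years * log1p(-p_annual))
}
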