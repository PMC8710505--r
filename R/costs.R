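#' Adjust a recorded cost to base-year US dollars
#'
#' Converts a cost recorded in an earlier calendar year to its base-year
#' value by compounding a constant annual inflation rate, optionally
#' converting currency first (e.g. CNY to USD). The default base year,
#' inflation rate and CNY/USD exchange rate follow the trial's costing
#' conventions (2021 base year, 2.5% inflation, 1 CNY = 0.156 USD when
#' `exchange_rate` is supplied).
#'
#' @param amount Non-negative cost in the recorded currency.
#' @param record_year Calendar year the cost was recorded.
#' @param base_year Calendar year to express the cost in; must not precede
#'   `record_year`.
#' @param inflation_rate Annual inflation rate as a proportion (>= 0).
#' @param exchange_rate Units of target currency per unit of recorded
#'   currency, applied before inflation. Default 1 (no conversion).
#' @return Cost in base-year currency.
#' @examples
#' adjust_cost(100, record_year = 2013, base_year = 2021) # 100 * 1.025^8
#' adjust_cost(100, 2021, 2021, exchange_rate = 0.156)    # CNY 100 -> $15.60
#' @export
adjust_cost <- function(amount, record_year, base_year = 2021,
                        inflation_rate = 0.025, exchange_rate = 1) {
  stopifnot(is.numeric(amount), is.numeric(record_year),
            is.numeric(base_year))
  if (any(amount < 0)) stop("'amount' must be non-negative", call. = FALSE)
  if (inflation_rate < 0) stop("'inflation_rate' must be >= 0", call. = FALSE)
  if (exchange_rate <= 0) stop("'exchange_rate' must be positive", call. = FALSE)
  if (base_year < record_year) {
    stop("'base_year' must not precede 'record_year'", call. = FALSE)
  }
  amount * exchange_rate * (1 + inflation_rate)^(base_year - record_year)
}

#' Labour cost of additional programme working time
#'
#' Human-capital costing of programme staff time: the mean annual salary is
#' reduced to an hourly wage (salary / working days / hours per day) and
#' multiplied by the additional hours worked on the programme.
#'
#' @param mean_annual_salary Mean annual salary in USD/year.
#' @param additional_hours Extra hours worked on the programme.
#' @param working_days Working days per year (default 250, i.e. 365 less
#'   statutory holidays and weekends).
#' @param hours_per_day Contracted hours per working day (default 8).
#' @return Labour cost in USD.
#' @examples
#' salary_cost(17979.40, additional_hours = 1) # hourly wage $8.9897
#' @export
salary_cost <- function(mean_annual_salary, additional_hours,
                        working_days = 250, hours_per_day = 8) {
  stopifnot(is.numeric(mean_annual_salary), is.numeric(additional_hours),
            is.numeric(working_days), is.numeric(hours_per_day))
  if (mean_annual_salary <= 0 || working_days <= 0 || hours_per_day <= 0) {
    stop("salary, working days and hours per day must be positive",
         call. = FALSE)
  }
  if (any(additional_hours < 0)) {
    stop("'additional_hours' must be non-negative", call. = FALSE)
  }
  mean_annual_salary / working_days / hours_per_day * additional_hours
}
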