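# Reference parameter tables for the three-arm community hypertension
# management evaluation (usual practice, Option 1 = MDT+MIP,
# Option 2 = MDT+MIP+SGB-P4P). Values are the published point estimates and
# sensitivity ranges; the packaged YAML fixtures under inst/extdata mirror
# the same numbers.

#' Age-banded natural mortality for the Chinese population over 35
#'
#' Annual probability of death by 5-year age band (2010 national census),
#' from age 35 up to an open-ended 100-and-over band. Used as the
#' background mortality of every living state in the cohort model.
#'
#' @return Data frame with columns `age_lower` (band lower bound in years)
#'   and `probability` (annual death probability).
#' @export
china_mortality <- function() {
  data.frame(
    age_lower = seq(35, 100, by = 5),
    probability = c(0.0012, 0.0018, 0.0026, 0.0042, 0.0062, 0.0103, 0.0172,
                    0.0306, 0.0495, 0.0848, 0.1274, 0.1908, 0.2171, 0.4543)
  )
}

#' Observed 2-year transition counts between blood-pressure levels
#'
#' Patient-level transitions from baseline blood-pressure level to the
#' level at the final (12th) bi-monthly follow-up, over the whole
#' analyzable cohort of 1,248 patients. Diagonal entries are patients whose
#' level did not change; rows involving normotension are recorded but do
#' not enter the model (see [estimate_parameters()]).
#'
#' @return A `transition_counts` object (data frame with columns `symbol`,
#'   `origin`, `destination`, `count`; total cohort size in
#'   `attr(, "total_n")`).
#' @export
cmboc_transition_counts <- function() {
  tab <- utils::read.csv(system.file("extdata", "transition_counts.csv",
                              package = "htncea"),
                  stringsAsFactors = FALSE)
  new_transition_counts(tab[c("symbol", "origin", "destination", "count")],
                        total_n = sum(tab$count))
}

#' Annual transition probabilities with sensitivity ranges
#'
#' The full annual transition-probability table of the nine-state model:
#' movements among the blood-pressure states (estimated from the trial via
#' the study-probability annualization), incidence of the complication
#' states, and complication-specific death, each with its one-way
#' sensitivity range and sampling distribution for probabilistic analysis.
#'
#' Three printed ranges contain obvious typographical slips (a bound
#' inconsistent with the point estimate and the +/-20% convention used for
#' its neighbours); they are repaired here: `pMI_Death` (0.0039, 0.0059),
#' `p3_2` (0.0006, 0.0010), `p1_0.5` (0.1340, 0.2010).
#'
#' @return Data frame with columns `name`, `origin`, `destination`,
#'   `value`, `low`, `high`, `distribution`.
#' @export
transition_probability_table <- function() {
  rows <- list(
    # name,          value,  low,     high
    c("p0.5_1",      0.0413, 0.0330,  0.0496),
    c("p0.5_2",      0.0056, 0.0045,  0.0067),
    c("p0.5_3",      0.0016, 0.0013,  0.0019),
    c("p1_0.5",      0.1675, 0.1340,  0.2010),
    c("p1_2",        0.0072, 0.0058,  0.0086),
    c("p1_3",        0.0016, 0.0013,  0.0019),
    c("p2_0.5",      0.0227, 0.0182,  0.0272),
    c("p2_1",        0.0289, 0.0231,  0.0347),
    c("p2_3",        0.0008, 0.0006,  0.0010),
    c("p3_0.5",      0.0060, 0.0048,  0.0072),
    c("p3_1",        0.0060, 0.0048,  0.0072),
    c("p3_2",        0.0008, 0.0006,  0.0010),
    c("p0.5_MI",     0.0014, 0.0012,  0.0017),
    c("p1_MI",       0.0022, 0.0018,  0.0027),
    c("p2_MI",       0.0035, 0.0028,  0.0042),
    c("p3_MI",       0.0035, 0.0028,  0.0042),
    c("p0.5_CHF",    0.0002, 0.0002,  0.0003),
    c("p1_CHF",      0.0003, 0.0003,  0.0004),
    c("p2_CHF",      0.0004, 0.0003,  0.0005),
    c("p3_CHF",      0.0004, 0.0003,  0.0005),
    c("p0.5_Stroke", 0.0011, 0.0009,  0.0013),
    c("p1_Stroke",   0.0020, 0.0016,  0.0024),
    c("p2_Stroke",   0.0035, 0.0028,  0.0042),
    c("p3_Stroke",   0.0035, 0.0028,  0.0042),
    c("p1_ESRD",     0.0152, 0.0121,  0.0182),
    c("p2_ESRD",     0.0078, 0.0063,  0.0094),
    c("p3_ESRD",     0.0017, 0.0014,  0.0020),
    c("pMI_Death",   0.0049, 0.0039,  0.0059),
    c("pCHF_Death",  0.0007, 0.00053, 0.00076),
    c("pStroke_Death", 0.0040, 0.0032, 0.0048),
    c("pESRD_Death", 0.0552, 0.0442,  0.0662)
  )
  name <- vapply(rows, `[`, "", 1L)
  out <- data.frame(
    name = name,
    t(vapply(name, parse_transition_symbol, c(origin = "", destination = ""))),
    value = as.numeric(vapply(rows, `[`, "", 2L)),
    low = as.numeric(vapply(rows, `[`, "", 3L)),
    high = as.numeric(vapply(rows, `[`, "", 4L)),
    distribution = "beta",
    stringsAsFactors = FALSE, row.names = NULL
  )
  out
}

#' Health-state utilities with 95% confidence intervals
#'
#' EQ-5D utility weights per living state: the blood-pressure states are
#' SF-36 scores mapped through [map_sf36_to_eq5d()]; the complication
#' states come from published clinical sources. Death has utility 0 and is
#' not listed.
#'
#' @return Data frame with columns `name`, `state`, `value`, `low`, `high`,
#'   `distribution`.
#' @export
utility_table <- function() {
  data.frame(
    name = c("U_pre", "U_1", "U_2", "U_3", "U_MI", "U_Stroke", "U_CHF",
             "U_ESRD"),
    state = c("prehypertension", "L1", "L2", "L3", "MI", "stroke", "CHF",
              "ESRD"),
    value = c(0.651375, 0.65525, 0.683, 0.669, 0.684, 0.605, 0.64, 0.60),
    low = c(0.6066, 0.6057, 0.5595, 0.5153, 0.6165, 0.5445, 0.6086, 0.39),
    high = c(0.6962, 0.7048, 0.8065, 0.8227, 0.7524, 0.6655, 0.6714, 0.81),
    distribution = "beta",
    stringsAsFactors = FALSE
  )
}

#' Annual treatment costs per health state (USD, 2021 base year)
#'
#' @return Data frame with columns `name`, `state`, `value`, `low`, `high`,
#'   `distribution`.
#' @export
state_cost_table <- function() {
  data.frame(
    name = c("cprehy", "chy1", "chy2", "chy3", "cMI", "cStroke", "cCHF",
             "cESRD"),
    state = c("prehypertension", "L1", "L2", "L3", "MI", "stroke", "CHF",
              "ESRD"),
    value = c(140.69, 150.87, 187.08, 468.15, 4953.07, 1974.68, 1754.30,
              19406.36),
    low = c(112.55, 120.70, 149.66, 374.52, 3962.45, 1579.74, 1403.44,
            15525.09),
    high = c(168.83, 181.05, 224.49, 561.78, 5943.68, 2369.61, 2105.16,
             23287.63),
    distribution = "gamma",
    stringsAsFactors = FALSE
  )
}

#' Arm-level parameters: control rates and programme costs
#'
#' Blood-pressure control rates (share of follow-up measurements with SBP
#' below 120 mmHg) and total human/project costs per arm at trial scale.
#' The project-cost symbol of Option 2 is kept as printed in the source
#' costing table (`cdproagram`).
#'
#' @return Data frame with one row per arm.
#' @export
arm_table <- function() {
  data.frame(
    arm = c("usual", "option1", "option2"),
    control_symbol = c("PSCR", "SSCR", "DSCR"),
    control_rate = c(0.61, 0.62, 0.69),
    control_low = c(0.25, 0.33, 0.42),
    control_high = c(0.83, 0.92, 1.00),
    human_symbol = c("cphuman", "cshuman", "cdhuman"),
    human_cost = c(346.10, 24469.97, 11938.33),
    human_low = c(258.89, 15798.43, 2519.22),
    human_high = c(433.32, 33141.50, 21357.40),
    project_symbol = c("cpprogram", "csprogram", "cdproagram"),
    project_cost = c(14.72, 1278.47, 699.40),
    project_low = c(0, 204.85, 648.90),
    project_high = c(55.52, 2352.09, 749.90),
    stringsAsFactors = FALSE
  )
}

#' Baseline distribution over blood-pressure states
#'
#' Proportion of the analyzable cohort in each blood-pressure state at
#' baseline.
#'
#' @return Named numeric vector over the four blood-pressure states,
#'   summing to 1.
#' @export
baseline_state_distribution <- function() {
  c(prehypertension = 0.32, L1 = 0.53, L2 = 0.12, L3 = 0.03)
}

#' Default parameter specifications for sensitivity analysis
#'
#' One row per uncertain model parameter: the point estimate, the one-way
#' range, and the sampling distribution used in probabilistic analysis
#' (beta for probabilities/utilities/control rates, gamma for costs, fixed
#' for the discount rate, which is varied one-way over 0-8% but not
#' sampled).
#'
#' @return A data frame of class `parameter_specs` with columns `name`,
#'   `base`, `low`, `high`, `distribution`.
#' @export
default_parameter_specs <- function() {
  tp <- transition_probability_table()
  ut <- utility_table()
  co <- state_cost_table()
  am <- arm_table()
  specs <- rbind(
    data.frame(name = tp$name, base = tp$value, low = tp$low, high = tp$high,
               distribution = tp$distribution, stringsAsFactors = FALSE),
    data.frame(name = ut$name, base = ut$value, low = ut$low, high = ut$high,
               distribution = ut$distribution, stringsAsFactors = FALSE),
    data.frame(name = co$name, base = co$value, low = co$low, high = co$high,
               distribution = co$distribution, stringsAsFactors = FALSE),
    data.frame(name = am$control_symbol, base = am$control_rate,
               low = am$control_low, high = am$control_high,
               distribution = "beta", stringsAsFactors = FALSE),
    data.frame(name = am$human_symbol, base = am$human_cost,
               low = am$human_low, high = am$human_high,
               distribution = "gamma", stringsAsFactors = FALSE),
    data.frame(name = am$project_symbol, base = am$project_cost,
               low = am$project_low, high = am$project_high,
               distribution = "gamma", stringsAsFactors = FALSE),
    data.frame(name = "discount_rate", base = 0.05, low = 0, high = 0.08,
               distribution = "fixed", stringsAsFactors = FALSE)
  )
  class(specs) <- c("parameter_specs", class(specs))
  specs
}
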