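#' Economic settings of a cohort run
#'
#' @param discount_rate Annual discount rate applied to costs and QALYs
#'   (default 5%).
#' @param wtp Willingness-to-pay threshold in USD per QALY (default
#'   $1,599.16/year).
#' @param horizon Number of 1-year cycles (default 65, a lifetime horizon
#'   for a cohort entering at age 35).
#' @param start_age Cohort age at model entry in years (>= 35, the first
#'   mortality band).
#' @param cycle_length Cycle length in years; the model is parameterized
#'   with annual probabilities, so this is fixed at 1.
#' @param initial_distribution Named proportions over the four
#'   blood-pressure states at entry; must sum to 1.
#' @param reference_control_rate Blood-pressure control rate of the arm
#'   whose data generated the transition matrix (usual practice, 0.61).
#'   Each arm's improvement transitions are scaled by
#'   `control_rate / reference_control_rate`.
#' @param half_cycle_correction Average start- and end-of-cycle occupancy
#'   when accumulating costs and effects (default `FALSE`: plain
#'   beginning-of-cycle accumulation).
#' @return List of class `economic_settings`.
#' @export
economic_settings <- function(discount_rate = 0.05,
                              wtp = 1599.16,
                              horizon = 65,
                              start_age = 35,
                              cycle_length = 1,
                              initial_distribution = baseline_state_distribution(),
                              reference_control_rate = 0.61,
                              half_cycle_correction = FALSE) {
  if (discount_rate < 0) stop("'discount_rate' must be >= 0", call. = FALSE)
  if (wtp <= 0) stop("'wtp' must be positive", call. = FALSE)
  if (horizon < 1) stop("'horizon' must be at least 1 cycle", call. = FALSE)
  if (cycle_length != 1) {
    stop("only 1-year cycles are supported ('cycle_length' must be 1)",
         call. = FALSE)
  }
  hs <- hypertension_states()
  if (is.null(names(initial_distribution)) ||
      !setequal(names(initial_distribution), hs)) {
    stop("'initial_distribution' must be named over: ",
         paste(hs, collapse = ", "), call. = FALSE)
  }
  initial_distribution <- initial_distribution[hs]
  if (any(initial_distribution < 0) ||
      abs(sum(initial_distribution) - 1) > 1e-8) {
    stop("'initial_distribution' must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (reference_control_rate <= 0 || reference_control_rate > 1) {
    stop("'reference_control_rate' must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(discount_rate = discount_rate, wtp = wtp, horizon = as.integer(horizon),
         start_age = start_age, cycle_length = cycle_length,
         initial_distribution = initial_distribution,
         reference_control_rate = reference_control_rate,
         half_cycle_correction = isTRUE(half_cycle_correction)),
    class = "economic_settings"
  )
}

.required_transitions <- function() transition_probability_table()$name
.required_utilities <- function() utility_table()$name
.required_costs <- function() state_cost_table()$name

#' Complete parameter set for one strategy arm
#'
#' Bundles everything one arm of the cohort model needs: annual transition
#' probabilities, state utilities and annual state costs (keyed by their
#' table symbols), the arm's blood-pressure control rate, its trial-scale
#' human and project costs with the enrolment and intervention span used to
#' convert them to a per-person annual intervention cost, the background
#' mortality table, and the economic settings.
#'
#' The per-person intervention cost applied each cycle is
#' `(human_cost + project_cost) / n_patients / intervention_years`. With
#' `lifelong_intervention = TRUE` (default) it accrues in every cycle a
#' person is alive, modelling a standing programme; otherwise it accrues
#' for `intervention_cycles` cycles only.
#'
#' @param arm Arm label (e.g. `"usual"`, `"option1"`, `"option2"`).
#' @param transitions Named numeric vector of annual transition
#'   probabilities covering every symbol in
#'   `transition_probability_table()$name`.
#' @param utilities Named numeric vector covering `U_pre` ... `U_ESRD`.
#' @param costs Named numeric vector covering `cprehy` ... `cESRD` (USD per
#'   year in state).
#' @param control_rate Proportion of follow-up measurements with SBP below
#'   120 mmHg in this arm.
#' @param human_cost,project_cost Total arm-level programme costs (USD) at
#'   trial scale.
#' @param n_patients Patients enrolled in the arm (used to convert
#'   programme costs to per-person terms).
#' @param intervention_years Span of the intervention over which programme
#'   costs accrued (years).
#' @param lifelong_intervention Apply the per-person intervention cost in
#'   every cycle (`TRUE`, default) or only for `intervention_cycles`.
#' @param intervention_cycles Number of cycles the intervention cost is
#'   applied when not lifelong.
#' @param mortality Mortality table as from [china_mortality()].
#' @param economics An [economic_settings()] object.
#' @return Object of class `markov_parameters`.
#' @seealso [default_parameters()] for the packaged strategy fixtures,
#'   [run_cohort()] to simulate.
#' @export
markov_parameters <- function(arm,
                              transitions,
                              utilities,
                              costs,
                              control_rate,
                              human_cost = 0,
                              project_cost = 0,
                              n_patients = 415,
                              intervention_years = 1.5,
                              lifelong_intervention = TRUE,
                              intervention_cycles = NULL,
                              mortality = china_mortality(),
                              economics = economic_settings()) {
  stopifnot(is.character(arm), length(arm) == 1L)
  check_named <- function(x, required, what) {
    if (is.null(names(x))) stop(what, " must be a named vector", call. = FALSE)
    missing <- setdiff(required, names(x))
    if (length(missing)) {
      stop("missing ", what, " parameter(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    extra <- setdiff(names(x), required)
    if (length(extra)) {
      stop("unknown ", what, " parameter(s): ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    x[required]
  }
  transitions <- check_named(transitions, .required_transitions(), "transition")
  utilities <- check_named(utilities, .required_utilities(), "utility")
  costs <- check_named(costs, .required_costs(), "cost")
  if (any(transitions < 0 | transitions > 1)) {
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(utilities < 0 | utilities > 1)) {
    stop("utilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(costs < 0)) stop("state costs must be non-negative", call. = FALSE)
  if (control_rate < 0 || control_rate > 1) {
    stop("'control_rate' must lie in [0, 1]", call. = FALSE)
  }
  if (human_cost < 0 || project_cost < 0) {
    stop("programme costs must be non-negative", call. = FALSE)
  }
  if (n_patients <= 0 || intervention_years <= 0) {
    stop("'n_patients' and 'intervention_years' must be positive",
         call. = FALSE)
  }
  if (!lifelong_intervention &&
      (is.null(intervention_cycles) || intervention_cycles < 0)) {
    stop("'intervention_cycles' required when intervention is not lifelong",
         call. = FALSE)
  }
  if (!is.data.frame(mortality) ||
      !all(c("age_lower", "probability") %in% names(mortality))) {
    stop("'mortality' must have columns age_lower and probability",
         call. = FALSE)
  }
  if (any(mortality$probability < 0 | mortality$probability > 1)) {
    stop("mortality probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!inherits(economics, "economic_settings")) {
    stop("'economics' must be an economic_settings object", call. = FALSE)
  }
  structure(
    list(arm = arm, transitions = transitions, utilities = utilities,
         costs = costs, control_rate = control_rate,
         human_cost = human_cost, project_cost = project_cost,
         n_patients = n_patients, intervention_years = intervention_years,
         lifelong_intervention = isTRUE(lifelong_intervention),
         intervention_cycles = intervention_cycles,
         mortality = mortality, economics = economics),
    class = "markov_parameters"
  )
}

#' Per-person intervention cost per cycle
#'
#' @param params A `markov_parameters` object.
#' @return USD per person per year.
#' @export
intervention_cost_per_cycle <- function(params) {
  stopifnot(inherits(params, "markov_parameters"))
  (params$human_cost + params$project_cost) /
    params$n_patients / params$intervention_years
}

#' @export
print.markov_parameters <- function(x, ...) {
  cat("Markov cohort parameter set -- arm:", x$arm, "\n")
  cat(sprintf("  control rate: %.2f (reference %.2f)\n", x$control_rate,
              x$economics$reference_control_rate))
  cat(sprintf("  intervention cost: $%.2f/person/year (%s)\n",
              intervention_cost_per_cycle(x),
              if (x$lifelong_intervention) "lifelong"
              else paste0(x$intervention_cycles, " cycles")))
  cat(sprintf("  horizon: %d x %g-year cycles from age %g, discount %.1f%%\n",
              x$economics$horizon, x$economics$cycle_length,
              x$economics$start_age, 100 * x$economics$discount_rate))
  cat("  transitions:", length(x$transitions), "annual probabilities;",
      "utilities/costs over", length(x$utilities), "living states\n")
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

.ps_top_keys <- c("arm", "control_rate", "human_cost", "project_cost",
                  "n_patients", "intervention_years", "lifelong_intervention",
                  "intervention_cycles", "transitions", "utilities", "costs",
                  "mortality", "economics")
.ps_econ_keys <- c("discount_rate", "wtp", "horizon", "start_age",
                   "cycle_length", "initial_distribution",
                   "reference_control_rate", "half_cycle_correction")

#' Read and write strategy parameter files
#'
#' Parameter sets are stored as YAML with sections `transitions`,
#' `utilities`, `costs`, `mortality`, `economics` plus arm-level scalars,
#' all keyed by their table symbols (`p0.5_1`, `U_MI`, `chy2`, ...).
#' `load_parameter_set()` validates the file: unknown keys and missing
#' mandatory symbols are reported by name.
#'
#' @param path File path.
#' @param params A `markov_parameters` object (for writing).
#' @return `load_parameter_set()` returns a `markov_parameters` object;
#'   `write_parameter_set()` returns `path` invisibly.
#' @examples
#' ps <- load_parameter_set(system.file("extdata", "usual.yaml",
#'                                      package = "htncea"))
#' ps$costs[["chy3"]]
#' @export
load_parameter_set <- function(path) {
  if (!file.exists(path)) stop("no such parameter file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .ps_top_keys)
  if (length(unknown)) {
    stop("unknown key(s) in ", path, ": ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  need <- function(key) {
    if (is.null(raw[[key]])) stop("missing key '", key, "' in ", path,
                                  call. = FALSE)
    raw[[key]]
  }
  sect <- function(key, required) {
    vals <- need(key)
    missing <- setdiff(required, names(vals))
    if (length(missing)) {
      stop("missing ", key, " symbol(s) in ", path, ": ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    unlist(vals)
  }
  eraw <- need("economics")
  eunknown <- setdiff(names(eraw), .ps_econ_keys)
  if (length(eunknown)) {
    stop("unknown economics key(s) in ", path, ": ",
         paste(eunknown, collapse = ", "), call. = FALSE)
  }
  econ <- do.call(economic_settings, c(
    eraw[setdiff(names(eraw), "initial_distribution")],
    list(initial_distribution = unlist(eraw$initial_distribution))
  ))
  mort <- need("mortality")
  markov_parameters(
    arm = need("arm"),
    transitions = sect("transitions", .required_transitions()),
    utilities = sect("utilities", .required_utilities()),
    costs = sect("costs", .required_costs()),
    control_rate = need("control_rate"),
    human_cost = need("human_cost"),
    project_cost = need("project_cost"),
    n_patients = need("n_patients"),
    intervention_years = need("intervention_years"),
    lifelong_intervention = isTRUE(raw$lifelong_intervention) ||
      is.null(raw$lifelong_intervention),
    intervention_cycles = raw$intervention_cycles,
    mortality = data.frame(age_lower = unlist(mort$age_lower),
                           probability = unlist(mort$probability)),
    economics = econ
  )
}

#' @rdname load_parameter_set
#' @export
write_parameter_set <- function(params, path) {
  stopifnot(inherits(params, "markov_parameters"))
  e <- params$economics
  out <- list(
    arm = params$arm,
    control_rate = params$control_rate,
    human_cost = params$human_cost,
    project_cost = params$project_cost,
    n_patients = params$n_patients,
    intervention_years = params$intervention_years,
    lifelong_intervention = params$lifelong_intervention,
    transitions = as.list(params$transitions),
    utilities = as.list(params$utilities),
    costs = as.list(params$costs),
    mortality = list(age_lower = params$mortality$age_lower,
                     probability = params$mortality$probability),
    economics = list(discount_rate = e$discount_rate, wtp = e$wtp,
                     horizon = e$horizon, start_age = e$start_age,
                     cycle_length = e$cycle_length,
                     initial_distribution = as.list(e$initial_distribution),
                     reference_control_rate = e$reference_control_rate,
                     half_cycle_correction = e$half_cycle_correction)
  )
  if (!is.null(params$intervention_cycles)) {
    out$intervention_cycles <- params$intervention_cycles
  }
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

#' Packaged strategy parameter sets
#'
#' Loads the packaged fixture for one of the three strategies, transcribing
#' the published parameter tables: usual practice, Option 1 (MDT + MIP),
#' or Option 2 (MDT + MIP + SGB-P4P).
#'
#' @param arm One of `"usual"`, `"option1"`, `"option2"`.
#' @return A `markov_parameters` object.
#' @export
default_parameters <- function(arm = c("usual", "option1", "option2")) {
  arm <- match.arg(arm)
  load_parameter_set(system.file("extdata", paste0(arm, ".yaml"),
                                 package = "htncea"))
}

#' All three packaged strategies
#'
#' @return Named list of `markov_parameters` in comparison order: usual,
#'   option1, option2.
#' @export
default_strategies <- function() {
  arms <- c("usual", "option1", "option2")
  stats::setNames(lapply(arms, default_parameters), arms)
}

# Map a sensitivity-analysis symbol onto the slot it occupies, across a
# named list of markov_parameters. Shared symbols (transitions, utilities,
# state costs, discount rate) are set in every arm; arm-level symbols only
# in their own arm.
.arm_symbol_map <- function() {
  am <- arm_table()
  rbind(
    data.frame(name = am$control_symbol, arm = am$arm, slot = "control_rate",
               stringsAsFactors = FALSE),
    data.frame(name = am$human_symbol, arm = am$arm, slot = "human_cost",
               stringsAsFactors = FALSE),
    data.frame(name = am$project_symbol, arm = am$arm, slot = "project_cost",
               stringsAsFactors = FALSE)
  )
}

#' Set a named model parameter across strategies
#'
#' Applies one parameter value, addressed by its table symbol, to a named
#' list of strategy parameter sets: transition symbols (`p...`), utilities
#' (`U_...`) and state costs update every arm; control-rate and programme
#' cost symbols (`SSCR`, `cphuman`, ...) update only their own arm;
#' `discount_rate` updates the economics of every arm.
#'
#' @param strategies Named list of `markov_parameters` (names must include
#'   the arm a symbol belongs to when an arm-level symbol is set).
#' @param name Parameter symbol.
#' @param value Numeric value.
#' @return The updated list of strategies.
#' @export
set_model_parameter <- function(strategies, name, value) {
  stopifnot(is.list(strategies), is.character(name), length(name) == 1L,
            is.numeric(value), length(value) == 1L)
  if (name == "discount_rate") {
    for (a in names(strategies)) {
      strategies[[a]]$economics$discount_rate <- value
    }
    return(strategies)
  }
  if (name %in% .required_transitions()) {
    for (a in names(strategies)) strategies[[a]]$transitions[[name]] <- value
    return(strategies)
  }
  if (name %in% .required_utilities()) {
    for (a in names(strategies)) strategies[[a]]$utilities[[name]] <- value
    return(strategies)
  }
  if (name %in% .required_costs()) {
    for (a in names(strategies)) strategies[[a]]$costs[[name]] <- value
    return(strategies)
  }
  map <- .arm_symbol_map()
  hit <- match(name, map$name)
  if (!is.na(hit)) {
    arm <- map$arm[hit]
    if (!arm %in% names(strategies)) {
      stop("symbol '", name, "' belongs to arm '", arm,
           "', which is not among the strategies", call. = FALSE)
    }
    strategies[[arm]][[map$slot[hit]]] <- value
    return(strategies)
  }
  stop("unknown model parameter: ", name, call. = FALSE)
}
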