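# Estimation of model parameters from longitudinal follow-up records.
#
# A follow-up record set is a data frame with one row per patient-visit:
# patient_id, arm, visit_index (0 = baseline), sbp, dbp, state, and the
# eight SF-36 dimension scores in lower case (pf, rp, bp, gh, vt, sf, re,
# mh).

.record_columns <- c("patient_id", "arm", "visit_index", "sbp", "dbp",
                     "state", "pf", "rp", "bp", "gh", "vt", "sf", "re", "mh")

.check_records <- function(records) {
  missing <- setdiff(.record_columns, names(records))
  if (length(missing)) {
    stop("follow-up records lack column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  records
}

new_transition_counts <- function(table, total_n, excluded = character(0)) {
  structure(table, total_n = as.integer(total_n), excluded = excluded,
            class = c("transition_counts", "data.frame"))
}

#' @export
print.transition_counts <- function(x, ...) {
  cat("Baseline-to-final transition counts (", attr(x, "total_n"),
      " patients)\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  excl <- attr(x, "excluded")
  if (length(excl)) {
    cat(length(excl), "patient(s) excluded (missing baseline or final visit)\n")
  }
  invisible(x)
}

#' Count baseline-to-final state transitions
#'
#' Tallies, per patient, the movement from the baseline blood-pressure
#' state (visit 0) to the state at the final follow-up visit. One
#' transition is counted per patient; patients lacking either endpoint
#' (e.g. lost to follow-up) are excluded and reported via
#' `attr(, "excluded")`. Visit-to-visit counting over consecutive visit
#' pairs is available as an alternative estimator.
#'
#' @param records Follow-up record data frame (see [generate_cohort()]).
#' @param final_visit Visit index of the study endpoint; defaults to the
#'   largest visit index present.
#' @param pairs Count all consecutive visit-to-visit pairs instead of the
#'   two endpoints only (default `FALSE`, the endpoint convention).
#' @return A `transition_counts` object: data frame with columns `origin`,
#'   `destination`, `count`; the number of counted patients (or pairs) in
#'   `attr(, "total_n")`.
#' @export
count_transitions <- function(records, final_visit = NULL, pairs = FALSE) {
  records <- .check_records(records)
  if (is.null(final_visit)) final_visit <- max(records$visit_index)
  if (pairs) {
    ord <- records[order(records$patient_id, records$visit_index), ]
    same <- ord$patient_id[-1L] == ord$patient_id[-nrow(ord)] &
      ord$visit_index[-1L] == ord$visit_index[-nrow(ord)] + 1L
    origin <- ord$state[-nrow(ord)][same]
    destination <- ord$state[-1L][same]
    excluded <- character(0)
  } else {
    base <- records[records$visit_index == 0L, c("patient_id", "state")]
    last <- records[records$visit_index == final_visit, c("patient_id", "state")]
    m <- merge(base, last, by = "patient_id", suffixes = c("_0", "_1"))
    excluded <- setdiff(unique(records$patient_id), m$patient_id)
    if (length(excluded)) {
      message(length(excluded),
              " patient(s) excluded from transition counting ",
              "(missing baseline or final visit)")
    }
    origin <- m$state_0
    destination <- m$state_1
  }
  tab <- as.data.frame(table(origin = origin, destination = destination),
                       stringsAsFactors = FALSE)
  names(tab)[3L] <- "count"
  tab <- tab[tab$count > 0L, ]
  tab <- tab[order(tab$origin, tab$destination), ]
  rownames(tab) <- NULL
  new_transition_counts(tab, total_n = length(origin), excluded = excluded)
}

#' Study probability of one transition
#'
#' The study probability of a directed state pair is its transition count
#' divided by the size of the whole analyzable cohort -- the convention of
#' the source costing study (e.g. 383/1248 = 0.3069 for grade-1
#' hypertension to prehypertension), *not* the count of patients starting
#' in the origin state. The conventional row-conditional estimate is
#' available with `denominator = "origin"`.
#'
#' @param counts A `transition_counts` object.
#' @param origin,destination State labels.
#' @param denominator `"cohort"` (default; whole-cohort convention) or
#'   `"origin"` (condition on the origin state).
#' @return Proportion in `[0, 1]`; 0 for pairs never observed.
#' @export
study_probability <- function(counts, origin, destination,
                              denominator = c("cohort", "origin")) {
  stopifnot(inherits(counts, "transition_counts"))
  denominator <- match.arg(denominator)
  total_n <- attr(counts, "total_n")
  if (is.null(total_n) || total_n == 0L) {
    stop("invalid transition table: total_n is zero", call. = FALSE)
  }
  hit <- counts$origin == origin & counts$destination == destination
  count <- if (any(hit)) sum(counts$count[hit]) else 0L
  denom <- switch(denominator,
    cohort = total_n,
    origin = {
      n0 <- sum(counts$count[counts$origin == origin])
      if (n0 == 0L) stop("no patients observed in origin state '", origin,
                         "'", call. = FALSE)
      n0
    })
  count / denom
}

#' Blood-pressure control rate of an arm
#'
#' The proportion of post-baseline blood-pressure measurements (visits 1
#' onward) with systolic blood pressure strictly below 120 mmHg, pooled
#' over all patients in the arm. A measurement of exactly 120 mmHg is not
#' controlled. A per-patient-then-average alternative is available.
#'
#' @param records Follow-up record data frame.
#' @param arm Arm label to estimate.
#' @param threshold Control threshold in mmHg (default 120).
#' @param method `"pooled"` (default) pools all measurements; `"patient"`
#'   averages per-patient control proportions.
#' @return List of class `control_rate_estimate` with elements `arm`,
#'   `control_rate`, `n_measurements`.
#' @export
estimate_control_rate <- function(records, arm, threshold = 120,
                                  method = c("pooled", "patient")) {
  records <- .check_records(records)
  method <- match.arg(method)
  sel <- records[records$arm == arm & records$visit_index > 0L, ]
  if (nrow(sel) == 0L) {
    stop("no post-baseline measurements for arm '", arm, "'", call. = FALSE)
  }
  controlled <- sel$sbp < threshold
  rate <- switch(method,
    pooled = mean(controlled),
    patient = mean(tapply(controlled, sel$patient_id, mean)))
  structure(list(arm = arm, control_rate = unname(rate),
                 n_measurements = nrow(sel)),
            class = "control_rate_estimate")
}

#' @export
print.control_rate_estimate <- function(x, ...) {
  cat(sprintf("Arm %s: control rate %.4f (%d measurements, SBP < 120 mmHg)\n",
              x$arm, x$control_rate, x$n_measurements))
  invisible(x)
}

#' Mean mapped utility of a blood-pressure state
#'
#' Maps each record's SF-36 scores to an EQ-5D index with
#' [map_sf36_to_eq5d()] and summarizes all records observed in the given
#' state by their mean with a normal-approximation 95% confidence interval
#' (mean +/- 1.96 SD / sqrt(n)).
#'
#' @param records Follow-up record data frame.
#' @param state State label.
#' @return List with elements `state`, `utility`, `low`, `high`, `n`.
#' @export
estimate_state_utility <- function(records, state) {
  records <- .check_records(records)
  sel <- records[records$state == state, ]
  if (nrow(sel) < 2L) {
    stop("need at least 2 records in state '", state,
         "' for a confidence interval", call. = FALSE)
  }
  sf36 <- sel[, c("pf", "rp", "bp", "gh", "vt", "sf", "re", "mh")]
  names(sf36) <- toupper(names(sf36))
  u <- map_sf36_to_eq5d(sf36)
  m <- mean(u)
  half <- 1.96 * stats::sd(u) / sqrt(length(u))
  list(state = state, utility = m, low = m - half, high = m + half,
       n = length(u))
}

#' Estimate model parameters from follow-up records
#'
#' Runs the full estimation pipeline on a longitudinal record set:
#' baseline-to-final transition counting, whole-cohort study
#' probabilities, annualization over the study window
#' (`-(1/t) ln(1-p)` then `1 - exp(-rate)`), per-arm blood-pressure
#' control rates, and SF-36-mapped state utilities.
#'
#' Transitions into normotension sit outside the model's state space
#' (managed patients are assumed not to regain normotension). By default
#' such transitions are dropped, matching the published annual
#' transition-probability table; `normotension = "fold"` instead relabels
#' normotension as prehypertension before counting.
#'
#' @param records Follow-up record data frame.
#' @param window_years Study window `t` in years over which the endpoint
#'   transitions were observed (default 2: twelve bi-monthly visits).
#' @param normotension `"drop"` (default) or `"fold"`; see Details.
#' @param denominator Passed to [study_probability()].
#' @return Object of class `trial_estimates` with components `counts`,
#'   `transitions` (data frame: `name`, `origin`, `destination`, `count`,
#'   `study_probability`, `annual_probability`), `control_rates`,
#'   `utilities`, and `window_years`.
#' @seealso [coef.trial_estimates()] to extract the annual probabilities,
#'   [parameters_from_estimates()] to build a runnable strategy from them.
#' @export
estimate_parameters <- function(records, window_years = 2,
                                normotension = c("drop", "fold"),
                                denominator = c("cohort", "origin")) {
  records <- .check_records(records)
  normotension <- match.arg(normotension)
  denominator <- match.arg(denominator)
  if (normotension == "fold") {
    records$state[records$state == "normotension"] <- "prehypertension"
  }
  counts <- count_transitions(records)
  hs <- hypertension_states()
  keep <- counts$origin %in% hs & counts$destination %in% hs
  tab <- counts[keep & counts$origin != counts$destination, , drop = FALSE]
  if (nrow(tab)) {
    tab$name <- mapply(transition_symbol, tab$origin, tab$destination)
    tab$study_probability <- vapply(seq_len(nrow(tab)), function(i) {
      study_probability(counts, tab$origin[i], tab$destination[i],
                        denominator = denominator)
    }, numeric(1))
    tab$annual_probability <- annualize_study_probability(
      tab$study_probability, t = window_years)
    tab <- as.data.frame(tab)[c("name", "origin", "destination", "count",
                                "study_probability", "annual_probability")]
  } else {
    tab <- data.frame(name = character(0), origin = character(0),
                      destination = character(0), count = integer(0),
                      study_probability = numeric(0),
                      annual_probability = numeric(0))
  }
  rownames(tab) <- NULL
  arms <- unique(records$arm)
  control <- do.call(rbind, lapply(arms, function(a) {
    est <- estimate_control_rate(records, a)
    data.frame(arm = a, control_rate = est$control_rate,
               n_measurements = est$n_measurements,
               stringsAsFactors = FALSE)
  }))
  states_present <- intersect(hs, unique(records$state))
  utilities <- do.call(rbind, lapply(states_present, function(s) {
    est <- estimate_state_utility(records, s)
    data.frame(state = s, utility = est$utility, low = est$low,
               high = est$high, n = est$n, stringsAsFactors = FALSE)
  }))
  structure(
    list(counts = counts, transitions = tab, control_rates = control,
         utilities = utilities, window_years = window_years,
         normotension = normotension, denominator = denominator),
    class = "trial_estimates"
  )
}

#' @export
print.trial_estimates <- function(x, ...) {
  cat("Trial parameter estimates (study window:", x$window_years, "years)\n")
  cat("\nAnnual transition probabilities (blood-pressure states):\n")
  print.data.frame(x$transitions, row.names = FALSE, digits = 4)
  cat("\nBlood-pressure control rates:\n")
  print.data.frame(x$control_rates, row.names = FALSE, digits = 4)
  cat("\nState utilities (SF-36 mapped to EQ-5D):\n")
  print.data.frame(x$utilities, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @describeIn estimate_parameters Extract the estimated annual transition
#'   probabilities as a named vector keyed by transition symbol.
#' @param object,... A `trial_estimates` object (method arguments).
#' @export
coef.trial_estimates <- function(object, ...) {
  stats::setNames(object$transitions$annual_probability,
                  object$transitions$name)
}

#' @export
summary.trial_estimates <- function(object, ...) {
  cat(sprintf(
    "Estimates from %d patients (%d transition pairs, %d arms, %d states)\n",
    attr(object$counts, "total_n"), nrow(object$transitions),
    nrow(object$control_rates), nrow(object$utilities)))
  print(object)
}

#' Build a runnable strategy from trial estimates
#'
#' Overlays estimated quantities on a template parameter set: the
#' blood-pressure transition probabilities present in the estimates, the
#' arm's control rate, and the utilities of the blood-pressure states.
#' Quantities the trial cannot estimate (complication transitions and
#' costs, complication utilities, mortality) are retained from the
#' template.
#'
#' @param estimates A `trial_estimates` object.
#' @param arm Arm label to extract the control rate for.
#' @param template A `markov_parameters` object supplying non-estimated
#'   quantities; defaults to the packaged usual-practice strategy.
#' @return A `markov_parameters` object.
#' @export
parameters_from_estimates <- function(estimates, arm,
                                      template = default_parameters("usual")) {
  stopifnot(inherits(estimates, "trial_estimates"),
            inherits(template, "markov_parameters"))
  params <- template
  params$arm <- arm
  tr <- estimates$transitions
  for (i in seq_len(nrow(tr))) {
    params$transitions[[tr$name[i]]] <- tr$annual_probability[i]
  }
  cr <- estimates$control_rates
  hit <- match(arm, cr$arm)
  if (is.na(hit)) stop("arm '", arm, "' absent from estimates", call. = FALSE)
  params$control_rate <- cr$control_rate[hit]
  umap <- c(prehypertension = "U_pre", L1 = "U_1", L2 = "U_2", L3 = "U_3")
  ut <- estimates$utilities
  for (i in seq_len(nrow(ut))) {
    key <- umap[[ut$state[i]]]
    if (!is.null(key)) params$utilities[[key]] <- min(1, max(0, ut$utility[i]))
  }
  params
}
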