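#' Look up age-specific background mortality
#'
#' Returns the annual death probability of the 5-year age band containing
#' `age`; ages at or beyond the last band use the open-ended terminal band.
#'
#' @param table Mortality table with columns `age_lower` and `probability`
#'   (see [china_mortality()]).
#' @param age Age in years; must be at least the first band's lower bound.
#' @return Annual death probability.
#' @examples
#' mortality_lookup(china_mortality(), 67) # 0.0172
#' @export
mortality_lookup <- function(table, age) {
  stopifnot(is.data.frame(table),
            all(c("age_lower", "probability") %in% names(table)))
  if (any(age < table$age_lower[1L])) {
    stop("age below the mortality table (first band starts at ",
         table$age_lower[1L], ")", call. = FALSE)
  }
  table$probability[findInterval(age, table$age_lower)]
}

#' Per-cycle discount factor
#'
#' `1 / (1 + rate)^cycle`; the first model year (cycle 0) is undiscounted.
#'
#' @param rate Annual discount rate (>= 0).
#' @param cycle Cycle index, non-negative integer.
#' @return Discount factor in `(0, 1]`.
#' @export
discount_factor <- function(rate, cycle) {
  if (rate < 0) stop("'rate' must be >= 0", call. = FALSE)
  if (any(cycle < 0)) stop("'cycle' must be >= 0", call. = FALSE)
  1 / (1 + rate)^cycle
}

#' Build the one-cycle transition matrix at a given age
#'
#' Assembles the 9x9 row-stochastic annual transition matrix: the listed
#' annual probabilities fill the off-diagonals, every living state
#' additionally moves to death with the age band's background mortality
#' (added to any disease-specific death probability), improvement
#' transitions (to a strictly less severe blood-pressure grade) are
#' multiplied by `control_scale`, and the residual probability stays in
#' state. Death is absorbing.
#'
#' @param transitions Named annual probabilities keyed by transition
#'   symbol, covering `transition_probability_table()$name` (symbols absent
#'   from that set, e.g. prehypertension to ESRD, are structural zeros).
#' @param mortality Mortality table (see [china_mortality()]).
#' @param age Age of the cohort this cycle, in years.
#' @param control_scale Multiplier applied to improvement transitions:
#'   the arm's control rate over the reference (usual-practice) control
#'   rate. Default 1.
#' @return 9x9 matrix with `ht_states()` dimnames; each row sums to 1.
#' @export
build_transition_matrix <- function(transitions, mortality, age,
                                    control_scale = 1) {
  idx <- transition_index(names(transitions))
  q_nat <- mortality_lookup(mortality, age)
  .build_matrix(as.numeric(transitions), idx, q_nat, control_scale, age)
}

# Precompute origin/destination indices and improvement flags for a vector
# of transition symbols, so per-cycle matrix assembly avoids re-parsing.
transition_index <- function(symbols) {
  states <- ht_states()
  pairs <- vapply(symbols, parse_transition_symbol,
                  c(origin = "", destination = ""))
  oi <- match(pairs["origin", ], states)
  di <- match(pairs["destination", ], states)
  imp <- improvement_transitions()
  is_imp <- vapply(seq_along(symbols), function(i) {
    any(imp$origin == pairs["origin", i] &
        imp$destination == pairs["destination", i])
  }, logical(1))
  list(oi = oi, di = di, improvement = is_imp)
}

.build_matrix <- function(values, idx, q_nat, control_scale, age = NA) {
  if (control_scale < 0) stop("'control_scale' must be >= 0", call. = FALSE)
  states <- ht_states()
  M <- matrix(0, 9L, 9L, dimnames = list(states, states))
  v <- values
  v[idx$improvement] <- v[idx$improvement] * control_scale
  M[cbind(idx$oi, idx$di)] <- M[cbind(idx$oi, idx$di)] + v
  death <- 9L
  M[-death, death] <- M[-death, death] + q_nat
  off <- rowSums(M)[-death] - diag(M)[-death]
  if (any(off > 1)) {
    bad <- states[-death][off > 1][1L]
    stop("off-diagonal probabilities of state '", bad, "' exceed 1",
         if (!is.na(age)) paste0(" at age ", age) else "",
         "; parameters are inconsistent", call. = FALSE)
  }
  diag(M)[-death] <- diag(M)[-death] + 1 - off
  M[death, ] <- 0
  M[death, death] <- 1
  M
}

#' Run the lifetime cohort simulation for one strategy
#'
#' Propagates the cohort's state-occupancy distribution through one
#' transition matrix per cycle (rebuilt each year at the cohort's current
#' age), accumulating per-cycle costs, life-years, and quality-adjusted
#' life-years, discounted at the strategy's discount rate. Costs comprise
#' the occupied state's annual treatment cost plus the arm's per-person
#' intervention cost for every living person. Accumulation uses
#' beginning-of-cycle occupancy (optionally half-cycle corrected).
#'
#' @param params A `markov_parameters` object.
#' @param horizon Override the number of cycles (default: the parameter
#'   set's economic settings).
#' @return Object of class `cohort_trace`: a list with `trace` (data frame,
#'   one row per cycle boundary, with per-state occupancy, the cohort age,
#'   and discounted/undiscounted cost, LY and QALY increments), `totals`
#'   (named vector: discounted `cost`, `ly`, `qaly`, plus undiscounted
#'   `ly_undiscounted`, `qaly_undiscounted`, `cost_undiscounted`), and the
#'   originating `params`.
#' @examples
#' tr <- run_cohort(default_parameters("usual"))
#' summary(tr)
#' @export
run_cohort <- function(params, horizon = NULL) {
  stopifnot(inherits(params, "markov_parameters"))
  e <- params$economics
  if (is.null(horizon)) horizon <- e$horizon
  states <- ht_states()
  # utilities/costs are keyed by table symbols; align to state order
  umap <- stats::setNames(utility_table()$name, utility_table()$state)
  cmap <- stats::setNames(state_cost_table()$name, state_cost_table()$state)
  util_by_state <- c(vapply(states[1:8], function(s) params$utilities[[umap[[s]]]],
                            numeric(1)), 0)
  cost_by_state <- c(vapply(states[1:8], function(s) params$costs[[cmap[[s]]]],
                            numeric(1)), 0)
  ivc <- intervention_cost_per_cycle(params)
  scale <- params$control_rate / e$reference_control_rate
  occ <- stats::setNames(numeric(9L), states)
  occ[names(e$initial_distribution)] <- e$initial_distribution
  n_rows <- horizon + 1L
  occ_mat <- matrix(NA_real_, n_rows, 9L, dimnames = list(NULL, states))
  inc <- matrix(NA_real_, n_rows, 6L,
                dimnames = list(NULL, c("cost", "ly", "qaly", "cost_disc",
                                        "ly_disc", "qaly_disc")))
  occ_mat[1L, ] <- occ
  tidx <- transition_index(names(params$transitions))
  tvals <- as.numeric(params$transitions)
  for (k in seq_len(horizon) - 1L) {
    M <- .build_matrix(tvals, tidx,
                       mortality_lookup(params$mortality, e$start_age + k),
                       scale, age = e$start_age + k)
    if (any(abs(rowSums(M) - 1) > 1e-9)) {
      stop("transition matrix is not row-stochastic at cycle ", k,
           call. = FALSE)
    }
    occ_next <- as.vector(occ %*% M)
    names(occ_next) <- states
    w <- if (e$half_cycle_correction) (occ + occ_next) / 2 else occ
    ivc_k <- if (params$lifelong_intervention ||
                 k < (params$intervention_cycles %||% 0)) ivc else 0
    alive <- sum(w[1:8])
    cost_k <- sum(w * cost_by_state) + alive * ivc_k
    qaly_k <- sum(w * util_by_state)
    df <- discount_factor(e$discount_rate, k)
    inc[k + 1L, ] <- c(cost_k, alive, qaly_k, cost_k * df, alive * df,
                       qaly_k * df)
    occ <- occ_next
    occ_mat[k + 2L, ] <- occ
  }
  trace <- data.frame(cycle = 0:horizon, age = e$start_age + 0:horizon,
                      occ_mat, inc, check.names = FALSE)
  totals <- c(
    cost = sum(inc[, "cost_disc"], na.rm = TRUE),
    ly = sum(inc[, "ly_disc"], na.rm = TRUE),
    qaly = sum(inc[, "qaly_disc"], na.rm = TRUE),
    cost_undiscounted = sum(inc[, "cost"], na.rm = TRUE),
    ly_undiscounted = sum(inc[, "ly"], na.rm = TRUE),
    qaly_undiscounted = sum(inc[, "qaly"], na.rm = TRUE)
  )
  structure(list(trace = trace, totals = totals, params = params),
            class = "cohort_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Discounted totals of a cohort trace
#'
#' @param trace A `cohort_trace` object.
#' @return Named vector with discounted `cost` (USD), `ly` (life-years) and
#'   `qaly` totals.
#' @export
total_outcomes <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  trace$totals[c("cost", "ly", "qaly")]
}

#' @export
print.cohort_trace <- function(x, ...) {
  e <- x$params$economics
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf("Cohort trace -- arm %s: %d cycles from age %g\n",
              x$params$arm, nrow(x$trace) - 1L, e$start_age))
  cat(sprintf("  dead at final cycle: %.1f%%\n", 100 * last$death))
  cat(sprintf(
    "  discounted totals: cost $%.2f, %.3f LYs, %.3f QALYs (rate %.1f%%)\n",
    x$totals[["cost"]], x$totals[["ly"]], x$totals[["qaly"]],
    100 * e$discount_rate))
  cat(sprintf("  undiscounted: cost $%.2f, %.3f LYs, %.3f QALYs\n",
              x$totals[["cost_undiscounted"]],
              x$totals[["ly_undiscounted"]],
              x$totals[["qaly_undiscounted"]]))
  invisible(x)
}

#' @export
summary.cohort_trace <- function(object, ...) {
  print(object)
  tr <- object$trace
  marks <- unique(pmin(c(1, 5, 10, 25, 45, 65), nrow(tr) - 1L))
  cat("\nOccupancy at selected cycles:\n")
  print(tr[tr$cycle %in% marks, c("cycle", "age", ht_states())],
        row.names = FALSE, digits = 3)
  invisible(object)
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) x$trace

#' Plot state occupancy over the model horizon
#'
#' @param x A `cohort_trace` object.
#' @param states States to draw (default all nine).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.cohort_trace <- function(x, states = ht_states(), ...) {
  tr <- x$trace
  graphics::matplot(tr$cycle, as.matrix(tr[states]), type = "l", lty = 1,
                    xlab = "cycle (years)", ylab = "occupancy",
                    main = paste("Cohort occupancy --", x$params$arm), ...)
  graphics::legend("right", legend = states, col = seq_along(states),
                   lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}

#' Write a cohort trace to CSV
#'
#' One row per cycle boundary with per-state occupancy and discounted and
#' undiscounted increments.
#'
#' @param trace A `cohort_trace` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_trace <- function(trace, path) {
  stopifnot(inherits(trace, "cohort_trace"))
  utils::write.csv(trace$trace, path, row.names = FALSE)
  invisible(path)
}
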