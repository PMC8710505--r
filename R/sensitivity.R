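# One-way (tornado) and probabilistic sensitivity analysis.

#' Method-of-moments beta parameters from a mean and 95% CI
#'
#' Treats the interval width as 3.92 standard deviations (the normal 95%
#' range), so SD = (high - low)/3.92, and matches beta moments:
#' `nu = mean (1 - mean) / SD^2 - 1`, `alpha = mean nu`,
#' `beta = (1 - mean) nu`. The returned distribution has the requested
#' mean exactly.
#'
#' @param mean Mean in (0, 1).
#' @param low,high Interval bounds, `low < high`.
#' @return Named vector `c(alpha, beta)`.
#' @examples
#' beta_from_mean_ci(0.62, 0.33, 0.92)
#' @export
beta_from_mean_ci <- function(mean, low, high) {
  if (mean <= 0 || mean >= 1) stop("'mean' must lie in (0, 1)", call. = FALSE)
  if (low >= high) stop("'low' must be below 'high'", call. = FALSE)
  sd <- (high - low) / 3.92
  v <- sd^2
  if (v >= mean * (1 - mean)) {
    stop("interval too wide: implied variance >= mean(1-mean)", call. = FALSE)
  }
  nu <- mean * (1 - mean) / v - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Method-of-moments gamma parameters from a mean and 95% CI
#'
#' As [beta_from_mean_ci()], with SD = (high - low)/3.92 and gamma
#' moments: `shape = mean^2/SD^2`, `scale = SD^2/mean`.
#'
#' @param mean Positive mean.
#' @param low,high Interval bounds, `low < high`.
#' @return Named vector `c(shape, scale)`.
#' @export
gamma_from_mean_ci <- function(mean, low, high) {
  if (mean <= 0) stop("'mean' must be positive", call. = FALSE)
  if (low >= high) stop("'low' must be below 'high'", call. = FALSE)
  sd <- (high - low) / 3.92
  c(shape = mean^2 / sd^2, scale = sd^2 / mean)
}

#' Sample a parameter according to its specification
#'
#' Draws from the beta or gamma distribution implied by the spec's base
#' value and interval (method of moments, see [beta_from_mean_ci()]).
#' Zero-width intervals and `"fixed"` specs return the base value
#' unchanged.
#'
#' @param spec One-row data frame (or list) with `name`, `base`, `low`,
#'   `high`, `distribution`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_parameter <- function(spec, n = 1) {
  base <- spec$base
  if (spec$distribution == "fixed" || spec$high <= spec$low) {
    return(rep(base, n))
  }
  switch(spec$distribution,
    beta = {
      ab <- beta_from_mean_ci(base, spec$low, spec$high)
      stats::rbeta(n, ab[["alpha"]], ab[["beta"]])
    },
    gamma = {
      ss <- gamma_from_mean_ci(base, spec$low, spec$high)
      stats::rgamma(n, shape = ss[["shape"]], scale = ss[["scale"]])
    },
    stop("unknown distribution '", spec$distribution, "' for parameter ",
         spec$name, call. = FALSE))
}

# Default decision outcome: ICER of the last arm vs the first
# (option2 vs usual when the strategies are in canonical order).
.default_outcome <- function(strategies) {
  arms <- names(strategies)
  a <- if ("option2" %in% arms) "option2" else arms[length(arms)]
  b <- if ("usual" %in% arms) "usual" else arms[1L]
  function(strat) {
    ta <- total_outcomes(run_cohort(strat[[a]]))
    tb <- total_outcomes(run_cohort(strat[[b]]))
    icer(ta[["cost"]] - tb[["cost"]], ta[["qaly"]] - tb[["qaly"]])$ratio
  }
}

#' One-way deterministic sensitivity analysis (tornado table)
#'
#' Recomputes a scalar decision outcome with each parameter set to the low
#' and then the high end of its range, all other parameters held at base.
#' Rows are sorted by decreasing swing (absolute difference between the
#' two outcomes), ready for a tornado diagram.
#'
#' @param strategies Named list of `markov_parameters` (see
#'   [default_strategies()]).
#' @param specs Parameter specifications as from
#'   [default_parameter_specs()].
#' @param outcome Function mapping a strategies list to a scalar outcome;
#'   default: ICER of Option 2 vs usual practice.
#' @return Object of class `tornado_table`: data frame with columns
#'   `name`, `low`, `high`, `outcome_low`, `outcome_high`, `swing`, plus
#'   the base outcome in `attr(, "base_outcome")`.
#' @export
one_way_analysis <- function(strategies, specs = default_parameter_specs(),
                             outcome = NULL) {
  if (is.null(outcome)) outcome <- .default_outcome(strategies)
  known <- c(.required_transitions(), .required_utilities(),
             .required_costs(), .arm_symbol_map()$name, "discount_rate")
  bad <- setdiff(specs$name, known)
  if (length(bad)) {
    stop("unknown parameter(s) in specs: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  base_outcome <- outcome(strategies)
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    sp <- specs[i, ]
    at <- function(v) outcome(set_model_parameter(strategies, sp$name, v))
    o_low <- at(sp$low)
    o_high <- at(sp$high)
    data.frame(name = sp$name, low = sp$low, high = sp$high,
               outcome_low = o_low, outcome_high = o_high,
               swing = abs(o_high - o_low), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$swing), ]
  rownames(out) <- NULL
  structure(out, base_outcome = base_outcome,
            class = c("tornado_table", "data.frame"))
}

#' @export
print.tornado_table <- function(x, n = 10L, ...) {
  cat("One-way sensitivity analysis (base outcome ",
      sprintf("%.2f", attr(x, "base_outcome")), ")\n", sep = "")
  print.data.frame(utils::head(x, n), row.names = FALSE, digits = 5)
  if (nrow(x) > n) cat("...", nrow(x) - n, "further parameters\n")
  invisible(x)
}

#' Tornado diagram
#'
#' Horizontal bars spanning the outcome at each parameter's low and high
#' value, widest swings on top.
#'
#' @param x A `tornado_table`.
#' @param n Number of parameters to draw (default 10).
#' @param ... Passed to [graphics::barplot()] (unused, reserved).
#' @export
plot.tornado_table <- function(x, n = 10L, ...) {
  d <- utils::head(x, n)
  d <- d[rev(seq_len(nrow(d))), ]
  base <- attr(x, "base_outcome")
  lo <- pmin(d$outcome_low, d$outcome_high)
  hi <- pmax(d$outcome_low, d$outcome_high)
  op <- graphics::par(mar = c(4, 9, 3, 1))
  on.exit(graphics::par(op))
  graphics::plot(NULL, xlim = range(c(lo, hi, base)),
                 ylim = c(0.5, nrow(d) + 0.5), yaxt = "n",
                 xlab = "outcome", ylab = "",
                 main = "One-way sensitivity (tornado)")
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$name, las = 1,
                 cex.axis = 0.7)
  graphics::rect(lo, seq_len(nrow(d)) - 0.35, hi, seq_len(nrow(d)) + 0.35,
                 col = "steelblue")
  graphics::abline(v = base, lty = 2)
  invisible(x)
}

#' Probabilistic sensitivity analysis (second-order Monte Carlo)
#'
#' Each iteration draws every uncertain parameter once from its
#' distribution (draws shared across arms), rebuilds all strategies, runs
#' the cohort model, and records discounted totals. The
#' cost-effectiveness acceptability curve (CEAC) reports, over a grid of
#' willingness-to-pay values, the fraction of iterations in which each arm
#' attains the highest net monetary benefit (ties split equally).
#'
#' @param strategies Named list of `markov_parameters`.
#' @param specs Parameter specifications; `"fixed"` rows are not sampled.
#' @param n_iter Number of Monte Carlo iterations (default 1000).
#' @param wtp_grid Willingness-to-pay grid for the CEAC; default 0 to 4x
#'   the base threshold in 100 steps, always including the base threshold
#'   itself.
#' @param seed Optional integer seed for reproducibility.
#' @return Object of class `psa_result`: list with `iterations` (data
#'   frame: `iteration`, `arm`, `cost`, `qaly`), `ceac` (data frame:
#'   `wtp`, `arm`, `probability`), `wtp` (base threshold), `n_iter`.
#' @export
run_psa <- function(strategies, specs = default_parameter_specs(),
                    n_iter = 1000, wtp_grid = NULL, seed = NULL) {
  stopifnot(n_iter >= 1)
  if (!is.null(seed)) set.seed(seed)
  wtp0 <- strategies[[1L]]$economics$wtp
  if (is.null(wtp_grid)) {
    wtp_grid <- sort(unique(c(seq(0, 4 * wtp0, length.out = 100L), wtp0)))
  }
  arms <- names(strategies)
  sampled <- specs[specs$distribution != "fixed" & specs$high > specs$low, ]
  cost <- qaly <- matrix(NA_real_, n_iter, length(arms),
                         dimnames = list(NULL, arms))
  for (it in seq_len(n_iter)) {
    strat <- strategies
    for (i in seq_len(nrow(sampled))) {
      strat <- set_model_parameter(strat, sampled$name[i],
                                   sample_parameter(sampled[i, ], 1L))
    }
    for (a in arms) {
      tot <- total_outcomes(run_cohort(strat[[a]]))
      cost[it, a] <- tot[["cost"]]
      qaly[it, a] <- tot[["qaly"]]
    }
  }
  iterations <- data.frame(
    iteration = rep(seq_len(n_iter), times = length(arms)),
    arm = rep(arms, each = n_iter),
    cost = as.vector(cost), qaly = as.vector(qaly),
    stringsAsFactors = FALSE)
  ceac <- ceac_from_iterations(cost, qaly, wtp_grid)
  structure(list(iterations = iterations, ceac = ceac, wtp = wtp0,
                 n_iter = n_iter, arms = arms),
            class = "psa_result")
}

# cost, qaly: n_iter x n_arm matrices
ceac_from_iterations <- function(cost, qaly, wtp_grid) {
  arms <- colnames(cost)
  out <- lapply(wtp_grid, function(w) {
    nb <- w * qaly - cost
    best <- nb == apply(nb, 1L, max)
    wins <- best / rowSums(best) # ties split equally
    data.frame(wtp = w, arm = arms, probability = colMeans(wins),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cost-effectiveness probability at a threshold
#'
#' @param psa A `psa_result`.
#' @param wtp Threshold; defaults to the base threshold of the analysis.
#' @return Named vector of per-arm probabilities (summing to 1).
#' @export
ce_probability <- function(psa, wtp = psa$wtp) {
  stopifnot(inherits(psa, "psa_result"))
  it <- psa$iterations
  cost <- matrix(it$cost, ncol = length(psa$arms),
                 dimnames = list(NULL, psa$arms))
  qaly <- matrix(it$qaly, ncol = length(psa$arms),
                 dimnames = list(NULL, psa$arms))
  cc <- ceac_from_iterations(cost, qaly, wtp)
  stats::setNames(cc$probability, cc$arm)
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d iterations, %d arms\n",
              x$n_iter, length(x$arms)))
  p <- ce_probability(x)
  cat(sprintf("Cost-effectiveness probability at WTP $%.2f/QALY:\n", x$wtp))
  print(round(p, 3))
  invisible(x)
}

#' Cost-effectiveness acceptability curves
#'
#' @param x A `psa_result`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.psa_result <- function(x, ...) {
  wide <- stats::reshape(x$ceac, idvar = "wtp", timevar = "arm",
                         direction = "wide")
  graphics::matplot(wide$wtp, as.matrix(wide[-1L]), type = "l", lty = 1,
                    ylim = c(0, 1), xlab = "willingness to pay ($/QALY)",
                    ylab = "P(cost-effective)",
                    main = "Cost-effectiveness acceptability", ...)
  graphics::abline(v = x$wtp, lty = 3)
  graphics::legend("right", legend = x$arms, col = seq_along(x$arms),
                   lty = 1, cex = 0.8, bty = "n")
  invisible(x)
}
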