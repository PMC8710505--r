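#' Incremental cost-effectiveness ratio with dominance flag
#'
#' The ICER is the incremental cost divided by the incremental
#' effectiveness. Dominance is reported alongside the raw ratio rather
#' than suppressing it: a strategy that is cheaper and more effective than
#' its comparator is `"dominant"` (its negative ICER is still returned),
#' one that is costlier and less effective is `"dominated"`. A zero
#' effectiveness difference yields an undefined ratio.
#'
#' @param delta_cost Incremental cost (USD).
#' @param delta_qaly Incremental effectiveness (QALYs).
#' @return List with `ratio` (USD/QALY, `NA` when undefined) and `flag`
#'   (one of `"dominant"`, `"dominated"`, `"undefined"`, `"ratio"`).
#' @examples
#' icer(-2237.30, 0.477) # dominant, ratio ~ -4690
#' @export
icer <- function(delta_cost, delta_qaly) {
  flag <- if (delta_cost < 0 && delta_qaly > 0) "dominant"
          else if (delta_cost > 0 && delta_qaly < 0) "dominated"
          else if (delta_qaly == 0) "undefined"
          else "ratio"
  ratio <- if (delta_qaly == 0) NA_real_ else delta_cost / delta_qaly
  list(ratio = ratio, flag = flag)
}

#' Net monetary and net health benefit
#'
#' `nmb()` returns `wtp * delta_qaly - delta_cost` (USD); `nhb()` returns
#' `delta_qaly - delta_cost / wtp` (QALYs). The two satisfy
#' `nmb = wtp * nhb` identically.
#'
#' @param delta_cost Incremental cost (USD).
#' @param delta_qaly Incremental effectiveness (QALYs).
#' @param wtp Willingness-to-pay threshold (USD/QALY), positive.
#' @return Numeric (vectorized over the deltas).
#' @examples
#' nmb(-2007.31, 0.545, 1599.16)
#' nhb(-2007.31, 0.545, 1599.16)
#' @export
nmb <- function(delta_cost, delta_qaly, wtp) {
  if (any(wtp <= 0)) stop("'wtp' must be positive", call. = FALSE)
  wtp * delta_qaly - delta_cost
}

#' @rdname nmb
#' @export
nhb <- function(delta_cost, delta_qaly, wtp) {
  if (any(wtp <= 0)) stop("'wtp' must be positive", call. = FALSE)
  delta_qaly - delta_cost / wtp
}

#' Pairwise incremental comparison of strategies
#'
#' Compares every ordered pair of strategies (each later arm against each
#' earlier one, in the supplied order) on discounted totals: incremental
#' cost and QALYs, ICER with dominance flag, net monetary and net health
#' benefit at the willingness-to-pay threshold, and a verdict. With arms
#' supplied as usual practice, Option 1, Option 2 this yields the standard
#' reporting order (Option 1 vs usual, Option 2 vs usual, Option 2 vs
#' Option 1). An efficiency-frontier summary marks strategies not
#' dominated by any other.
#'
#' @param outcomes Named list of per-arm totals -- each element either a
#'   `cohort_trace` or a named vector with `cost` and `qaly` (and
#'   optionally `ly`). At least two arms; names must be unique.
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @return Object of class `cea_comparison`: list with `totals` (per-arm
#'   data frame), `comparisons` (one row per ordered pair), `frontier`
#'   (non-dominated arm labels), and `wtp`.
#' @examples
#' out <- list(usual = c(cost = 10999.55, qaly = 15.263),
#'             option1 = c(cost = 11229.54, qaly = 15.331),
#'             option2 = c(cost = 8992.24, qaly = 15.808))
#' compare_strategies(out, wtp = 1599.16)
#' @export
compare_strategies <- function(outcomes, wtp = 1599.16) {
  if (length(outcomes) < 2L) stop("need at least two arms", call. = FALSE)
  if (is.null(names(outcomes)) || anyDuplicated(names(outcomes))) {
    stop("arm labels must be unique and named", call. = FALSE)
  }
  get_tot <- function(x) {
    if (inherits(x, "cohort_trace")) x <- x$totals
    c(cost = unname(x[["cost"]]), qaly = unname(x[["qaly"]]),
      ly = if ("ly" %in% names(x)) unname(x[["ly"]]) else NA_real_)
  }
  tot <- t(vapply(outcomes, get_tot, c(cost = 0, qaly = 0, ly = 0)))
  totals <- data.frame(arm = rownames(tot), tot, row.names = NULL,
                       stringsAsFactors = FALSE)
  arms <- totals$arm
  pairs <- list()
  for (j in seq_along(arms)[-1L]) {
    for (i in seq_len(j - 1L)) {
      pairs[[length(pairs) + 1L]] <- c(arms[j], arms[i])
    }
  }
  # Table-8 order: each later arm vs the earliest comparators first
  ord <- order(vapply(pairs, function(p) match(p[2L], arms), 0),
               vapply(pairs, function(p) match(p[1L], arms), 0))
  comparisons <- do.call(rbind, lapply(pairs[ord], function(p) {
    a <- tot[p[1L], ]; b <- tot[p[2L], ]
    dc <- a[["cost"]] - b[["cost"]]
    dq <- a[["qaly"]] - b[["qaly"]]
    ic <- icer(dc, dq)
    nm <- nmb(dc, dq, wtp)
    verdict <- switch(ic$flag,
      dominant = "dominant",
      dominated = "dominated",
      if (nm > 0) "cost_effective_at_wtp" else "not_cost_effective_at_wtp")
    data.frame(intervention = p[1L], comparator = p[2L],
               delta_cost = dc, delta_qaly = dq,
               icer = ic$ratio, icer_flag = ic$flag,
               nmb = nm, nhb = nhb(dc, dq, wtp), verdict = verdict,
               stringsAsFactors = FALSE)
  }))
  rownames(comparisons) <- NULL
  dominated <- vapply(arms, function(a) {
    any(tot[, "cost"] < tot[a, "cost"] & tot[, "qaly"] > tot[a, "qaly"])
  }, logical(1))
  structure(list(totals = totals, comparisons = comparisons,
                 frontier = arms[!dominated], wtp = wtp),
            class = "cea_comparison")
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat("Cost-utility comparison (WTP $", format(x$wtp, big.mark = ","),
      "/QALY)\n\n", sep = "")
  tot <- x$totals
  tot$cost <- sprintf("$%.2f", tot$cost)
  tot$qaly <- sprintf("%.3f", tot$qaly)
  tot$ly <- ifelse(is.na(tot$ly), "", sprintf("%.3f", tot$ly))
  print.data.frame(tot, row.names = FALSE)
  cat("\nIncremental comparisons:\n")
  cmp <- x$comparisons
  out <- data.frame(
    pair = paste(cmp$intervention, "vs", cmp$comparator),
    `dCost` = sprintf("$%.2f", cmp$delta_cost),
    `dQALY` = sprintf("%.3f", cmp$delta_qaly),
    ICER = ifelse(is.na(cmp$icer), "undefined",
                  sprintf("$%.2f/QALY", cmp$icer)),
    NMB = sprintf("$%.2f", cmp$nmb),
    NHB = sprintf("%.4f", cmp$nhb),
    verdict = cmp$verdict, check.names = FALSE, stringsAsFactors = FALSE)
  print.data.frame(out, row.names = FALSE)
  cat("\nEfficiency frontier:", paste(x$frontier, collapse = ", "), "\n")
  invisible(x)
}

#' Write a comparison report to CSV
#'
#' Writes two files: `<stem>_totals.csv` (per-arm discounted totals) and
#' `<stem>_comparisons.csv` (incremental rows).
#'
#' @param comparison A `cea_comparison` object.
#' @param stem Path stem for the two output files.
#' @return Character vector of the written paths, invisibly.
#' @export
write_cea_report <- function(comparison, stem) {
  stopifnot(inherits(comparison, "cea_comparison"))
  paths <- paste0(stem, c("_totals.csv", "_comparisons.csv"))
  utils::write.csv(comparison$totals, paths[1L], row.names = FALSE)
  utils::write.csv(comparison$comparisons, paths[2L], row.names = FALSE)
  invisible(paths)
}
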