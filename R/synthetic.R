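# Synthetic-trial generator: longitudinal follow-up records with known
# ground truth, emulating a three-arm community hypertension-management
# trial with bi-monthly follow-up visits.

#' Default bi-monthly transition matrix over blood-pressure states
#'
#' Converts the annual blood-pressure transition probabilities to a
#' 2-month step via [annual_to_step_probability()] and fills the diagonal
#' with the residual stay probability, giving the ground-truth step matrix
#' the generator evolves states with.
#'
#' @param annual Named annual probabilities (defaults to the packaged
#'   point estimates); only blood-pressure pairs are used.
#' @param step_years Step length in years (default 1/6, bi-monthly).
#' @return 4x4 row-stochastic matrix over [hypertension_states()].
#' @export
default_step_matrix <- function(annual = NULL, step_years = 1 / 6) {
  if (is.null(annual)) {
    tp <- transition_probability_table()
    annual <- stats::setNames(tp$value, tp$name)
  }
  hs <- hypertension_states()
  S <- matrix(0, 4L, 4L, dimnames = list(hs, hs))
  for (nm in names(annual)) {
    pair <- parse_transition_symbol(nm)
    if (pair[["origin"]] %in% hs && pair[["destination"]] %in% hs) {
      S[pair[["origin"]], pair[["destination"]]] <-
        annual_to_step_probability(annual[[nm]], step_years)
    }
  }
  diag(S) <- 1 - rowSums(S)
  if (any(diag(S) < 0)) stop("step matrix rows exceed 1", call. = FALSE)
  S
}

#' Configuration of the synthetic trial generator
#'
#' Defines the study conditions the generator emulates: a three-arm cohort
#' with twelve bi-monthly follow-ups over two years, baseline
#' blood-pressure mix 0.32/0.53/0.12/0.03, arm-specific blood-pressure
#' control frequencies, Markovian state evolution under a known step
#' matrix, state-banded blood-pressure emissions, SF-36 scores whose
#' mapped utilities match the state utilities, and per-visit dropout
#' calibrated to an overall 12.63% loss to follow-up.
#'
#' @param n_patients Patients per arm (default 416, one third of an
#'   analyzable cohort of ~1,248).
#' @param arms Named per-arm control frequencies (probability a
#'   post-baseline visit is controlled, i.e. SBP drawn below 120 mmHg).
#' @param n_visits Number of post-baseline follow-up visits (default 12).
#' @param visit_interval_years Time between visits (default 1/6 year).
#' @param baseline_distribution Baseline state mix over the four
#'   blood-pressure states.
#' @param step_matrix Ground-truth per-visit transition matrix (default
#'   [default_step_matrix()]).
#' @param sf36_means Per-state mean SF-36 score (one scalar per state,
#'   applied to all eight dimensions); defaults solve the mapping so each
#'   state's expected utility equals its published value.
#' @param sf36_sd SD of the additive SF-36 noise (default 8 points,
#'   truncated to the 0-100 scale).
#' @param dropout_per_visit Per-visit dropout probability; the default
#'   `1 - (1 - 0.1263)^(1/12)` yields 12.63% overall loss by the final
#'   visit.
#' @param seed Integer seed; mandatory, the generator is deterministic
#'   given the configuration.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_patients = 416,
                             arms = c(usual = 0.61, option1 = 0.62,
                                      option2 = 0.69),
                             n_visits = 12,
                             visit_interval_years = 1 / 6,
                             baseline_distribution = baseline_state_distribution(),
                             step_matrix = NULL,
                             sf36_means = NULL,
                             sf36_sd = 8,
                             dropout_per_visit = 1 - (1 - 0.1263)^(1 / 12),
                             seed) {
  if (missing(seed) || is.null(seed)) {
    stop("'seed' is mandatory for reproducibility", call. = FALSE)
  }
  if (is.null(names(arms)) || any(arms < 0 | arms > 1)) {
    stop("'arms' must be named control frequencies in [0, 1]", call. = FALSE)
  }
  hs <- hypertension_states()
  baseline_distribution <- baseline_distribution[hs]
  if (anyNA(baseline_distribution) || any(baseline_distribution < 0) ||
      abs(sum(baseline_distribution) - 1) > 1e-8) {
    stop("'baseline_distribution' must be a distribution over the four ",
         "blood-pressure states", call. = FALSE)
  }
  if (is.null(step_matrix)) {
    step_matrix <- default_step_matrix(step_years = visit_interval_years)
  }
  if (!all(dim(step_matrix) == c(4L, 4L)) ||
      any(abs(rowSums(step_matrix) - 1) > 1e-8) || any(step_matrix < 0)) {
    stop("'step_matrix' must be 4x4 row-stochastic", call. = FALSE)
  }
  if (is.null(sf36_means)) {
    # invert the affine mapping at equal dimension scores:
    # U = intercept + m * sum(coefs)  =>  m = (U - intercept) / sum(coefs)
    beta <- sf36_eq5d_coefficients()
    csum <- sum(beta[-1L])
    ut <- utility_table()
    u4 <- stats::setNames(ut$value, ut$state)[hs]
    sf36_means <- (u4 - beta[["(Intercept)"]]) / csum
  }
  if (dropout_per_visit < 0 || dropout_per_visit >= 1) {
    stop("'dropout_per_visit' must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients), arms = arms,
         n_visits = as.integer(n_visits),
         visit_interval_years = visit_interval_years,
         baseline_distribution = baseline_distribution,
         step_matrix = step_matrix, sf36_means = sf36_means,
         sf36_sd = sf36_sd, dropout_per_visit = dropout_per_visit,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# SBP/DBP bands by blood-pressure state (mmHg); controlled visits draw
# SBP from the sub-120 band regardless of state.
.sbp_bands <- rbind(prehypertension = c(120, 140), L1 = c(140, 160),
                    L2 = c(160, 180), L3 = c(180, 200))
.dbp_bands <- rbind(prehypertension = c(80, 90), L1 = c(90, 100),
                    L2 = c(100, 110), L3 = c(110, 120))

#' Generate a synthetic follow-up cohort
#'
#' Simulates the configured trial: per patient a baseline state is drawn
#' from the baseline mix, the state evolves by the ground-truth step
#' matrix at each bi-monthly visit, blood pressure is drawn uniformly
#' within the occupied state's band -- except that each post-baseline
#' visit is "controlled" with the arm's control frequency, in which case
#' SBP is drawn below 120 mmHg (the recorded state is the underlying
#' Markov state either way). SF-36 dimension scores are the state's mean
#' plus truncated Gaussian noise. Dropout truncates a patient's record
#' after a geometric number of visits; the baseline visit is always
#' retained. Deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @return Data frame of follow-up records, one row per retained
#'   patient-visit, with columns `patient_id`, `arm`, `visit_index`,
#'   `sbp`, `dbp`, `state`, `pf`, `rp`, `bp`, `gh`, `vt`, `sf`, `re`,
#'   `mh`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  hs <- hypertension_states()
  nv <- config$n_visits
  out <- lapply(names(config$arms), function(arm) {
    n <- config$n_patients
    ids <- sprintf("%s_%04d", arm, seq_len(n))
    # state paths: n x (nv + 1)
    states <- matrix(NA_integer_, n, nv + 1L)
    states[, 1L] <- sample.int(4L, n, replace = TRUE,
                               prob = config$baseline_distribution)
    for (v in seq_len(nv)) {
      prev <- states[, v]
      nxt <- integer(n)
      for (s in 1:4) {
        idx <- which(prev == s)
        if (length(idx)) {
          nxt[idx] <- sample.int(4L, length(idx), replace = TRUE,
                                 prob = config$step_matrix[s, ])
        }
      }
      states[, v + 1L] <- nxt
    }
    # retention: patient observed at visits 0..last_visit
    last_visit <- if (config$dropout_per_visit > 0) {
      pmin(stats::rgeom(n, config$dropout_per_visit), nv)
    } else rep(nv, n)
    keep <- sequence(last_visit + 1L) - 1L # visit indices per patient
    pid <- rep(ids, times = last_visit + 1L)
    st <- states[cbind(rep(seq_len(n), times = last_visit + 1L), keep + 1L)]
    m <- length(pid)
    controlled <- keep > 0L & stats::runif(m) < config$arms[[arm]]
    sbp <- stats::runif(m, .sbp_bands[st, 1L], .sbp_bands[st, 2L])
    dbp <- stats::runif(m, .dbp_bands[st, 1L], .dbp_bands[st, 2L])
    sbp[controlled] <- stats::runif(sum(controlled), 100, 120)
    dbp[controlled] <- stats::runif(sum(controlled), 65, 80)
    scores <- matrix(
      pmin(100, pmax(0, config$sf36_means[st] +
                       stats::rnorm(m * 8L, sd = config$sf36_sd))),
      m, 8L, dimnames = list(NULL, c("pf", "rp", "bp", "gh", "vt", "sf",
                                     "re", "mh")))
    data.frame(patient_id = pid, arm = arm, visit_index = keep,
               sbp = sbp, dbp = dbp, state = hs[st], scores,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Read and write follow-up record CSV files
#'
#' @param path File path.
#' @param records Follow-up record data frame.
#' @return `read_followup_records()` returns the validated data frame;
#'   `write_followup_records()` returns `path` invisibly.
#' @export
read_followup_records <- function(path) {
  if (!file.exists(path)) stop("no such record file: ", path, call. = FALSE)
  .check_records(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_followup_records
#' @export
write_followup_records <- function(records, path) {
  utils::write.csv(.check_records(records), path, row.names = FALSE)
  invisible(path)
}
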