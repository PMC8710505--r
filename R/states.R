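#' Health states of the hypertension cohort model
#'
#' The model tracks nine mutually exclusive health states: prehypertension,
#' the three hypertension grades (L1, L2, L3), four complication states
#' (myocardial infarction, stroke, congestive heart failure, end-stage renal
#' disease), and death. Death is the single absorbing state. Normotension is
#' deliberately absent: managed patients are assumed never to return below
#' the prehypertensive range, so prehypertension is the best attainable
#' state.
#'
#' @return Character vector of the nine state labels, in canonical order
#'   (death last).
#' @examples
#' ht_states()
#' @export
ht_states <- function() {
  c("prehypertension", "L1", "L2", "L3",
    "MI", "stroke", "CHF", "ESRD", "death")
}

#' @rdname ht_states
#' @return `hypertension_states()` returns the four blood-pressure states an
#'   incident cohort can occupy at baseline.
#' @export
hypertension_states <- function() ht_states()[1:4]

# Tokens used in transition-parameter symbols ("p<origin>_<destination>"):
# 0.5 = prehypertension, 1..3 = hypertension grades, named complication
# states, Death.
.state_tokens <- c(prehypertension = "0.5", L1 = "1", L2 = "2", L3 = "3",
                   MI = "MI", stroke = "Stroke", CHF = "CHF", ESRD = "ESRD",
                   death = "Death")

#' Transition parameter symbols
#'
#' Annual transition probabilities are addressed by compact symbols of the
#' form `p<origin>_<destination>`, where prehypertension is written `0.5`
#' and the hypertension grades `1`-`3` (e.g. `p1_0.5` is the annual
#' probability of moving from grade-1 hypertension back to
#' prehypertension). `transition_symbol()` builds the symbol for a state
#' pair; `parse_transition_symbol()` inverts it.
#'
#' @param origin,destination State labels as in [ht_states()].
#' @return `transition_symbol()`: a character symbol.
#'   `parse_transition_symbol()`: a named character vector with elements
#'   `origin` and `destination`.
#' @examples
#' transition_symbol("L1", "prehypertension")
#' parse_transition_symbol("p0.5_MI")
#' @export
transition_symbol <- function(origin, destination) {
  origin <- match.arg(origin, ht_states())
  destination <- match.arg(destination, ht_states())
  paste0("p", .state_tokens[[origin]], "_", .state_tokens[[destination]])
}

#' @rdname transition_symbol
#' @param symbol A transition symbol such as `"p0.5_1"`. Case of the leading
#'   `p` and of the state tokens is ignored.
#' @export
parse_transition_symbol <- function(symbol) {
  stopifnot(is.character(symbol), length(symbol) == 1L)
  body <- sub("^[pP]", "", symbol)
  parts <- strsplit(body, "_", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) {
    stop("malformed transition symbol: ", symbol, call. = FALSE)
  }
  lookup <- function(tok) {
    hit <- match(tolower(tok), tolower(.state_tokens))
    if (is.na(hit)) stop("unknown state token '", tok, "' in symbol ", symbol,
                         call. = FALSE)
    names(.state_tokens)[hit]
  }
  c(origin = lookup(parts[1L]), destination = lookup(parts[2L]))
}

#' Improvement transitions
#'
#' The directed state pairs that represent a clinical improvement (a move to
#' a strictly less severe blood-pressure grade). These are the transitions
#' scaled by an arm's blood-pressure control rate in
#' [build_transition_matrix()].
#'
#' @return Data frame with columns `origin` and `destination`.
#' @export
improvement_transitions <- function() {
  data.frame(
    origin = c("L1", "L2", "L2", "L3", "L3", "L3"),
    destination = c("prehypertension", "prehypertension", "L1",
                    "prehypertension", "L1", "L2"),
    stringsAsFactors = FALSE
  )
}
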