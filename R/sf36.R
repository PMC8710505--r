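#' Coefficients of the SF-36 to EQ-5D mapping
#'
#' The published Ara-Brazier additive mapping (their Model 1) predicting an
#' EQ-5D utility index from the eight SF-36 dimension scores. The intercept
#' is returned under the name `"(Intercept)"`; the remaining coefficients
#' are keyed by the SF-36 dimension abbreviations: PF (physical
#' functioning), RP (role physical), BP (bodily pain), GH (general health),
#' VT (vitality), SF (social functioning), RE (role emotional), MH (mental
#' health).
#'
#' @return Named numeric vector of length 9.
#' @export
sf36_eq5d_coefficients <- function() {
  c("(Intercept)" = 0.03256,
    PF = 0.0037, SF = 0.00111, RP = -0.00024, RE = 0.00024,
    MH = 0.00256, VT = -0.00063, BP = 0.00286, GH = 0.00052)
}

#' Map SF-36 dimension scores to an EQ-5D utility index
#'
#' Applies the additive mapping in [sf36_eq5d_coefficients()] to eight
#' SF-36 dimension scores on the 0-100 scale. The mapping is affine, so it
#' is applied row-wise to a data frame or matrix of scores. Because the RP
#' and VT coefficients are negative the prediction can fall below 0 for
#' extreme profiles; such values are clamped to 0 (with a warning) so that
#' downstream quality-adjusted life-year arithmetic stays well defined.
#'
#' @param scores A named numeric vector with elements `PF`, `RP`, `BP`,
#'   `GH`, `VT`, `SF`, `RE`, `MH`, or a data frame / matrix with those
#'   columns (case-insensitive). All scores must lie in `[0, 100]`.
#' @return Numeric vector of utility indices, one per row of input.
#' @examples
#' map_sf36_to_eq5d(c(PF = 100, RP = 0, BP = 0, GH = 0,
#'                    VT = 0, SF = 0, RE = 0, MH = 0))
#' @export
map_sf36_to_eq5d <- function(scores) {
  dims <- c("PF", "RP", "BP", "GH", "VT", "SF", "RE", "MH")
  if (is.data.frame(scores)) scores <- as.matrix(scores)
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L,
                                             dimnames = list(NULL, names(scores)))
  cn <- colnames(scores)
  if (is.null(cn)) stop("SF-36 scores must be named by dimension", call. = FALSE)
  idx <- match(dims, toupper(cn))
  if (anyNA(idx)) {
    stop("missing SF-36 dimension(s): ",
         paste(dims[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  x <- scores[, idx, drop = FALSE]
  storage.mode(x) <- "double"
  if (anyNA(x) || any(x < 0) || any(x > 100)) {
    stop("SF-36 dimension scores must lie in [0, 100]", call. = FALSE)
  }
  beta <- sf36_eq5d_coefficients()
  u <- as.vector(beta[["(Intercept)"]] + x %*% beta[dims])
  if (any(u < 0)) {
    warning("mapped utility below 0 clamped to 0 for ", sum(u < 0),
            " observation(s)", call. = FALSE)
    u[u < 0] <- 0
  }
  u
}
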