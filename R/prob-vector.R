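#' Validate (and optionally renormalize) a categorical probability vector
#'
#' Belief distributions, transition rows and policy rows must be valid
#' points on the probability simplex. Elicited probabilities (e.g. a
#' clinician's differential diagnosis) rarely sum to exactly 1 in floating
#' point, so a small deviation from 1 is tolerated and can be repaired by
#' renormalization. Negative entries are never repaired: a negative
#' "probability" signals corrupted input, not rounding error.
#'
#' @param values Numeric vector of candidate probabilities, one entry per
#'   state (or action).
#' @param tolerance Maximum allowed absolute deviation of `sum(values)`
#'   from 1. Default `1e-8`.
#' @param renormalize If `TRUE` and the sum deviates from 1 by at most
#'   `tolerance`, entries are divided by their sum so the result sums to
#'   exactly 1. If `FALSE` (default) the values are returned unchanged.
#'
#' @return The validated (possibly renormalized) numeric vector.
#' @examples
#' validate_prob_vector(c(0.25, 0.25, 0.25, 0.25))
#' validate_prob_vector(c(0.3333333, 0.3333333, 0.3333334),
#'                      tolerance = 1e-6, renormalize = TRUE)
#' @export
validate_prob_vector <- function(values, tolerance = 1e-8, renormalize = FALSE) {
  if (length(values) == 0L) {
    abort("Probability vector must be non-empty.")
  }
  if (!is.numeric(values) || anyNA(values)) {
    abort("Probability vector must be numeric with no missing values.")
  }
  if (any(values < 0)) {
    bad <- which(values < 0)
    abort(sprintf(
      "Probability vector has negative entries at position(s) %s.",
      paste(bad, collapse = ", ")
    ))
  }
  s <- sum(values)
  if (abs(s - 1) > tolerance) {
    abort(sprintf(
      "Probabilities must sum to 1 (within tolerance %g); observed sum %.10g.",
      tolerance, s
    ))
  }
  if (renormalize) values / s else values
}

# internal: validate each row of a numeric matrix as a probability vector,
# reporting the offending row label on failure
validate_prob_rows <- function(mat, row_labels, tolerance = 1e-8,
                               renormalize = FALSE, what = "row") {
  out <- mat
  for (i in seq_len(nrow(mat))) {
    res <- tryCatch(
      validate_prob_vector(mat[i, ], tolerance = tolerance,
                           renormalize = renormalize),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      abort(sprintf("Invalid %s '%s': %s", what, row_labels[i],
                    conditionMessage(res)))
    }
    out[i, ] <- res
  }
  out
}
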