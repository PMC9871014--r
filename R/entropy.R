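#' Shannon entropy of a categorical distribution
#'
#' H(p) = -sum_i p_i log(p_i), with the standard information-theoretic
#' convention 0 * log 0 := 0. In base 2 the result is in bits ("yes/no
#' questions left to resolve"); it ranges from 0 for a degenerate
#' distribution to log_base(K) for the uniform distribution over K states.
#'
#' @param p Numeric probability vector (validated internally).
#' @param base Logarithm base, > 1. Default 2 (bits); use `exp(1)` for nats.
#' @param tolerance Sum tolerance for validation.
#' @return Entropy in units of `log(base)`.
#' @examples
#' shannon_entropy(c(0.25, 0.25, 0.25, 0.25)) # 2 bits
#' shannon_entropy(c(1, 0, 0))                # 0 bits
#' shannon_entropy(c(0.5, 0.25, 0.25))        # 1.5 bits
#' @export
shannon_entropy <- function(p, base = 2, tolerance = 1e-8) {
  check_base(base)
  p <- validate_prob_vector(p, tolerance = tolerance)
  pos <- p > 0
  -sum(p[pos] * log(p[pos], base = base))
}

#' Cross-entropy of q relative to p
#'
#' H(p, q) = -sum_i p_i log(q_i): the expected surprise when outcomes are
#' p-distributed but coded under q. If q places zero mass where p does not,
#' the cross-entropy is `+Inf`; an optional epsilon floor (off by default,
#' because it silently changes the metric) replaces zeros in q with
#' `epsilon` and renormalizes before the sum.
#'
#' @inheritParams shannon_entropy
#' @param q Numeric probability vector, same length as `p`.
#' @param epsilon Optional smoothing constant in (0, 1e-3]; default `NULL`
#'   (no smoothing).
#' @return Cross-entropy in units of `log(base)`, possibly `Inf`.
#' @examples
#' cross_entropy(c(1, 0), c(0.5, 0.5))   # 1 bit
#' cross_entropy(c(0.5, 0.5), c(1, 0))   # Inf
#' @export
cross_entropy <- function(p, q, base = 2, epsilon = NULL, tolerance = 1e-8) {
  check_base(base)
  check_epsilon(epsilon)
  p <- validate_prob_vector(p, tolerance = tolerance)
  q <- validate_prob_vector(q, tolerance = tolerance)
  if (length(p) != length(q)) {
    abort(sprintf("Length mismatch: p has %d entries, q has %d.",
                  length(p), length(q)))
  }
  if (!is.null(epsilon)) {
    q <- pmax(q, epsilon)
    q <- q / sum(q)
  }
  pos <- p > 0
  if (any(q[pos] == 0)) return(Inf)
  -sum(p[pos] * log(q[pos], base = base))
}

#' Kullback-Leibler divergence of q from p
#'
#' KL(p || q) = sum_i p_i log(p_i / q_i) = cross_entropy(p, q) -
#' shannon_entropy(p). Non-negative (Gibbs' inequality), zero iff p = q,
#' `+Inf` when q has zero mass where p does not. Used here to interpret the
#' "as printed" reading of the action-phase metric, whose per-sample value
#' equals -KL(p0 || pm).
#'
#' @inheritParams cross_entropy
#' @return Divergence in units of `log(base)`, >= 0, possibly `Inf`.
#' @examples
#' kl_divergence(c(1, 0), c(0.5, 0.5)) # 1 bit
#' kl_divergence(c(0.3, 0.7), c(0.3, 0.7)) # 0
#' @export
kl_divergence <- function(p, q, base = 2, epsilon = NULL, tolerance = 1e-8) {
  check_base(base)
  check_epsilon(epsilon)
  p <- validate_prob_vector(p, tolerance = tolerance)
  q <- validate_prob_vector(q, tolerance = tolerance)
  if (length(p) != length(q)) {
    abort(sprintf("Length mismatch: p has %d entries, q has %d.",
                  length(p), length(q)))
  }
  if (!is.null(epsilon)) {
    q <- pmax(q, epsilon)
    q <- q / sum(q)
  }
  pos <- p > 0
  if (any(q[pos] == 0)) return(Inf)
  sum(p[pos] * log(p[pos] / q[pos], base = base))
}

check_base <- function(base) {
  if (!is.numeric(base) || length(base) != 1L || base <= 1) {
    abort("`base` must be a single number > 1.")
  }
}

check_epsilon <- function(epsilon) {
  if (is.null(epsilon)) return(invisible(NULL))
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon <= 0 || epsilon > 1e-3) {
    abort("`epsilon` must be in (0, 1e-3].")
  }
}

# row-wise entropy of a probability matrix
row_entropy <- function(mat, base = 2) {
  apply(mat, 1L, shannon_entropy, base = base, tolerance = 1e-6)
}
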