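#' Policy-marginalized future-state distribution
#'
#' Given the transition model p*(s'|s, a) and a policy pi(a|s), the
#' distribution over next states from current state s is the policy-weighted
#' mixture of transition rows:
#' p(s'|s) = sum_a p*(s'|s, a) * pi(a|s).
#' This is the one-step POMDP marginalization: the uncertainty a clinician
#' faces about where the patient will be after acting according to the
#' policy.
#'
#' @param transitions A [transition_model()].
#' @param pol A [policy()] sharing the same state and action spaces.
#' @param current_state A state label.
#' @return A named numeric probability vector over next states.
#' @examples
#' p <- array(0, dim = c(2, 2, 2))
#' p[1, 1, ] <- c(0.9, 0.1); p[1, 2, ] <- c(0.5, 0.5)
#' p[2, 1, ] <- c(1, 0);     p[2, 2, ] <- c(0, 1)
#' tm <- transition_model(c("fever", "resolved"), c("A", "B"), p)
#' pol <- policy(c("fever", "resolved"), c("A", "B"),
#'               matrix(0.5, 2, 2), "clinician")
#' future_state_distribution(tm, pol, "fever") # 0.7, 0.3
#' @export
future_state_distribution <- function(transitions, pol, current_state) {
  stopifnot(inherits(transitions, "transition_model"), inherits(pol, "policy"))
  check_shared_spaces(transitions, pol)
  if (!current_state %in% transitions$states) {
    abort(sprintf("Unknown state '%s'; known states: %s.", current_state,
                  paste(transitions$states, collapse = ", ")))
  }
  w <- pol$prob[current_state, ]                     # pi(a | s)
  rows <- transitions$prob[current_state, , , drop = FALSE] # p*(s' | s, a)
  out <- drop(apply(rows, 3L, function(col) sum(col * w)))
  setNames(as.numeric(out), transitions$states)
}

check_shared_spaces <- function(transitions, pol) {
  if (!identical(transitions$states, pol$states) ||
      !identical(transitions$actions, pol$actions)) {
    abort("Transition model and policy must share identical state and action spaces (same labels, same order).")
  }
}

#' Action-phase actionability: entropy reduction of future-state
#' distributions
#'
#' For each test sample (with a known current state) the reference policy
#' and the candidate policy each induce a future-state distribution via
#' [future_state_distribution()]. The per-sample metric compares their
#' uncertainty:
#'
#' * `mode = "self_entropy"` (default): delta = H(p0) - H(pm), the
#'   difference of the two distributions' own Shannon entropies — the
#'   reading consistent with comparing "entropies of the future state
#'   distributions with and without ML".
#' * `mode = "as_printed"`: delta = H(p0) - CE(p0, pm), where the candidate
#'   term is the cross-entropy of the candidate distribution under
#'   reference weights. Algebraically this is -KL(p0 || pm), which is <= 0
#'   for every sample with equality iff the two distributions coincide: in
#'   this reading a candidate policy can never show positive actionability.
#'   Both readings are provided so the choice is explicit, never silent.
#'
#' Per-sample deltas are averaged into `mean_delta` exactly as in the
#' diagnosis phase.
#'
#' @inheritParams future_state_distribution
#' @param reference_policy,candidate_policy [policy()] objects sharing
#'   spaces with `transitions`.
#' @param current_states Character vector of current-state labels, one per
#'   test sample, or a data frame with columns `sample_id` and
#'   `current_state`.
#' @param mode `"self_entropy"` or `"as_printed"` (see Details).
#' @param base Logarithm base (default 2, bits).
#' @param epsilon Optional cross-entropy smoothing floor, see
#'   [cross_entropy()]. Only used in `as_printed` mode.
#' @return An `actionability` object (phase `"action"`); infinite
#'   per-sample deltas (from unsupported zeros in `as_printed` mode) are
#'   flagged in its `warnings`.
#' @export
action_actionability <- function(transitions, reference_policy,
                                 candidate_policy, current_states,
                                 mode = c("self_entropy", "as_printed"),
                                 base = 2, epsilon = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(transitions, "transition_model"),
            inherits(reference_policy, "policy"),
            inherits(candidate_policy, "policy"))
  check_shared_spaces(transitions, reference_policy)
  check_shared_spaces(transitions, candidate_policy)

  if (is.data.frame(current_states)) {
    if (!all(c("sample_id", "current_state") %in% names(current_states))) {
      abort("current_states data frame needs 'sample_id' and 'current_state' columns.")
    }
    ids <- as.character(current_states$sample_id)
    st <- as.character(current_states$current_state)
  } else {
    st <- as.character(current_states)
    ids <- names(st) %||% as.character(seq_along(st))
  }
  unknown <- setdiff(unique(st), transitions$states)
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown current state(s): %s.",
                  paste(unknown, collapse = ", ")))
  }

  # future distributions depend only on the state: compute once per state
  per_state <- purrr::map(setNames(transitions$states, transitions$states),
    function(s) {
      p0 <- future_state_distribution(transitions, reference_policy, s)
      pm <- future_state_distribution(transitions, candidate_policy, s)
      h0 <- shannon_entropy(p0, base = base, tolerance = 1e-6)
      term <- switch(mode,
        self_entropy = shannon_entropy(pm, base = base, tolerance = 1e-6),
        as_printed = cross_entropy(p0, pm, base = base, epsilon = epsilon,
                                   tolerance = 1e-6)
      )
      tibble::tibble(current_state = s, h_reference = h0,
                     candidate_term = term, delta = h0 - term)
    })

  samples <- dplyr::bind_rows(per_state[st])
  samples <- dplyr::mutate(samples, sample_id = ids, .before = 1L)
  res <- new_actionability(
    phase = "action",
    mode = mode,
    reference_name = reference_policy$policy_name,
    candidate_name = candidate_policy$policy_name,
    samples = samples,
    base = base
  )
  n_inf <- sum(!is.finite(samples$delta))
  if (n_inf > 0L) {
    res$warnings <- c(res$warnings, sprintf(
      "%d of %d per-sample deltas are infinite (candidate future distribution has zero mass where the reference does not).",
      n_inf, nrow(samples)))
  }
  res
}
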