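#' Construct a transition model
#'
#' The transition model is the POMDP ingredient p*(s'|s, a): for every
#' (current state, action) pair, a probability distribution over next
#' states. Clinically it encodes the benefit:risk structure of each
#' treatment given each underlying condition, and is accepted as input
#' (elicited from clinicians or estimated from retrospective cohorts).
#'
#' @param states Ordered character vector of unique state labels.
#' @param actions Ordered character vector of unique action labels.
#' @param prob A 3-d numeric array with `dim = c(length(states),
#'   length(actions), length(states))` where `prob[s, a, ]` is the
#'   next-state distribution for current state `s` under action `a`.
#'   Dimnames are set from `states` and `actions`.
#' @param tolerance,renormalize Row validation, see [validate_prob_vector()].
#' @return A `transition_model` object.
#' @examples
#' p <- array(0, dim = c(2, 2, 2))
#' p[1, 1, ] <- c(0.9, 0.1); p[1, 2, ] <- c(0.5, 0.5)
#' p[2, 1, ] <- c(0.2, 0.8); p[2, 2, ] <- c(0.4, 0.6)
#' transition_model(c("fever", "resolved"), c("regimen_A", "regimen_B"), p)
#' @export
transition_model <- function(states, actions, prob, tolerance = 1e-8,
                             renormalize = FALSE) {
  check_labels(states, "states")
  check_labels(actions, "actions")
  if (!is.array(prob) || length(dim(prob)) != 3L ||
      !all(dim(prob) == c(length(states), length(actions), length(states)))) {
    abort("`prob` must be a |S| x |A| x |S| array of next-state probabilities.")
  }
  dimnames(prob) <- list(states, actions, states)
  for (s in states) {
    rows <- matrix(prob[s, , ], nrow = length(actions),
                   dimnames = list(actions, states))
    rows <- validate_prob_rows(rows, paste0("(", s, ", ", actions, ")"),
                               tolerance = tolerance,
                               renormalize = renormalize,
                               what = "transition row")
    prob[s, , ] <- rows
  }
  structure(list(states = states, actions = actions, prob = prob),
            class = "transition_model")
}

#' Construct a policy
#'
#' A policy pi(a|s) gives, for every current state, a probability
#' distribution over actions — the clinician's (or model's) treatment
#' strategy. A deterministic choice is a one-hot row.
#'
#' @param states,actions Ordered character vectors of unique labels.
#' @param prob A |S| x |A| numeric matrix; row `s` is the action
#'   distribution in state `s`.
#' @param policy_name Name recorded for the policy.
#' @param tolerance,renormalize Row validation, see [validate_prob_vector()].
#' @return A `policy` object.
#' @export
policy <- function(states, actions, prob, policy_name = "policy",
                   tolerance = 1e-8, renormalize = FALSE) {
  check_labels(states, "states")
  check_labels(actions, "actions")
  prob <- as.matrix(prob)
  if (!all(dim(prob) == c(length(states), length(actions)))) {
    abort("`prob` must be a |S| x |A| matrix of action probabilities.")
  }
  dimnames(prob) <- list(states, actions)
  prob <- validate_prob_rows(prob, states, tolerance = tolerance,
                             renormalize = renormalize, what = "policy row")
  structure(list(states = states, actions = actions, prob = prob,
                 policy_name = policy_name),
            class = "policy")
}

check_labels <- function(x, what) {
  if (length(x) == 0L || anyDuplicated(x) || anyNA(x) || any(x == "")) {
    abort(sprintf("`%s` must be a non-empty vector of unique labels.", what))
  }
}

#' Read and write transition models and policies as JSON
#'
#' The JSON layout is explicit about ordering: `states` and `actions` give
#' the label order, and `table` is keyed by current state, then (for a
#' transition model) by action, each leaf being the probability vector over
#' next states (transition) or actions (policy).
#'
#' @param path JSON file path.
#' @param x Object to write.
#' @name transition_io
#' @return Readers return the parsed object; writers return `x` invisibly.
#' @export
read_transition_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("states", "actions", "table")
  if (!all(need %in% names(j))) {
    abort(sprintf("'%s': transition JSON must have keys %s.", path,
                  paste(need, collapse = ", ")))
  }
  S <- as.character(j$states); A <- as.character(j$actions)
  prob <- array(NA_real_, dim = c(length(S), length(A), length(S)),
                dimnames = list(S, A, S))
  for (s in S) {
    for (a in A) {
      v <- j$table[[s]][[a]]
      if (is.null(v) || length(v) != length(S)) {
        abort(sprintf("'%s': missing or malformed row for state '%s', action '%s'.",
                      path, s, a))
      }
      prob[s, a, ] <- as.numeric(v)
    }
  }
  transition_model(S, A, prob)
}

#' @rdname transition_io
#' @export
write_transition_model <- function(x, path) {
  stopifnot(inherits(x, "transition_model"))
  tab <- lapply(setNames(x$states, x$states), function(s) {
    lapply(setNames(x$actions, x$actions), function(a) unname(x$prob[s, a, ]))
  })
  jsonlite::write_json(list(states = x$states, actions = x$actions, table = tab),
                       path, auto_unbox = FALSE, digits = I(17), pretty = TRUE)
  invisible(x)
}

#' @rdname transition_io
#' @export
read_policy <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("states", "actions", "table")
  if (!all(need %in% names(j))) {
    abort(sprintf("'%s': policy JSON must have keys %s.", path,
                  paste(need, collapse = ", ")))
  }
  S <- as.character(j$states); A <- as.character(j$actions)
  prob <- matrix(NA_real_, length(S), length(A), dimnames = list(S, A))
  for (s in S) {
    v <- j$table[[s]]
    if (is.null(v) || length(v) != length(A)) {
      abort(sprintf("'%s': missing or malformed policy row for state '%s'.",
                    path, s))
    }
    prob[s, ] <- as.numeric(v)
  }
  policy(S, A, prob, policy_name = j$policy_name %||%
           sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname transition_io
#' @export
write_policy <- function(x, path) {
  stopifnot(inherits(x, "policy"))
  tab <- lapply(setNames(x$states, x$states), function(s) unname(x$prob[s, ]))
  jsonlite::write_json(list(states = x$states, actions = x$actions,
                            policy_name = x$policy_name, table = tab),
                       path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(x)
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("# Transition model p*(s'|s,a): %d states x %d actions\n",
              length(x$states), length(x$actions)))
  print(tidy(x), ...)
  invisible(x)
}

#' @export
print.policy <- function(x, ...) {
  cat(sprintf("# Policy '%s' pi(a|s): %d states x %d actions\n",
              x$policy_name, length(x$states), length(x$actions)))
  print(x$prob, ...)
  invisible(x)
}

#' Tidy a transition model or policy into a long tibble
#'
#' @param x A `transition_model` or `policy`.
#' @param ... Unused.
#' @return A tibble in long format: one row per probability entry.
#' @method tidy transition_model
#' @export
tidy.transition_model <- function(x, ...) {
  grid <- tidyr::expand_grid(state = x$states, action = x$actions,
                             next_state = x$states)
  grid$prob <- purrr::pmap_dbl(grid, function(state, action, next_state) {
    x$prob[state, action, next_state]
  })
  grid
}

#' @rdname tidy.transition_model
#' @method tidy policy
#' @export
tidy.policy <- function(x, ...) {
  grid <- tidyr::expand_grid(state = x$states, action = x$actions)
  grid$prob <- purrr::pmap_dbl(grid, function(state, action) {
    x$prob[state, action]
  })
  grid
}
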