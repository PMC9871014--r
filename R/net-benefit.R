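#' Net benefit across probability thresholds (decision curve)
#'
#' The decision-analytic companion to the actionability screen. At a
#' threshold probability t, a sample is classified positive when its
#' predicted probability is >= t (inclusive, by convention), and
#'
#'   NB(t) = TP/n - FP/n * t / (1 - t)
#'
#' weighs true positives against false positives at the harm:benefit ratio
#' the threshold implies. The returned curve includes the two reference
#' strategies: treat-all, whose closed form is
#' prevalence - (1 - prevalence) * t / (1 - t), and treat-none, identically
#' zero. The formula comes from the standard decision-curve literature.
#'
#' @param data A data frame with one row per sample.
#' @param probs Column (tidy-eval) of predicted probabilities of the
#'   positive class, in `[0, 1]`.
#' @param outcomes Column (tidy-eval) of binary outcomes (0/1 or logical).
#' @param thresholds Increasing numeric vector of thresholds, all strictly
#'   inside (0, 1).
#' @return An `nb_curve` tibble with columns `threshold`, `model`,
#'   `treat_all`, `treat_none`, and attributes `n` and `prevalence`.
#' @examples
#' d <- tibble::tibble(prob = c(0.9, 0.8, 0.2, 0.1),
#'                     truth = c(1, 1, 0, 0))
#' net_benefit(d, prob, truth, thresholds = c(0.25, 0.5, 0.75))
#' @export
net_benefit <- function(data, probs, outcomes,
                        thresholds = seq(0.05, 0.95, by = 0.05)) {
  p <- dplyr::pull(data, {{ probs }})
  y <- dplyr::pull(data, {{ outcomes }})
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) abort("`outcomes` must be binary (0/1 or logical).")
  if (any(p < 0 | p > 1)) abort("`probs` must lie in [0, 1].")
  if (any(thresholds <= 0 | thresholds >= 1)) {
    abort("All thresholds must lie strictly inside (0, 1).")
  }
  if (is.unsorted(thresholds, strictly = TRUE)) {
    abort("`thresholds` must be strictly increasing.")
  }
  n <- length(y)
  prevalence <- mean(y)
  out <- purrr::map_dfr(thresholds, function(t) {
    pos <- p >= t
    tp <- sum(pos & y == 1)
    fp <- sum(pos & y == 0)
    tibble::tibble(
      threshold = t,
      model = tp / n - fp / n * t / (1 - t),
      treat_all = prevalence - (1 - prevalence) * t / (1 - t),
      treat_none = 0
    )
  })
  structure(out, n = n, prevalence = prevalence,
            class = c("nb_curve", class(out)))
}

#' Extract binary positive-class probabilities from a multiclass belief
#' table
#'
#' Bridges multiclass beliefs to binary net benefit by taking the
#' probability assigned to one designated positive state. If the table
#' carries true states, a binary `outcome` column (`true_state ==
#' positive_state`) is included so the result pipes directly into
#' [net_benefit()].
#'
#' @param x A `belief_tbl`.
#' @param positive_state A state label of `x`.
#' @return A tibble with `sample_id`, `prob`, and (when true states are
#'   present) `outcome`.
#' @export
binarize_beliefs <- function(x, positive_state) {
  stopifnot(inherits(x, "belief_tbl"))
  if (!positive_state %in% states(x)) {
    abort(sprintf("Unknown state '%s'; known states: %s.", positive_state,
                  paste(states(x), collapse = ", ")))
  }
  out <- tibble::tibble(sample_id = x$sample_id,
                        prob = as.numeric(x[[positive_state]]))
  if ("true_state" %in% names(x)) {
    out$outcome <- as.integer(x$true_state == positive_state)
  }
  out
}

#' Plot a decision curve
#'
#' Net benefit of the model against the treat-all and treat-none reference
#' strategies across thresholds.
#'
#' @param object An `nb_curve` from [net_benefit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nb_curve
#' @export
autoplot.nb_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("model", "treat_all", "treat_none"),
                              names_to = "strategy", values_to = "net_benefit")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold,
                                     y = .data$net_benefit,
                                     colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-0.05, max(attr(object, "prevalence"),
                                                 long$net_benefit))) +
    ggplot2::labs(x = "threshold probability", y = "net benefit",
                  title = "Decision curve",
                  subtitle = sprintf("n = %d, prevalence = %.3f",
                                     attr(object, "n"),
                                     attr(object, "prevalence")))
}

#' @rdname net_benefit
#' @param x An `nb_curve`.
#' @param ... Unused.
#' @method glance nb_curve
#' @export
glance.nb_curve <- function(x, ...) {
  tibble::tibble(n = attr(x, "n"), prevalence = attr(x, "prevalence"),
                 n_thresholds = nrow(x),
                 max_model_nb = max(x$model),
                 best_threshold = x$threshold[which.max(x$model)])
}
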