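#' Diagnosis-phase actionability: mean entropy reduction of belief tables
#'
#' For each sample the Shannon entropy of the reference belief distribution
#' (by default the clinician-alone differential diagnosis) and of the
#' candidate model's predicted distribution are computed; the per-sample
#' difference delta = H(reference) - H(candidate) is the sample's
#' uncertainty reduction, and the cohort mean of those differences is the
#' diagnosis-phase actionability. Positive values mean the candidate leaves
#' the clinician with less diagnostic uncertainty than the reference.
#'
#' The metric is deliberately ground-truth-free: a model can score highly
#' while being confidently wrong. Use [stratify_actionability()] to expose
#' that failure mode when true states are available.
#'
#' @param reference,candidate `belief_tbl` objects over the same state set
#'   and samples (aligned internally via [align_beliefs()]).
#' @param base Logarithm base for all entropies (default 2, bits).
#' @return An `actionability` object: per-sample entropies and deltas as a
#'   tibble plus the cohort `mean_delta`. Access per-sample values with
#'   [tidy()], the one-row summary with [glance()].
#' @examples
#' ref <- belief_table(tibble::tibble(
#'   sample_id = c("p1", "p2"),
#'   a = c(0.25, 0.25), b = c(0.25, 0.25),
#'   c = c(0.25, 0.25), d = c(0.25, 0.25)), model_name = "clinician")
#' cand <- belief_table(tibble::tibble(
#'   sample_id = c("p1", "p2"),
#'   a = c(1, 0.5), b = c(0, 0.5), c = c(0, 0), d = c(0, 0)),
#'   model_name = "ml")
#' diagnosis_actionability(ref, cand)
#' @export
diagnosis_actionability <- function(reference, candidate, base = 2) {
  aligned <- align_beliefs(reference, candidate)
  ref_mat <- belief_matrix(aligned$reference)
  cand_mat <- belief_matrix(aligned$candidate)
  h_ref <- row_entropy(ref_mat, base = base)
  h_cand <- row_entropy(cand_mat, base = base)
  samples <- tibble::tibble(
    sample_id = aligned$reference$sample_id,
    h_reference = unname(h_ref),
    h_candidate = unname(h_cand),
    delta = unname(h_ref - h_cand)
  )
  one_hot <- mean(apply(cand_mat, 1L, max) >= 1 - 1e-12)
  new_actionability(
    phase = "diagnosis",
    mode = NULL,
    reference_name = model_name(aligned$reference),
    candidate_name = model_name(aligned$candidate),
    samples = samples,
    base = base,
    candidate_one_hot_fraction = one_hot,
    candidate_true_states =
      if ("true_state" %in% names(aligned$candidate)) {
        aligned$candidate$true_state
      },
    candidate_top1 = states(aligned$candidate)[
      max.col(cand_mat, ties.method = "first")],
    candidate_top1_ties = sum(apply(cand_mat, 1L, function(r) {
      sum(r >= max(r) - 1e-12) > 1L
    }))
  )
}

# shared constructor for diagnosis- and action-phase results
new_actionability <- function(phase, mode, reference_name, candidate_name,
                              samples, base, ...) {
  structure(
    list(
      phase = phase,
      mode = mode,
      reference_name = reference_name,
      candidate_name = candidate_name,
      samples = samples,
      mean_delta = mean(samples$delta),
      base = base,
      n = nrow(samples),
      bootstrap_ci = NULL,
      n_boot = NULL,
      warnings = character(),
      ...
    ),
    class = "actionability"
  )
}

#' Stratify an actionability result by candidate correctness
#'
#' Entropy reduction alone cannot distinguish a sharply correct model from
#' one that is confidently wrong: a degenerate model that always outputs
#' 100% for one diagnosis maximizes the metric regardless of accuracy. This
#' report partitions the cohort by whether the candidate's top-1 state
#' equals the recorded true state (top-1 ties broken toward the lowest
#' state index and counted), so high-delta/incorrect strata are visible.
#'
#' @param result An `actionability` object from
#'   [diagnosis_actionability()] whose candidate table carried a
#'   `true_state` column.
#' @return A tibble with one row per stratum (`correct`, `incorrect`):
#'   sample count, mean delta, mean candidate entropy, and the fraction of
#'   the cohort in the stratum. The number of top-1 ties is attached as
#'   attribute `n_ties` and as a column.
#' @export
stratify_actionability <- function(result) {
  stopifnot(inherits(result, "actionability"))
  truth <- result$candidate_true_states
  if (is.null(truth)) {
    abort("Stratified report needs true states: build the candidate belief table with a 'true_state' column.")
  }
  df <- dplyr::mutate(result$samples,
                      correct = result$candidate_top1 == truth,
                      stratum = ifelse(.data$correct, "correct", "incorrect"))
  out <- df |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_delta = mean(.data$delta),
      mean_candidate_entropy = mean(.data$h_candidate),
      .groups = "drop"
    ) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n),
                  n_top1_ties = result$candidate_top1_ties)
  attr(out, "n_ties") <- result$candidate_top1_ties
  out
}

#' Percentile bootstrap interval for the cohort mean delta
#'
#' Resamples sample indices with replacement and records the 2.5 and 97.5
#' percentiles of the resampled mean delta. Seeded and reproducible; the
#' caller's RNG state is left untouched.
#'
#' @param result An `actionability` object.
#' @param n_boot Number of bootstrap resamples (default 1000). Fewer than
#'   100 triggers a warning recorded in the result's metadata.
#' @param seed Integer seed.
#' @return `result` with `bootstrap_ci` (named low/high) and `n_boot` set.
#' @export
bootstrap_mean_delta <- function(result, n_boot = 1000, seed = 1) {
  stopifnot(inherits(result, "actionability"))
  if (result$n < 2L) abort("Bootstrap needs at least 2 samples.")
  if (n_boot < 100) {
    msg <- sprintf("n_boot = %d is below 100; interval will be unstable.", n_boot)
    warn(msg)
    result$warnings <- c(result$warnings, msg)
  }
  deltas <- result$samples$delta
  means <- with_preserved_rng(seed, {
    vapply(seq_len(n_boot), function(i) {
      mean(deltas[sample.int(length(deltas), replace = TRUE)])
    }, numeric(1))
  })
  ci <- quantile(means, c(0.025, 0.975), names = FALSE, type = 7)
  result$bootstrap_ci <- c(low = ci[1], high = ci[2])
  result$n_boot <- n_boot
  result
}

# evaluate `expr` under set.seed(seed) without disturbing the caller's RNG
with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @export
print.actionability <- function(x, ...) {
  cat(sprintf("# %s-phase actionability%s\n", x$phase,
              if (!is.null(x$mode)) sprintf(" (mode: %s)", x$mode) else ""))
  cat(sprintf("  reference: %s | candidate: %s | n = %d | base = %g\n",
              x$reference_name, x$candidate_name, x$n, x$base))
  cat(sprintf("  mean delta = %.6g %s\n", x$mean_delta,
              if (isTRUE(all.equal(x$base, 2))) "bits" else
                sprintf("(log base %g units)", x$base)))
  if (!is.null(x$bootstrap_ci)) {
    cat(sprintf("  95%% bootstrap CI: [%.6g, %.6g] (%d resamples)\n",
                x$bootstrap_ci[["low"]], x$bootstrap_ci[["high"]], x$n_boot))
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Per-sample and cohort-level views of an actionability result
#'
#' `tidy()` returns the per-sample tibble (entropies and deltas); `glance()`
#' returns a one-row cohort summary.
#'
#' @param x An `actionability` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy actionability
#' @export
tidy.actionability <- function(x, ...) x$samples

#' @rdname tidy.actionability
#' @method glance actionability
#' @export
glance.actionability <- function(x, ...) {
  tibble::tibble(
    phase = x$phase,
    mode = x$mode %||% NA_character_,
    reference = x$reference_name,
    candidate = x$candidate_name,
    n = x$n,
    mean_delta = x$mean_delta,
    ci_low = if (!is.null(x$bootstrap_ci)) x$bootstrap_ci[["low"]] else NA_real_,
    ci_high = if (!is.null(x$bootstrap_ci)) x$bootstrap_ci[["high"]] else NA_real_,
    base = x$base
  )
}

#' Plot the per-sample entropy-reduction distribution
#'
#' Histogram of per-sample deltas with the cohort mean marked; the natural
#' first look at whether a candidate's uncertainty reduction is broad or
#' driven by a few samples.
#'
#' @param object An `actionability` object.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot actionability
#' @export
autoplot.actionability <- function(object, bins = 30, ...) {
  ggplot2::ggplot(object$samples, ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$mean_delta, linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("per-sample entropy reduction (base %g)", object$base),
      y = "samples",
      title = sprintf("%s-phase actionability: %s vs %s",
                      object$phase, object$candidate_name,
                      object$reference_name),
      subtitle = sprintf("mean delta = %.4g (dashed)", object$mean_delta)
    )
}
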