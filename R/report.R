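#' Assemble a machine-readable actionability report
#'
#' Bundles a diagnosis-phase result with optional action-phase, stratified
#' and net-benefit companions into a single versioned document, ordered the
#' way the evaluation pipeline runs: actionability screen first, calibration
#' and decision-curve analysis downstream. Warnings are aggregated,
#' including the degenerate-candidate flag raised when more than half of
#' the candidate's beliefs are one-hot — the regime in which entropy
#' reduction is maximal whether or not the model is right.
#'
#' @param diag An `actionability` object from [diagnosis_actionability()].
#' @param action Optional `actionability` object from
#'   [action_actionability()].
#' @param nb Optional `nb_curve` from [net_benefit()].
#' @param strata Optional stratified report from
#'   [stratify_actionability()].
#' @param degenerate_threshold Fraction of one-hot candidate beliefs above
#'   which the degenerate-candidate warning is raised (default 0.5).
#' @return An `actionability_report`: a named list serializable with
#'   [write_report()].
#' @export
full_report <- function(diag, action = NULL, nb = NULL, strata = NULL,
                        degenerate_threshold = 0.5) {
  stopifnot(inherits(diag, "actionability"), diag$phase == "diagnosis")
  warnings <- diag$warnings
  if (!is.null(diag$candidate_one_hot_fraction) &&
      diag$candidate_one_hot_fraction > degenerate_threshold) {
    warnings <- c(warnings, sprintf(
      "degenerate candidate: %.1f%% of candidate beliefs are one-hot; entropy reduction may reflect overconfidence, not accuracy.",
      100 * diag$candidate_one_hot_fraction))
  }
  doc <- list(
    schema_version = "1.0",
    diagnosis = actionability_as_list(diag),
    action = if (!is.null(action)) {
      stopifnot(inherits(action, "actionability"), action$phase == "action")
      warnings <- c(warnings, action$warnings)
      actionability_as_list(action)
    },
    strata = if (!is.null(strata)) {
      lapply(seq_len(nrow(strata)), function(i) as.list(strata[i, ]))
    },
    net_benefit = if (!is.null(nb)) {
      stopifnot(inherits(nb, "nb_curve"))
      list(
        note = "net benefit per the standard decision-curve literature; a downstream companion, not part of the actionability metric",
        n = attr(nb, "n"),
        prevalence = attr(nb, "prevalence"),
        thresholds = nb$threshold,
        model_nb = nb$model,
        treat_all_nb = nb$treat_all,
        treat_none_nb = nb$treat_none
      )
    },
    warnings = as.list(warnings)
  )
  doc <- doc[!vapply(doc, is.null, logical(1))]
  structure(doc, class = "actionability_report")
}

actionability_as_list <- function(x) {
  out <- list(
    phase = x$phase,
    reference = x$reference_name,
    candidate = x$candidate_name,
    n = x$n,
    log_base = x$base,
    mean_delta = x$mean_delta,
    per_sample = lapply(seq_len(nrow(x$samples)), function(i) {
      as.list(x$samples[i, ])
    })
  )
  if (!is.null(x$mode)) out$mode <- x$mode
  if (!is.null(x$bootstrap_ci)) {
    out$bootstrap_ci <- list(low = x$bootstrap_ci[["low"]],
                             high = x$bootstrap_ci[["high"]],
                             n_boot = x$n_boot)
  }
  if (!is.null(x$candidate_one_hot_fraction)) {
    out$candidate_one_hot_fraction <- x$candidate_one_hot_fraction
  }
  out
}

#' Write / read an actionability report as JSON
#'
#' Floats are serialized with 17 significant digits — enough to reproduce
#' every IEEE double bit-for-bit on read-back. Infinities are encoded as
#' the strings `"Inf"` / `"-Inf"`.
#'
#' @param report An `actionability_report` from [full_report()].
#' @param path Output JSON path.
#' @return `write_report()` returns `report` invisibly; `read_report()` the
#'   parsed list.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "actionability_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, na = "string")
  invisible(report)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = FALSE),
            class = "actionability_report")
}

#' Validate a report against the shipped schema
#'
#' Structural validation mirroring the JSON schema at
#' `system.file("schema", "actionability-report.schema.json", package =
#' "actionability")`: required keys present, types correct, per-sample
#' records consistent with `n`.
#'
#' @param report An `actionability_report` (or a list parsed from one).
#' @return `TRUE` invisibly; errors describe the first violation found.
#' @export
validate_report <- function(report) {
  must_have <- function(x, keys, where) {
    miss <- setdiff(keys, names(x))
    if (length(miss) > 0L) {
      abort(sprintf("Report invalid: missing %s in %s.",
                    paste(miss, collapse = ", "), where))
    }
  }
  must_have(report, c("schema_version", "diagnosis", "warnings"), "top level")
  if (!identical(as.character(report$schema_version), "1.0")) {
    abort("Report invalid: unsupported schema_version.")
  }
  check_phase <- function(x, where) {
    must_have(x, c("phase", "reference", "candidate", "n", "log_base",
                   "mean_delta", "per_sample"), where)
    if (length(x$per_sample) != x$n) {
      abort(sprintf("Report invalid: %s has %d per_sample records but n = %d.",
                    where, length(x$per_sample), x$n))
    }
  }
  check_phase(report$diagnosis, "diagnosis")
  if (!is.null(report$action)) check_phase(report$action, "action")
  if (!is.null(report$net_benefit)) {
    must_have(report$net_benefit,
              c("n", "prevalence", "thresholds", "model_nb",
                "treat_all_nb", "treat_none_nb"), "net_benefit")
  }
  invisible(TRUE)
}

#' @export
print.actionability_report <- function(x, ...) {
  cat(sprintf("# Actionability report (schema %s)\n", x$schema_version))
  cat(sprintf("  diagnosis: mean delta = %s over n = %s\n",
              format(x$diagnosis$mean_delta), format(x$diagnosis$n)))
  if (!is.null(x$action)) {
    cat(sprintf("  action (%s): mean delta = %s over n = %s\n",
                x$action$mode %||% "?", format(x$action$mean_delta),
                format(x$action$n)))
  }
  if (!is.null(x$net_benefit)) {
    cat(sprintf("  net benefit: %s thresholds, prevalence %s\n",
                length(x$net_benefit$thresholds),
                format(x$net_benefit$prevalence)))
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
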