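#' Construct a belief table
#'
#' A belief table holds one categorical probability distribution per sample
#' over a shared, ordered set of state labels — for example, a model's
#' predicted differential diagnosis for each patient in a test set, or the
#' reference distribution elicited from clinicians. It is stored as a tibble
#' with a `sample_id` column, one numeric column per state, and an optional
#' `true_state` column, carrying the state ordering and model name as
#' attributes.
#'
#' The state ordering is fixed at construction and shared by every
#' downstream computation; [align_beliefs()] reconciles two tables whose
#' columns arrived in different orders.
#'
#' @param data A data frame with a `sample_id` column, one numeric column
#'   per state, and optionally a `true_state` column whose values are state
#'   labels.
#' @param states Character vector giving the state labels in order. Defaults
#'   to every column of `data` other than `sample_id` and `true_state`, in
#'   their column order.
#' @param model_name Name recorded for the model that produced the beliefs.
#' @param tolerance,renormalize Passed to [validate_prob_vector()] for each
#'   row.
#'
#' @return A `belief_tbl`: a tibble of per-sample distributions with
#'   attributes `states` and `model_name`.
#' @examples
#' belief_table(
#'   tibble::tibble(
#'     sample_id = c("p1", "p2"),
#'     infection = c(0.7, 0.25),
#'     malignancy = c(0.1, 0.25),
#'     heart_failure = c(0.1, 0.25),
#'     drug_fever = c(0.1, 0.25)
#'   ),
#'   model_name = "clinician"
#' )
#' @export
belief_table <- function(data, states = NULL, model_name = "model",
                         tolerance = 1e-8, renormalize = FALSE) {
  data <- tibble::as_tibble(data)
  if (!"sample_id" %in% names(data)) {
    abort("Belief table must have a 'sample_id' column.")
  }
  data$sample_id <- as.character(data$sample_id)
  if (anyDuplicated(data$sample_id)) {
    dup <- unique(data$sample_id[duplicated(data$sample_id)])
    abort(sprintf("Duplicate sample_id(s): %s.", paste(dup, collapse = ", ")))
  }
  states <- states %||% setdiff(names(data), c("sample_id", "true_state"))
  if (length(states) == 0L || anyDuplicated(states)) {
    abort("State labels must be non-empty and unique.")
  }
  missing_cols <- setdiff(states, names(data))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Missing state column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  mat <- as.matrix(data[states])
  if (!is.numeric(mat)) abort("State columns must be numeric.")
  mat <- validate_prob_rows(mat, data$sample_id, tolerance = tolerance,
                            renormalize = renormalize, what = "belief row")
  keep <- c("sample_id", states, intersect("true_state", names(data)))
  out <- data[keep]
  out[states] <- as.data.frame(mat)
  if ("true_state" %in% names(out)) {
    out$true_state <- as.character(out$true_state)
    bad <- setdiff(unique(out$true_state), states)
    if (length(bad) > 0L) {
      abort(sprintf("true_state value(s) not in the state set: %s.",
                    paste(bad, collapse = ", ")))
    }
  }
  structure(out,
            states = states,
            model_name = model_name,
            class = c("belief_tbl", class(tibble::tibble())))
}

#' State labels, model name, and belief matrix of a belief table
#'
#' @param x A `belief_tbl`.
#' @return `states()` returns the ordered character vector of state labels;
#'   `model_name()` the recorded model name; `belief_matrix()` the numeric
#'   matrix of per-sample distributions (rows named by `sample_id`).
#' @export
states <- function(x) attr(x, "states")

#' @rdname states
#' @export
model_name <- function(x) attr(x, "model_name")

#' @rdname states
#' @export
belief_matrix <- function(x) {
  m <- as.matrix(as.data.frame(x)[states(x)])
  rownames(m) <- x$sample_id
  m
}

#' Read a belief table from CSV
#'
#' Expects a header `sample_id,<state label 1>,...,<state label K>` with an
#' optional trailing `true_state` column. The column order of the CSV
#' defines the state ordering.
#'
#' @param path Path to a CSV file (UTF-8, "." decimal separator).
#' @param model_name Model name to record; defaults to the file name without
#'   extension.
#' @inheritParams belief_table
#' @return A [belief_table()].
#' @export
read_beliefs <- function(path, model_name = NULL, tolerance = 1e-8,
                         renormalize = FALSE) {
  model_name <- model_name %||% sub("\\.[^.]*$", "", basename(path))
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (names(data)[1] != "sample_id") {
    abort(sprintf("'%s': first column must be 'sample_id' (found '%s').",
                  path, names(data)[1]))
  }
  belief_table(data, model_name = model_name, tolerance = tolerance,
               renormalize = renormalize)
}

#' Write a belief table to CSV
#'
#' Inverse of [read_beliefs()]: probabilities are written at full double
#' precision so a round trip reproduces them to better than 1e-12.
#'
#' @param x A `belief_tbl`.
#' @param path Output CSV path.
#' @return `x`, invisibly.
#' @export
write_beliefs <- function(x, path) {
  stopifnot(inherits(x, "belief_tbl"))
  readr::write_csv(as.data.frame(x), path, progress = FALSE)
  invisible(x)
}

#' Align a candidate belief table to a reference
#'
#' The diagnosis-phase metric averages per-sample entropy differences, so
#' the two tables must describe the same patients over the same states.
#' Alignment permutes the candidate's state columns to the reference
#' ordering and matches samples by `sample_id` (never by row position),
#' returning both tables in the reference's sample order.
#'
#' @param reference,candidate Two `belief_tbl` objects over the same state
#'   label set (order may differ) and the same sample ids.
#' @return A named list with elements `reference` and `candidate`, aligned.
#' @export
align_beliefs <- function(reference, candidate) {
  stopifnot(inherits(reference, "belief_tbl"), inherits(candidate, "belief_tbl"))
  ref_states <- states(reference)
  cand_states <- states(candidate)
  if (!setequal(ref_states, cand_states)) {
    only_ref <- setdiff(ref_states, cand_states)
    only_cand <- setdiff(cand_states, ref_states)
    abort(sprintf(
      "State label sets differ. Only in reference: {%s}; only in candidate: {%s}.",
      paste(only_ref, collapse = ", "), paste(only_cand, collapse = ", ")
    ))
  }
  if (!setequal(reference$sample_id, candidate$sample_id)) {
    miss_cand <- setdiff(reference$sample_id, candidate$sample_id)
    miss_ref <- setdiff(candidate$sample_id, reference$sample_id)
    abort(sprintf(
      "Sample ids differ. Missing from candidate: {%s}; missing from reference: {%s}.",
      paste(miss_cand, collapse = ", "), paste(miss_ref, collapse = ", ")
    ))
  }
  cand <- as.data.frame(candidate)
  cand <- cand[match(reference$sample_id, cand$sample_id),
               c("sample_id", ref_states, intersect("true_state", names(cand)))]
  candidate_aligned <- belief_table(cand, states = ref_states,
                                    model_name = model_name(candidate))
  list(reference = reference, candidate = candidate_aligned)
}

#' @export
print.belief_tbl <- function(x, ...) {
  cat(sprintf("# Belief table '%s': %d samples x %d states (%s)\n",
              model_name(x), nrow(x), length(states(x)),
              if ("true_state" %in% names(x)) "with true states"
              else "no true states"))
  NextMethod()
}
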