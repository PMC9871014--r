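test_that("diagnosis actionability reproduces hand-computed cohort deltas", {
  n <- 6
  ref <- make_beliefs(matrix(0.25, n, 4), "clin")
  onehot <- make_beliefs(matrix(rep(c(1, 0, 0, 0), each = n), n, 4), "ml")
  res <- diagnosis_actionability(ref, onehot)
  expect_identical(res$mean_delta, 2)

  half <- make_beliefs(matrix(rep(c(0.5, 0.5, 0, 0), each = n), n, 4), "ml")
  expect_identical(diagnosis_actionability(ref, half)$mean_delta, 1)

  # frozen oracle value: 2 - H(0.7, 0.1, 0.1, 0.1) = 2 - 1.356779649447040
  tilted <- make_beliefs(matrix(rep(c(0.7, 0.1, 0.1, 0.1), each = n), n, 4),
                         "ml")
  expect_equal(diagnosis_actionability(ref, tilted)$mean_delta,
               2 - 1.356779649447040, tolerance = 1e-12)
})

test_that("a table measured against itself has exactly zero actionability", {
  withr::local_seed(21)
  mat <- t(vapply(1:20, function(i) random_simplex(5), numeric(5)))
  tbl <- make_beliefs(mat, "m")
  res <- diagnosis_actionability(tbl, tbl)
  expect_identical(res$mean_delta, 0)
  expect_identical(unique(res$samples$delta), 0)
})

test_that("per-sample deltas are invariant to the candidate's column order", {
  withr::local_seed(22)
  mat_ref <- t(vapply(1:10, function(i) random_simplex(4), numeric(4)))
  mat_cand <- t(vapply(1:10, function(i) random_simplex(4), numeric(4)))
  ref <- make_beliefs(mat_ref, "ref")
  cand <- make_beliefs(mat_cand, "cand")
  perm <- c(3, 1, 4, 2)
  perm_df <- tibble::as_tibble(as.data.frame(mat_cand[, perm]))
  names(perm_df) <- paste0("d", perm)
  cand_perm <- belief_table(
    dplyr::bind_cols(tibble::tibble(sample_id = cand$sample_id), perm_df),
    model_name = "cand")
  r1 <- diagnosis_actionability(ref, cand)
  r2 <- diagnosis_actionability(ref, cand_perm)
  expect_equal(r1$samples$delta, r2$samples$delta, tolerance = 1e-12)
})

test_that("delta invariants of the result object hold", {
  withr::local_seed(23)
  ref <- make_beliefs(t(vapply(1:15, function(i) random_simplex(3),
                               numeric(3))), "ref")
  cand <- make_beliefs(t(vapply(1:15, function(i) random_simplex(3),
                                numeric(3))), "cand")
  res <- diagnosis_actionability(ref, cand)
  expect_identical(res$samples$delta,
                   res$samples$h_reference - res$samples$h_candidate)
  expect_identical(res$mean_delta, mean(res$samples$delta))
  expect_identical(nrow(tidy(res)), 15L)
  expect_identical(glance(res)$mean_delta, res$mean_delta)
})

test_that("stratified report separates correct from confidently wrong predictions", {
  # degenerate candidate: always state d1 at 100%; half the truths are d1
  n <- 8
  truths <- rep(c("d1", "d2"), each = n / 2)
  ref <- make_beliefs(matrix(0.25, n, 4), "clin", true_states = truths)
  cand <- make_beliefs(matrix(rep(c(1, 0, 0, 0), each = n), n, 4), "ml",
                       true_states = truths)
  res <- diagnosis_actionability(ref, cand)
  strata <- stratify_actionability(res)
  expect_setequal(strata$stratum, c("correct", "incorrect"))
  expect_identical(strata$n, c(4L, 4L))
  expect_identical(strata$mean_delta, c(2, 2))
  expect_identical(strata$mean_candidate_entropy, c(0, 0))
  expect_identical(attr(strata, "n_ties"), 0L)

  # perfectly correct degenerate candidate: a single "correct" stratum
  eye <- diag(4)[match(truths, paste0("d", 1:4)), ]
  perfect <- make_beliefs(eye, "ml", true_states = truths)
  s2 <- stratify_actionability(diagnosis_actionability(ref, perfect))
  expect_identical(s2$stratum, "correct")
  expect_identical(s2$n, 8L)

  # indifferent candidate over 2 states: all deltas zero, ties counted
  ref2 <- make_beliefs(matrix(0.5, 4, 2), "clin",
                       true_states = c("d1", "d1", "d2", "d2"))
  cand2 <- make_beliefs(matrix(0.5, 4, 2), "ml",
                        true_states = c("d1", "d1", "d2", "d2"))
  r2 <- diagnosis_actionability(ref2, cand2)
  s3 <- stratify_actionability(r2)
  expect_identical(sum(s3$n * s3$mean_delta), 0)
  expect_identical(attr(s3, "n_ties"), 4L)

  # no true states -> informative error
  res_nt <- diagnosis_actionability(make_beliefs(matrix(0.5, 2, 2)),
                                    make_beliefs(matrix(0.5, 2, 2)))
  expect_error(stratify_actionability(res_nt), "true_state")
})

test_that("bootstrap interval is seeded, degenerate under zero variance, and covers a symmetric zero", {
  ref <- make_beliefs(matrix(0.25, 10, 4), "clin")
  cand <- make_beliefs(matrix(rep(c(1, 0, 0, 0), each = 10), 10, 4), "ml")
  res <- diagnosis_actionability(ref, cand)
  b1 <- bootstrap_mean_delta(res, n_boot = 500, seed = 9)
  b2 <- bootstrap_mean_delta(res, n_boot = 500, seed = 9)
  expect_identical(b1$bootstrap_ci, b2$bootstrap_ci)
  # all deltas identical -> degenerate interval at the common value
  expect_identical(unname(b1$bootstrap_ci), c(2, 2))
  expect_warning(bootstrap_mean_delta(res, n_boot = 50, seed = 1), "100")

  # symmetric deltas around zero: interval contains 0 in the vast majority
  # of seeded replicates
  withr::local_seed(24)
  deltas <- rep(c(-1, 1), 100)
  fake <- res
  fake$samples <- tibble::tibble(sample_id = as.character(1:200),
                                 h_reference = 0, h_candidate = -deltas,
                                 delta = deltas)
  fake$mean_delta <- mean(deltas)
  fake$n <- 200L
  covered <- vapply(1:100, function(s) {
    ci <- bootstrap_mean_delta(fake, n_boot = 200, seed = s)$bootstrap_ci
    ci[["low"]] <= 0 && 0 <= ci[["high"]]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("bootstrap leaves the caller's RNG stream untouched", {
  ref <- make_beliefs(matrix(0.5, 5, 2), "a")
  cand <- make_beliefs(matrix(0.5, 5, 2), "b")
  res <- diagnosis_actionability(ref, cand)
  set.seed(42); before <- runif(1)
  set.seed(42); invisible(bootstrap_mean_delta(res, 200, seed = 1))
  after <- runif(1)
  expect_identical(before, after)
})
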