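worked_example <- function() {
  # 2 outcomes {resolve, persist}; action A row (0.9, 0.1), action B row
  # (0.5, 0.5); reference policy 50/50 -> future (0.7, 0.3); candidate
  # deterministic on A -> future (0.9, 0.1)
  S <- c("resolve", "persist"); A <- c("A", "B")
  tr <- array(NA_real_, c(2, 2, 2))
  tr[1, 1, ] <- c(0.9, 0.1); tr[1, 2, ] <- c(0.5, 0.5)
  tr[2, 1, ] <- c(0.9, 0.1); tr[2, 2, ] <- c(0.5, 0.5)
  list(
    transitions = transition_model(S, A, tr),
    mixed = policy(S, A, matrix(0.5, 2, 2), "clinician"),
    on_A = policy(S, A, matrix(c(1, 1, 0, 0), 2, 2), "model")
  )
}

test_that("future-state distribution reproduces the worked mixture arithmetic", {
  w <- worked_example()
  expect_equal(unname(future_state_distribution(w$transitions, w$mixed,
                                                "resolve")),
               c(0.7, 0.3), tolerance = 1e-15)
  # deterministic policy returns the chosen action's row itself
  expect_identical(unname(future_state_distribution(w$transitions, w$on_A,
                                                    "resolve")),
                   c(0.9, 0.1))
  expect_error(future_state_distribution(w$transitions, w$mixed, "fever"),
               "Unknown state")
})

test_that("a mixture of identical transition rows is that row for any policy", {
  S <- c("x", "y"); A <- c("a", "b", "c")
  tr <- array(rep(c(0.6, 0.4), each = 6), c(2, 3, 2))
  tm <- transition_model(S, A, tr)
  withr::local_seed(31)
  pol <- policy(S, A, rbind(random_simplex(3), random_simplex(3)), "any")
  expect_equal(unname(future_state_distribution(tm, pol, "x")), c(0.6, 0.4),
               tolerance = 1e-15)
})

test_that("marginalization matches the triple-loop oracle and is linear in the policy", {
  withr::local_seed(32)
  for (i in 1:100) {
    K <- sample(2:4, 1); J <- sample(2:3, 1)
    mdp <- random_mdp(K, J)
    s <- sample(K, 1)
    via_pkg <- future_state_distribution(mdp$transitions,
                                         mdp$reference_policy, mdp$states[s])
    via_oracle <- oracle_future(mdp$array, mdp$reference_policy$prob, s)
    expect_equal(unname(via_pkg), via_oracle, tolerance = 1e-12)
    expect_equal(sum(via_pkg), 1, tolerance = 1e-12)

    # linearity: mixing policies mixes futures with the same weight
    w <- runif(1)
    mixed <- policy(mdp$states, mdp$actions,
                    w * mdp$reference_policy$prob +
                      (1 - w) * mdp$candidate_policy$prob, "mix")
    f_mix <- future_state_distribution(mdp$transitions, mixed, mdp$states[s])
    f0 <- future_state_distribution(mdp$transitions, mdp$reference_policy,
                                    mdp$states[s])
    fm <- future_state_distribution(mdp$transitions, mdp$candidate_policy,
                                    mdp$states[s])
    expect_equal(unname(f_mix), unname(w * f0 + (1 - w) * fm),
                 tolerance = 1e-12)
  }
})

test_that("self-entropy action actionability matches frozen hand-summed values on the worked example", {
  w <- worked_example()
  res <- action_actionability(w$transitions, w$mixed, w$on_A,
                              current_states = c("resolve", "resolve"),
                              mode = "self_entropy")
  # frozen: H2(0.7, 0.3) = 0.881290899230693; H2(0.9, 0.1) = 0.468995593589281
  expect_equal(res$samples$h_reference, rep(0.881290899230693, 2),
               tolerance = 1e-12)
  expect_equal(res$samples$candidate_term, rep(0.468995593589281, 2),
               tolerance = 1e-12)
  expect_equal(res$mean_delta, 0.412295305641411, tolerance = 1e-12)
  expect_identical(res$mode, "self_entropy")
})

test_that("identical policies give exactly zero delta in both modes", {
  w <- worked_example()
  for (mode in c("self_entropy", "as_printed")) {
    res <- action_actionability(w$transitions, w$mixed, w$mixed,
                                current_states = c("resolve", "persist"),
                                mode = mode)
    expect_identical(res$mean_delta, 0)
  }
})

test_that("as-printed deltas equal -KL(p0 || pm) and are never positive", {
  withr::local_seed(33)
  for (i in 1:150) {
    K <- sample(2:4, 1); J <- sample(2:3, 1)
    mdp <- random_mdp(K, J)
    st <- sample(mdp$states, 5, replace = TRUE)
    res <- action_actionability(mdp$transitions, mdp$reference_policy,
                                mdp$candidate_policy, st,
                                mode = "as_printed")
    for (j in seq_along(st)) {
      p0 <- future_state_distribution(mdp$transitions, mdp$reference_policy,
                                      st[j])
      pm <- future_state_distribution(mdp$transitions, mdp$candidate_policy,
                                      st[j])
      expect_lt(abs(res$samples$delta[j] + unname(oracle_kl(p0, pm))),
                1e-12)
    }
    expect_true(all(res$samples$delta <= 1e-12))
  }
})

test_that("self-entropy delta is antisymmetric under swapping the policies", {
  withr::local_seed(34)
  mdp <- random_mdp(3, 2)
  st <- c("s1", "s2", "s3")
  fwd <- action_actionability(mdp$transitions, mdp$reference_policy,
                              mdp$candidate_policy, st)
  rev <- action_actionability(mdp$transitions, mdp$candidate_policy,
                              mdp$reference_policy, st)
  expect_equal(fwd$samples$delta, -rev$samples$delta, tolerance = 1e-12)
})

test_that("infinite cross-entropies are flagged, and current states accept a sample table", {
  # candidate future puts zero mass where the reference does not
  S <- c("x", "y"); A <- c("a", "b")
  tr <- array(NA_real_, c(2, 2, 2))
  tr[1, 1, ] <- c(1, 0); tr[1, 2, ] <- c(0.5, 0.5)
  tr[2, 1, ] <- c(1, 0); tr[2, 2, ] <- c(0.5, 0.5)
  tm <- transition_model(S, A, tr)
  p0 <- policy(S, A, matrix(0.5, 2, 2), "ref")
  pm <- policy(S, A, matrix(c(1, 1, 0, 0), 2, 2), "onehot")
  res <- action_actionability(tm, p0, pm,
                              tibble::tibble(sample_id = "p1",
                                             current_state = "x"),
                              mode = "as_printed")
  expect_identical(res$samples$delta, -Inf)
  expect_match(res$warnings, "infinite", all = FALSE)
  expect_identical(res$samples$sample_id, "p1")

  expect_error(action_actionability(tm, p0, pm, "zz"), "Unknown")
})
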