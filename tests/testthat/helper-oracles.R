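# Independent oracles: deliberately naive loop implementations that share
# no code with the package, used to cross-check the library path.

oracle_entropy <- function(p, base = 2) {
  total <- 0
  for (x in p) if (x > 0) total <- total - x * log(x) / log(base)
  total
}

oracle_cross_entropy <- function(p, q, base = 2) {
  total <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) {
      if (q[i] == 0) return(Inf)
      total <- total - p[i] * log(q[i]) / log(base)
    }
  }
  total
}

oracle_kl <- function(p, q, base = 2) {
  total <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) {
      if (q[i] == 0) return(Inf)
      total <- total + p[i] * log(p[i] / q[i]) / log(base)
    }
  }
  total
}

# triple-loop policy marginalization: p(s'|s) = sum_a p*(s'|s,a) pi(a|s)
oracle_future <- function(trans_array, policy_matrix, s_idx) {
  K <- dim(trans_array)[1]
  J <- dim(trans_array)[2]
  out <- numeric(K)
  for (sp in seq_len(K)) {
    for (a in seq_len(J)) {
      out[sp] <- out[sp] + trans_array[s_idx, a, sp] * policy_matrix[s_idx, a]
    }
  }
  out
}

# random point on the K-simplex (exponential spacings construction)
random_simplex <- function(k) {
  x <- -log(runif(k))
  x / sum(x)
}

# quick belief table from a row matrix
make_beliefs <- function(mat, model_name = "m", true_states = NULL,
                         state_labels = paste0("d", seq_len(ncol(mat)))) {
  df <- tibble::as_tibble(as.data.frame(mat))
  names(df) <- state_labels
  df <- dplyr::bind_cols(
    tibble::tibble(sample_id = paste0("p", seq_len(nrow(mat)))), df)
  if (!is.null(true_states)) df$true_state <- true_states
  belief_table(df, states = state_labels, model_name = model_name)
}

# random small transition model + policies for property tests
random_mdp <- function(K, J) {
  S <- paste0("s", seq_len(K)); A <- paste0("a", seq_len(J))
  tr <- array(NA_real_, c(K, J, K))
  for (s in seq_len(K)) for (a in seq_len(J)) tr[s, a, ] <- random_simplex(K)
  list(
    transitions = transition_model(S, A, tr),
    reference_policy = policy(S, A,
      t(vapply(seq_len(K), function(i) random_simplex(J), numeric(J))),
      "p0"),
    candidate_policy = policy(S, A,
      t(vapply(seq_len(K), function(i) random_simplex(J), numeric(J))),
      "pm"),
    states = S, actions = A, array = tr
  )
}
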