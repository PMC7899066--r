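# independent oracles and small model builders used across the suite

# minimal single-factor, single-epoch model with plain probability arrays
# (no Dirichlet semantics), for comparison against analytic posteriors
toy_model <- function(prior, lik) {
  ns <- length(prior)
  no <- nrow(lik)
  stopifnot(ncol(lik) == ns)
  structure(list(
    factors = list(factor_spec("state", paste0("s", seq_len(ns)))),
    modalities = list(modality_spec("obs", paste0("o", seq_len(no)))),
    a = list(array(lik, dim = c(no, ns))),
    b = list(array(diag(ns), dim = c(ns, ns, 1))),
    C = list(matrix(0, no, 1)),
    D = list(prior),
    policies = matrix(integer(0), nrow = 1, ncol = 0),
    n_epochs = 1L,
    alpha = 16, beta_prior = 1,
    learn = list(a = FALSE, b = FALSE, d = FALSE),
    dirichlet = list(a = FALSE, b = FALSE),
    spurious = FALSE
  ), class = "wr_model")
}

# single-factor T-epoch hidden Markov chain with one observation per epoch
chain_model <- function(prior, B, lik, T) {
  ns <- length(prior)
  structure(list(
    factors = list(factor_spec("state", paste0("s", seq_len(ns)))),
    modalities = list(modality_spec("obs", paste0("o", seq_len(nrow(lik))))),
    a = list(array(lik, dim = c(nrow(lik), ns))),
    b = list(array(B, dim = c(ns, ns, 1))),
    C = list(matrix(0, nrow(lik), T)),
    D = list(prior),
    policies = matrix(1L, nrow = 1, ncol = T - 1),
    n_epochs = as.integer(T),
    alpha = 16, beta_prior = 1,
    learn = list(a = FALSE, b = FALSE, d = FALSE),
    dirichlet = list(a = FALSE, b = FALSE),
    spurious = FALSE
  ), class = "wr_model")
}

# exact posterior over a chain by brute-force enumeration of all state
# trajectories (independent of the package's forward-backward code)
enumerate_chain_posterior <- function(prior, B, lik, obs) {
  T <- length(obs)
  ns <- length(prior)
  grids <- rep(list(seq_len(ns)), T)
  paths <- as.matrix(expand.grid(grids))
  w <- apply(paths, 1, function(s) {
    p <- prior[s[1]] * lik[obs[1], s[1]]
    if (T > 1) for (t in 2:T) p <- p * B[s[t], s[t - 1]] * lik[obs[t], s[t]]
    p
  })
  w <- w / sum(w)
  marg <- sapply(seq_len(T), function(t)
    vapply(seq_len(ns), function(i) sum(w[paths[, t] == i]), 0))
  list(marginals = marg, evidence = NA)
}

# brute-force expected free energy for the word repetition model: explicit
# loops over joint states and outcomes, written independently of the
# package's vectorized implementation (novelty omitted; use on models with
# learning disabled)
efe_oracle <- function(model, qs, horizon) {
  dims <- vapply(model$factors, function(f) length(f$levels), 1L)
  no <- vapply(model$modalities, function(m) length(m$levels), 1L)
  Abar <- lapply(model$a, function(a) {
    m <- matrix(a, nrow = dim(a)[1])
    sweep(m, 2, colSums(m), "/")
  })
  G <- 0
  for (tau in horizon) {
    # joint state probabilities
    w <- numeric(prod(dims))
    k <- 1
    for (r in seq_len(dims[3])) for (t in seq_len(dims[2]))
      for (e in seq_len(dims[1])) {
        w[k] <- qs[[1]][e, tau] * qs[[2]][t, tau] * qs[[3]][r, tau]
        k <- k + 1
      }
    for (m in seq_along(Abar)) {
      o_pred <- numeric(no[m])
      for (o in seq_len(no[m])) o_pred[o] <- sum(Abar[[m]][o, ] * w)
      pref <- exp(model$C[[m]][, tau]) / sum(exp(model$C[[m]][, tau]))
      for (o in seq_len(no[m])) {
        if (o_pred[o] > 0)
          G <- G + o_pred[o] * (log(o_pred[o]) - log(max(pref[o], exp(-16))))
      }
      # ambiguity
      for (s in seq_along(w)) {
        H_s <- -sum(ifelse(Abar[[m]][, s] > 0,
                           Abar[[m]][, s] * log(Abar[[m]][, s]), 0))
        G <- G + w[s] * H_s
      }
    }
  }
  G
}

# deterministic env oracle: expected outcome indices from the paradigm rules
env_oracle <- function(e, t, r) {
  sound <- c(1, 1, 3, 4, 2)  # red, read, triangle, square, blue
  prop <- if (e == 2) 2L else 1L
  aud <- if (e == 1) t else sound[r]
  ev <- if (e < 3) 1L else if (sound[r] == t) 2L else 3L
  c(prop, aud, ev)
}
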