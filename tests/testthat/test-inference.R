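# belief updating, expected free energy, policy posterior, precision,
# action selection, and the trial loop

test_that("converged inference matches the exact Bayes posterior", {
  # spelled-out case: prior (.5,.5), likelihood column (.9,.2)
  toy <- toy_model(c(0.5, 0.5), rbind(c(0.9, 0.2), c(0.1, 0.8)))
  r <- infer_states(toy, matrix(1L, 1, 1), 1)
  expect_equal(r$qs[[1]][, 1], c(0.45, 0.1) / 0.55, tolerance = 1e-9)
  expect_equal(r$F, -log(0.55), tolerance = 1e-9)

  # property over random instances
  set.seed(77)
  for (i in 1:200) {
    ns <- sample(2:6, 1); no <- sample(2:5, 1)
    prior <- as.vector(rmultinom(1, 100, rep(1, ns))) + 1
    prior <- prior / sum(prior)
    lik <- matrix(runif(no * ns, 0.05, 1), no, ns)
    lik <- sweep(lik, 2, colSums(lik), "/")
    o <- sample(no, 1)
    r <- infer_states(toy_model(prior, lik), matrix(o, 1, 1), 1)
    exact <- prior * lik[o, ] / sum(prior * lik[o, ])
    expect_equal(r$qs[[1]][, 1], exact, tolerance = 1e-6)
  }
})

test_that("chain smoothing matches brute-force enumeration", {
  set.seed(31)
  for (i in 1:20) {
    ns <- 3
    prior <- c(0.5, 0.3, 0.2)
    B <- matrix(runif(9, 0.05, 1), 3, 3)
    B <- sweep(B, 2, colSums(B), "/")
    lik <- matrix(runif(9, 0.05, 1), 3, 3)
    lik <- sweep(lik, 2, colSums(lik), "/")
    obs <- sample(3, 3, replace = TRUE)
    m <- chain_model(prior, B, lik, 3)
    r <- infer_states(m, matrix(obs, 1), 1)
    exact <- enumerate_chain_posterior(prior, B, lik, obs)
    expect_equal(unname(r$qs[[1]]), unname(exact$marginals), tolerance = 1e-9)
  }
})

test_that("deterministic likelihood with a matching prior is a fixed point", {
  toy <- toy_model(c(1, 0), rbind(c(1, 0), c(0, 1)))
  r <- infer_states(toy, matrix(1L, 1, 1), 1)
  expect_equal(r$qs[[1]][, 1], c(1, 0), tolerance = 1e-6)
  fe <- free_energy_components(r$qs[[1]][, 1], c(1, 0) * (1 - 1e-16) + 5e-17,
                               loglik = 0)
  expect_lt(fe["complexity"], 1e-8)
})

test_that("hearing the target concentrates beliefs at all time points", {
  m <- word_repetition_model(TRUE)
  r <- infer_states(m, matrix(c(1L, 1L, 1L), 3, 1), 1)  # hear "red"
  for (tau in 1:3) {
    expect_equal(which.max(r$qs[[2]][, tau]), 1L)  # "red" everywhere
  }
  # the prospective belief keeps most of its mass into the future
  expect_gt(r$qs[[2]][1, 3], 0.4)
})

test_that("free energy is non-increasing over variational sweeps", {
  set.seed(5)
  m <- learned_cohort$models[[1]]
  for (i in 1:5) {
    rec <- run_trial(m)
    for (t in 1:3) for (fi in rec$F_sweeps[[t]]) {
      if (!is.null(fi) && length(fi) > 1) expect_true(all(diff(fi) <= 1e-6))
    }
  }
})

test_that("policy posterior is a softmax of -F - gamma G", {
  expect_equal(policy_posterior(rep(1, 5), rep(2, 5), 1), rep(0.2, 5))
  p <- policy_posterior(c(0, 1), c(0, 0), 1)
  expect_equal(p, c(exp(0), exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(p[1], 0.7310586, tolerance = 1e-6)
  # shift invariance
  expect_equal(policy_posterior(c(3, 4, 2) + 7, c(1, 0, 5), 0.5),
               policy_posterior(c(3, 4, 2), c(1, 0, 5) + 2, 0.5),
               tolerance = 1e-12)
})

test_that("precision updates move beta against the G-weighted evidence", {
  G <- c(1, 3)
  # pi equal to the G-only posterior leaves beta at its prior
  piG <- softmax(-G)
  out <- update_precision(1, G, piG)
  expect_equal(out$beta, 1, tolerance = 1e-9)
  expect_equal(out$gamma, 1, tolerance = 1e-9)
  # pi more concentrated on the low-G policy than piG: beta falls, gamma rises
  out2 <- update_precision(1, G, c(0.95, 0.05))
  expect_lt(out2$beta, 1)
  expect_gt(out2$gamma, 1)
  # equal G: the update vanishes whatever pi is
  out3 <- update_precision(2, c(1, 1, 1), c(0.7, 0.2, 0.1))
  expect_equal(out3$beta, 2, tolerance = 1e-9)
})

test_that("action sampling follows the alpha-powered policy marginal", {
  pols <- matrix(1:5, 5, 2)
  set.seed(99)
  draws <- replicate(10000, select_action(rep(0.2, 5), pols, 1, 16))
  freq <- tabulate(draws, 5) / 10000
  expect_true(all(abs(freq - 0.2) < 0.02))
  # marginals (0.7, 0.3) at alpha 16: action 1 essentially always
  pols2 <- matrix(1:2, 2, 1)
  draws2 <- replicate(500, select_action(c(0.7, 0.3), pols2, 1, 16))
  expect_true(all(draws2 == 1L))
  expect_equal(0.7^16 / (0.7^16 + 0.3^16), 0.9999987, tolerance = 1e-6)
  expect_error(select_action(c(0, 0), pols2, 1, 16), "positive marginal")
})

test_that("expected free energy agrees with the brute-force oracle", {
  m <- word_repetition_model(TRUE)
  m$learn$a <- FALSE  # novelty off so the oracle applies
  outc <- matrix(c(1L, 3L, 1L), 3, 1)  # hear "triangle"
  G <- numeric(5)
  for (p in 1:5) {
    r <- infer_states(m, outc, p)
    G[p] <- expected_free_energy(m, r$qs, 2:3, p)
    expect_equal(G[p], efe_oracle(m, r$qs, 2:3), tolerance = 1e-8)
  }
  # the policy that repeats "triangle" has strictly the lowest G
  expect_equal(which.min(G), 3L)
  expect_true(all(G[-3] > G[3]))
  # empty horizon
  r <- infer_states(m, outc, 1)
  expect_identical(expected_free_energy(m, r$qs, integer(0), 1), 0)
})

test_that("trial records are well-formed and simplex-valued", {
  set.seed(21)
  rec <- run_trial(word_repetition_model(TRUE))
  expect_s3_class(rec, "wr_trial")
  for (t in 1:3) {
    expect_equal(sum(rec$policy[[t]]$pi), 1, tolerance = 1e-9)
    expect_true(all(rec$policy[[t]]$pi >= 0))
    expect_gt(rec$policy[[t]]$gamma, 0)
    for (f in 1:3) {
      expect_true(all(abs(colSums(rec$bma[[t]][[f]]) - 1) < 1e-9))
      expect_true(all(rec$bma[[t]][[f]] >= -1e-12))
    }
  }
  expect_equal(dim(rec$components), c(3, 3, 6))
  expect_false(anyNA(rec$components))
})

test_that("post-learning control repeats the target and is rewarded", {
  m <- learned_cohort$models[[1]]
  m$learn <- list(a = FALSE, b = FALSE, d = FALSE)
  set.seed(8)
  correct <- replicate(20, run_trial(m)$correct)
  expect_gt(mean(correct), 0.7)
})

test_that("forced negative evaluation is recorded regardless of performance", {
  m <- learned_cohort$models[[1]]
  set.seed(3)
  rec <- run_trial(m, trial_config(forced_target = "red",
                                   forced_evaluation = "negative"))
  expect_equal(rec$outcomes[3, 3], 3L)
  expect_true(rec$forced)
  expect_false(rec$correct)
})
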