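# Dirichlet learning, structure learning (spurious-level removal), lesions

# a minimal fake record with known sharp beliefs, for exact increment checks
fake_record <- function(model, states, outcomes, actions) {
  T <- model$n_epochs
  q <- lapply(seq_along(model$factors), function(f) {
    nf <- length(model$factors[[f]]$levels)
    qm <- matrix(0, nf, T)
    for (t in 1:T) qm[states[f, t], t] <- 1
    qm
  })
  structure(list(outcomes = outcomes, states = states, actions = actions,
                 bma = rep(list(q), T), correct = TRUE, forced = FALSE),
            class = "wr_trial")
}

test_that("delta posteriors increment exactly one tied parameter per epoch", {
  m <- word_repetition_model(TRUE)
  states <- rbind(1:3, rep(3, 3), c(1, 3, 3))  # epoch; target tri; say tri
  outcomes <- sapply(1:3, function(t)
    emit_outcome(structure(list(epoch = t, target = 3L,
                                repeated = states[3, t]),
                           class = "true_state")))
  rec <- fake_record(m, states, outcomes, c(3L, 3L))
  m2 <- accumulate_dirichlet(m, rec)
  for (mm in seq_along(m2$a)) {
    d <- m2$a[[mm]] - m$a[[mm]]
    expect_true(all(d >= 0))
    # one unit of evidence per epoch, replicated over each tied column
    inc_per_epoch <- sum(d) / 3
    tg <- m$tie_groups[[mm]]
    expect_equal(sum(d) %% 1, 0, tolerance = 1e-9)
    expect_gte(inc_per_epoch, 1)
  }
  # the audition epoch-2 increment lands on the spoken word's sound, pooled
  # over all four targets (tied columns move together)
  d_aud <- m2$a$audition - m$a$audition
  for (t in 1:4) expect_equal(d_aud[3, 2, t, 3], 1)
  expect_equal(sum(d_aud[, 2, , ] != 0), 4)
})

test_that("fractional posteriors yield outer-product increments", {
  m <- word_repetition_model(TRUE)
  m$learn$b <- TRUE
  states <- rbind(1:3, rep(1, 3), c(1, 2, 2))
  outcomes <- matrix(c(1, 1, 1, 2, 1, 1, 1, 1, 2), 3)
  rec <- fake_record(m, states, outcomes, c(2L, 2L))
  # soften the repeated-word beliefs at time 2
  for (t in 1:3) rec$bma[[t]][[3]][, 2] <- c(0.6, 0.4, 0, 0, 0)
  rec$bma <- rep(list(rec$bma[[3]]), 3)
  m2 <- accumulate_dirichlet(m, rec)
  d_b <- m2$b$repeated[, , 2] - m$b$repeated[, , 2]
  # transition 1 under action 2: q(tau2) %o% q(tau1) = (0.6,0.4,..) x e_1
  expect_equal(d_b[1, 1], 0.6 + 0)   # plus transition 2 contribution
  expect_equal(sum(d_b), 2, tolerance = 1e-9)
})

test_that("learning is additive and order-independent", {
  m <- word_repetition_model(TRUE)
  set.seed(12)
  r1 <- run_trial(m)
  r2 <- run_trial(m)
  a12 <- accumulate_dirichlet(accumulate_dirichlet(m, r1), r2)
  a21 <- accumulate_dirichlet(accumulate_dirichlet(m, r2), r1)
  expect_equal(a12$a, a21$a, tolerance = 1e-9)
  # counts never decrease
  for (mm in seq_along(m$a)) expect_true(all(a12$a[[mm]] >= m$a[[mm]]))
})

test_that("repeated pairings strictly increase the learned probability", {
  m <- word_repetition_model(TRUE)
  states <- rbind(1:3, rep(2, 3), c(1, 5, 5))  # target blue, say blue
  outcomes <- sapply(1:3, function(t)
    emit_outcome(structure(list(epoch = t, target = 2L,
                                repeated = states[3, t]),
                           class = "true_state")))
  rec <- fake_record(m, states, outcomes, c(5L, 5L))
  p_prev <- -Inf
  for (n in 1:4) {
    m <- accumulate_dirichlet(m, rec)
    p <- normalize_counts(m$a$audition)[2, 2, 2, 5]  # hear blue | say blue
    expect_gt(p, p_prev)
    p_prev <- p
  }
})

test_that("parameter-update complexity is positive and diminishes", {
  m0 <- word_repetition_model(TRUE)
  expect_equal(dirichlet_update_complexity(m0, m0), 0)
  set.seed(13)
  rec <- run_trial(m0)
  m1 <- accumulate_dirichlet(m0, rec)
  kl_early <- dirichlet_update_complexity(m1, m0)
  expect_gt(kl_early, 0)
  # the same increment on a mature model costs far less
  mature <- learned_cohort$models[[1]]
  mat2 <- accumulate_dirichlet(mature, rec)
  expect_lt(dirichlet_update_complexity(mat2, mature), kl_early)
})

test_that("structure learning flattens exactly the read mappings", {
  m <- learned_cohort$models[[1]]
  n <- make_nonspurious(m)
  read <- 2L
  # audition given "read" at epochs 2-3: concentration 10, uniform
  expect_true(all(n$a$audition[, 2:3, , read] == 10))
  A <- normalize_counts(n$a$audition)
  for (e in 2:3) for (t in 1:4) {
    expect_equal(A[, e, t, read], rep(0.25, 4), tolerance = 1e-12)
  }
  # evaluation epoch-3 columns conditioned on "read": flattened
  expect_true(all(n$a$evaluation[, 3, , read] == 10))
  # modalities with no repeated-word dependence are untouched
  expect_identical(n$a$proprioception, m$a$proprioception)
  expect_identical(n$a$audition[, 1, , ], m$a$audition[, 1, , ])
  # all other entries untouched
  expect_identical(n$a$audition[, 2:3, , -read], m$a$audition[, 2:3, , -read])
  # idempotent
  expect_identical(make_nonspurious(n), n)
  expect_false(n$spurious)
})

test_that("lesion applies the stated power transform to columns", {
  m <- toy_model(c(0.5, 0.5), rbind(c(0.9, 0.1), c(0.1, 0.9)))
  les <- lesion(m, lesion_spec("likelihood", "obs", 0.5))
  p <- normalize_counts(les$a[[1]])
  expect_equal(p[, 1], c(0.75, 0.25), tolerance = 1e-12)
  expect_equal(p[, 2], c(0.25, 0.75), tolerance = 1e-12)
  # column totals preserved
  expect_equal(colSums(matrix(les$a[[1]], 2)),
               colSums(matrix(m$a[[1]], 2)), tolerance = 1e-12)
  # exponent 1 is a no-op
  expect_equal(lesion(m, lesion_spec("likelihood", "obs", 1))$a, m$a,
               tolerance = 1e-12)
  expect_error(lesion_spec("likelihood", "obs", 0), "exponent")
  expect_error(lesion_spec("likelihood", "obs", 1.5), "exponent")
  expect_error(lesion(m, lesion_spec("likelihood", "nope", 0.5)), "unknown")
})

test_that("lesions flatten extremes and reduce negentropy monotonically", {
  m <- word_repetition_model(TRUE)
  col_entropy <- function(model) {
    p <- normalize_counts(model$b$target[, , 1])
    apply(p, 2, function(q) -sum(q * log(q)))
  }
  h <- col_entropy(m)
  h_prev <- h
  for (eta in c(0.8, 0.6, 0.4)) {
    les <- lesion(m, lesion_spec("transition", "target", eta))
    h_new <- col_entropy(les)
    expect_true(all(h_new > h_prev - 1e-12))
    p0 <- normalize_counts(m$b$target[, , 1])
    p1 <- normalize_counts(les$b$target[, , 1])
    expect_true(all(apply(p1, 2, max) < apply(p0, 2, max)))
    expect_true(all(apply(p1, 2, min) > apply(p0, 2, min)))
    h_prev <- h_new
  }
  # uniform columns are fixed points
  u <- word_repetition_model(FALSE)
  les_u <- lesion(u, lesion_spec("likelihood", "audition", 0.5))
  A0 <- normalize_counts(u$a$audition)
  A1 <- normalize_counts(les_u$a$audition)
  expect_equal(A1[, 2, 1, 2], A0[, 2, 1, 2], tolerance = 1e-12)  # read col
})
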