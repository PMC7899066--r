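# free-energy decompositions, aggregation, behavioral accuracy, group rows

test_that("free energy components match the hand-computed oracle", {
  # identical distributions, no data: everything from entropy
  fe <- free_energy_components(rep(0.25, 4), rep(0.25, 4), loglik = 0)
  expect_equal(unname(fe["complexity"]), 0, tolerance = 1e-12)
  expect_equal(unname(fe["entropy"]), log(4), tolerance = 1e-12)
  expect_equal(unname(fe["cost"]), log(4), tolerance = 1e-12)
  expect_equal(unname(fe["F"]), 0, tolerance = 1e-12)

  # Q=(0.8,0.2), P=(0.5,0.5), E_Q[ln p(o|s)] under columns (0.9,0.2)
  ll <- 0.8 * log(0.9) + 0.2 * log(0.2)
  fe2 <- free_energy_components(c(0.8, 0.2), c(0.5, 0.5), loglik = ll)
  expect_equal(unname(fe2["complexity"]), 0.192745, tolerance = 1e-4)
  expect_equal(unname(fe2["entropy"]), 0.500402, tolerance = 1e-4)
  expect_equal(unname(fe2["cost"]), log(2), tolerance = 1e-6)
  expect_equal(unname(fe2["accuracy"]), -0.406176, tolerance = 1e-4)
  expect_equal(unname(fe2["F"]), 0.598921, tolerance = 1e-4)
  expect_equal(unname(fe2["energy"]), 1.099323, tolerance = 1e-4)

  expect_error(free_energy_components(c(0.5, 0.6), c(0.5, 0.5)), "probability")
})

test_that("component identities hold for random inputs", {
  set.seed(14)
  for (i in 1:100) {
    n <- sample(2:8, 1)
    q <- as.vector(rmultinom(1, 200, runif(n) + 0.1)) + 0.5
    q <- q / sum(q)
    p <- as.vector(rmultinom(1, 200, runif(n) + 0.1)) + 0.5
    p <- p / sum(p)
    fe <- free_energy_components(q, p, loglik = -runif(1, 0, 3))
    expect_equal(unname(fe["F"]),
                 unname(fe["complexity"] - fe["accuracy"]), tolerance = 1e-10)
    expect_equal(unname(fe["F"]),
                 unname(fe["energy"] - fe["entropy"]), tolerance = 1e-10)
    expect_equal(unname(fe["complexity"]),
                 unname(fe["cost"] - fe["entropy"]), tolerance = 1e-10)
    expect_gte(unname(fe["complexity"]), 0)
    expect_gte(unname(fe["entropy"]), 0)
  }
})

test_that("redundancy decomposition: cost minus degeneracy", {
  rd <- redundancy_decomposition(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(unname(rd["redundancy"]), 0, tolerance = 1e-12)
  expect_equal(unname(rd["degeneracy"]), log(2), tolerance = 1e-12)
  rd2 <- redundancy_decomposition(c(1, 0), c(0.5, 0.5))
  expect_equal(unname(rd2["degeneracy"]), 0, tolerance = 1e-12)
  expect_equal(unname(rd2["cost"]), log(2), tolerance = 1e-12)
  expect_equal(unname(rd2["redundancy"]), log(2), tolerance = 1e-12)
  rd3 <- redundancy_decomposition(c(0.8, 0.2), c(0.5, 0.5))
  expect_equal(unname(rd3), c(0.6931, 0.5004, 0.1927), tolerance = 1e-3)
  expect_equal(unname(rd3["redundancy"]),
               unname(rd3["cost"] - rd3["degeneracy"]), tolerance = 1e-12)
})

test_that("redundancy is invariant to relabeling of levels", {
  set.seed(4)
  q <- softmax(rnorm(5)); p <- softmax(rnorm(5))
  base <- redundancy_decomposition(q, p)
  for (i in 1:10) {
    perm <- sample(5)
    expect_equal(redundancy_decomposition(q[perm], p[perm]), base,
                 tolerance = 1e-12)
  }
})

test_that("trial aggregation reduces components as configured", {
  comp <- array(0, dim = c(2, 3, 6),
                dimnames = list(NULL, NULL, COMPONENT_NAMES))
  comp[1, , "F"] <- c(1, 2, 3)
  comp[2, , "F"] <- c(3, 4, 5)
  expect_equal(unname(trial_measures(comp, fe_aggregation("sum", "mean"))["F"]),
               (6 + 12) / 2)
  expect_equal(unname(trial_measures(comp, fe_aggregation("mean", "sum"))["F"]),
               2 + 4)
  expect_equal(unname(trial_measures(comp, fe_aggregation("sum", "sum"))["F"]),
               18)
  # all-zero components aggregate to zero
  expect_equal(unname(trial_measures(array(0, c(3, 3, 6)))), rep(0, 6),
               ignore_attr = TRUE)
})

test_that("identities and bounds hold on aggregated trial measures", {
  set.seed(2)
  m <- learned_cohort$models[[2]]
  for (i in 1:4) {
    rec <- run_trial(m)
    tm <- trial_measures(rec)
    expect_equal(unname(tm["F"]), unname(tm["complexity"] - tm["accuracy"]),
                 tolerance = 1e-8)
    expect_equal(unname(tm["F"]), unname(tm["energy"] - tm["entropy"]),
                 tolerance = 1e-8)
    expect_equal(unname(tm["complexity"]), unname(tm["cost"] - tm["entropy"]),
                 tolerance = 1e-8)
    # per-factor degeneracy bounded by the log cardinality of the factor
    for (t in 1:3) {
      expect_lte(rec$components_current[t, 1, "entropy"], log(3) + 1e-9)
      expect_lte(rec$components_current[t, 2, "entropy"], log(4) + 1e-9)
      expect_lte(rec$components_current[t, 3, "entropy"], log(5) + 1e-9)
    }
  }
})

test_that("behavioral accuracy scores unforced positive evaluations", {
  mk <- function(correct, forced = FALSE)
    structure(list(correct = correct, forced = forced), class = "wr_trial")
  expect_equal(behavioral_accuracy(list(mk(TRUE), mk(TRUE))), 100)
  expect_equal(behavioral_accuracy(list(mk(FALSE), mk(FALSE))), 0)
  expect_equal(behavioral_accuracy(list(mk(TRUE), mk(FALSE))), 50)
  # forced trials are excluded
  expect_equal(behavioral_accuracy(list(mk(TRUE), mk(FALSE, TRUE))), 100)
  expect_error(behavioral_accuracy(list(mk(TRUE, TRUE))), "no unforced")
})

test_that("group summaries preserve the component identities", {
  set.seed(6)
  meas <- matrix(NA, 5, 6, dimnames = list(NULL, COMPONENT_NAMES))
  m <- learned_cohort$models[[1]]
  for (i in 1:5) meas[i, ] <- trial_measures(run_trial(m))
  g <- group_summary(meas, 80, "Control", TRUE, 5)
  expect_s3_class(g, "wr_group")
  expect_equal(g$F, g$redundancy - g$accuracy, tolerance = 1e-8)
  expect_equal(g$F, g$energy - g$degeneracy, tolerance = 1e-8)
  expect_equal(g$redundancy, g$cost - g$degeneracy, tolerance = 1e-8)
  # single trial: the row equals that trial's measures
  g1 <- group_summary(meas[1, , drop = FALSE], 100, "x", FALSE, 1)
  expect_equal(g1$F, unname(meas[1, "F"]))
  expect_equal(g1$degeneracy, unname(meas[1, "entropy"]))
})
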