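# Variational belief updating, expected free energy, policy posterior,
# precision and action selection: the per-trial active inference loop.

#' Inference settings
#'
#' @param iterations maximum variational sweeps per epoch (default 16).
#' @param tol early-stop tolerance on the free-energy decrease per sweep, in
#'   nats (default 1/128). Set to 0 to force all sweeps (used when iteration
#'   traces must share a common grid, e.g. for simulated evoked responses).
#' @param log_floor floor applied inside logarithms.
#' @return an `inference_settings` list.
#' @export
inference_settings <- function(iterations = 16L, tol = 1 / 128,
                               log_floor = exp(-16)) {
  stopifnot(iterations >= 1, tol >= 0, log_floor > 0)
  structure(list(iterations = as.integer(iterations), tol = tol,
                 log_floor = log_floor),
            class = "inference_settings")
}

# Precompute the log-parameter and normalized arrays used throughout a trial
# (counts are fixed within a trial). Expected-log (digamma) parameters are
# used for arrays held as Dirichlet counts; plain logs of normalized values
# otherwise.
prepare_params <- function(model) {
  dims <- state_dims(model)
  S <- prod(dims)
  no <- outcome_dims(model)
  nm <- length(model$a)
  lnA <- vector("list", nm)
  Abar <- vector("list", nm)
  for (m in seq_len(nm)) {
    am <- matrix(model$a[[m]], nrow = no[m])
    Abar[[m]] <- matrix(normalize_counts(am), nrow = no[m])
    lnA[[m]] <- if (isTRUE(model$dirichlet$a)) {
      matrix(expected_log_probability(am), nrow = no[m])
    } else {
      safe_log(Abar[[m]])
    }
  }
  # ambiguity: conditional entropy of the (normalized) likelihood per joint
  # state, summed over modalities
  H <- numeric(S)
  for (m in seq_len(nm)) H <- H - colSums(Abar[[m]] * safe_log(Abar[[m]]))
  # novelty (expected information gain about the likelihood counts),
  # active only while the likelihood is both Dirichlet and plastic; without
  # it, experience-dependent sharpening of the likelihood makes familiar
  # actions ever less ambiguous and the agent perseverates
  NV <- numeric(S)
  if (isTRUE(model$dirichlet$a) && isTRUE(model$learn$a)) {
    for (m in seq_len(nm)) {
      am <- matrix(model$a[[m]], nrow = no[m])
      W <- 0.5 * (1 / am - rep(1 / colSums(am), each = no[m]))
      NV <- NV + colSums(Abar[[m]] * W)
    }
  }
  nvB <- NULL
  if (isTRUE(model$dirichlet$b) && isTRUE(model$learn$b)) {
    nvB <- lapply(seq_along(model$b), function(f) {
      bf <- model$b[[f]]
      lapply(seq_len(dim(bf)[3]), function(u) {
        bm <- bf[, , u, drop = TRUE]
        W <- 0.5 * (1 / bm - rep(1 / colSums(bm), each = nrow(bm)))
        colSums(normalize_counts(bm) * W)
      })
    })
  }
  lnB <- vector("list", length(model$b))
  for (f in seq_along(model$b)) {
    bf <- model$b[[f]]
    nact <- dim(bf)[3]
    lnB[[f]] <- lapply(seq_len(nact), function(u) {
      if (isTRUE(model$dirichlet$b)) {
        expected_log_probability(bf[, , u, drop = TRUE])
      } else {
        safe_log(normalize_counts(bf[, , u, drop = TRUE]))
      }
    })
  }
  Bbar <- lapply(model$b, function(bf) {
    lapply(seq_len(dim(bf)[3]), function(u)
      normalize_counts(bf[, , u, drop = TRUE]))
  })
  lnD <- lapply(model$D, function(d) safe_log(d / sum(d)))
  pref <- lapply(model$C, function(cm) apply(cm, 2, softmax))
  list(dims = dims, S = S, no = no, lnA = lnA, Abar = Abar, H = H,
       NV = NV, nvB = nvB, lnB = lnB, Bbar = Bbar, lnD = lnD,
       ln_pref = lapply(pref, safe_log))
}

# exact prior marginals over the trajectory for one policy: forward
# propagation of the initial-state prior through the (mean) transition
# probabilities. (Mean-field iteration is not used here: on a
# near-deterministic chain with no data its forward/backward messages break
# the symmetry of the prior and collapse it to an arbitrary corner.)
prior_chain <- function(model, params, policy) {
  T <- model$n_epochs
  lapply(seq_along(model$factors), function(f) {
    q <- matrix(0, params$dims[f], T)
    q[, 1] <- model$D[[f]] / sum(model$D[[f]])
    ctrl <- model$factors[[f]]$controllable
    for (tau in seq_len(T - 1)) {
      u <- if (ctrl) model$policies[policy, tau] else 1L
      q[, tau + 1] <- params$Bbar[[f]][[u]] %*% q[, tau]
    }
    q
  })
}

# per-policy log-transition matrices: each deep policy is conditioned on its
# own full action sequence (policies inconsistent with actions already taken
# are pruned from the posterior instead of being re-conditioned)
policy_lnB <- function(model, params, policy_row) {
  T <- model$n_epochs
  lapply(seq_along(model$factors), function(f) {
    if (!model$factors[[f]]$controllable) {
      rep(params$lnB[[f]][1], T - 1)
    } else {
      lapply(seq_len(T - 1), function(tr) params$lnB[[f]][[policy_row[tr]]])
    }
  })
}

# summed expected-log-likelihood over modalities, evaluated at an observed
# outcome vector; flat array over the joint state space
outcome_loglik <- function(params, o) {
  L <- params$lnA[[1]][o[1], ]
  for (m in seq_along(o)[-1]) L <- L + params$lnA[[m]][o[m], ]
  L
}

#' Variational state inference for one policy
#'
#' Runs coordinate-ascent variational inference on the factorized posterior
#' over the full state trajectory (all time points, all factors) conditioned
#' on a policy, given the outcomes observed so far. Updates are exact
#' mean-field coordinate updates, so the variational free energy is
#' non-increasing across sweeps.
#'
#' @param model a `wr_model` (or compatible generic model).
#' @param outcomes integer matrix (modalities x observed epochs) of outcome
#'   indices, columns ordered by epoch starting at 1.
#' @param policy policy index (row of `model$policies`).
#' @param settings an [inference_settings()].
#' @param trace keep per-sweep snapshots of the expectations?
#' @return list with `qs` (per-factor matrices of expectations, levels x
#'   time points), `F` (final free energy, nats), `F_iter` (free energy per
#'   sweep) and optionally `trace`.
#' @export
infer_states <- function(model, outcomes, policy, settings = inference_settings(),
                         trace = FALSE) {
  params <- prepare_params(model)
  outcomes <- as.matrix(outcomes)
  n_obs <- ncol(outcomes)
  L <- lapply(seq_len(n_obs), function(t) outcome_loglik(params, outcomes[, t]))
  infer_states_prepared(model, params, L, seq_len(n_obs), policy, settings,
                        trace)
}

infer_states_prepared <- function(model, params, L, obs_tau, policy, settings,
                                  trace = FALSE) {
  lnB <- policy_lnB(model, params, model$policies[policy, ])
  cpp_infer_policy(L, as.integer(obs_tau), lnB, params$lnD,
                   as.integer(params$dims), model$n_epochs,
                   settings$iterations, settings$tol, trace)
}

#' Expected free energy of a policy
#'
#' Sums risk and ambiguity over the requested future time points. Risk is
#' the divergence of the predicted outcome distribution from the preference
#' distribution (the softmax of the log-preferences); ambiguity is the
#' expected conditional entropy of the likelihood under the predicted
#' states. While Dirichlet arrays are plastic, a novelty term (the expected
#' information gain about the concentration parameters) is subtracted, so
#' unfamiliar state-outcome pairings attract the agent; once learning is
#' disabled the term vanishes.
#'
#' @param model a `wr_model`.
#' @param qs policy-conditioned expectations, as returned by
#'   [infer_states()] (`$qs`).
#' @param horizon integer vector of future time points; empty gives 0.
#' @param policy policy index (used for the transition novelty term).
#' @return expected free energy G in nats.
#' @export
expected_free_energy <- function(model, qs, horizon, policy = 1L) {
  params <- prepare_params(model)
  efe_prepared(params, qs, horizon, model, policy)
}

efe_prepared <- function(params, qs, horizon, model = NULL, policy = 1L) {
  G <- 0
  for (tau in horizon) {
    w <- joint_weights(lapply(qs, function(q) q[, tau]))
    for (m in seq_along(params$Abar)) {
      o_pred <- as.vector(params$Abar[[m]] %*% w)
      G <- G + sum(o_pred * (safe_log(o_pred) - params$ln_pref[[m]][, tau]))
    }
    G <- G + sum(params$H * w) - sum(params$NV * w)
    if (!is.null(params$nvB) && !is.null(model)) {
      for (f in seq_along(params$nvB)) {
        u <- if (model$factors[[f]]$controllable) {
          model$policies[policy, tau - 1]
        } else 1L
        G <- G - sum(params$nvB[[f]][[u]] * qs[[f]][, tau - 1])
      }
    }
  }
  G
}

#' Posterior over policies
#'
#' @param F_per_policy variational free energy per policy (nats).
#' @param G_per_policy expected free energy per policy (nats).
#' @param gamma policy precision.
#' @return probability vector `softmax(-F - gamma * G)`.
#' @export
policy_posterior <- function(F_per_policy, G_per_policy, gamma) {
  stopifnot(all(is.finite(F_per_policy)), all(is.finite(G_per_policy)),
            gamma > 0)
  softmax(-F_per_policy - gamma * G_per_policy)
}

#' Update the policy precision
#'
#' Fixed-point update of the precision rate: `beta = beta_prior +
#' (pi - pi_G) . G`, where `pi_G = softmax(-gamma * G)` and `gamma = 1/beta`,
#' iterated to tolerance. When the policy posterior concentrates on low-G
#' policies more than `pi_G`, beta decreases and the precision gamma rises.
#'
#' @param beta_prior prior rate of gamma (> 0).
#' @param G_per_policy expected free energy per policy.
#' @param pi policy posterior.
#' @param n_iter,tol iteration controls.
#' @return list with `gamma` and `beta`.
#' @export
update_precision <- function(beta_prior, G_per_policy, pi,
                             n_iter = 16L, tol = 1e-6) {
  stopifnot(beta_prior > 0)
  beta <- beta_prior
  for (i in seq_len(n_iter)) {
    pi_G <- softmax(-(1 / beta) * G_per_policy)
    beta_new <- beta_prior + sum((pi - pi_G) * G_per_policy)
    if (beta_new <= 0) {
      warning("precision rate driven nonpositive; clipped")
      beta_new <- 1e-8
    }
    if (abs(beta_new - beta) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  list(gamma = 1 / beta, beta = beta)
}

# joint loop over policy posterior and precision
infer_policies <- function(F_per_policy, G_per_policy, beta_prior,
                           n_iter = 16L, tol = 1e-6) {
  beta <- beta_prior
  pi <- softmax(-F_per_policy - (1 / beta) * G_per_policy)
  for (i in seq_len(n_iter)) {
    prec <- update_precision(beta_prior, G_per_policy, pi, n_iter = 1L)
    pi_new <- policy_posterior(F_per_policy, G_per_policy, prec$gamma)
    done <- max(abs(pi_new - pi)) < tol && abs(prec$beta - beta) < tol
    pi <- pi_new
    beta <- prec$beta
    if (done) break
  }
  list(pi = pi, gamma = 1 / beta, beta = beta,
       F = F_per_policy, G = G_per_policy)
}

#' Sample an action from the policy posterior
#'
#' Marginalizes the policy posterior over the actions prescribed at the
#' given transition and samples with action precision `alpha`
#' (probabilities proportional to `marginal^alpha`).
#'
#' @param pi policy posterior.
#' @param policies policy matrix (policies x transitions).
#' @param transition transition index (1-based).
#' @param alpha action precision (> 0).
#' @return sampled action index.
#' @export
select_action <- function(pi, policies, transition, alpha) {
  stopifnot(alpha > 0)
  n_actions <- max(policies)
  marg <- vapply(seq_len(n_actions),
                 function(k) sum(pi[policies[, transition] == k]), 0)
  if (all(marg <= 0)) stop("no action has positive marginal probability")
  p <- softmax(alpha * safe_log(marg))
  sample.int(n_actions, 1L, prob = p)
}

#' Simulate one trial of the word repetition paradigm
#'
#' Runs the full perception-action loop for one trial: at each epoch the
#' agent observes the outcomes, infers states under every policy, evaluates
#' expected free energy, updates the policy posterior and its precision,
#' and (before the final epoch) samples an action that drives the
#' environment. Per-epoch free-energy components (accuracy, complexity,
#' entropy, energy, cost) are computed per hidden factor from the Bayesian
#' model average of the policy-conditioned expectations, against the
#' policy-averaged predictive beliefs held before the epoch's observation.
#'
#' @param model a `wr_model`.
#' @param config a [trial_config()].
#' @param settings an [inference_settings()].
#' @param trace keep per-sweep expectation snapshots (needed for simulated
#'   evoked responses)?
#' @return a `wr_trial` record: outcomes, true states, actions, per-epoch
#'   policy inference (`F`, `G`, `pi`, `gamma`), Bayesian-model-average
#'   expectations, per-epoch per-factor free-energy components, per-sweep
#'   free energies, and the `correct` flag (epoch-3 evaluation positive).
#' @export
run_trial <- function(model, config = trial_config(),
                      settings = inference_settings(), trace = FALSE) {
  params <- prepare_params(model)
  T <- model$n_epochs
  npol <- nrow(model$policies)
  nf <- length(model$factors)
  state <- init_trial(config)

  outcomes <- matrix(NA_integer_, length(model$modalities), T)
  states <- matrix(NA_integer_, nf, T)
  actions <- integer(T - 1)
  L <- list()
  allowed <- rep(TRUE, npol)  # policies consistent with actions taken so far
  comp_dn <- list(NULL, factor_names(model),
                  c("F", "accuracy", "complexity", "energy",
                    "entropy", "cost"))
  comp <- array(NA_real_, dim = c(T, nf, 6), dimnames = comp_dn)
  comp_t <- array(NA_real_, dim = c(T, nf, 6), dimnames = comp_dn)
  policy_info <- vector("list", T)
  bma_list <- vector("list", T)
  prior_list <- vector("list", T)
  F_sweeps <- vector("list", T)
  traces <- if (trace) vector("list", T) else NULL

  # prior beliefs before any observation: exact chain marginals per policy,
  # averaged under a uniform policy prior
  prior_qs <- lapply(seq_len(npol), function(p) prior_chain(model, params, p))
  prior_bma <- bma_beliefs(prior_qs, rep(1 / npol, npol), nf)

  for (t in seq_len(T)) {
    states[, t] <- c(state$epoch, state$target, state$repeated)
    o <- emit_outcome(state, config)
    outcomes[, t] <- o
    L[[t]] <- outcome_loglik(params, o)

    live <- which(allowed)
    res <- vector("list", npol)
    for (p in live) {
      res[[p]] <- infer_states_prepared(model, params, L, seq_len(t), p,
                                        settings, trace)
    }
    Fv <- rep(NA_real_, npol)
    Gv <- rep(0, npol)
    Fv[live] <- vapply(res[live], `[[`, 0, "F")
    if (t < T) {
      Gv[live] <- vapply(live, function(p)
        efe_prepared(params, res[[p]]$qs, (t + 1):T, model, p), 0)
    }
    pol <- infer_policies(Fv[live], Gv[live], model$beta_prior)
    pi_full <- numeric(npol)
    pi_full[live] <- pol$pi
    pol$pi <- pi_full
    bma <- bma_beliefs(lapply(res[live], `[[`, "qs"), pi_full[live], nf)

    ec <- epoch_components(bma, prior_bma, L[[t]], t, params)
    comp[t, , ] <- ec$sum
    comp_t[t, , ] <- ec$current
    policy_info[[t]] <- pol
    bma_list[[t]] <- bma
    prior_list[[t]] <- prior_bma
    F_sweeps[[t]] <- lapply(res, function(r) if (is.null(r)) NULL else r$F_iter)
    if (trace) traces[[t]] <- list(policy = lapply(res[live], `[[`, "trace"),
                                   pi = pi_full[live], Abar = params$Abar,
                                   dims = params$dims)

    if (t < T) {
      u <- select_action(pi_full, model$policies, t, model$alpha)
      actions[t] <- u
      allowed <- allowed & (model$policies[, t] == u)
      state <- apply_action(state, u)
    }
    # beliefs prior to the next epoch's outcomes: the policy-averaged
    # predictive held at the end of this epoch. Resolving an indecisive
    # policy mixture by observation is genuine belief updating, so it is
    # scored as complexity at the next epoch.
    prior_bma <- bma
  }

  structure(list(
    outcomes = outcomes, states = states, actions = actions,
    policy = policy_info, bma = bma_list, prior = prior_list,
    components = comp, components_current = comp_t,
    F_sweeps = F_sweeps, traces = traces,
    correct = unname(outcomes[3, T] == 2L),
    forced = !is.null(config$forced_evaluation),
    config = config
  ), class = "wr_trial")
}

# Bayesian model average of per-policy expectations
bma_beliefs <- function(qs_list, pi, nf) {
  lapply(seq_len(nf), function(f) {
    acc <- qs_list[[1]][[f]] * pi[1]
    for (p in seq_along(qs_list)[-1]) acc <- acc + qs_list[[p]][[f]] * pi[p]
    acc
  })
}

# per-factor free-energy components for one epoch: posterior Q (BMA over the
# trajectory) against the pre-observation prior P, plus the epoch's expected
# log-likelihood shared equally across factors. Returns both time-point
# reductions: summed over the three represented time points, and at the
# current time point only.
epoch_components <- function(bma, prior, L_t, t, params) {
  nf <- length(bma)
  acc_total <- cpp_contract(L_t, as.integer(params$dims),
                            lapply(bma, function(q) q[, t]), 0L)
  nms <- c("F", "accuracy", "complexity", "energy", "entropy", "cost")
  sum_out <- matrix(NA_real_, nf, 6, dimnames = list(NULL, nms))
  cur_out <- matrix(NA_real_, nf, 6, dimnames = list(NULL, nms))
  acc <- acc_total / nf
  for (f in seq_len(nf)) {
    cx <- numeric(ncol(bma[[f]]))
    en <- numeric(ncol(bma[[f]]))
    for (tau in seq_len(ncol(bma[[f]]))) {
      cx[tau] <- kl_nats(bma[[f]][, tau], prior[[f]][, tau])
      en[tau] <- entropy_nats(bma[[f]][, tau])
    }
    pack <- function(cxv, env)
      c(cxv - acc, acc, cxv, cxv - acc + env, env, cxv + env)
    sum_out[f, ] <- pack(sum(cx), sum(en))
    cur_out[f, ] <- pack(cx[t], en[t])
  }
  list(sum = sum_out, current = cur_out)
}

#' @export
print.wr_trial <- function(x, ...) {
  lv <- .wr_levels
  cat(sprintf("word repetition trial: target=%s said=%s -> %s\n",
              lv$target[x$states[2, 1]],
              paste(lv$repeated[x$actions], collapse = ","),
              lv$evaluation[x$outcomes[3, 3]]))
  m <- trial_measures(x)
  cat(sprintf("  F=%.3f redundancy=%.3f degeneracy=%.3f accuracy=%.3f\n",
              m["F"], m["complexity"], m["entropy"], m["accuracy"]))
  invisible(x)
}

#' Simulate trials from a model
#'
#' `simulate` method: runs `nsim` independent trials of the paradigm.
#'
#' @param object a `wr_model`.
#' @param nsim number of trials.
#' @param seed optional RNG seed.
#' @param ... passed to [run_trial()].
#' @return list of `wr_trial` records.
#' @export
simulate.wr_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) run_trial(object, ...))
}
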