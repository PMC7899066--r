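# Free-energy decompositions: accuracy/complexity (Occam), energy/entropy
# (Jaynes) and the cost identity
#
#   F          = complexity - accuracy = energy - entropy
#   complexity = cost - entropy
#
# with the identifications used throughout the package: redundancy is the
# complexity D_KL[Q(s) || P(s)] (the cost of belief updating / Bayesian
# surprise) and degeneracy is the posterior entropy E_Q[-ln Q(s)].

COMPONENT_NAMES <- c("F", "accuracy", "complexity", "energy", "entropy", "cost")

#' Free-energy components from posterior, prior and expected log-likelihood
#'
#' Computes the four-way decomposition from a posterior `Q`, a prior `P` and
#' the expected log-likelihood of the observed outcomes under `Q`:
#' complexity `= sum Q ln(Q/P)`, entropy `= -sum Q ln Q`, cost
#' `= -sum Q ln P`, `F = complexity - accuracy` and
#' `energy = F + entropy`. The identities above hold by construction and are
#' re-verified before returning.
#'
#' `Q` and `P` may be single probability vectors or lists of vectors (e.g.
#' marginals over several time points); list input sums the divergence and
#' entropy terms.
#'
#' @param Q posterior probability vector(s).
#' @param P prior probability vector(s), conformable with `Q`.
#' @param loglik expected log-likelihood `E_Q[ln P(o|s)]` in nats (<= 0 for
#'   categorical outcomes).
#' @return named numeric vector with elements `F`, `accuracy`, `complexity`,
#'   `energy`, `entropy`, `cost`.
#' @export
free_energy_components <- function(Q, P, loglik = 0) {
  if (!is.list(Q)) Q <- list(Q)
  if (!is.list(P)) P <- list(P)
  stopifnot(length(Q) == length(P))
  cx <- 0; en <- 0
  for (i in seq_along(Q)) {
    q <- Q[[i]]; p <- P[[i]]
    if (!is_prob_vector(q)) stop("Q is not a probability vector")
    if (!is_prob_vector(p)) stop("P is not a probability vector")
    cx <- cx + kl_nats(q, p)
    en <- en + entropy_nats(q)
  }
  out <- c(F = cx - loglik, accuracy = loglik, complexity = cx,
           energy = cx - loglik + en, entropy = en, cost = cx + en)
  stopifnot(abs(out["F"] - (out["complexity"] - out["accuracy"])) < 1e-8,
            abs(out["F"] - (out["energy"] - out["entropy"])) < 1e-8,
            abs(out["complexity"] - (out["cost"] - out["entropy"])) < 1e-8)
  out
}

#' Redundancy, degeneracy and cost of a belief update
#'
#' Redundancy is the complexity `KL(Q || P)`, degeneracy the entropy of `Q`,
#' and cost the cross entropy `-E_Q[ln P]`; redundancy = cost - degeneracy.
#'
#' @inheritParams free_energy_components
#' @return named vector with `cost`, `degeneracy`, `redundancy`.
#' @export
redundancy_decomposition <- function(Q, P) {
  fe <- free_energy_components(Q, P, loglik = 0)
  c(cost = unname(fe["cost"]), degeneracy = unname(fe["entropy"]),
    redundancy = unname(fe["complexity"]))
}

#' Aggregation convention for trial-level measures
#'
#' The per-epoch, per-factor components are reduced to one scalar per
#' component and trial. The defaults — components evaluated at the epoch's
#' current time point, summed over hidden factors and over the three epochs
#' — were calibrated once against the published control conditions of the
#' word-repetition study and then frozen; they put the trial-level measures
#' on the scale used by the group summaries.
#'
#' @param factors `"sum"` or `"mean"` over hidden factors.
#' @param epochs `"sum"` or `"mean"` over epochs.
#' @param tau `"sum"` over the three represented time points, or `"current"`
#'   (the time point of the epoch being processed).
#' @return an `fe_aggregation` list.
#' @export
fe_aggregation <- function(factors = "sum", epochs = "sum", tau = "current") {
  factors <- match.arg(factors, c("sum", "mean"))
  epochs <- match.arg(epochs, c("sum", "mean"))
  tau <- match.arg(tau, c("sum", "current"))
  structure(list(factors = factors, epochs = epochs, tau = tau),
            class = "fe_aggregation")
}

#' Trial-level free-energy measures
#'
#' Reduces a trial record's per-epoch, per-factor components to scalar
#' components under an aggregation convention. The component identities are
#' preserved by linearity.
#'
#' @param record a `wr_trial` from [run_trial()], or a bare components array
#'   (epochs x factors x components).
#' @param aggregation an [fe_aggregation()].
#' @return named numeric vector over `COMPONENT_NAMES`.
#' @export
trial_measures <- function(record, aggregation = fe_aggregation()) {
  comp <- if (is.array(record)) {
    record
  } else if (aggregation$tau == "current" &&
             !is.null(record$components_current)) {
    record$components_current
  } else {
    record$components
  }
  if (is.null(comp)) stop("record carries no per-epoch components")
  red_f <- if (aggregation$factors == "sum") colSums else colMeans
  red_e <- if (aggregation$epochs == "sum") colSums else colMeans
  # comp: epochs x factors x components -> factors x components -> components
  per_epoch <- t(apply(comp, 1, function(m) red_f(m)))
  out <- red_e(per_epoch)
  names(out) <- dimnames(comp)[[3]]
  out
}

#' Behavioral accuracy
#'
#' Percentage of unforced trials whose epoch-3 evaluation was positive.
#'
#' @param records list of `wr_trial` records.
#' @return percent correct (0-100).
#' @export
behavioral_accuracy <- function(records) {
  unforced <- Filter(function(r) !isTRUE(r$forced), records)
  if (!length(unforced)) stop("no unforced trials to score")
  100 * mean(vapply(unforced, `[[`, TRUE, "correct"))
}

#' Summarize a group of simulated subjects
#'
#' Means over trials and subjects for each free-energy component plus the
#' behavioral accuracy: the machine twin of one results-table row.
#'
#' @param measures numeric matrix (trials x components) or 3-d array
#'   (subjects x trials x components) of per-trial measures.
#' @param behavioral percent correct for the group.
#' @param label group label.
#' @param spurious logical flag for the model variant.
#' @param trials_per_agent number of trials per subject.
#' @return a one-row `wr_group` data.frame.
#' @export
group_summary <- function(measures, behavioral, label, spurious,
                          trials_per_agent) {
  m <- if (length(dim(measures)) == 3) {
    apply(measures, 3, mean)
  } else colMeans(measures)
  names(m) <- COMPONENT_NAMES
  out <- data.frame(
    group = label, spurious = ifelse(spurious, "Y", "N"),
    trials = trials_per_agent,
    F = m["F"], redundancy = m["complexity"], degeneracy = m["entropy"],
    cost = m["cost"], energy = m["energy"], accuracy = m["accuracy"],
    behavioral_accuracy = behavioral,
    row.names = NULL
  )
  class(out) <- c("wr_group", "data.frame")
  out
}
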