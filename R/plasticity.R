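# Experience-dependent Dirichlet learning, structure-learning removal of the
# spurious level, and precision-based in silico lesions.

#' Accumulate Dirichlet counts from a trial
#'
#' Hebbian-like learning: for each epoch, the likelihood count at the
#' observed outcome is incremented by `rate` times the posterior expectation
#' over its conditioning states (outer product over factors), and each
#' transition count under the taken action by `rate` times the outer product
#' of consecutive posterior expectations. The posterior used is the
#' Bayesian model average held at the end of the trial. Counts never
#' decrease.
#'
#' @param model a `wr_model` with learning enabled for the target arrays.
#' @param record a `wr_trial` from [run_trial()].
#' @param rate learning rate (default 1: raw pseudocounts).
#' @return the updated model.
#' @export
accumulate_dirichlet <- function(model, record, rate = 1) {
  T <- model$n_epochs
  q <- record$bma[[T]]  # final beliefs about the whole trajectory
  if (length(q) != length(model$factors))
    stop("record and model disagree on the number of factors")
  dims <- state_dims(model)
  no <- outcome_dims(model)
  if (isTRUE(model$learn$a)) {
    for (m in seq_along(model$a)) {
      am <- matrix(model$a[[m]], nrow = no[m])
      inc <- matrix(0, no[m], ncol(am))
      for (t in seq_len(T)) {
        w <- joint_weights(lapply(q, function(x) x[, t]))
        o <- record$outcomes[m, t]
        inc[o, ] <- inc[o, ] + rate * w
      }
      tg <- model$tie_groups[[m]]
      if (is.null(tg)) {
        am <- am + inc
      } else {
        # tied conditioning columns share one parameter: pool the evidence
        for (g in unique(tg)) {
          cols <- which(tg == g)
          am[, cols] <- am[, cols] + rowSums(inc[, cols, drop = FALSE])
        }
      }
      model$a[[m]] <- array(am, dim = c(no[m], dims))
    }
  }
  if (isTRUE(model$learn$b)) {
    for (f in seq_along(model$b)) {
      ctrl <- model$factors[[f]]$controllable
      for (t in seq_len(T - 1)) {
        u <- if (ctrl) record$actions[t] else 1L
        model$b[[f]][, , u] <- model$b[[f]][, , u] +
          rate * (q[[f]][, t + 1] %o% q[[f]][, t])
      }
    }
  }
  model
}

#' Belief-updating cost of a Dirichlet learning step
#'
#' KL divergence from the pre-update to the post-update Dirichlet beliefs,
#' summed over every conditioning column of the likelihood and transition
#' arrays. This is the complexity incurred by updating beliefs about
#' parameters (synaptic efficacies), the counterpart of the state-level
#' Bayesian surprise: it is large while counts are small and plateaus as
#' evidence accumulates.
#'
#' @param new,old models before and after [accumulate_dirichlet()] (order:
#'   updated model first).
#' @return total KL in nats.
#' @export
dirichlet_update_complexity <- function(new, old) {
  kl_dirichlet_cols <- function(a_new, a_old, groups = NULL) {
    n1 <- matrix(a_new, nrow = dim(a_new)[1])
    n0 <- matrix(a_old, nrow = dim(a_old)[1])
    # tied columns share one parameter: count each tie group once
    cols <- if (is.null(groups)) seq_len(ncol(n1)) else
      which(!duplicated(groups))
    tot <- 0
    for (j in cols) {
      ap <- n1[, j]; a <- n0[, j]
      if (all(ap == a)) next
      tot <- tot + lgamma(sum(ap)) - sum(lgamma(ap)) -
        lgamma(sum(a)) + sum(lgamma(a)) +
        sum((ap - a) * (digamma(ap) - digamma(sum(ap))))
    }
    tot
  }
  kl <- 0
  for (m in seq_along(new$a)) {
    kl <- kl + kl_dirichlet_cols(new$a[[m]], old$a[[m]],
                                 new$tie_groups[[m]])
  }
  for (f in seq_along(new$b)) {
    for (u in seq_len(dim(new$b[[f]])[3])) {
      kl <- kl + kl_dirichlet_cols(new$b[[f]][, , u, drop = TRUE],
                                   old$b[[f]][, , u, drop = TRUE])
    }
  }
  kl
}

#' Remove the spurious level by flattening its likelihood mappings
#'
#' Structure learning as performed offline (e.g. during sleep): every
#' likelihood concentration, in every modality, whose conditioning context
#' has the repeated word "read" is set to `flatten_value`, so the normalized
#' likelihood columns for "read" become uniform and the level no longer
#' makes informative predictions. All other entries are untouched;
#' the operation is idempotent.
#'
#' @param model a `wr_model` containing the "read" level.
#' @param flatten_value concentration assigned to the flattened mappings
#'   (default 10).
#' @return the modified model (with `spurious = FALSE`).
#' @export
make_nonspurious <- function(model, flatten_value = 10) {
  f_rep <- match("repeated", factor_names(model))
  read_idx <- match("read", model$factors[[f_rep]]$levels)
  if (is.na(read_idx)) stop("model has no 'read' level to flatten")
  dims <- state_dims(model)
  # repeated-word level of each flattened conditioning context
  ctx_r <- rep(seq_len(dims[f_rep]), each = prod(dims[-f_rep]))
  for (m in seq_along(model$a)) {
    am <- matrix(model$a[[m]], nrow = dim(model$a[[m]])[1])
    tg <- model$tie_groups[[m]]
    if (is.null(tg)) {
      am[, ctx_r == read_idx] <- flatten_value
    } else {
      # flatten only parameters that the dependency structure actually
      # assigns to "read" (a modality with no repeated-word dependence has
      # no "read" mapping to remove)
      for (g in unique(tg[ctx_r == read_idx])) {
        if (all(ctx_r[tg == g] == read_idx)) am[, tg == g] <- flatten_value
      }
    }
    model$a[[m]] <- array(am, dim = dim(model$a[[m]]))
  }
  model$spurious <- FALSE
  model
}

#' Specify an in silico lesion
#'
#' @param target `"likelihood"` or `"transition"`.
#' @param label modality label (for likelihood lesions) or factor label (for
#'   transition lesions).
#' @param exponent precision hyperparameter in (0, 1]; 1 is a no-op.
#' @return a `lesion_spec` list.
#' @export
lesion_spec <- function(target, label, exponent) {
  target <- match.arg(target, c("likelihood", "transition"))
  if (!is.numeric(exponent) || exponent <= 0 || exponent > 1)
    stop("lesion exponent must lie in (0, 1]")
  structure(list(target = target, label = label, exponent = exponent),
            class = "lesion_spec")
}

#' Lesion a likelihood or transition array
#'
#' Reduces the precision of the targeted array: each conditioning column's
#' normalized probabilities `p` are replaced by `normalize(p^exponent)` and
#' rescaled to preserve the column's total concentration. The largest
#' entries shrink and the smallest grow; an exponent of 1 leaves the model
#' unchanged. Likelihood lesions model extrinsic (between-region)
#' disconnections; transition lesions model intrinsic (within-region)
#' synaptic loss.
#'
#' @param model a `wr_model`.
#' @param spec a [lesion_spec()].
#' @return the lesioned model.
#' @export
lesion <- function(model, spec) {
  stopifnot(inherits(spec, "lesion_spec"))
  pow_cols <- function(x) {
    d <- dim(x)
    m <- matrix(x, nrow = d[1])
    tot <- colSums(m)
    p <- sweep(m, 2, tot, "/")
    p <- p ^ spec$exponent
    p <- sweep(p, 2, colSums(p), "/")
    array(sweep(p, 2, tot, "*"), dim = d)
  }
  if (spec$target == "likelihood") {
    m <- match(spec$label, modality_names(model))
    if (is.na(m)) stop(sprintf("unknown modality '%s'", spec$label))
    model$a[[m]] <- pow_cols(model$a[[m]])
  } else {
    f <- match(spec$label, factor_names(model))
    if (is.na(f)) stop(sprintf("unknown factor '%s'", spec$label))
    for (u in seq_len(dim(model$b[[f]])[3])) {
      model$b[[f]][, , u] <- pow_cols(model$b[[f]][, , u, drop = TRUE])
    }
  }
  model
}
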