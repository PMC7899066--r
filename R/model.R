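# Generative-model specification: factors, modalities, Dirichlet
# concentration arrays, preferences, policies, and the word-repetition model.

#' Specify a hidden-state factor
#'
#' @param name factor label.
#' @param levels character vector of level labels (>= 2, unique).
#' @param controllable logical; can the agent act on this factor's
#'   transitions?
#' @return a `factor_spec` list.
#' @export
factor_spec <- function(name, levels, controllable = FALSE) {
  stopifnot(is.character(name), length(levels) >= 2,
            !anyDuplicated(levels))
  structure(list(name = name, levels = levels,
                 controllable = isTRUE(controllable)),
            class = "factor_spec")
}

#' Specify an outcome modality
#'
#' @param name modality label.
#' @param levels character vector of outcome labels (>= 2, unique).
#' @return a `modality_spec` list.
#' @export
modality_spec <- function(name, levels) {
  stopifnot(is.character(name), length(levels) >= 2,
            !anyDuplicated(levels))
  structure(list(name = name, levels = levels), class = "modality_spec")
}

#' Normalize Dirichlet concentration counts to probabilities
#'
#' Divides each conditioning column (everything beyond the first dimension)
#' by its sum. Works on matrices and higher-dimensional arrays whose first
#' dimension indexes the outcome (or next state).
#'
#' @param counts nonnegative numeric array; first dimension is the
#'   outcome/next-state dimension.
#' @return array of the same shape whose columns sum to one.
#' @export
normalize_counts <- function(counts) {
  d <- dim(counts)
  if (is.null(d)) d <- c(length(counts), 1L)
  m <- matrix(counts, nrow = d[1])
  tot <- colSums(m)
  if (any(tot <= 0)) {
    stop("degenerate concentration array: column(s) ",
         paste(which(tot <= 0), collapse = ", "), " have zero sum")
  }
  out <- sweep(m, 2, tot, "/")
  array(out, dim = d, dimnames = dimnames(counts))
}

#' Expected log-probability under a Dirichlet distribution
#'
#' For concentration counts `a` with column sums `a0`, returns
#' `digamma(a) - digamma(a0)` per entry, i.e. the Dirichlet expectation of the
#' log of the categorical parameter. This is the quantity used by the belief
#' update scheme when probability arrays are themselves uncertain.
#'
#' @param counts strictly positive numeric array; first dimension is the
#'   outcome/next-state dimension.
#' @return array of the same shape with entries `E[ln p]` (all negative).
#' @export
expected_log_probability <- function(counts) {
  if (any(counts <= 0)) stop("expected_log_probability requires strictly positive counts")
  d <- dim(counts)
  if (is.null(d)) d <- c(length(counts), 1L)
  m <- matrix(counts, nrow = d[1])
  out <- digamma(m) - rep(digamma(colSums(m)), each = d[1])
  array(out, dim = d, dimnames = dimnames(counts))
}

# ---------------------------------------------------------------------------
# word repetition model

# shared vocabulary tables: map state levels to the sound that is heard
.wr_levels <- list(
  epoch    = c("epoch1", "epoch2", "epoch3"),
  target   = c("red", "blue", "triangle", "square"),
  repeated = c("red", "read", "triangle", "square", "blue"),
  proprioception = c("still", "moving"),
  audition = c("red", "blue", "triangle", "square"),
  evaluation = c("neutral", "positive", "negative")
)

# audition index produced by each repeated-word level ("read" sounds like
# "red": the homophone is what makes the level spurious, not wrong)
.spoken_sound <- c(red = 1L, read = 1L, triangle = 3L, square = 4L, blue = 2L)

#' Build the word-repetition generative model
#'
#' Constructs the three-factor, three-modality Markov decision process for a
#' word repetition trial. Hidden factors: epoch (3 levels), target word
#' (red, blue, triangle, square) and repeated word (red, read, triangle,
#' square, blue; controllable). Outcome modalities: proprioception
#' (still/moving), audition (the four word sounds) and evaluation
#' (neutral/positive/negative). A trial has three epochs: hear the target,
#' repeat it, receive evaluation.
#'
#' Dirichlet concentration parameters are initialized to 1 on plausible
#' (outcome, context) pairs and 0.5 elsewhere, for both likelihood and
#' transition arrays. Initial-state counts are 10 on every target/repeated
#' level and concentrated on epoch 1. The agent prefers a positive
#' evaluation at epoch 3 (+0.5 nats) and selects among five deep policies,
#' one per sayable word (say it at both transitions), with action precision
#' `alpha = 16`.
#'
#' The spurious level "read" is a homophone of "red": it maps to auditory
#' "red" when spoken and earns a positive evaluation when the target is
#' "red", so it duplicates — rather than contradicts — the function of the
#' "red" level. Setting `spurious = FALSE` keeps the level but flattens all
#' of its likelihood mappings (concentration 10, uniform after
#' normalization), which disconnects it from the outcomes.
#'
#' @param spurious logical; keep the informative likelihood mappings of the
#'   spurious repeated-word level "read"?
#' @return an object of class `wr_model`.
#' @seealso [make_nonspurious()], [lesion()], [run_trial()]
#' @export
word_repetition_model <- function(spurious = TRUE) {
  lv <- .wr_levels
  factors <- list(
    factor_spec("epoch", lv$epoch, controllable = FALSE),
    factor_spec("target", lv$target, controllable = FALSE),
    factor_spec("repeated", lv$repeated, controllable = TRUE)
  )
  modalities <- list(
    modality_spec("proprioception", lv$proprioception),
    modality_spec("audition", lv$audition),
    modality_spec("evaluation", lv$evaluation)
  )
  dims <- c(3L, 4L, 5L)
  no <- c(2L, 4L, 3L)

  # likelihood counts: 0.5 everywhere, 1 on the outcome each context
  # generates with nonzero probability
  a <- lapply(no, function(n) array(0.5, dim = c(n, dims)))
  for (e in 1:3) for (t in 1:4) for (r in 1:5) {
    o <- .wr_outcome_indices(e, t, r)
    a[[1]][o[1], e, t, r] <- 1
    a[[2]][o[2], e, t, r] <- 1
    a[[3]][o[3], e, t, r] <- 1
  }
  names(a) <- vapply(modalities, `[[`, "", "name")

  # parameter tying: each likelihood carries only its stated conditional
  # dependencies, so conditioning columns that the dependency structure
  # does not distinguish share one Dirichlet parameter (learning pools
  # their evidence). Group ids per flattened (epoch, target, repeated)
  # context, epoch fastest.
  ctx <- expand.grid(e = 1:3, t = 1:4, r = 1:5)
  tie <- list(
    # proprioception depends on the epoch only
    proprioception = ctx$e,
    # audition: target word at epoch 1, repeated word at epochs 2-3
    audition = ifelse(ctx$e == 1, ctx$t,
                      4 + (ctx$e - 2) * 5 + ctx$r),
    # evaluation: epoch alone at epochs 1-2, the full joint at epoch 3
    evaluation = ifelse(ctx$e < 3, ctx$e,
                        2 + ctx$t + 4 * (ctx$r - 1))
  )
  tie <- lapply(tie, as.integer)

  # transitions: epoch chain (3 absorbing), target identity, repeated-word
  # action k sends every level to level k. Transition priors encode task
  # structure and motor efficacy the subject brings to the task (trial
  # phases always advance, the experimenter never changes the target
  # mid-trial, choosing to say a word reliably produces that word), so
  # their plausible entries carry a confident concentration of 10. The
  # plastic arrays under study -- the likelihood mappings -- start at the
  # vague 1-plausible / 0.5-implausible regime. Without a reliable
  # scaffold of beliefs about trial dynamics, the latent credit assignment
  # that drives likelihood learning does not converge.
  b_epoch <- array(0.5, dim = c(3, 3, 1))
  b_epoch[2, 1, 1] <- 10; b_epoch[3, 2, 1] <- 10; b_epoch[3, 3, 1] <- 10
  b_target <- array(0.5, dim = c(4, 4, 1))
  for (i in 1:4) b_target[i, i, 1] <- 10
  b_rep <- array(0.5, dim = c(5, 5, 5))
  for (k in 1:5) b_rep[k, , k] <- 10
  b <- list(epoch = b_epoch, target = b_target, repeated = b_rep)

  # log preferences (nats) per modality: outcomes x epochs
  C <- lapply(no, function(n) matrix(0, n, 3))
  C[[3]][2, 3] <- 0.5
  names(C) <- names(a)

  D <- list(epoch = c(10, LOG_FLOOR, LOG_FLOOR),
            target = rep(10, 4), repeated = rep(10, 5))

  model <- structure(list(
    factors = factors,
    modalities = modalities,
    a = a, b = b, C = C, D = D,
    tie_groups = tie,
    policies = matrix(rep(1:5, 2), nrow = 5, ncol = 2),
    n_epochs = 3L,
    alpha = 16,
    beta_prior = 1,
    # likelihoods are plastic; transition priors (task structure, motor
    # efficacy) stay fixed -- accumulating transition counts from uncertain
    # state estimates lets off-diagonal mass snowball until the target can
    # no longer be held in mind
    learn = list(a = TRUE, b = FALSE, d = FALSE),
    dirichlet = list(a = TRUE, b = TRUE),
    spurious = isTRUE(spurious)
  ), class = "wr_model")

  if (!spurious) model <- make_nonspurious(model)
  model
}

#' @rdname word_repetition_model
#' @export
build_word_repetition_model <- word_repetition_model

# deterministic outcome indices (proprioception, audition, evaluation) for a
# true state (epoch e, target t, repeated r); the single source of truth for
# plausible likelihood entries, shared with the environment module
.wr_outcome_indices <- function(e, t, r) {
  prop <- if (e == 2) 2L else 1L
  aud <- if (e == 1) t else .spoken_sound[[r]]
  ev <- if (e < 3) 1L else if (.spoken_sound[[r]] == t) 2L else 3L
  c(prop, aud, ev)
}

factor_names <- function(model) vapply(model$factors, `[[`, "", "name")
modality_names <- function(model) vapply(model$modalities, `[[`, "", "name")
state_dims <- function(model) vapply(model$factors, function(f) length(f$levels), 1L)
outcome_dims <- function(model) vapply(model$modalities, function(m) length(m$levels), 1L)

#' Validate a generative model
#'
#' Checks the structural invariants of a model (array shapes, nonnegative
#' concentrations, strictly positive column sums, policy count and length,
#' preference shapes) and returns human-readable diagnostics instead of
#' raising errors.
#'
#' @param model a `wr_model`.
#' @return character vector of diagnostics; empty if the model is valid.
#' @export
validate_model <- function(model) {
  diags <- character()
  dims <- state_dims(model)
  no <- outcome_dims(model)
  for (m in seq_along(model$a)) {
    am <- model$a[[m]]
    nm <- model$modalities[[m]]$name
    if (!identical(dim(am), c(no[m], dims)))
      diags <- c(diags, sprintf("likelihood '%s': wrong dimensions", nm))
    if (any(am < 0))
      diags <- c(diags, sprintf("likelihood '%s': negative concentration", nm))
    cs <- colSums(matrix(am, nrow = dim(am)[1]))
    if (any(cs <= 0))
      diags <- c(diags, sprintf(
        "likelihood '%s': zero-sum conditioning column(s) %s", nm,
        paste(which(cs <= 0), collapse = ", ")))
  }
  for (f in seq_along(model$b)) {
    bf <- model$b[[f]]
    nm <- model$factors[[f]]$name
    if (dim(bf)[1] != dims[f] || dim(bf)[2] != dims[f])
      diags <- c(diags, sprintf("transition '%s': wrong dimensions", nm))
    if (any(bf < 0))
      diags <- c(diags, sprintf("transition '%s': negative concentration", nm))
    cs <- colSums(matrix(bf, nrow = dim(bf)[1]))
    if (any(cs <= 0))
      diags <- c(diags, sprintf("transition '%s': zero-sum column(s)", nm))
  }
  for (f in seq_along(model$D)) {
    if (any(model$D[[f]] < 0) || sum(model$D[[f]]) <= 0)
      diags <- c(diags, sprintf("initial counts '%s': not a valid count vector",
                                model$factors[[f]]$name))
  }
  if (nrow(model$policies) != 5)
    diags <- c(diags, sprintf("policy count is %d, expected 5",
                              nrow(model$policies)))
  if (ncol(model$policies) != model$n_epochs - 1)
    diags <- c(diags, "policy length must equal n_epochs - 1")
  if (model$alpha <= 0) diags <- c(diags, "action precision alpha must be > 0")
  if (model$beta_prior <= 0) diags <- c(diags, "policy precision rate beta must be > 0")
  diags
}

#' @export
print.wr_model <- function(x, ...) {
  cat("Word repetition generative model",
      if (x$spurious) "(spurious 'read' level active)" else "(nonspurious)", "\n")
  cat("  factors:   ",
      paste(sprintf("%s[%d]", factor_names(x), state_dims(x)), collapse = ", "),
      "\n")
  cat("  modalities:",
      paste(sprintf("%s[%d]", modality_names(x), outcome_dims(x)), collapse = ", "),
      "\n")
  cat(sprintf("  policies: %d x %d | alpha = %g | beta prior = %g\n",
              nrow(x$policies), ncol(x$policies), x$alpha, x$beta_prior))
  cat(sprintf("  learning: a=%s b=%s d=%s\n",
              x$learn$a, x$learn$b, x$learn$d))
  invisible(x)
}

#' @export
summary.wr_model <- function(object, ...) {
  diags <- validate_model(object)
  print(object)
  tot <- vapply(object$a, sum, 0)
  cat("  total likelihood counts:",
      paste(sprintf("%s=%.1f", names(tot), tot), collapse = ", "), "\n")
  if (length(diags)) {
    cat("  diagnostics:\n")
    for (d in diags) cat("   -", d, "\n")
  } else cat("  model is valid\n")
  invisible(diags)
}

# ---------------------------------------------------------------------------
# serialization (JSON schema; count arrays round-trip bit-stable)

#' Serialize a model to JSON
#'
#' Writes factors, modalities, concentration arrays (column-major nested
#' lists at full precision), preferences, initial counts, policies and
#' hyperparameters. [model_from_json()] restores the model; count arrays
#' round-trip bit-stable.
#'
#' @param model a `wr_model`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
model_to_json <- function(model, path) {
  ser_array <- function(x) list(dim = dim(x), values = as.vector(x))
  obj <- list(
    factors = lapply(model$factors, unclass),
    modalities = lapply(model$modalities, unclass),
    a = lapply(model$a, ser_array),
    b = lapply(model$b, ser_array),
    tie_groups = model$tie_groups,
    C = lapply(model$C, ser_array),
    D = model$D,
    policies = ser_array(model$policies),
    n_epochs = model$n_epochs,
    alpha = model$alpha,
    beta_prior = model$beta_prior,
    learn = model$learn,
    dirichlet = model$dirichlet,
    spurious = model$spurious
  )
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  de_array <- function(x) array(as.numeric(x$values), dim = as.integer(x$dim))
  factors <- lapply(seq_len(nrow(obj$factors)), function(i)
    factor_spec(obj$factors$name[i], obj$factors$levels[[i]],
                obj$factors$controllable[i]))
  modalities <- lapply(seq_len(nrow(obj$modalities)), function(i)
    modality_spec(obj$modalities$name[i], obj$modalities$levels[[i]]))
  pol <- de_array(obj$policies)
  structure(list(
    factors = factors, modalities = modalities,
    a = lapply(obj$a, de_array), b = lapply(obj$b, de_array),
    tie_groups = if (is.null(obj$tie_groups)) NULL else
      lapply(obj$tie_groups, as.integer),
    C = lapply(obj$C, function(x) matrix(de_array(x), dim(de_array(x))[1])),
    D = lapply(obj$D, as.numeric),
    policies = matrix(as.integer(pol), nrow(pol), ncol(pol)),
    n_epochs = as.integer(obj$n_epochs),
    alpha = obj$alpha, beta_prior = obj$beta_prior,
    learn = obj$learn, dirichlet = obj$dirichlet,
    spurious = obj$spurious
  ), class = "wr_model")
}
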