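# Orchestration of the four experiment families: Dirichlet learning,
# structure-learning comparison, lesion groups, and the violation (oddball)
# paradigm.

# canonical lesion definitions: extrinsic (A, evaluation likelihood,
# exponent 0.4) and intrinsic (B, target-word transitions, exponent 0.5)
lesion_A <- function() lesion_spec("likelihood", "evaluation", 0.4)
lesion_B <- function() lesion_spec("transition", "target", 0.5)

#' Specify a simulated group
#'
#' @param label group label: `"Control"`, `"B"` (intrinsic/transition
#'   lesion), `"A"` (extrinsic/likelihood lesion) or `"A and B"`.
#' @param spurious keep the spurious level's likelihood mappings?
#' @param lesions list of [lesion_spec()] objects applied in order.
#' @param n_subjects simulated subjects (default 50).
#' @param n_trials trials per subject for the evaluation run (default 10).
#' @param base_seed per-subject seeds are `base_seed + subject`.
#' @return a `group_spec` list.
#' @export
group_spec <- function(label, spurious = TRUE, lesions = list(),
                       n_subjects = 50L, n_trials = 10L, base_seed = 0L) {
  stopifnot(n_subjects >= 1, n_trials >= 1)
  structure(list(label = label, spurious = spurious, lesions = lesions,
                 n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials),
                 base_seed = as.integer(base_seed)),
            class = "group_spec")
}

#' Run the learning phase
#'
#' Simulates `n_trials` word-repetition trials for `n_subjects` independent
#' subjects, each starting from a fresh spurious model, with Dirichlet
#' learning of the likelihood and transition arrays after every trial.
#' Targets are drawn uniformly. Per-subject seeds are
#' `base_seed + subject`, so the run is fully reproducible.
#'
#' @param n_subjects number of simulated subjects (default 50).
#' @param n_trials trials per subject (default 500).
#' @param settings an [inference_settings()].
#' @param base_seed integer seed offset.
#' @param aggregation an [fe_aggregation()].
#' @param progress print per-subject progress?
#' @return a `wr_learning` object: `curves` (per-trial-index means over
#'   subjects of every component), `models` (post-learning model per
#'   subject), `measures` (subjects x trials x components array) and
#'   `correct` (subjects x trials logical matrix).
#' @export
run_learning_phase <- function(n_subjects = 50L, n_trials = 500L,
                               settings = inference_settings(),
                               base_seed = 0L,
                               aggregation = fe_aggregation(),
                               progress = FALSE) {
  measures <- array(NA_real_, dim = c(n_subjects, n_trials, 6),
                    dimnames = list(NULL, NULL, COMPONENT_NAMES))
  correct <- matrix(NA, n_subjects, n_trials)
  models <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    set.seed(base_seed + i)
    model <- word_repetition_model(spurious = TRUE)
    for (j in seq_len(n_trials)) {
      rec <- run_trial(model, trial_config(), settings)
      measures[i, j, ] <- trial_measures(rec, aggregation)
      correct[i, j] <- rec$correct
      updated <- accumulate_dirichlet(model, rec)
      # belief updating extends to the Dirichlet parameters while learning
      # is on: add the parameter-level complexity to the trial's complexity
      # (and, by the component identities, to F, energy and cost)
      pkl <- dirichlet_update_complexity(updated, model)
      measures[i, j, c("F", "complexity", "energy", "cost")] <-
        measures[i, j, c("F", "complexity", "energy", "cost")] + pkl
      model <- updated
    }
    models[[i]] <- model
    if (progress) message(sprintf("subject %d/%d done", i, n_subjects))
  }
  curves <- data.frame(trial = seq_len(n_trials),
                       apply(measures, c(2, 3), mean))
  names(curves) <- c("trial", COMPONENT_NAMES)
  structure(list(curves = curves, models = models, measures = measures,
                 correct = correct, base_seed = base_seed,
                 aggregation = aggregation),
            class = "wr_learning")
}

#' @export
print.wr_learning <- function(x, ...) {
  n <- nrow(x$curves)
  cat(sprintf("learning phase: %d subjects x %d trials\n",
              dim(x$measures)[1], n))
  head_n <- min(50, n)
  cat(sprintf("  mean F: first %d trials %.3f -> last %d trials %.3f\n",
              head_n, mean(x$curves$F[seq_len(head_n)]),
              head_n, mean(x$curves$F[(n - head_n + 1):n])))
  cat(sprintf("  mean redundancy: %.3f -> %.3f\n",
              mean(x$curves$complexity[seq_len(head_n)]),
              mean(x$curves$complexity[(n - head_n + 1):n])))
  invisible(x)
}

#' @export
plot.wr_learning <- function(x, components = c("F", "complexity", "entropy"),
                             ...) {
  graphics::matplot(x$curves$trial, as.matrix(x$curves[components]),
                    type = "l", lty = 1, xlab = "trial",
                    ylab = "nats", ...)
  graphics::legend("topright", legend = components, lty = 1,
                   col = seq_along(components))
  invisible(x)
}

# apply a group's structural manipulations to one subject's learned model
prepare_group_model <- function(model, spec) {
  if (!spec$spurious) model <- make_nonspurious(model)
  for (ls in spec$lesions) model <- lesion(model, ls)
  model$learn <- list(a = FALSE, b = FALSE, d = FALSE)
  model
}

#' Run one evaluation group
#'
#' Applies the group's structural manipulations (spurious-level removal,
#' lesions) to each subject's post-learning model, then simulates
#' `n_trials` trials per subject with learning disabled and summarizes the
#' free-energy components and behavioral accuracy.
#'
#' @param spec a [group_spec()].
#' @param models list of post-learning models (one per subject), as returned
#'   in `run_learning_phase()$models`.
#' @param settings an [inference_settings()].
#' @param aggregation an [fe_aggregation()].
#' @return a one-row `wr_group` summary with per-subject detail in
#'   attributes `subject_measures` (subjects x components) and
#'   `subject_accuracy`.
#' @export
run_group <- function(spec, models, settings = inference_settings(),
                      aggregation = fe_aggregation()) {
  n_subjects <- min(spec$n_subjects, length(models))
  measures <- array(NA_real_, dim = c(n_subjects, spec$n_trials, 6),
                    dimnames = list(NULL, NULL, COMPONENT_NAMES))
  correct <- matrix(NA, n_subjects, spec$n_trials)
  for (i in seq_len(n_subjects)) {
    model <- prepare_group_model(models[[i]], spec)
    set.seed(spec$base_seed + i)
    for (j in seq_len(spec$n_trials)) {
      rec <- run_trial(model, trial_config(), settings)
      measures[i, j, ] <- trial_measures(rec, aggregation)
      correct[i, j] <- rec$correct
    }
  }
  out <- group_summary(measures, 100 * mean(correct), spec$label,
                       spec$spurious, spec$n_trials)
  attr(out, "subject_measures") <- apply(measures, c(1, 3), mean)
  attr(out, "subject_accuracy") <- 100 * rowMeans(correct)
  out
}

#' Run the full set of evaluation groups
#'
#' Produces the eight-row results table: {Control, B, A, A and B} x
#' {spurious Y, N}. All groups reuse the same per-subject post-learning
#' models, so group differences are purely structural. The Control/Y row is
#' summarized over the learning run itself (500 trials per agent, with the
#' behavioral accuracy scored over the last 10 trials); every other row is
#' a fresh 10-trial evaluation run with learning disabled.
#'
#' @param learning a `wr_learning` object from [run_learning_phase()].
#' @param settings an [inference_settings()].
#' @param n_trials trials per subject for the evaluation groups.
#' @param base_seed seed offset for the evaluation runs (shared across
#'   groups so comparisons are paired over subjects).
#' @param aggregation an [fe_aggregation()].
#' @param progress print per-group progress?
#' @return a `wr_group_table` data.frame with one row per group and
#'   per-subject detail rows in attribute `subject_measures` (a list by
#'   row label).
#' @export
run_all_groups <- function(learning, settings = inference_settings(),
                           n_trials = 10L, base_seed = NULL,
                           aggregation = fe_aggregation(),
                           progress = FALSE) {
  if (is.null(base_seed)) base_seed <- learning$base_seed + 100000L
  models <- learning$models
  n_subjects <- length(models)
  n_learn <- dim(learning$measures)[2]

  # Control/Y: the learning run itself; behavioral accuracy post-learning
  last10 <- max(1L, n_learn - 9L):n_learn
  control_y <- group_summary(learning$measures,
                             100 * mean(learning$correct[, last10]),
                             "Control", TRUE, n_learn)
  attr(control_y, "subject_measures") <-
    apply(learning$measures, c(1, 3), mean)
  attr(control_y, "subject_accuracy") <-
    100 * rowMeans(learning$correct[, last10, drop = FALSE])

  specs <- list(
    list(label = "Control", spurious = FALSE, lesions = list()),
    list(label = "B", spurious = TRUE, lesions = list(lesion_B())),
    list(label = "B", spurious = FALSE, lesions = list(lesion_B())),
    list(label = "A", spurious = TRUE, lesions = list(lesion_A())),
    list(label = "A", spurious = FALSE, lesions = list(lesion_A())),
    list(label = "A and B", spurious = TRUE,
         lesions = list(lesion_A(), lesion_B())),
    list(label = "A and B", spurious = FALSE,
         lesions = list(lesion_A(), lesion_B()))
  )
  rows <- vector("list", 1 + length(specs))
  rows[[1]] <- control_y
  for (k in seq_along(specs)) {
    s <- specs[[k]]
    gs <- group_spec(s$label, s$spurious, s$lesions,
                     n_subjects = n_subjects, n_trials = n_trials,
                     base_seed = base_seed)
    rows[[k + 1]] <- run_group(gs, models, settings, aggregation)
    if (progress) message(sprintf("group %s/%s done", s$label,
                                  ifelse(s$spurious, "Y", "N")))
  }
  detail <- lapply(rows, function(r) list(
    measures = attr(r, "subject_measures"),
    accuracy = attr(r, "subject_accuracy")))
  tab <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  # table order: Control Y/N, B Y/N, A Y/N, A and B Y/N
  ord <- c(1, 2, 3, 4, 5, 6, 7, 8)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  names(detail) <- paste(tab$group, tab$spurious, sep = "/")
  class(tab) <- c("wr_group_table", "data.frame")
  attr(tab, "subject_detail") <- detail
  tab
}

#' @export
print.wr_group_table <- function(x, digits = 3, ...) {
  cat("Free energy and its components (nats; behavioral accuracy in %)\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], round, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Run the violation (oddball) paradigm
#'
#' For each group (control and the three lesion groups, all nonspurious)
#' and each subject: one standard trial (correct evaluation) and one
#' deviant trial in which the evaluation is forced to "negative" at epoch
#' 3. The target word is always "red". Both trials use the same seed, so
#' they are identical up to the epoch-3 evaluation outcome. Iteration
#' traces are retained (all variational sweeps are run so traces share a
#' grid).
#'
#' @param learning a `wr_learning` object (its models are used).
#' @param settings an [inference_settings()] — its `tol` is forced to 0.
#' @param n_subjects subjects per group (default: all available).
#' @param base_seed seed offset.
#' @return a `wr_erp_data` list: `records[[group]][[condition]]` is a list
#'   of `wr_trial` records with traces.
#' @export
run_violation_paradigm <- function(learning, settings = inference_settings(),
                                   n_subjects = NULL, base_seed = NULL) {
  if (is.null(base_seed)) base_seed <- learning$base_seed + 200000L
  models <- learning$models
  if (is.null(n_subjects)) n_subjects <- length(models)
  n_subjects <- min(n_subjects, length(models))
  settings$tol <- 0  # fixed sweep count -> common peristimulus grid
  groups <- list(
    control = list(),
    B = list(lesion_B()),
    A = list(lesion_A()),
    `A and B` = list(lesion_A(), lesion_B())
  )
  out <- lapply(names(groups), function(g) {
    spec <- group_spec(g, spurious = FALSE, lesions = groups[[g]],
                       n_subjects = n_subjects, n_trials = 1L)
    std <- vector("list", n_subjects)
    dev <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      model <- prepare_group_model(models[[i]], spec)
      set.seed(base_seed + i)
      std[[i]] <- run_trial(model, trial_config(forced_target = "red"),
                            settings, trace = TRUE)
      set.seed(base_seed + i)
      dev[[i]] <- run_trial(model,
                            trial_config(forced_target = "red",
                                         forced_evaluation = "negative"),
                            settings, trace = TRUE)
    }
    list(standard = std, deviant = dev)
  })
  names(out) <- names(groups)
  structure(list(records = out, n_subjects = n_subjects),
            class = "wr_erp_data")
}
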