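# The generative process: the experimenter + world that emit true states and
# outcomes for each trial of the word repetition paradigm. Deterministic given
# the true state (the paradigm is a deterministic experiment); the only
# randomness is the draw of the target word.

#' Configure a trial of the word repetition paradigm
#'
#' @param forced_target optional target word (label or index among red, blue,
#'   triangle, square); if `NULL` the target is drawn uniformly.
#' @param forced_evaluation optional evaluation outcome (label or index)
#'   imposed at epoch 3 regardless of performance; used to build the
#'   violation (oddball) paradigm.
#' @param n_epochs number of epochs; the paradigm has exactly 3.
#' @return a `trial_config` list.
#' @export
trial_config <- function(forced_target = NULL, forced_evaluation = NULL,
                         n_epochs = 3L) {
  if (n_epochs != 3L) stop("the word repetition paradigm has exactly 3 epochs")
  lv <- .wr_levels
  if (!is.null(forced_target)) {
    forced_target <- match_level(forced_target, lv$target, "forced_target")
  }
  if (!is.null(forced_evaluation)) {
    forced_evaluation <- match_level(forced_evaluation, lv$evaluation,
                                     "forced_evaluation")
  }
  structure(list(forced_target = forced_target,
                 forced_evaluation = forced_evaluation,
                 n_epochs = 3L),
            class = "trial_config")
}

match_level <- function(x, levels, what) {
  if (is.character(x)) {
    i <- match(x, levels)
    if (is.na(i)) stop(sprintf("%s '%s' is not one of: %s", what, x,
                               paste(levels, collapse = ", ")))
    return(as.integer(i))
  }
  x <- as.integer(x)
  if (x < 1L || x > length(levels))
    stop(sprintf("%s index %d out of range 1..%d", what, x, length(levels)))
  x
}

#' Initialize the true state of a trial
#'
#' Sets epoch 1, draws the target word (uniformly over the four words unless
#' forced) and initializes the repeated-word state to its reference level
#' ("red"; nothing has been spoken yet, so the choice affects no epoch-1
#' outcome).
#'
#' @param config a [trial_config()].
#' @return a `true_state` list with 1-based level indices `epoch`, `target`,
#'   `repeated`.
#' @export
init_trial <- function(config = trial_config()) {
  target <- if (is.null(config$forced_target)) {
    sample.int(4L, 1L)
  } else config$forced_target
  structure(list(epoch = 1L, target = target, repeated = 1L),
            class = "true_state")
}

#' Generate the outcomes for a true state
#'
#' Pure deterministic function of the state (and config): proprioception is
#' "moving" iff epoch 2; audition carries the target word at epoch 1 and the
#' spoken word (with the read/red homophony) at epochs 2-3; evaluation is
#' neutral at epochs 1-2 and, at epoch 3, positive iff the spoken word sounds
#' like the target (spoken "read" matches target "red") and negative
#' otherwise. A `forced_evaluation` overrides the epoch-3 evaluation.
#'
#' @param state a `true_state`.
#' @param config a [trial_config()].
#' @return integer vector of outcome indices, named `proprioception`,
#'   `audition`, `evaluation`.
#' @export
emit_outcome <- function(state, config = trial_config()) {
  o <- .wr_outcome_indices(state$epoch, state$target, state$repeated)
  if (!is.null(config$forced_evaluation) && state$epoch == 3L) {
    o[3] <- config$forced_evaluation
  }
  names(o) <- c("proprioception", "audition", "evaluation")
  o
}

#' Apply an action to the true state
#'
#' Advances the epoch (epoch 3 is absorbing), leaves the target unchanged and
#' sets the repeated word to the word named by the action, regardless of what
#' was previously spoken.
#'
#' @param state a `true_state`.
#' @param action action index in 1..5 (one per sayable word).
#' @return the next `true_state`.
#' @export
apply_action <- function(state, action) {
  action <- as.integer(action)
  if (action < 1L || action > 5L) stop("action index out of range 1..5")
  structure(list(epoch = min(state$epoch + 1L, 3L),
                 target = state$target,
                 repeated = action),
            class = "true_state")
}

#' @export
print.true_state <- function(x, ...) {
  lv <- .wr_levels
  cat(sprintf("true state: epoch=%s target=%s repeated=%s\n",
              lv$epoch[x$epoch], lv$target[x$target], lv$repeated[x$repeated]))
  invisible(x)
}

#' Write trial logs as tabular records
#'
#' One row per epoch: trial id, epoch, true states, outcomes and the action
#' taken at the end of the epoch (NA at the final epoch).
#'
#' @param records list of trial records as returned by [run_trial()].
#' @param path CSV file to write (optional).
#' @return data.frame of the log (invisibly if written to file).
#' @export
trial_log <- function(records, path = NULL) {
  lv <- .wr_levels
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    data.frame(
      trial = i, epoch = 1:3,
      target = lv$target[r$states[2, ]],
      repeated = lv$repeated[r$states[3, ]],
      proprioception = lv$proprioception[r$outcomes[1, ]],
      audition = lv$audition[r$outcomes[2, ]],
      evaluation = lv$evaluation[r$outcomes[3, ]],
      action = c(lv$repeated[r$actions], NA)
    )
  })
  log <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(log, path, row.names = FALSE)
    return(invisible(log))
  }
  log
}
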