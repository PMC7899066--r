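# Simulated local-field-potential responses: belief-updating iteration
# traces mapped onto peristimulus time, with difference (mismatch) waves.

#' Select the neuronal population to read out
#'
#' A population is one coordinate of the evolving expectations: either a
#' hidden-state expectation (factor, level, time point) or a predicted
#' outcome probability (modality, level, time point). The default is the
#' population encoding the positive evaluation expected at epoch 3.
#'
#' @param kind `"outcome"` or `"state"`.
#' @param name modality name (outcome) or factor name (state).
#' @param level level label or index within the modality/factor.
#' @param tau represented time point (epoch index, 1-3).
#' @return a `population_selector` list.
#' @export
population_selector <- function(kind = "outcome", name = "evaluation",
                                level = "positive", tau = 3L) {
  kind <- match.arg(kind, c("outcome", "state"))
  structure(list(kind = kind, name = name, level = level,
                 tau = as.integer(tau)),
            class = "population_selector")
}

# resolve (index of array in list, level index) for a selector
resolve_selector <- function(record, selector) {
  lv <- .wr_levels
  if (selector$kind == "outcome") {
    names_ <- c("proprioception", "audition", "evaluation")
  } else {
    names_ <- c("epoch", "target", "repeated")
  }
  k <- if (is.character(selector$name)) match(selector$name, names_)
       else as.integer(selector$name)
  if (is.na(k)) stop(sprintf("selector does not resolve: unknown %s '%s'",
                             selector$kind, selector$name))
  levels <- lv[[if (selector$kind == "outcome") c("proprioception",
                                                  "audition",
                                                  "evaluation")[k]
                else c("epoch", "target", "repeated")[k]]]
  l <- if (is.character(selector$level)) match(selector$level, levels)
       else as.integer(selector$level)
  if (is.na(l) || l < 1 || l > length(levels))
    stop("selector does not resolve: bad level")
  list(array = k, level = l)
}

#' Simulated population response for one trial
#'
#' Reads the selected expectation out of the trial's per-sweep iteration
#' traces (Bayesian-model-averaged over policies with the epoch's policy
#' posterior), maps each epoch's sweeps onto its span of peristimulus time,
#' and returns the first temporal derivative of the expectation as a
#' depolarization proxy. Constant expectations yield zero amplitude.
#'
#' @param record a `wr_trial` simulated with `trace = TRUE`.
#' @param selector a [population_selector()].
#' @param epoch_duration seconds of peristimulus time per epoch (default
#'   0.25).
#' @param n_sweeps sweeps per epoch on the common grid (default 16; shorter
#'   traces are padded with their converged value).
#' @return an `erp_trace` with `time` (s) and `amplitude` (a.u.).
#' @export
simulate_population_response <- function(record, selector = population_selector(),
                                         epoch_duration = 0.25,
                                         n_sweeps = 16L) {
  if (is.null(record$traces)) stop("record has no iteration traces; rerun with trace = TRUE")
  sel <- resolve_selector(record, selector)
  T <- length(record$traces)
  x <- numeric(0)
  for (t in seq_len(T)) {
    tr <- record$traces[[t]]
    pol_traces <- tr$policy
    npol <- length(pol_traces)
    for (i in seq_len(n_sweeps)) {
      val <- 0
      for (p in seq_len(npol)) {
        sweeps <- pol_traces[[p]]
        snap <- sweeps[[min(i, length(sweeps))]]
        v <- if (selector$kind == "state") {
          snap[[sel$array]][sel$level, selector$tau]
        } else {
          w <- joint_weights(lapply(snap, function(q) q[, selector$tau]))
          (tr$Abar[[sel$array]] %*% w)[sel$level]
        }
        val <- val + tr$pi[p] * v
      }
      x <- c(x, val)
    }
  }
  dt <- epoch_duration / n_sweeps
  time <- seq_len(length(x)) * dt
  amplitude <- c(0, diff(x) / dt)
  structure(list(time = time, amplitude = amplitude, expectation = x),
            class = "erp_trace")
}

#' Mismatch (difference) wave
#'
#' Pointwise deviant minus standard response on a shared time grid.
#'
#' @param standard,deviant `erp_trace` objects with identical time grids.
#' @return an `erp_trace` of the difference wave.
#' @export
mmn_difference <- function(standard, deviant) {
  if (!isTRUE(all.equal(standard$time, deviant$time)))
    stop("traces do not share a time grid")
  structure(list(time = standard$time,
                 amplitude = deviant$amplitude - standard$amplitude),
            class = "erp_trace")
}

#' @export
print.erp_trace <- function(x, ...) {
  cat(sprintf("simulated population response: %d samples over %.2f s, peak |amplitude| %.4f\n",
              length(x$time), max(x$time), max(abs(x$amplitude))))
  invisible(x)
}

#' @export
plot.erp_trace <- function(x, ...) {
  graphics::plot(x$time, x$amplitude, type = "l", xlab = "time (s)",
                 ylab = "response (a.u.)", ...)
  invisible(x)
}

#' Group-level evoked responses from a violation-paradigm run
#'
#' Averages the per-subject population responses within each group and
#' condition and adds the difference (deviant - standard) wave.
#'
#' @param erp_data a `wr_erp_data` from [run_violation_paradigm()].
#' @param selector a [population_selector()].
#' @param epoch_duration seconds per epoch.
#' @return a `wr_erp` data.frame: group, condition (standard / deviant /
#'   difference), time_s, amplitude.
#' @export
erp_traces <- function(erp_data, selector = population_selector(),
                       epoch_duration = 0.25) {
  rows <- list()
  for (g in names(erp_data$records)) {
    recs <- erp_data$records[[g]]
    mean_trace <- function(cond) {
      tr <- lapply(recs[[cond]], simulate_population_response,
                   selector = selector, epoch_duration = epoch_duration)
      amp <- rowMeans(vapply(tr, `[[`, tr[[1]]$amplitude, "amplitude"))
      structure(list(time = tr[[1]]$time, amplitude = amp),
                class = "erp_trace")
    }
    std <- mean_trace("standard")
    dev <- mean_trace("deviant")
    dif <- mmn_difference(std, dev)
    rows[[g]] <- rbind(
      data.frame(group = g, condition = "standard", time_s = std$time,
                 amplitude = std$amplitude),
      data.frame(group = g, condition = "deviant", time_s = dev$time,
                 amplitude = dev$amplitude),
      data.frame(group = g, condition = "difference", time_s = dif$time,
                 amplitude = dif$amplitude))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("wr_erp", "data.frame")
  out
}

#' @export
plot.wr_erp <- function(x, ...) {
  groups <- unique(x$group)
  old <- graphics::par(mfrow = c(length(groups), 2), mar = c(3, 3, 2, 1))
  on.exit(graphics::par(old))
  for (g in groups) {
    sub <- x[x$group == g, ]
    std <- sub[sub$condition == "standard", ]
    dev <- sub[sub$condition == "deviant", ]
    dif <- sub[sub$condition == "difference", ]
    ylim <- range(sub$amplitude)
    graphics::plot(std$time_s, std$amplitude, type = "l", col = "red",
                   ylim = ylim, main = g, xlab = "", ylab = "")
    graphics::lines(dev$time_s, dev$amplitude, col = "blue")
    graphics::plot(dif$time_s, dif$amplitude, type = "l",
                   main = paste(g, "difference"), xlab = "", ylab = "")
  }
  invisible(x)
}
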