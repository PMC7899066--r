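# Run configuration and CSV output: everything is written as diffable text
# with fixed headers and 6 significant digits.

config_defaults <- function() {
  list(
    seed = 0L,
    n_subjects = 50L,
    n_trials_learning = 500L,
    n_trials_evaluation = 10L,
    iterations = 16L,
    tol = 1 / 128,
    aggregation = list(factors = "sum", epochs = "sum", tau = "current"),
    output_dir = ".",
    verbose = FALSE,
    lesions = list(
      A = list(target = "likelihood", label = "evaluation", exponent = 0.4),
      B = list(target = "transition", label = "target", exponent = 0.5)
    )
  )
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON) configuration file, validates it against the known
#' keys and fills in documented defaults (seed 0, 50 subjects, 500 learning
#' trials, 10 evaluation trials, the standard lesion set). An empty file
#' yields the all-defaults configuration.
#'
#' @param path configuration file; `NULL` returns the defaults.
#' @return a validated `run_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
    user <- if (grepl("\\.json$", path)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  with(cfg, {
    if (n_subjects < 1) stop("invalid value for 'n_subjects': must be >= 1")
    if (n_trials_learning < 1) stop("invalid value for 'n_trials_learning'")
    if (n_trials_evaluation < 1) stop("invalid value for 'n_trials_evaluation'")
    if (iterations < 1) stop("invalid value for 'iterations'")
    if (tol < 0) stop("invalid value for 'tol'")
  })
  for (nm in names(cfg$lesions)) {
    ls <- cfg$lesions[[nm]]
    # constructor validates (exponent range, target kind)
    cfg$lesions[[nm]] <- unclass(lesion_spec(ls$target, ls$label, ls$exponent))
  }
  cfg$aggregation <- fe_aggregation(cfg$aggregation$factors,
                                    cfg$aggregation$epochs,
                                    cfg$aggregation$tau)
  structure(cfg, class = "run_config")
}

#' Save a run configuration
#'
#' @param config a `run_config`.
#' @param path YAML file to write.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$aggregation <- unclass(cfg$aggregation)
  attributes(cfg$aggregation) <- list(names = names(cfg$aggregation))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

write_signif_csv <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], signif, 6)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write the group results table
#'
#' CSV with columns group, spurious, trials, F, redundancy, degeneracy,
#' cost, energy, accuracy, behavioral_accuracy; floats at 6 significant
#' digits.
#'
#' @param results a `wr_group_table` (or any data.frame of group rows).
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  if (is.null(results) || nrow(results) == 0) stop("empty results; nothing to write")
  write_signif_csv(as.data.frame(results), path)
}

#' Write the learning curves
#'
#' CSV with columns trial, F, accuracy, complexity, energy, entropy, cost
#' (per-trial-index means over subjects).
#'
#' @param curves the `curves` data.frame of a `wr_learning` object (the
#'   object itself is also accepted).
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  if (inherits(curves, "wr_learning")) curves <- curves$curves
  if (is.null(curves) || nrow(curves) == 0) stop("empty curves; nothing to write")
  write_signif_csv(curves, path)
}

#' Write evoked-response traces
#'
#' Long-format CSV: group, condition, time_s, amplitude.
#'
#' @param erp a `wr_erp` data.frame from [erp_traces()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_erp <- function(erp, path) {
  if (is.null(erp) || nrow(erp) == 0) stop("empty ERP dataset; nothing to write")
  write_signif_csv(as.data.frame(erp), path)
}
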