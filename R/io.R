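# File-format contracts: CSV schemas for schedules, choices, fits, CV/BMS
# and recovery results; YAML task configuration; JSON run manifests.
# All CSVs are UTF-8 with "." decimals.  Doubles that must round-trip
# exactly (initial samples) are printed with 17 significant digits.

fmt_samples <- function(samples) {
  vapply(samples, function(s) paste(sprintf("%.17g", s), collapse = ";"),
         character(1))
}

parse_samples <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE), function(s) {
    if (length(s) == 1 && (is.na(s) || s == "")) numeric(0) else as.numeric(s)
  })
}

#' Write a schedule to trials.csv
#'
#' One row per trial x position: `subject_id`, `trial_index`, `horizon`,
#' `position`, `bandit_type`, `generative_mean`, `sampling_sd`,
#' `initial_samples` (semicolon-joined decimals; empty for the novel bandit).
#'
#' @param schedule A `session_schedule` or named list of them.
#' @param path Output file.
#' @param subject_id Identifier used when a single schedule is given.
#' @export
write_trials_csv <- function(schedule, path, subject_id = "sim") {
  schedules <- if (is.data.frame(schedule)) {
    stats::setNames(list(schedule), subject_id)
  } else schedule
  rows <- lapply(names(schedules), function(sid) {
    s <- schedules[[sid]]
    data.frame(subject_id = sid, trial_index = s$trial_index,
               horizon = s$horizon, position = s$position,
               bandit_type = s$bandit_type,
               generative_mean = sprintf("%.17g", s$generative_mean),
               sampling_sd = sprintf("%.17g", s$sampling_sd),
               initial_samples = fmt_samples(s$initial_samples),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read trials.csv back into schedules
#'
#' @param path File written by [write_trials_csv()].
#' @param config The [task_config()] to attach (schedules carry their config
#'   as an attribute; the CSV stores only the realised trials).
#' @return Named list of `session_schedule` objects keyed by subject.
#' @export
read_trials_csv <- function(path, config = task_config()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(initial_samples = "character"))
  out <- lapply(split(df, df$subject_id), function(s) {
    sched <- data.frame(trial_index = s$trial_index, horizon = s$horizon,
                        position = s$position, bandit_type = s$bandit_type,
                        generative_mean = as.numeric(s$generative_mean),
                        sampling_sd = as.numeric(s$sampling_sd),
                        n_initial = lengths(parse_samples(s$initial_samples)),
                        stringsAsFactors = FALSE)
    sched$initial_samples <- parse_samples(s$initial_samples)
    sched <- sched[order(sched$trial_index, sched$position), ]
    rownames(sched) <- NULL
    structure(sched, class = c("session_schedule", class(sched)),
              config = config)
  })
  out[unique(df$subject_id)]
}

#' Write / read choices.csv
#'
#' Schema: `subject_id`, `trial_index`, `draw_index` (1-based),
#' `choice_position` (0-based), `reward`.
#' @param choices Choice-record data frame.
#' @param path File path.
#' @export
write_choices_csv <- function(choices, path) {
  out <- choices
  out$reward <- sprintf("%.17g", out$reward)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_choices_csv
#' @export
read_choices_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$reward <- as.numeric(df$reward)
  df
}

#' Write per-subject fits to fits.csv
#' @param fits Named list of `fit_result` objects keyed by subject.
#' @param path File path.
#' @export
write_fits_csv <- function(fits, path) {
  rows <- lapply(names(fits), function(sid) {
    f <- fits[[sid]]
    nm <- free_param_names(model_from_label(f$model))
    row <- data.frame(subject_id = sid, model = f$model,
                      stringsAsFactors = FALSE)
    for (p in nm) row[[p]] <- f$params[[p]]
    row$nll <- f$nll
    row$converged <- f$converged
    row
  })
  all_cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) { r[setdiff(all_cols, names(r))] <- NA; r[all_cols] })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write cross-validation scores to cv.csv
#' @param cv A `cv_result`.
#' @param path File path.
#' @export
write_cv_csv <- function(cv, path) {
  if (is.null(rownames(cv$scores))) {
    rownames(cv$scores) <- sprintf("sub%03d", seq_len(nrow(cv$scores)))
  }
  long <- expand.grid(subject_id = rownames(cv$scores),
                      model = colnames(cv$scores),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$mean_heldout_likelihood <- as.vector(cv$scores)
  long$K <- cv$K
  long$seed <- cv$seed
  utils::write.csv(long, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write BMS results to bms.csv
#' @param bms A `bms_result`.
#' @param path File path.
#' @export
write_bms_csv <- function(bms, path) {
  utils::write.csv(as.data.frame(bms), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a task configuration as YAML
#' @param config A [task_config()].
#' @param path File path.
#' @export
write_task_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_task_config
#' @export
read_task_config <- function(path) {
  do.call(task_config, yaml::read_yaml(path))
}

# 32-bit polynomial rolling hash; fingerprints a config string in manifests.
config_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) {
    h <- (h * 31 + b) %% 4294967296  # stays < 2^53: exact in doubles
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a run manifest
#'
#' Records the command, seed, a fingerprint of the configuration, and the
#' package/R versions, as `manifest.json` in the output directory.
#'
#' @param dir Output directory.
#' @param command Subcommand name.
#' @param config List of configuration values used.
#' @param seed Seed used.
#' @export
write_manifest <- function(dir, command, config, seed) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  manifest <- list(
    command = command, seed = seed,
    config_hash = config_hash(as.character(cfg_json)),
    config = config,
    package_version = as.character(utils::packageVersion("explorehorizon")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(file.path(dir, "manifest.json"))
}
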