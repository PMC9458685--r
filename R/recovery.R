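# Recovery simulations: can generative parameters be re-estimated from one
# session's worth of data (parameter recovery), and does cross-validated
# selection identify the generating model (model recovery)?

#' Full-factorial parameter-recovery grid
#'
#' Places `levels` equally spaced values per free parameter across the
#' central 80% of its bound interval and takes the full factorial.  For the
#' seven-parameter winning model (`thompson+eps+eta`) the default four levels
#' give a 4^7 = 16384-cell grid.
#'
#' @param model A [model_spec()].
#' @param levels Levels per parameter (>= 2).
#' @param bounds Bounds list as in [fit_config()].
#' @return A `recovery_grid`: list with `model` (label), `levels`,
#'   `param_levels` (named list) and `cells` (data frame, one row per cell).
#' @export
build_recovery_grid <- function(model, levels = 4L,
                                bounds = default_bounds()) {
  if (levels < 2) stop("levels must be >= 2", call. = FALSE)
  nm <- free_param_names(model)
  param_levels <- lapply(bounds[nm], function(b) {
    span <- b[2] - b[1]
    seq(b[1] + 0.1 * span, b[2] - 0.1 * span, length.out = levels)
  })
  cells <- expand.grid(param_levels, KEEP.OUT.ATTRS = FALSE)
  structure(list(model = model_label(model), levels = as.integer(levels),
                 param_levels = param_levels, cells = cells),
            class = "recovery_grid")
}

#' Parameter recovery over a grid (or subsample)
#'
#' For each cell: simulate one agent playing a fresh seeded session, refit
#' the same model to its first draws, and record generative vs. recovered
#' values.  Fit failures are recorded per cell, not fatal.
#'
#' @param grid A [build_recovery_grid()] result.
#' @param n_cells Optional seeded subsample size; `NULL` runs the full grid.
#' @param task_cfg A [task_config()] for the simulated sessions.
#' @param config A [fit_config()].
#' @param seed Integer seed driving cell subsampling, sessions, simulation
#'   and fitting.
#' @return A `recovery_result`: list with `draws` (long data frame: cell_id,
#'   parameter, generative, recovered), `r` (named Pearson correlations),
#'   `errors` (per-cell messages), `model`.
#' @export
run_parameter_recovery <- function(grid, n_cells = NULL,
                                   task_cfg = task_config(),
                                   config = fit_config(), seed = 1L) {
  model <- model_from_label(grid$model)
  cells <- grid$cells
  seed <- as.integer(seed)
  if (!is.null(n_cells) && n_cells < nrow(cells)) {
    idx <- withr::with_seed(seed, sample.int(nrow(cells), n_cells))
    cells <- cells[idx, , drop = FALSE]
  }
  nm <- names(cells)
  draws <- vector("list", nrow(cells))
  errors <- character(0)
  for (i in seq_len(nrow(cells))) {
    gen <- merge_params(unlist(cells[i, ]))
    sched <- build_schedule(task_cfg, seed = seed + 7L * i)
    sim <- simulate_agent(model, gen, sched, seed = seed + 7L * i + 1L,
                          subject_id = sprintf("cell%05d", i))
    fit <- tryCatch(
      fit_subject(model, first_draws(sim), sched, config = config,
                  seed = seed + 7L * i + 2L),
      error = function(e) e)
    if (inherits(fit, "error")) {
      errors <- c(errors, sprintf("cell %d: %s", i, conditionMessage(fit)))
      next
    }
    draws[[i]] <- data.frame(
      cell_id = i, parameter = nm,
      generative = unlist(cells[i, ], use.names = FALSE),
      recovered = unlist(fit$params[nm], use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  draws <- do.call(rbind, draws)
  r <- vapply(nm, function(p) {
    d <- draws[draws$parameter == p, ]
    if (stats::sd(d$generative) == 0 || stats::sd(d$recovered) == 0) {
      return(NA_real_)  # degenerate subsample: correlation undefined
    }
    stats::cor(d$generative, d$recovered)
  }, numeric(1))
  structure(list(draws = draws, r = r, errors = errors, model = grid$model),
            class = "recovery_result")
}

#' Model-recovery confusion matrix
#'
#' Simulates `n_sim_per_model` agents from each candidate model at
#' mid-bound parameter values, runs K-fold cross-validation over all
#' candidates, and tabulates how often each model wins.
#'
#' @param models List of [model_spec()] candidates.
#' @param n_sim_per_model Simulated agents per generating model (>= 1).
#' @param task_cfg A [task_config()].
#' @param K Cross-validation folds.
#' @param config A [fit_config()].
#' @param seed Integer seed.
#' @param gen_params Optional named list mapping model labels to generating
#'   [param_set()]s; defaults to mid-bound values of each free parameter.
#' @return A `confusion_matrix`: generating x selected matrix of winning
#'   frequencies; rows sum to 1.
#' @export
run_model_recovery <- function(models, n_sim_per_model = 5L,
                               task_cfg = task_config(), K = 6L,
                               config = fit_config(), seed = 1L,
                               gen_params = NULL) {
  stopifnot(n_sim_per_model >= 1)
  labels <- vapply(models, model_label, character(1))
  conf <- matrix(0, length(models), length(models),
                 dimnames = list(labels, labels))
  seed <- as.integer(seed)
  for (gi in seq_along(models)) {
    gen_model <- models[[gi]]
    gp <- if (!is.null(gen_params) && !is.null(gen_params[[labels[gi]]])) {
      gen_params[[labels[gi]]]
    } else {
      nm <- free_param_names(gen_model)
      merge_params(vapply(config$bounds[nm], mean, numeric(1)))
    }
    for (s in seq_len(n_sim_per_model)) {
      sim_seed <- seed + 100L * gi + s
      sched <- build_schedule(task_cfg, seed = sim_seed)
      sim <- simulate_agent(gen_model, gp, sched, seed = sim_seed + 1L,
                            subject_id = "rec")
      cv <- kfold_cv(sim, sched, models, K = K, config = config,
                     seed = sim_seed + 2L)
      win <- select_winning(cv)
      conf[gi, match(as.character(win), labels)] <-
        conf[gi, match(as.character(win), labels)] + 1
    }
  }
  structure(conf / n_sim_per_model, class = c("confusion_matrix", "matrix"))
}
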