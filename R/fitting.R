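# Maximum-likelihood fitting of first-draw choices.
#
# The likelihood only involves each trial's initial posterior, so it is
# evaluated in vectorised form over all trials at once.  Optimisation runs in
# a transformed space (logit for probabilities, log for positive scales) with
# seeded Latin-hypercube multi-starts and box constraints via L-BFGS-B.

PROB_FLOOR <- 1e-12  # guards log() under near-deterministic policies

#' Fitting configuration
#'
#' @param n_restarts Number of seeded Latin-hypercube restarts.
#' @param maxit Iteration cap per restart (L-BFGS-B).
#' @param bounds Named list of `c(lower, upper)` per parameter, natural space.
#'   Defaults: `Q0` within the reward scale, `sigma0` in \[0.1, 20\],
#'   `eps`/`w` in \[0, 1\], `eta`/`gamma` in \[0, 10\], `tau` in \[0.01, 20\].
#' @param converge_tol Best two optima must agree within this many nats for
#'   the fit to be flagged converged.
#' @return A `fit_config`.
#' @export
fit_config <- function(n_restarts = 10L, maxit = 200L,
                       bounds = default_bounds(), converge_tol = 1e-3) {
  stopifnot(n_restarts >= 1, maxit >= 1)
  structure(list(n_restarts = as.integer(n_restarts),
                 maxit = as.integer(maxit), bounds = bounds,
                 converge_tol = converge_tol),
            class = "fit_config")
}

#' Default parameter bounds
#'
#' Scale-based bounds: `Q0` spans the reward scale; the prior SD `sigma0`,
#' the novelty bonus `eta` and the information-bonus weight `gamma` are
#' capped near the width of the reward scale.  Beyond that the likelihood
#' saturates (e.g. once `sigma0` exceeds the reward range, one further unit
#' changes the posterior SD of a sampled bandit by well under 1%), so wider
#' boxes only add structurally non-identifiable volume.
#'
#' @param reward_min,reward_max Reward scale limits (bound `Q0`).
#' @return Named list of `c(lower, upper)`.
#' @export
default_bounds <- function(reward_min = 1, reward_max = 10) {
  list(Q0 = c(reward_min, reward_max),
       sigma0_s = c(0.1, 6), sigma0_l = c(0.1, 6),
       eps_s = c(0, 1), eps_l = c(0, 1),
       eta_s = c(0, 5), eta_l = c(0, 5),
       gamma_s = c(0, 5), gamma_l = c(0, 5),
       tau = c(0.01, 20), w = c(0, 1))
}

# parameter -> transform kind
.TRANSFORM <- c(Q0 = "identity",
                sigma0_s = "log", sigma0_l = "log",
                eps_s = "logit", eps_l = "logit",
                eta_s = "log", eta_l = "log",
                gamma_s = "log", gamma_l = "log",
                tau = "log", w = "logit")

.LOG_FLOOR <- 1e-6  # lower clamp for log-transformed parameters bounded at 0

#' Map parameters to the unconstrained fitting space
#'
#' `eps` and `w` use the logit; `sigma0`, `tau`, `eta` and `gamma` the log
#' (values at a zero lower bound are clamped to 1e-6 first); `Q0` is passed
#' through unchanged.
#'
#' @param values Named numeric vector in natural space.
#' @return Named numeric vector in transformed space.
#' @export
transform_params <- function(values) {
  kind <- .TRANSFORM[names(values)]
  out <- values
  out[kind == "log"] <- log(pmax(values[kind == "log"], .LOG_FLOOR))
  out[kind == "logit"] <- stats::qlogis(values[kind == "logit"])
  out
}

#' Inverse of [transform_params()]
#' @param values Named numeric vector in transformed space.
#' @return Named numeric vector in natural space.
#' @export
untransform_params <- function(values) {
  kind <- .TRANSFORM[names(values)]
  out <- values
  out[kind == "log"] <- exp(values[kind == "log"])
  out[kind == "logit"] <- stats::plogis(values[kind == "logit"])
  out
}

transformed_bounds <- function(names, bounds) {
  lo <- vapply(bounds[names], `[`, numeric(1), 1L)
  hi <- vapply(bounds[names], `[`, numeric(1), 2L)
  kind <- .TRANSFORM[names]
  tlo <- ifelse(kind == "log", log(pmax(lo, .LOG_FLOOR)),
         ifelse(kind == "logit", stats::qlogis(pmax(lo, 1e-6)), lo))
  thi <- ifelse(kind == "log", log(hi),
         ifelse(kind == "logit", stats::qlogis(pmin(hi, 1 - 1e-6)), hi))
  list(lower = stats::setNames(tlo, names),
       upper = stats::setNames(thi, names))
}

# Precompute per-trial arrays used by the vectorised likelihood.
schedule_arrays <- function(schedule) {
  s <- schedule[order(schedule$trial_index, schedule$position), ]
  n <- nrow(s) %/% 3L
  first <- seq(1L, nrow(s), by = 3L)
  list(trial_index = s$trial_index[first],
       horizon = s$horizon[first],
       n_init = matrix(lengths(s$initial_samples), n, 3, byrow = TRUE),
       sum_init = matrix(vapply(s$initial_samples, sum, numeric(1)),
                         n, 3, byrow = TRUE),
       sampling_var = s$sampling_sd[first]^2, n = n)
}

# Initial-posterior means/variances for all trials at once (n x 3 matrices).
posterior_matrices <- function(model, params, arr) {
  long <- arr$horizon == "long"
  sigma0 <- ifelse(long, params$sigma0_l, params$sigma0_s)
  V0 <- sigma0^2
  m0 <- matrix(params$Q0, arr$n, 3)
  if (model$use_novelty) {
    eta <- ifelse(long, params$eta_l, params$eta_s)
    m0 <- m0 + eta * (arr$n_init == 0L)
  }
  prec <- 1 / V0 + arr$n_init / arr$sampling_var
  list(Q = (m0 / V0 + arr$sum_init / arr$sampling_var) / prec, V = 1 / prec)
}

softmax_rows <- function(U) {
  U <- U - apply(U, 1, max)
  E <- exp(U)
  E / rowSums(E)
}

# First-draw choice probabilities for all trials (n x 3 matrix).
choice_prob_matrix <- function(model, params, arr) {
  post <- posterior_matrices(model, params, arr)
  long <- arr$horizon == "long"
  P <- switch(model$core,
    thompson = thompson_probs_matrix(post$Q, post$V),
    ucb = {
      gamma <- ifelse(long, params$gamma_l, params$gamma_s)
      softmax_rows((post$Q + gamma * sqrt(post$V)) / params$tau)
    },
    hybrid = {
      gamma <- ifelse(long, params$gamma_l, params$gamma_s)
      params$w * softmax_rows((post$Q + gamma * sqrt(post$V)) / params$tau) +
        (1 - params$w) * thompson_probs_matrix(post$Q, post$V)
    })
  if (model$use_epsilon) {
    eps <- ifelse(long, params$eps_l, params$eps_s)
    P <- (1 - eps) * P + eps / 3
  }
  P
}

first_draws <- function(choices) {
  choices[choices$draw_index == 1L, , drop = FALSE]
}

#' Negative log-likelihood of first-draw choices
#'
#' Sums `-log P(choice)` over every first draw in `choices` under the given
#' model and parameters; probabilities are floored at 1e-12 before the log.
#' Later draws are ignored: the models are fitted to first draws only.
#'
#' @param model A [model_spec()].
#' @param params A [param_set()].
#' @param choices Choice-record data frame (see [simulate_agent()]).
#' @param schedule The schedule the choices were made on.
#' @return Negative log-likelihood in nats.
#' @export
negative_log_likelihood <- function(model, params, choices, schedule) {
  arr <- schedule_arrays(schedule)
  fd <- first_draws(choices)
  row <- match(fd$trial_index, arr$trial_index)
  if (anyNA(row)) stop("choices reference trials absent from the schedule",
                       call. = FALSE)
  P <- choice_prob_matrix(model, params, arr)
  -sum(log(pmax(P[cbind(row, fd$choice_position + 1L)], PROB_FLOOR)))
}

# Data-driven starting point: epsilon from the low-value pick rate (an
# epsilon-greedy agent picks it on eps/3 of eligible trials), Q0 from the
# observed initial samples, the rest mid-scale.  Finding the interior basin
# from random starts alone needs many more restarts because the likelihood
# is ridge-shaped in (eps, sigma0).
heuristic_start <- function(model, fd, schedule, bounds) {
  info <- trial_info(schedule)
  row <- match(fd$trial_index, info$trial_index)
  chosen_type <- info$type_by_pos[cbind(row, fd$choice_position + 1L)]
  long <- info$horizon[row] == "long"
  vals <- c(Q0 = mean(unlist(schedule$initial_samples)),
            sigma0_s = 2, sigma0_l = 2, gamma_s = 1, gamma_l = 1,
            tau = 1, w = 0.5, eta_s = 1, eta_l = 1, eps_s = 0.1, eps_l = 0.2)
  for (h in c(FALSE, TRUE)) {
    present <- info$has_type[row, "low_value"] & (long == h)
    if (any(present)) {
      f <- mean(chosen_type[present] == "low_value")
      vals[[if (h) "eps_l" else "eps_s"]] <- min(max(3 * f, 0.02), 0.9)
    }
  }
  nm <- free_param_names(model)
  v <- vals[nm]
  for (p in nm) v[p] <- min(max(v[p], bounds[[p]][1]), bounds[[p]][2])
  transform_params(v)
}

# Latin-hypercube starting points (n_restarts x k) in transformed space.
lhs_starts <- function(n, lower, upper) {
  k <- length(lower)
  S <- matrix(0, n, k)
  for (j in seq_len(k)) {
    strata <- (sample.int(n) - stats::runif(n)) / n
    S[, j] <- lower[j] + strata * (upper[j] - lower[j])
  }
  colnames(S) <- names(lower)
  S
}

merge_params <- function(values) {
  do.call(param_set, as.list(values)[intersect(names(values), PARAM_NAMES)])
}

#' Fit a model to one subject's first draws
#'
#' Multi-start bounded maximum likelihood: `n_restarts` L-BFGS-B runs, the
#' first from a data-driven heuristic start (epsilon from the observed
#' low-value pick rate) and the rest from a seeded Latin hypercube over the
#' transformed parameter box; the best optimum is returned.  The fit is
#' flagged converged when the two best optima agree within `converge_tol`
#' nats.
#'
#' @param model A [model_spec()].
#' @param choices Choice records for one subject (first draws are used).
#' @param schedule The session schedule.
#' @param config A [fit_config()].
#' @param seed Integer seed controlling the restarts.
#' @return A `fit_result`: list with `model` (label), `params` (full
#'   [param_set()] at the optimum), `nll`, `n_restarts`, `converged`, and
#'   `optima` (per-restart transformed optima and their nll).
#' @export
fit_subject <- function(model, choices, schedule, config = fit_config(),
                        seed = 1L) {
  fd <- first_draws(choices)
  if (nrow(fd) < 20L) {
    stop("need at least 20 first-draw choices to fit", call. = FALSE)
  }
  arr <- schedule_arrays(schedule)
  row <- match(fd$trial_index, arr$trial_index)
  if (anyNA(row)) stop("choices reference trials absent from the schedule",
                       call. = FALSE)
  idx <- cbind(row, fd$choice_position + 1L)
  nm <- free_param_names(model)
  tb <- transformed_bounds(nm, config$bounds)

  # hot path: avoid name matching and validation inside the objective
  base <- unclass(param_set())
  kind <- .TRANSFORM[nm]
  is_log <- kind == "log"
  is_logit <- kind == "logit"
  objective <- function(theta) {
    v <- theta
    v[is_log] <- exp(theta[is_log])
    v[is_logit] <- stats::plogis(theta[is_logit])
    p <- base
    p[nm] <- v
    P <- choice_prob_matrix(model, p, arr)
    -sum(log(pmax(P[idx], PROB_FLOOR)))
  }

  # forward-difference gradient (one-sided, stepping inward at the bounds);
  # roughly halves the optimiser's per-iteration cost vs central differences
  gradient <- function(theta) {
    f0 <- objective(theta)
    g <- numeric(length(theta))
    for (j in seq_along(theta)) {
      hj <- 1e-6 * max(1, abs(theta[j]))
      if (theta[j] + hj > tb$upper[j]) hj <- -hj
      tj <- theta
      tj[j] <- tj[j] + hj
      g[j] <- (objective(tj) - f0) / hj
    }
    g
  }
  run_optim <- function(start) {
    tryCatch(
      stats::optim(start, objective, gradient, method = "L-BFGS-B",
                   lower = tb$lower, upper = tb$upper,
                   control = list(maxit = config$maxit, factr = 1e9)),
      error = function(e) NULL)
  }
  fits <- withr::with_seed(as.integer(seed), {
    starts <- lhs_starts(config$n_restarts, tb$lower, tb$upper)
    # first restart starts from the data-driven heuristic point
    starts[1, ] <- heuristic_start(model, fd, schedule, config$bounds)
    lapply(seq_len(config$n_restarts), function(r) run_optim(starts[r, ]))
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits)) {
    stop("all ", config$n_restarts, " restarts failed for model ",
         model_label(model), call. = FALSE)
  }
  nlls <- vapply(fits, function(f) f$value, numeric(1))
  best <- which.min(nlls)
  theta <- fits[[best]]$par
  names(theta) <- nm
  sorted <- sort(nlls)
  converged <- length(sorted) >= 2 &&
    (sorted[2] - sorted[1]) <= config$converge_tol
  optima <- as.data.frame(t(vapply(fits, function(f) f$par,
                                   numeric(length(nm)))))
  names(optima) <- nm
  optima$nll <- nlls
  structure(
    list(model = model_label(model),
         params = merge_params(untransform_params(theta)),
         nll = fits[[best]]$value, n_restarts = config$n_restarts,
         converged = converged, optima = optima),
    class = "fit_result")
}
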