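# Choice models: Bayesian belief updating over bandit means plus the
# twelve-member model family.  Three cores -- Thompson sampling, UCB with a
# softmax, and a hybrid mixture of the two -- each optionally extended with
# epsilon-greedy value-free random exploration and/or a novelty bonus for
# options without initial samples.

MODEL_CORES <- c("thompson", "ucb", "hybrid")

#' Specify a member of the model family
#'
#' @param core `"thompson"`, `"ucb"`, or `"hybrid"`.
#' @param use_epsilon Add epsilon-greedy value-free random exploration?
#' @param use_novelty Add a novelty bonus for zero-sample bandits?
#' @return A `model_spec`.
#' @export
model_spec <- function(core = "thompson", use_epsilon = FALSE,
                       use_novelty = FALSE) {
  core <- match.arg(core, MODEL_CORES)
  structure(list(core = core, use_epsilon = isTRUE(use_epsilon),
                 use_novelty = isTRUE(use_novelty)),
            class = "model_spec")
}

#' Canonical label of a model
#' @param model A `model_spec`.
#' @return String like `"thompson+eps+eta"`.
#' @export
model_label <- function(model) {
  paste0(model$core,
         if (model$use_epsilon) "+eps" else "",
         if (model$use_novelty) "+eta" else "")
}

#' Look up a model by label
#' @param label A label produced by [model_label()].
#' @return The matching `model_spec`.
#' @export
model_from_label <- function(label) {
  fam <- enumerate_model_family()
  i <- match(label, vapply(fam, model_label, character(1)))
  if (is.na(i)) stop("unknown model label: ", label, call. = FALSE)
  fam[[i]]
}

#' Enumerate the full model family
#'
#' The three cores crossed with the four heuristic extensions (none,
#' epsilon-greedy, novelty bonus, both), in a stable order.
#'
#' @return List of 12 `model_spec` objects with unique labels.
#' @export
enumerate_model_family <- function() {
  variants <- list(c(FALSE, FALSE), c(TRUE, FALSE),
                   c(FALSE, TRUE), c(TRUE, TRUE))  # none, +eps, +eta, +eps+eta
  out <- list()
  for (core in MODEL_CORES) {
    for (v in variants) {
      out[[length(out) + 1L]] <- model_spec(core, v[1], v[2])
    }
  }
  out
}

PARAM_NAMES <- c("Q0", "sigma0_s", "sigma0_l", "eps_s", "eps_l",
                 "eta_s", "eta_l", "gamma_s", "gamma_l", "tau", "w")

#' Full parameter set
#'
#' All model parameters live in one named list; a given `model_spec` only
#' reads the subset relevant to it (see [free_param_names()]).  `sigma0`,
#' `eps`, `eta` and `gamma` are horizon-specific (`_s` short, `_l` long);
#' `Q0`, `tau` and `w` are shared across horizons.
#'
#' @param Q0 Prior mean (reward units).
#' @param sigma0_s,sigma0_l Prior SD per horizon (> 0).
#' @param eps_s,eps_l Epsilon-greedy lapse rate per horizon, in \[0, 1\].
#' @param eta_s,eta_l Novelty bonus per horizon (>= 0), added to the prior
#'   mean of bandits with no initial samples.
#' @param gamma_s,gamma_l Information-bonus weight per horizon (UCB/hybrid).
#' @param tau Softmax temperature (> 0; UCB/hybrid).
#' @param w Hybrid mixture weight in \[0, 1\] (1 = pure UCB).
#' @return A `param_set`.
#' @export
param_set <- function(Q0 = 5, sigma0_s = 2, sigma0_l = 2,
                      eps_s = 0, eps_l = 0, eta_s = 0, eta_l = 0,
                      gamma_s = 1, gamma_l = 1, tau = 1, w = 0.5) {
  p <- list(Q0 = Q0, sigma0_s = sigma0_s, sigma0_l = sigma0_l,
            eps_s = eps_s, eps_l = eps_l, eta_s = eta_s, eta_l = eta_l,
            gamma_s = gamma_s, gamma_l = gamma_l, tau = tau, w = w)
  stopifnot(sigma0_s > 0, sigma0_l > 0,
            eps_s >= 0, eps_s <= 1, eps_l >= 0, eps_l <= 1,
            eta_s >= 0, eta_l >= 0, tau > 0, w >= 0, w <= 1)
  structure(p, class = "param_set")
}

#' Free parameters of a model
#' @param model A `model_spec`.
#' @return Character vector of the parameter names the model actually fits.
#' @export
free_param_names <- function(model) {
  nm <- c("Q0", "sigma0_s", "sigma0_l")
  if (model$core %in% c("ucb", "hybrid")) nm <- c(nm, "gamma_s", "gamma_l", "tau")
  if (model$core == "hybrid") nm <- c(nm, "w")
  if (model$use_epsilon) nm <- c(nm, "eps_s", "eps_l")
  if (model$use_novelty) nm <- c(nm, "eta_s", "eta_l")
  nm
}

hparam <- function(params, name, horizon) {
  params[[paste0(name, if (horizon == "short") "_s" else "_l")]]
}

#' Initial posterior over the three bandits of a trial
#'
#' Every bandit starts at the prior `(Q0, sigma0^2)` for the trial's horizon;
#' under a novelty model, bandits with no initial samples start at
#' `(Q0 + eta, sigma0^2)`.  Each initial sample is then folded in by the
#' conjugate Gaussian update with known sampling variance.
#'
#' @param params A [param_set()].
#' @param trial A `trial_spec`.
#' @param model A [model_spec()].
#' @return A `posterior_state`: list with numeric `Q` (posterior means) and
#'   `V` (posterior variances), one entry per position 0..2.
#' @export
init_posterior <- function(params, trial, model = model_spec("thompson")) {
  horizon <- attr(trial, "horizon")
  sigma0 <- hparam(params, "sigma0", horizon)
  if (!is.numeric(sigma0) || sigma0 <= 0) {
    stop("sigma0 must be positive", call. = FALSE)
  }
  m0 <- rep(params$Q0, 3)
  if (model$use_novelty) {
    eta <- hparam(params, "eta", horizon)
    m0 <- m0 + eta * (trial$n_initial == 0L)
  }
  V0 <- rep(sigma0^2, 3)
  sv <- trial$sampling_sd[1]^2
  n <- vapply(trial$initial_samples, length, integer(1))
  s <- vapply(trial$initial_samples, sum, numeric(1))
  prec <- 1 / V0 + n / sv
  structure(list(Q = (m0 / V0 + s / sv) / prec, V = 1 / prec),
            class = "posterior_state")
}

#' Conjugate Gaussian posterior update for one observed reward
#'
#' Precision-weighted update of the chosen bandit only; the other bandits'
#' beliefs are untouched.
#'
#' @param state A `posterior_state`.
#' @param bandit_position 0-based position of the sampled bandit.
#' @param reward Observed reward.
#' @param sampling_var Known sampling variance (> 0).
#' @return Updated `posterior_state`.
#' @export
update_posterior <- function(state, bandit_position, reward, sampling_var) {
  if (!is.numeric(sampling_var) || sampling_var <= 0) {
    stop("sampling_var must be positive", call. = FALSE)
  }
  i <- bandit_position + 1L
  prec <- 1 / state$V[i] + 1 / sampling_var
  state$Q[i] <- (state$Q[i] / state$V[i] + reward / sampling_var) / prec
  state$V[i] <- 1 / prec
  state
}

#' Thompson-sampling choice probabilities
#'
#' `P(i)` is the probability that an independent draw from bandit `i`'s
#' posterior `N(Q_i, V_i)` exceeds draws from the other two posteriors.  The
#' two pairwise differences are jointly Gaussian, so `P(i)` is evaluated
#' exactly as a bivariate-normal orthant probability (see [pbvn_upper()]);
#' this stays accurate for arbitrary posterior variance ratios, where
#' fixed-node quadrature of the product of CDFs does not.  Stochasticity
#' scales with posterior uncertainty and the rule has no temperature
#' parameter.
#'
#' @param state A `posterior_state` with finite `Q`, positive `V`.
#' @return Probability triple summing to 1.
#' @export
thompson_choice_probs <- function(state) {
  if (!all(is.finite(state$Q)) || !all(is.finite(state$V)) ||
      any(state$V <= 0)) {
    stop("posterior state must be finite with positive variances",
         call. = FALSE)
  }
  drop(thompson_probs_matrix(matrix(state$Q, 1), matrix(state$V, 1)))
}

# Vectorised Thompson probabilities: Q, V are n x 3 matrices; returns n x 3.
# P(i) = P(X_i - X_j > 0, X_i - X_k > 0); the differences are bivariate
# normal with correlation V_i / sqrt((V_i + V_j)(V_i + V_k)).  All three
# arms are evaluated in one stacked orthant-probability call.
thompson_probs_matrix <- function(Q, V) {
  n <- nrow(Q)
  j <- c(2, 1, 1); k <- c(3, 3, 2)
  Vi <- c(V[, 1], V[, 2], V[, 3])
  Qi <- c(Q[, 1], Q[, 2], Q[, 3])
  sj <- sqrt(Vi + c(V[, j[1]], V[, j[2]], V[, j[3]]))
  sk <- sqrt(Vi + c(V[, k[1]], V[, k[2]], V[, k[3]]))
  h <- (c(Q[, j[1]], Q[, j[2]], Q[, j[3]]) - Qi) / sj
  kk <- (c(Q[, k[1]], Q[, k[2]], Q[, k[3]]) - Qi) / sk
  P <- matrix(pbvn_upper(h, kk, Vi / (sj * sk)), n, 3)
  P / rowSums(P)  # exact up to ~1e-14; renormalise the residual away
}

#' UCB choice probabilities
#'
#' Each bandit's utility is its posterior mean plus an information bonus
#' proportional to the posterior SD, `U_i = Q_i + gamma * sqrt(V_i)`; choice
#' probabilities are `softmax(U / tau)`.
#'
#' @param state A `posterior_state`.
#' @param gamma_h Information-bonus weight for the current horizon.
#' @param tau Softmax temperature (> 0).
#' @return Probability triple summing to 1.
#' @export
ucb_choice_probs <- function(state, gamma_h, tau) {
  if (!is.numeric(tau) || tau <= 0) stop("tau must be positive", call. = FALSE)
  u <- (state$Q + gamma_h * sqrt(state$V)) / tau
  u <- u - max(u)
  e <- exp(u)
  e / sum(e)
}

#' Hybrid choice probabilities
#'
#' A probability mixture of the UCB and Thompson rules:
#' `P = w * P_UCB + (1 - w) * P_Thompson`.
#'
#' @inheritParams ucb_choice_probs
#' @param w Mixture weight in \[0, 1\]; 1 recovers UCB, 0 recovers Thompson.
#' @return Probability triple summing to 1.
#' @export
hybrid_choice_probs <- function(state, gamma_h, tau, w) {
  stopifnot(w >= 0, w <= 1)
  w * ucb_choice_probs(state, gamma_h, tau) +
    (1 - w) * thompson_choice_probs(state)
}

#' Mix in epsilon-greedy value-free random exploration
#'
#' With probability `eps` the agent ignores all values and picks uniformly:
#' `P' = (1 - eps) * P + eps / 3`.
#'
#' @param probs Probability triple summing to 1.
#' @param eps_h Lapse rate in \[0, 1\].
#' @return Probability triple summing to 1.
#' @export
apply_epsilon <- function(probs, eps_h) {
  if (!is.numeric(eps_h) || eps_h < 0 || eps_h > 1) {
    stop("eps must be in [0, 1]", call. = FALSE)
  }
  (1 - eps_h) * probs + eps_h / 3
}

core_probs <- function(model, params, state, horizon) {
  switch(model$core,
         thompson = thompson_choice_probs(state),
         ucb = ucb_choice_probs(state, hparam(params, "gamma", horizon),
                                params$tau),
         hybrid = hybrid_choice_probs(state, hparam(params, "gamma", horizon),
                                      params$tau, params$w))
}

#' First-draw choice probabilities of a model on a trial
#'
#' Composes the pipeline: initial posterior (with novelty bonus if the model
#' uses one), the core choice rule, and the epsilon-greedy mixture if the
#' model uses one.  Horizon-specific parameters are selected by the trial's
#' horizon.
#'
#' @param model A [model_spec()].
#' @param params A [param_set()].
#' @param trial A `trial_spec`.
#' @param state Optional `posterior_state` to use instead of the initial one
#'   (for draws after the first).
#' @return Probability triple summing to 1.
#' @export
choice_probs <- function(model, params, trial, state = NULL) {
  horizon <- attr(trial, "horizon")
  if (is.null(state)) state <- init_posterior(params, trial, model)
  p <- core_probs(model, params, state, horizon)
  if (model$use_epsilon) p <- apply_epsilon(p, hparam(params, "eps", horizon))
  p
}

#' Simulate an agent playing a session
#'
#' For each trial the agent makes 1 (short horizon) or 6 (long horizon)
#' draws.  The first draw uses the initial posterior; later draws fold
#' observed rewards into the posterior of the chosen bandit and reuse the
#' same choice policy.
#'
#' @param model A [model_spec()].
#' @param params A [param_set()].
#' @param schedule A [build_schedule()] result.
#' @param seed Integer seed; output is a pure function of the inputs.
#' @param subject_id Identifier stamped on every record.
#' @return A data frame of choice records: `subject_id`, `trial_index`,
#'   `draw_index` (1-based), `choice_position` (0-based), `reward`.
#' @export
simulate_agent <- function(model, params, schedule, seed = 1L,
                           subject_id = "sim") {
  config <- attr(schedule, "config")
  trial_ids <- unique(schedule$trial_index)
  out <- vector("list", length(trial_ids))
  withr::with_seed(as.integer(seed), {
    for (k in seq_along(trial_ids)) {
      trial <- get_trial(schedule, trial_ids[k])
      horizon <- attr(trial, "horizon")
      n_draws <- horizon_draws(horizon)
      sv <- trial$sampling_sd[1]^2
      state <- init_posterior(params, trial, model)
      choices <- integer(n_draws)
      rewards <- numeric(n_draws)
      for (d in seq_len(n_draws)) {
        p <- choice_probs(model, params, trial, state = state)
        ch <- sample.int(3L, 1L, prob = p) - 1L
        r <- draw_reward(trial, ch)
        choices[d] <- ch
        rewards[d] <- r
        if (d < n_draws) state <- update_posterior(state, ch, r, sv)
      }
      out[[k]] <- data.frame(
        subject_id = subject_id, trial_index = trial_ids[k],
        draw_index = seq_len(n_draws), choice_position = choices,
        reward = rewards, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}
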