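# Model comparison: K-fold cross-validated held-out likelihood per subject
# and model, followed by random-effects Bayesian model selection (variational
# Dirichlet posterior over model frequencies, exceedance probabilities by
# Monte-Carlo Dirichlet sampling).

#' K-fold cross-validated held-out likelihood
#'
#' Each subject's first-draw trials are partitioned into K folds, stratified
#' by horizon so that every training set constrains both horizons' parameter
#' sets.  Each model is fitted on K-1 folds and evaluated on the held-out
#' fold; the per-subject score of a model is the geometric mean of the
#' predictive probabilities of all held-out first draws.
#'
#' @param choices Choice records for one or more subjects.
#' @param schedule A single shared `session_schedule`, or a named list of
#'   schedules keyed by `subject_id`.
#' @param models List of [model_spec()] objects to compare.
#' @param K Number of folds (>= 2); if K does not divide the per-horizon
#'   trial count a warning is issued and folds are made near-equal.
#' @param config A [fit_config()].
#' @param seed Integer seed (fold assignment and fit restarts).
#' @return A `cv_result`: list with `scores` (subject x model matrix of mean
#'   held-out likelihoods), `n_trials` (per subject), `folds` (per-subject
#'   fold assignment), `K`, `seed`.
#' @export
kfold_cv <- function(choices, schedule, models, K = 6L,
                     config = fit_config(), seed = 1L) {
  stopifnot(K >= 2)
  K <- as.integer(K)
  labels <- vapply(models, model_label, character(1))
  subjects <- unique(choices$subject_id)
  scores <- matrix(NA_real_, length(subjects), length(models),
                   dimnames = list(subjects, labels))
  n_trials <- stats::setNames(integer(length(subjects)), subjects)
  folds_out <- list()

  for (si in seq_along(subjects)) {
    sid <- subjects[si]
    sched <- if (is.data.frame(schedule)) schedule else schedule[[sid]]
    sub <- first_draws(choices[choices$subject_id == sid, , drop = FALSE])
    arr <- schedule_arrays(sched)
    row <- match(sub$trial_index, arr$trial_index)
    horizon <- arr$horizon[row]
    per_h <- table(horizon)
    if (any(per_h %% K != 0)) {
      warning("K = ", K, " does not divide the per-horizon trial count; ",
              "folds will be near-equal", call. = FALSE)
    }
    fold <- integer(nrow(sub))
    withr::with_seed(as.integer(seed) + si - 1L, {
      for (h in unique(horizon)) {
        ih <- which(horizon == h)
        fold[ih] <- rep_len(seq_len(K), length(ih))[sample.int(length(ih))]
      }
    })
    folds_out[[sid]] <- data.frame(trial_index = sub$trial_index, fold = fold)
    n_trials[si] <- nrow(sub)

    logp <- matrix(NA_real_, nrow(sub), length(models))
    for (mi in seq_along(models)) {
      for (f in seq_len(K)) {
        held <- fold == f
        fit <- fit_subject(models[[mi]], sub[!held, , drop = FALSE], sched,
                           config = config,
                           seed = as.integer(seed) + 1000L * f + si)
        P <- choice_prob_matrix(models[[mi]], fit$params, arr)
        p_held <- P[cbind(row[held], sub$choice_position[held] + 1L)]
        logp[held, mi] <- log(pmax(p_held, PROB_FLOOR))
      }
      scores[si, mi] <- exp(mean(logp[, mi]))
    }
  }
  structure(list(scores = scores, n_trials = n_trials, folds = folds_out,
                 K = K, seed = as.integer(seed)),
            class = "cv_result")
}

#' Winning model of a cross-validation
#'
#' The model with the highest subject-averaged held-out likelihood.  Exact
#' ties are resolved lexicographically and flagged via the `tie` attribute.
#'
#' @param cv A `cv_result`.
#' @return The winning model label (with attribute `tie`).
#' @export
select_winning <- function(cv) {
  m <- colMeans(cv$scores)
  top <- which(m == max(m))
  label <- sort(colnames(cv$scores)[top])[1]
  structure(label, tie = length(top) > 1L)
}

#' Paired t-test between two models' held-out likelihoods
#'
#' @param cv A `cv_result` with at least 3 subjects.
#' @param model_a,model_b Model labels (columns of `cv$scores`).
#' @return List with `t`, `df` (= n - 1), `p`, and the mean difference.
#' @export
paired_model_comparison <- function(cv, model_a, model_b) {
  a <- cv$scores[, model_a]
  b <- cv$scores[, model_b]
  if (length(a) < 3) stop("need at least 3 subjects", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0) {
    stop("zero variance of paired differences", call. = FALSE)
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate))
}

#' Per-subject log evidence from a cross-validation result
#'
#' The cross-validation estimate of model evidence: the summed held-out log
#' predictive probability, i.e. `n_trials * log(geometric-mean likelihood)`.
#'
#' @param cv A `cv_result`.
#' @return Subject x model matrix of log evidences (nats).
#' @export
cv_log_evidence <- function(cv) {
  log(cv$scores) * cv$n_trials
}

#' Random-effects Bayesian model selection
#'
#' Variational inference on the Dirichlet posterior over population model
#' frequencies (uniform Dirichlet prior, `alpha0 = 1` per model): posterior
#' model responsibilities combine each subject's log evidence with the
#' digamma of the current concentrations, and the concentrations accumulate
#' the responsibilities, iterated to `max |delta alpha| < 1e-6`.  Exceedance
#' probabilities (the posterior probability that each model is the most
#' frequent) are estimated from Dirichlet Monte-Carlo samples.
#'
#' @param log_evidence Finite subject x model matrix of log evidences; column
#'   names are used as model labels.
#' @param n_samples Dirichlet samples for the exceedance estimate (>= 1e5 by
#'   default).
#' @param seed Integer seed for the sampling step.
#' @param alpha0 Prior concentration per model.
#' @return A `bms_result` data frame: `model`, `alpha`, `expected_freq`,
#'   `exceedance_prob`.
#' @export
bms_exceedance <- function(log_evidence, n_samples = 1e5, seed = 1L,
                           alpha0 = 1) {
  log_evidence <- as.matrix(log_evidence)
  if (!all(is.finite(log_evidence))) {
    stop("log evidences must be finite", call. = FALSE)
  }
  if (ncol(log_evidence) < 2) stop("need at least 2 models", call. = FALSE)
  M <- ncol(log_evidence)
  labels <- colnames(log_evidence)
  if (is.null(labels)) labels <- paste0("model", seq_len(M))
  alpha <- rep(alpha0, M)
  for (iter in 1:10000) {
    lu <- sweep(log_evidence, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lu <- lu - apply(lu, 1, max)
    u <- exp(lu)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < 1e-6) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  ep <- withr::with_seed(as.integer(seed), {
    g <- matrix(stats::rgamma(n_samples * M, shape = rep(alpha, each = n_samples)),
                n_samples, M)
    tabulate(max.col(g, ties.method = "first"), nbins = M) / n_samples
  })
  structure(data.frame(model = labels, alpha = alpha,
                       expected_freq = alpha / sum(alpha),
                       exceedance_prob = ep, stringsAsFactors = FALSE),
            class = c("bms_result", "data.frame"))
}
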