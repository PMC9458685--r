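# Behavioural signatures and group statistics: bandit-choice frequencies,
# familiarity / expected value of the chosen option, reward trajectories,
# split-plot (mixed-design) ANOVA, symptom correlations, and the clinical
# cutoff split.

schedule_for <- function(schedule, sid) {
  if (is.data.frame(schedule)) schedule else schedule[[sid]]
}

#' First-draw behavioural metrics
#'
#' For every subject and horizon (the short horizon's single draw is compared
#' to the long horizon's first draw): the frequency of choosing the
#' high-value, low-value and novel bandit -- each conditioned on trials where
#' that bandit is present -- plus the mean familiarity (number of initial
#' samples) and mean expected value (mean of initial samples) of the chosen
#' bandit, and mean rewards.  Expected value is undefined for a chosen novel
#' bandit; such draws are excluded from `mean_expected_value`.
#'
#' @param choices Choice records (one or more subjects).
#' @param schedule Shared `session_schedule` or named list per subject.
#' @return Data frame, one row per subject x horizon, with columns
#'   `freq_high_value`, `freq_low_value`, `freq_novel`, `mean_familiarity`,
#'   `mean_expected_value`, `mean_reward_first_draw`, `mean_reward_all_draws`.
#' @export
compute_first_draw_metrics <- function(choices, schedule) {
  subjects <- unique(choices$subject_id)
  out <- list()
  for (sid in subjects) {
    sched <- schedule_for(schedule, sid)
    sub <- choices[choices$subject_id == sid, , drop = FALSE]
    fd <- first_draws(sub)
    info <- trial_info(sched)
    row <- match(fd$trial_index, info$trial_index)
    if (anyNA(row)) stop("choices reference unknown trials", call. = FALSE)
    chosen_type <- info$type_by_pos[cbind(row, fd$choice_position + 1L)]
    chosen_fam <- info$n_init[cbind(row, fd$choice_position + 1L)]
    chosen_ev <- info$mean_init[cbind(row, fd$choice_position + 1L)]
    is_high <- fd$choice_position == info$high_value[row]
    for (h in c("short", "long")) {
      ih <- info$horizon[row] == h
      all_h <- sub$trial_index %in% info$trial_index[info$horizon == h]
      freq_present <- function(type, chosen) {
        present <- info$has_type[row, type] & ih
        if (!any(present)) return(NA_real_)
        mean(chosen[present])
      }
      out[[length(out) + 1L]] <- data.frame(
        subject_id = sid, horizon = h,
        freq_high_value = mean(is_high[ih]),
        freq_low_value = freq_present("low_value", chosen_type == "low_value"),
        freq_novel = freq_present("novel", chosen_type == "novel"),
        mean_familiarity = mean(chosen_fam[ih]),
        mean_expected_value = mean(chosen_ev[ih], na.rm = TRUE),
        mean_reward_first_draw = mean(fd$reward[ih]),
        mean_reward_all_draws = mean(sub$reward[all_h]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Per-trial lookup tables used by the behavioural metrics.
trial_info <- function(schedule) {
  s <- schedule[order(schedule$trial_index, schedule$position), ]
  n <- nrow(s) %/% 3L
  first <- seq(1L, nrow(s), by = 3L)
  type_by_pos <- matrix(s$bandit_type, n, 3, byrow = TRUE)
  n_init <- matrix(lengths(s$initial_samples), n, 3, byrow = TRUE)
  means <- vapply(s$initial_samples, function(x) {
    if (length(x)) mean(x) else NA_real_
  }, numeric(1))
  maxs <- vapply(s$initial_samples, function(x) {
    if (length(x)) max(x) else -Inf
  }, numeric(1))
  mean_init <- matrix(means, n, 3, byrow = TRUE)
  # high-value bandit: max initial-sample mean, ties to the lowest position
  hv_means <- mean_init
  hv_means[is.na(hv_means)] <- -Inf
  high_value <- max.col(hv_means, ties.method = "first") - 1L
  has_type <- vapply(BANDIT_TYPES$label,
                     function(tp) rowSums(type_by_pos == tp) > 0,
                     logical(n))
  colnames(has_type) <- BANDIT_TYPES$label
  list(trial_index = s$trial_index[first], horizon = s$horizon[first],
       type_by_pos = type_by_pos, n_init = n_init, mean_init = mean_init,
       max_init = apply(matrix(maxs, n, 3, byrow = TRUE), 1, max),
       high_value = high_value, has_type = has_type)
}

#' Classify long-horizon first draws as exploit or explore
#'
#' A first draw is exploitative iff it picks the high-value bandit (the one
#' with the highest mean of initial samples); any other choice is
#' exploratory.
#'
#' @param choices Choice records.
#' @param schedule Shared `session_schedule` or named list per subject.
#' @return Data frame: `subject_id`, `trial_index`, `class`
#'   (`"exploit"`/`"explore"`) for every long-horizon trial.
#' @export
classify_explore_exploit <- function(choices, schedule) {
  subjects <- unique(choices$subject_id)
  out <- list()
  for (sid in subjects) {
    sched <- schedule_for(schedule, sid)
    info <- trial_info(sched)
    fd <- first_draws(choices[choices$subject_id == sid, , drop = FALSE])
    row <- match(fd$trial_index, info$trial_index)
    keep <- info$horizon[row] == "long"
    out[[length(out) + 1L]] <- data.frame(
      subject_id = sid, trial_index = fd$trial_index[keep],
      class = ifelse(fd$choice_position[keep] == info$high_value[row][keep],
                     "exploit", "explore"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Reward trajectories in the long horizon
#'
#' Per subject, long-horizon trials are split by the first-draw class
#' (explore vs. exploit) and the mean reward increase -- obtained reward
#' minus the highest initial sample shown on that trial -- is computed for
#' each of the six draws.
#'
#' @param choices Choice records.
#' @param schedule Shared `session_schedule` or named list per subject.
#' @return Data frame: `subject_id`, `class`, `draw_index`,
#'   `mean_reward_increase`.
#' @export
reward_trajectory <- function(choices, schedule) {
  cls <- classify_explore_exploit(choices, schedule)
  subjects <- unique(choices$subject_id)
  out <- list()
  for (sid in subjects) {
    sched <- schedule_for(schedule, sid)
    info <- trial_info(sched)
    sub <- choices[choices$subject_id == sid, , drop = FALSE]
    ci <- cls[cls$subject_id == sid, ]
    sub <- sub[sub$trial_index %in% ci$trial_index, , drop = FALSE]
    sub$class <- ci$class[match(sub$trial_index, ci$trial_index)]
    sub$increase <- sub$reward -
      info$max_init[match(sub$trial_index, info$trial_index)]
    agg <- stats::aggregate(increase ~ class + draw_index, data = sub, FUN = mean)
    out[[length(out) + 1L]] <- data.frame(
      subject_id = sid, class = agg$class, draw_index = agg$draw_index,
      mean_reward_increase = agg$increase, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Mixed-design (split-plot) ANOVA
#'
#' One between-subject factor and one within-subject factor, classical
#' split-plot sums of squares with weighted (proportional-frequency) means;
#' every subject contributes all within levels, so main effects and the
#' interaction decompose orthogonally even with unequal group sizes.
#' Effect sizes are partial eta squared, `SS_effect / (SS_effect +
#' SS_error)` with each effect's own error term.
#'
#' @param values Numeric matrix or data frame, one row per subject, one
#'   column per within level (complete cases only).
#' @param groups Between-subject factor, one entry per subject; every group
#'   needs at least 2 subjects.
#' @return An `anova_table` data frame: `effect` (between / within /
#'   interaction), `F`, `df1`, `df2`, `p`, `partial_eta_sq`.
#' @export
mixed_anova <- function(values, groups) {
  X <- as.matrix(values)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("every group needs at least 2 subjects", call. = FALSE)
  }
  if (ncol(X) < 2) stop("need at least 2 within levels", call. = FALSE)
  if (anyNA(X)) stop("values must be complete", call. = FALSE)
  N <- nrow(X); a <- nlevels(groups); b <- ncol(X)
  GM <- mean(X)
  subj_mean <- rowMeans(X)
  grp_mean <- tapply(subj_mean, groups, mean)
  n_j <- as.vector(table(groups))
  col_mean <- colMeans(X)
  cell_mean <- apply(X, 2, function(col) tapply(col, groups, mean))  # a x b

  ss_A <- b * sum(n_j * (grp_mean - GM)^2)
  ss_SwA <- b * sum((subj_mean - grp_mean[groups])^2)
  ss_B <- N * sum((col_mean - GM)^2)
  dev <- sweep(sweep(cell_mean, 1, grp_mean), 2, col_mean) + GM
  ss_AB <- sum(n_j * dev^2)
  ss_total <- sum((X - GM)^2)
  ss_BxS <- ss_total - ss_A - ss_SwA - ss_B - ss_AB

  eff <- function(effect, ss_e, df1, ss_err, df2) {
    if (ss_e <= 1e-300) {
      F <- 0; p <- 1
    } else if (ss_err <= 1e-300) {
      F <- Inf; p <- 0
    } else {
      F <- (ss_e / df1) / (ss_err / df2)
      p <- stats::pf(F, df1, df2, lower.tail = FALSE)
    }
    data.frame(effect = effect, F = F, df1 = df1, df2 = df2, p = p,
               partial_eta_sq = if (ss_e + ss_err > 0) ss_e / (ss_e + ss_err)
                                else 0,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    eff("between", ss_A, a - 1, ss_SwA, N - a),
    eff("within", ss_B, b - 1, ss_BxS, (N - a) * (b - 1)),
    eff("interaction", ss_AB, (a - 1) * (b - 1), ss_BxS, (N - a) * (b - 1)))
  structure(out, class = c("anova_table", "data.frame"))
}

#' Bonferroni correction
#' @param p P-value(s).
#' @param n Number of tests in the family.
#' @return `min(1, p * n)` elementwise.
#' @export
bonferroni <- function(p, n) pmin(1, p * n)

#' Bivariate and partial Pearson correlation with a symptom score
#'
#' The partial correlation residualises both variables on the covariates
#' (with intercept) by least squares and correlates the residuals;
#' `df = n - 2 - k` for `k` covariates.
#'
#' @param param Per-subject parameter values (e.g. epsilon averaged across
#'   horizons).
#' @param score Per-subject symptom scores.
#' @param covariates Optional data frame / matrix of covariates (e.g. age,
#'   IQ).
#' @return List with `r`, `p`, `df` (bivariate) and -- when covariates are
#'   given -- `partial_r`, `partial_p`, `partial_df`.
#' @export
correlate_with_symptoms <- function(param, score, covariates = NULL) {
  n <- length(param)
  stopifnot(length(score) == n)
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n < k + 3L) stop("need n >= covariates + 3", call. = FALSE)
  if (stats::sd(param) == 0 || stats::sd(score) == 0) {
    stop("zero variance input", call. = FALSE)
  }
  r <- stats::cor(param, score)
  rp <- function(r, df) {
    r <- min(max(r, -1), 1)
    if (abs(r) >= 1) return(0)
    t <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(abs(t), df, lower.tail = FALSE)
  }
  out <- list(r = r, p = rp(r, n - 2L), df = n - 2L)
  if (k > 0) {
    Z <- cbind(1, as.matrix(covariates))
    res <- function(y) stats::lsfit(Z, y, intercept = FALSE)$residuals
    pr <- stats::cor(res(param), res(score))
    out$partial_r <- pr
    out$partial_df <- n - 2L - k
    out$partial_p <- rp(pr, n - 2L - k)
  }
  out
}

#' Clinical cutoff split analysis
#'
#' Splits subjects at `score >= cutoff` into very-elevated vs. below-cutoff
#' groups, runs a mixed ANOVA (score group x horizon) on the supplied
#' per-horizon parameter values, pairwise Welch t-tests per horizon with
#' Bonferroni correction over the horizons tested, and (optionally) compares
#' mean total points per horizon between groups.
#'
#' @param values Subject x horizon matrix/data frame of the parameter (e.g.
#'   epsilon), columns named by horizon.
#' @param scores Per-subject symptom scores (T-score-like scale).
#' @param cutoff Clinical cutoff (default 70).
#' @param points Optional subject x horizon matrix of total points earned.
#' @return List with `n_high`, `n_low`, `anova`, `pairwise` (per-horizon t,
#'   df, p, p_bonferroni), and `points` (group means and t-tests per horizon)
#'   when `points` is supplied.
#' @export
clinical_split_analysis <- function(values, scores, cutoff = 70,
                                    points = NULL) {
  X <- as.matrix(values)
  high <- scores >= cutoff
  if (sum(high) < 2 || sum(!high) < 2) {
    stop("clinical split needs at least 2 subjects on each side of the cutoff",
         call. = FALSE)
  }
  grp <- factor(ifelse(high, "high", "low"), levels = c("high", "low"))
  pair <- lapply(colnames(X), function(h) {
    tt <- stats::t.test(X[high, h], X[!high, h])
    data.frame(horizon = h, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               mean_high = mean(X[high, h]), mean_low = mean(X[!high, h]),
               stringsAsFactors = FALSE)
  })
  pair <- do.call(rbind, pair)
  pair$p_bonferroni <- bonferroni(pair$p, nrow(pair))
  out <- list(n_high = sum(high), n_low = sum(!high),
              anova = mixed_anova(X, grp), pairwise = pair)
  if (!is.null(points)) {
    P <- as.matrix(points)
    pts <- lapply(colnames(P), function(h) {
      tt <- stats::t.test(P[high, h], P[!high, h])
      data.frame(horizon = h, mean_high = mean(P[high, h]),
                 mean_low = mean(P[!high, h]), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 stringsAsFactors = FALSE)
    })
    out$points <- do.call(rbind, pts)
  }
  out
}
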