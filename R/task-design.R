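# Task design: the three-option horizon bandit ("apple gathering") task.
#
# Each trial presents three bandits drawn without repetition from four types
# that differ in how many initial samples are shown (3 / 1 / 0) and in their
# generative mean (standard vs. deliberately low).  A trial allows either one
# draw (short horizon) or six draws (long horizon).

BANDIT_TYPES <- data.frame(
  label      = c("certain_standard", "standard", "novel", "low_value"),
  n_initial  = c(3L, 1L, 0L, 1L),
  mean_class = c("standard", "standard", "standard", "low"),
  stringsAsFactors = FALSE
)

# The four admissible type triples: each leaves one of the four types out.
bandit_type_triples <- function() {
  lab <- BANDIT_TYPES$label
  lapply(seq_along(lab), function(i) lab[-i])
}

#' Task configuration
#'
#' Bundles the generative settings of the bandit task: the reward scale
#' ("apple size", clipped to `[reward_min, reward_max]`), the range from which
#' per-trial standard generative means are drawn, the offset that puts the
#' low-value bandit below every standard bandit, the shared sampling standard
#' deviation, and the session length.
#'
#' Defaults place rewards on a 1-10 scale with standard means uniform on
#' \[4.5, 7.5\], the low mean 2 units below the smallest standard mean of the
#' trial, and a sampling SD of 0.8, so the low-value bandit is unambiguously
#' the worst option on every trial.
#'
#' @param reward_min,reward_max Reward bounds (rewards are clipped to these).
#' @param standard_mean_low,standard_mean_high Uniform bounds for standard
#'   generative means, re-drawn independently per trial and bandit.
#' @param low_value_offset Positive offset subtracted from the smallest
#'   standard mean on a trial to obtain the low-value mean.
#' @param sampling_sd Positive reward noise SD, shared by all bandits.
#' @param n_trials Session length; must be divisible by 8
#'   (2 horizons x 4 type triples).
#' @return An object of class `task_config`.
#' @export
task_config <- function(reward_min = 1, reward_max = 10,
                        standard_mean_low = 4.5, standard_mean_high = 7.5,
                        low_value_offset = 2.0, sampling_sd = 0.8,
                        n_trials = 96L) {
  stopifnot(reward_min < reward_max,
            standard_mean_low < standard_mean_high,
            low_value_offset > 0, sampling_sd > 0)
  n_trials <- as.integer(n_trials)
  if (n_trials %% 8L != 0L) {
    stop("n_trials must be divisible by 8 (2 horizons x 4 bandit-type triples)",
         call. = FALSE)
  }
  structure(
    list(reward_min = reward_min, reward_max = reward_max,
         standard_mean_low = standard_mean_low,
         standard_mean_high = standard_mean_high,
         low_value_offset = low_value_offset,
         sampling_sd = sampling_sd, n_trials = n_trials),
    class = "task_config")
}

clip_reward <- function(x, config) {
  pmin(pmax(x, config$reward_min), config$reward_max)
}

#' Number of draws allowed by a horizon
#' @param horizon `"short"` or `"long"`.
#' @return 1 for short, 6 for long.
#' @export
horizon_draws <- function(horizon) {
  ifelse(horizon == "short", 1L, 6L)
}

#' Build a balanced session schedule
#'
#' Generates the full trial schedule of one session: `n_trials` trials, half
#' per horizon, with each of the four bandit-type triples occurring equally
#' often within each horizon.  Generative means are re-drawn per trial, screen
#' positions are randomly permuted per trial so that position carries no
#' information, the horizon sequence is randomly interleaved, and initial
#' samples are drawn from each bandit's own reward distribution (clipped to
#' the reward bounds).
#'
#' @param config A [task_config()].
#' @param seed Integer seed; the schedule is a pure function of
#'   `(config, seed)`.
#' @return A `session_schedule`: a data frame with one row per trial x
#'   position (`trial_index`, `horizon`, `position` 0-based, `bandit_type`,
#'   `generative_mean`, `sampling_sd`, `n_initial`) and a list column
#'   `initial_samples`.  The config and seed are kept as attributes.
#' @export
build_schedule <- function(config = task_config(), seed = 1L) {
  stopifnot(inherits(config, "task_config"))
  n_trials <- config$n_trials
  per_cell <- n_trials %/% 8L

  withr::with_seed(as.integer(seed), {
    cells <- expand.grid(horizon = c("short", "long"), triple = 1:4,
                         stringsAsFactors = FALSE)
    plan <- cells[rep(seq_len(nrow(cells)), each = per_cell), ]
    plan <- plan[sample.int(nrow(plan)), ]  # interleave horizons randomly

    triples <- bandit_type_triples()
    rows <- vector("list", n_trials)
    for (t in seq_len(n_trials)) {
      types <- triples[[plan$triple[t]]]
      types <- types[sample.int(3L)]  # permute screen positions
      info <- BANDIT_TYPES[match(types, BANDIT_TYPES$label), ]
      means <- stats::runif(3L, config$standard_mean_low,
                            config$standard_mean_high)
      is_low <- info$mean_class == "low"
      if (any(is_low)) {
        means[is_low] <- min(means[!is_low]) - config$low_value_offset
      }
      init <- lapply(seq_len(3L), function(i) {
        clip_reward(stats::rnorm(info$n_initial[i], means[i],
                                 config$sampling_sd), config)
      })
      rows[[t]] <- data.frame(
        trial_index = t, horizon = plan$horizon[t], position = 0:2,
        bandit_type = types, generative_mean = means,
        sampling_sd = config$sampling_sd, n_initial = info$n_initial,
        stringsAsFactors = FALSE)
      rows[[t]]$initial_samples <- init
    }
    sched <- do.call(rbind, rows)
  })
  structure(sched, class = c("session_schedule", class(sched)),
            config = config, seed = as.integer(seed))
}

#' Extract one trial from a schedule
#' @param schedule A `session_schedule`.
#' @param trial_index Trial number (1-based).
#' @return A `trial_spec`: the trial's three rows, positions 0..2, with the
#'   task config and horizon attached as attributes.
#' @export
get_trial <- function(schedule, trial_index) {
  rows <- schedule[schedule$trial_index == trial_index, , drop = FALSE]
  if (nrow(rows) != 3L) stop("unknown trial_index: ", trial_index, call. = FALSE)
  rows <- rows[order(rows$position), , drop = FALSE]
  structure(rows, class = c("trial_spec", "data.frame"),
            config = attr(schedule, "config"), horizon = rows$horizon[1])
}

#' Sample a reward from a bandit
#'
#' Draws from a Gaussian with the bandit's generative mean and the trial's
#' sampling SD, clipped to the configured reward bounds.  Uses the current
#' RNG state.
#'
#' @param trial A `trial_spec` (see [get_trial()]).
#' @param bandit_position 0-based position in 0..2.
#' @param n Number of draws.
#' @return Numeric vector of rewards.
#' @export
draw_reward <- function(trial, bandit_position, n = 1L) {
  if (length(bandit_position) != 1L || !bandit_position %in% 0:2) {
    stop("bandit_position must be a single value in 0..2", call. = FALSE)
  }
  config <- attr(trial, "config")
  i <- match(bandit_position, trial$position)
  clip_reward(stats::rnorm(n, trial$generative_mean[i], trial$sampling_sd[i]),
              config)
}

#' Position of the high-value bandit
#'
#' The high-value bandit is the one whose initial samples have the highest
#' mean; only bandits with at least one initial sample compete.  Ties are
#' broken in favour of the lowest screen position.
#'
#' @param trial A `trial_spec`.
#' @return 0-based position of the high-value bandit.
#' @export
high_value_bandit <- function(trial) {
  means <- vapply(trial$initial_samples, function(s) {
    if (length(s) == 0L) -Inf else mean(s)
  }, numeric(1))
  trial$position[which.max(means)]
}
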