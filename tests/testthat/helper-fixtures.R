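# Shared fixtures: everything is generated in code at test time.

# A fast fitting configuration for tests that exercise the pipeline rather
# than estimator quality.
quick_fit <- function(n_restarts = 3L) fit_config(n_restarts = n_restarts)

# Hand-constructed trial with full control over types / samples.
toy_trial <- function(types = c("certain_standard", "standard", "novel"),
                      means = c(5, 6, 5.5), sd = 0.8, horizon = "short",
                      samples = list(c(5, 5.2, 4.8), 6.1, numeric(0)),
                      config = task_config()) {
  df <- data.frame(trial_index = 1L, horizon = horizon, position = 0:2,
                   bandit_type = types, generative_mean = means,
                   sampling_sd = sd, n_initial = lengths(samples),
                   stringsAsFactors = FALSE)
  df$initial_samples <- samples
  structure(df, class = c("trial_spec", "data.frame"),
            config = config, horizon = horizon)
}

# Hand-built 4-trial session (2 short, 2 long) with known structure, used by
# the behavioural-metrics hand-tally tests.
toy_schedule <- function() {
  mk <- function(ti, horizon, types, means, samples) {
    df <- data.frame(trial_index = ti, horizon = horizon, position = 0:2,
                     bandit_type = types, generative_mean = means,
                     sampling_sd = 0.8, n_initial = lengths(samples),
                     stringsAsFactors = FALSE)
    df$initial_samples <- samples
    df
  }
  sched <- rbind(
    mk(1L, "short", c("certain_standard", "standard", "novel"),
       c(6, 5, 5.5), list(c(6.2, 5.8, 6.0), 5.1, numeric(0))),
    mk(2L, "short", c("low_value", "standard", "certain_standard"),
       c(3, 5, 6), list(3.2, 5.0, c(6.1, 5.9, 6.0))),
    mk(3L, "long", c("novel", "low_value", "standard"),
       c(5.5, 3, 5), list(numeric(0), 2.8, 5.2)),
    mk(4L, "long", c("standard", "certain_standard", "low_value"),
       c(5, 6, 3), list(4.9, c(5.8, 6.2, 6.0), 3.1)))
  structure(sched, class = c("session_schedule", "data.frame"),
            config = task_config(), seed = 0L)
}

# Choice records against toy_schedule(); rewards are placeholders.
toy_choices <- function() {
  data.frame(
    subject_id = "t1",
    trial_index = c(1L, 2L, 3L, rep(3L, 5), 4L, rep(4L, 5)),
    draw_index = c(1L, 1L, 1:6, 1:6),
    choice_position = c(0L,          # trial 1: certain_standard (high value)
                        0L,          # trial 2: low_value
                        0L, 2L, 2L, 2L, 2L, 2L,  # trial 3: novel first
                        1L, 1L, 1L, 1L, 1L, 1L), # trial 4: high value first
    reward = c(6.0, 3.0, 5.4, 5.1, 5.0, 5.2, 4.9, 5.1,
               6.1, 6.0, 5.9, 6.2, 6.0, 6.1),
    stringsAsFactors = FALSE)
}

# A mid-sized simulated dataset reused across fitting tests.
sim_dataset <- function(eps_l = 0.3, n_trials = 96L, seed = 42L,
                        eps_s = 0.1, eta_s = 0.8, eta_l = 0.8) {
  m <- model_from_label("thompson+eps+eta")
  ps <- param_set(eps_s = eps_s, eps_l = eps_l, eta_s = eta_s, eta_l = eta_l)
  sched <- build_schedule(task_config(n_trials = n_trials), seed = seed)
  list(model = m, params = ps, schedule = sched,
       choices = simulate_agent(m, ps, sched, seed = seed + 1L,
                                subject_id = "s1"))
}
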