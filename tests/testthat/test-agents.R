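test_that("conjugate posterior updating matches closed form and grid Bayes", {
  # Q0 = 5, sigma0^2 = 4, sampling var 1, samples {6, 7, 8}
  tr <- toy_trial(means = c(7, 6, 5.5), sd = 1,
                  samples = list(c(6, 7, 8), 6.1, numeric(0)))
  st <- init_posterior(param_set(Q0 = 5, sigma0_s = 2), tr)
  expect_equal(st$Q[1], 22.25 / 3.25, tolerance = 1e-12)
  expect_equal(st$V[1], 1 / 3.25, tolerance = 1e-12)

  # independent oracle: grid-approximated Bayes rule
  mu <- seq(-10, 20, by = 1e-3)
  post <- dnorm(mu, 5, 2)
  for (x in c(6, 7, 8)) post <- post * dnorm(x, mu, 1)
  post <- post / sum(post)
  expect_equal(sum(mu * post), st$Q[1], tolerance = 1e-6)
  expect_equal(sum((mu - st$Q[1])^2 * post), st$V[1], tolerance = 1e-6)

  # zero-sample bandit keeps the prior
  expect_equal(st$Q[3], 5)
  expect_equal(st$V[3], 4)
})

test_that("update_posterior is conjugate, local, and validated", {
  st <- structure(list(Q = c(5, 5, 5), V = c(4, 4, 4)),
                  class = "posterior_state")
  # two sequential updates equal one batch update with both samples
  seq2 <- update_posterior(update_posterior(st, 0L, 6, 1), 0L, 7, 1)
  prec <- 1 / 4 + 2 / 1
  expect_equal(seq2$Q[1], (5 / 4 + 13) / prec, tolerance = 1e-12)
  expect_equal(seq2$V[1], 1 / prec, tolerance = 1e-12)
  # unchosen bandits are bit-identical
  expect_identical(seq2$Q[2:3], st$Q[2:3])
  expect_identical(seq2$V[2:3], st$V[2:3])

  # uninformative prior: posterior mean equals the observation
  flat <- structure(list(Q = c(0, 0, 0), V = c(1e12, 1, 1)),
                    class = "posterior_state")
  expect_equal(update_posterior(flat, 0L, 7.3, 1)$Q[1], 7.3,
               tolerance = 1e-9)

  expect_error(update_posterior(st, 0L, 6, 0), "positive")
})

test_that("Thompson probabilities match symmetry, probit and Monte Carlo", {
  sym <- structure(list(Q = c(5, 5, 5), V = c(2, 2, 2)),
                   class = "posterior_state")
  expect_equal(thompson_choice_probs(sym), rep(1 / 3, 3), tolerance = 1e-9)

  # two-bandit reduction: P = pnorm(1 / sqrt(2)), third arm negligible
  two <- structure(list(Q = c(5, 6, -50), V = c(1, 1, 1e-6)),
                   class = "posterior_state")
  expect_equal(thompson_choice_probs(two)[2], pnorm(1 / sqrt(2)),
               tolerance = 1e-6)

  # Monte-Carlo oracle over randomised states, incl. extreme variance ratios
  withr::with_seed(5, {
    for (i in 1:12) {
      st <- structure(list(Q = runif(3, 1, 10),
                           V = exp(runif(3, log(0.01), log(400)))),
                      class = "posterior_state")
      p <- thompson_choice_probs(st)
      expect_equal(sum(p), 1, tolerance = 1e-8)
      draws <- matrix(rnorm(3 * 2e5, st$Q, sqrt(st$V)), ncol = 3,
                      byrow = TRUE)
      mc <- tabulate(max.col(draws), 3) / 2e5
      expect_true(max(abs(p - mc)) < 0.01)
    }
  })

  expect_error(thompson_choice_probs(
    structure(list(Q = c(NA, 1, 1), V = c(1, 1, 1)),
              class = "posterior_state")), "finite")
})

test_that("UCB softmax and hybrid mixture behave as specified", {
  st <- structure(list(Q = c(1, 2, 3), V = c(0, 0, 0) + 1e-20),
                  class = "posterior_state")
  expect_equal(ucb_choice_probs(st, gamma_h = 0, tau = 1),
               exp(1:3) / sum(exp(1:3)), tolerance = 1e-9)
  expect_equal(round(ucb_choice_probs(st, 0, 1), 4),
               c(0.0900, 0.2447, 0.6652))

  eq <- structure(list(Q = c(4, 4, 4), V = c(1, 1, 1)),
                  class = "posterior_state")
  expect_equal(ucb_choice_probs(eq, 2, 0.7), rep(1 / 3, 3), tolerance = 1e-9)

  # greedy limit: tau -> 0 concentrates on argmax
  expect_gt(ucb_choice_probs(st, 0, 1e-3)[3], 1 - 1e-9)
  expect_error(ucb_choice_probs(st, 0, 0), "tau")

  st2 <- structure(list(Q = c(5, 6, 4), V = c(2, 1, 3)),
                   class = "posterior_state")
  expect_equal(hybrid_choice_probs(st2, 1, 1, w = 1),
               ucb_choice_probs(st2, 1, 1), tolerance = 1e-12)
  expect_equal(hybrid_choice_probs(st2, 1, 1, w = 0),
               thompson_choice_probs(st2), tolerance = 1e-12)
  expect_equal(hybrid_choice_probs(st2, 1, 1, w = 0.5),
               (ucb_choice_probs(st2, 1, 1) + thompson_choice_probs(st2)) / 2,
               tolerance = 1e-12)
})

test_that("epsilon-greedy mixing is exact and bounded", {
  expect_equal(apply_epsilon(c(0.7, 0.2, 0.1), 0), c(0.7, 0.2, 0.1))
  expect_equal(apply_epsilon(c(0.9, 0.05, 0.05), 1), rep(1 / 3, 3))
  expect_equal(apply_epsilon(c(0.7, 0.2, 0.1), 0.3), c(0.59, 0.24, 0.17),
               tolerance = 1e-12)
  expect_error(apply_epsilon(c(0.5, 0.3, 0.2), 1.2), "eps")
})

test_that("choice_probs composes the pipeline and respects invariants", {
  sched <- build_schedule(task_config(), seed = 11)
  tr <- get_trial(sched, 5)
  ps <- param_set(eps_s = 0, eps_l = 0, eta_s = 0, eta_l = 0)

  bare <- choice_probs(model_spec("thompson"), ps, tr)
  withnull <- choice_probs(model_spec("thompson", TRUE, TRUE), ps, tr)
  expect_equal(bare, withnull, tolerance = 1e-12)
  expect_equal(bare, thompson_choice_probs(init_posterior(ps, tr)),
               tolerance = 1e-12)

  # full lapse makes all cores coincide
  lapse <- param_set(eps_s = 1, eps_l = 1)
  ps_all <- lapply(c("thompson", "ucb", "hybrid"), function(core) {
    choice_probs(model_spec(core, use_epsilon = TRUE), lapse, tr)
  })
  for (p in ps_all) expect_equal(p, rep(1 / 3, 3), tolerance = 1e-9)

  # every family member emits a normalised triple
  for (m in enumerate_model_family()) {
    p <- choice_probs(m, param_set(eps_s = .2, eps_l = .2, eta_s = 1,
                                   eta_l = 1), tr)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-8)
  }
})

test_that("epsilon and novelty monotonicity properties hold", {
  sched <- build_schedule(task_config(), seed = 13)
  ps <- param_set(eta_s = 0, eta_l = 0)
  withr::with_seed(1, trial_ids <- sample(unique(sched$trial_index), 10))
  for (ti in trial_ids) {
    tr <- get_trial(sched, ti)
    base <- choice_probs(model_spec("thompson"), ps, tr)
    lo <- which.min(base)
    if (base[lo] < 1 / 3) {
      p1 <- apply_epsilon(base, 0.2)
      p2 <- apply_epsilon(base, 0.5)
      expect_gt(p2[lo], p1[lo])
      expect_gt(p1[lo], base[lo])
    }
    # novelty bonus raises the zero-sample bandit's probability in all cores
    novel_pos <- tr$position[tr$n_initial == 0L]
    if (length(novel_pos) == 1L) {
      for (core in c("thompson", "ucb", "hybrid")) {
        m <- model_spec(core, use_novelty = TRUE)
        p_lo <- choice_probs(m, param_set(eta_s = 0.2, eta_l = 0.2), tr)
        p_hi <- choice_probs(m, param_set(eta_s = 2, eta_l = 2), tr)
        expect_gt(p_hi[novel_pos + 1L], p_lo[novel_pos + 1L])
      }
    }
  }
})

test_that("the model family enumerates 12 uniquely labelled members", {
  fam <- enumerate_model_family()
  expect_length(fam, 12L)
  labels <- vapply(fam, model_label, character(1))
  expect_identical(anyDuplicated(labels), 0L)
  expect_true("thompson+eps+eta" %in% labels)
  expect_identical(model_label(model_from_label("ucb+eps")), "ucb+eps")
  expect_error(model_from_label("nonsense"), "unknown")
})

test_that("simulate_agent respects horizons, seeds, and the lapse rate", {
  d <- sim_dataset(seed = 21L)
  per_trial <- table(d$choices$trial_index)
  horiz <- tapply(d$schedule$horizon, d$schedule$trial_index, `[`, 1)
  expect_true(all(per_trial[horiz == "short"] == 1L))
  expect_true(all(per_trial[horiz == "long"] == 6L))
  expect_identical(nrow(d$choices), 48L * 1L + 48L * 6L)

  expect_identical(d$choices,
                   simulate_agent(d$model, d$params, d$schedule, seed = 22L,
                                  subject_id = "s1"))

  # full-lapse agent picks the low-value bandit ~1/3 of eligible first draws
  cfg <- task_config(n_trials = 400L)
  sched <- build_schedule(cfg, seed = 31)
  lapse <- simulate_agent(model_spec("thompson", use_epsilon = TRUE),
                          param_set(eps_s = 1, eps_l = 1), sched, seed = 32)
  fd <- lapse[lapse$draw_index == 1L, ]
  info_type <- tapply(seq_len(nrow(sched)), sched$trial_index, function(i) {
    sched$bandit_type[i][order(sched$position[i])]
  })
  eligible <- vapply(info_type, function(x) "low_value" %in% x, logical(1))
  chose_low <- mapply(function(ti, ch) info_type[[as.character(ti)]][ch + 1] == "low_value",
                      fd$trial_index, fd$choice_position)
  f <- mean(chose_low[eligible[as.character(fd$trial_index)]])
  n <- sum(eligible)
  se <- sqrt((1 / 3) * (2 / 3) / n)
  expect_lt(abs(f - 1 / 3), 3 * se)
})
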