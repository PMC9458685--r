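test_that("first-draw metrics match an exhaustive hand tally", {
  met <- compute_first_draw_metrics(toy_choices(), toy_schedule())
  s <- met[met$horizon == "short", ]
  l <- met[met$horizon == "long", ]

  expect_equal(s$freq_high_value, 1 / 2)
  expect_equal(s$freq_low_value, 1)     # low-value present only on trial 2
  expect_equal(s$freq_novel, 0)         # novel present only on trial 1
  expect_equal(s$mean_familiarity, 2)
  expect_equal(s$mean_expected_value, (6.0 + 3.2) / 2)
  expect_equal(s$mean_reward_first_draw, 4.5)
  expect_equal(s$mean_reward_all_draws, 4.5)

  expect_equal(l$freq_high_value, 1 / 2)
  expect_equal(l$freq_low_value, 0)
  expect_equal(l$freq_novel, 1)
  expect_equal(l$mean_familiarity, 1.5)
  expect_equal(l$mean_expected_value, 6.0)  # novel first draw excluded
  expect_equal(l$mean_reward_first_draw, (5.4 + 6.1) / 2)
  expect_equal(l$mean_reward_all_draws, (30.7 + 36.3) / 12)
})

test_that("explore/exploit classification and trajectories follow the rule", {
  cls <- classify_explore_exploit(toy_choices(), toy_schedule())
  expect_identical(cls$class[cls$trial_index == 3], "explore")
  expect_identical(cls$class[cls$trial_index == 4], "exploit")
  expect_identical(nrow(cls), 2L)

  traj <- reward_trajectory(toy_choices(), toy_schedule())
  expect_identical(nrow(traj), 12L)  # 2 classes x 6 draws
  # increases are relative to the highest shown initial sample of the trial:
  # trial 3 max = 5.2 (standard's sample), trial 4 max = 6.2
  expect_equal(traj$mean_reward_increase[traj$class == "explore" &
                                           traj$draw_index == 1], 0.2,
               tolerance = 1e-12)
  expect_equal(traj$mean_reward_increase[traj$class == "exploit" &
                                           traj$draw_index == 1], -0.1,
               tolerance = 1e-12)
  expect_equal(traj$mean_reward_increase[traj$class == "exploit" &
                                           traj$draw_index == 4], 0.0,
               tolerance = 1e-12)
})

test_that("a full-lapse agent picks the low-value bandit about a third", {
  cfg <- task_config(n_trials = 400L)
  sched <- build_schedule(cfg, seed = 41)
  sim <- simulate_agent(model_spec("thompson", use_epsilon = TRUE),
                        param_set(eps_s = 1, eps_l = 1), sched, seed = 42,
                        subject_id = "lapse")
  met <- compute_first_draw_metrics(sim, sched)
  for (h in c("short", "long")) {
    f <- met$freq_low_value[met$horizon == h]
    n <- 150  # 400 trials x 3/4 low-present, half per horizon
    expect_lt(abs(f - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / n))
  }
})

test_that("mixed ANOVA agrees with aov() and a hand-coded decomposition", {
  # fixed small dataset: 3 groups x 4 subjects x 2 within levels
  withr::with_seed(8, {
    g <- factor(rep(c("c", "e", "l"), each = 4))
    X <- matrix(rnorm(24, mean = rep(c(2, 3, 2.5), each = 4)), 12, 2)
  })
  res <- mixed_anova(X, g)

  # independent GLM route: aov with an Error() stratum
  long <- data.frame(y = c(X[, 1], X[, 2]),
                     w = factor(rep(c("a", "b"), each = 12)),
                     g = rep(g, 2), id = factor(rep(1:12, 2)))
  av <- summary(stats::aov(y ~ g * w + Error(id), data = long))
  f_g <- av[["Error: id"]][[1]]["g", "F value"]
  f_w <- av[["Error: Within"]][[1]]["w", "F value"]
  f_gw <- av[["Error: Within"]][[1]]["g:w", "F value"]
  expect_equal(res$F[res$effect == "between"], f_g, tolerance = 1e-8)
  expect_equal(res$F[res$effect == "within"], f_w, tolerance = 1e-8)
  expect_equal(res$F[res$effect == "interaction"], f_gw, tolerance = 1e-8)

  # hand-coded sums of squares on the same dataset
  GM <- mean(X); b <- 2; n_j <- c(4, 4, 4)
  sm <- rowMeans(X); gm <- tapply(sm, g, mean); cm <- colMeans(X)
  ssA <- b * sum(n_j * (gm - GM)^2)
  ssS <- b * sum((sm - gm[g])^2)
  ssB <- 12 * sum((cm - GM)^2)
  cell <- rbind(tapply(X[, 1], g, mean), tapply(X[, 2], g, mean))
  ssAB <- sum(4 * (t(cell) - outer(gm - GM, cm, "+"))^2)
  ssE <- sum((X - GM)^2) - ssA - ssS - ssB - ssAB
  expect_equal(res$F[res$effect == "between"], (ssA / 2) / (ssS / 9),
               tolerance = 1e-8)
  expect_equal(res$F[res$effect == "within"], (ssB / 1) / (ssE / 9),
               tolerance = 1e-8)
  expect_equal(res$F[res$effect == "interaction"], (ssAB / 2) / (ssE / 9),
               tolerance = 1e-8)
  expect_equal(res$partial_eta_sq[res$effect == "between"],
               ssA / (ssA + ssS), tolerance = 1e-10)

  # unbalanced random datasets still match aov (proportional frequencies)
  withr::with_seed(19, {
    for (i in 1:5) {
      g2 <- factor(rep(c("c", "e", "l"), times = c(5, 8, 6)))
      X2 <- matrix(rnorm(38), 19, 2)
      r2 <- mixed_anova(X2, g2)
      long2 <- data.frame(y = c(X2[, 1], X2[, 2]),
                          w = factor(rep(c("a", "b"), each = 19)),
                          g = rep(g2, 2), id = factor(rep(1:19, 2)))
      av2 <- summary(stats::aov(y ~ g * w + Error(id), data = long2))
      expect_equal(r2$F[r2$effect == "between"],
                   av2[["Error: id"]][[1]]["g", "F value"], tolerance = 1e-8)
      expect_equal(r2$F[r2$effect == "within"],
                   av2[["Error: Within"]][[1]]["w", "F value"],
                   tolerance = 1e-8)
      expect_equal(r2$F[r2$effect == "interaction"],
                   av2[["Error: Within"]][[1]]["g:w", "F value"],
                   tolerance = 1e-8)
    }
  })
})

test_that("mixed ANOVA handles degenerate and scaled inputs", {
  g <- factor(rep(c("a", "b"), each = 3))
  flat <- matrix(5, 6, 2)
  res <- mixed_anova(flat, g)
  expect_true(all(res$F == 0))
  expect_true(all(res$p == 1))

  withr::with_seed(4, X <- matrix(rnorm(12), 6, 2))
  expect_equal(mixed_anova(2 * X, g)$F, mixed_anova(X, g)$F,
               tolerance = 1e-9)
  expect_error(mixed_anova(X, factor(rep("a", 6))), "2 groups")
  expect_error(mixed_anova(X[, 1, drop = FALSE], g), "2 within")
  expect_error(mixed_anova(X, factor(c("a", rep("b", 5)))), "at least 2")
})

test_that("symptom correlations match an explicit normal-equations oracle", {
  # 8-point hand dataset
  eps <- c(0.10, 0.22, 0.15, 0.35, 0.28, 0.05, 0.40, 0.18)
  score <- c(48, 55, 50, 66, 60, 43, 70, 52)
  age <- c(9, 13, 17, 9, 13, 17, 9, 13)
  iq <- c(100, 105, 95, 110, 98, 102, 99, 104)

  res <- correlate_with_symptoms(eps, score, covariates = cbind(age, iq))
  expect_equal(res$r, cor(eps, score), tolerance = 1e-12)

  Z <- cbind(1, age, iq)
  H <- Z %*% solve(t(Z) %*% Z) %*% t(Z)
  r_hand <- cor(eps - H %*% eps, score - H %*% score)[1, 1]
  expect_equal(res$partial_r, r_hand, tolerance = 1e-10)
  expect_identical(res$partial_df, 8L - 2L - 2L)
  t_hand <- r_hand * sqrt(4 / (1 - r_hand^2))
  expect_equal(res$partial_p, 2 * pt(abs(t_hand), 4, lower.tail = FALSE),
               tolerance = 1e-10)

  # covariates orthogonal to both variables leave r unchanged
  withr::with_seed(6, {
    x <- rnorm(40); y <- 0.5 * x + rnorm(40)
    z <- rnorm(40)
    z <- residuals(lm(z ~ x + y))  # orthogonalise
    res2 <- correlate_with_symptoms(x, y, covariates = cbind(z))
  })
  expect_equal(res2$partial_r, res2$r, tolerance = 1e-10)

  # exact linear relation
  expect_equal(correlate_with_symptoms(eps, 2 * eps + 1)$r, 1,
               tolerance = 1e-12)
  expect_error(correlate_with_symptoms(rep(1, 8), score), "zero variance")
  expect_error(correlate_with_symptoms(eps[1:4], score[1:4],
                                       covariates = cbind(age[1:4], iq[1:4],
                                                          iq[1:4])),
               "n >=")
})

test_that("the clinical cutoff split detects a designed epsilon excess", {
  expect_error(clinical_split_analysis(matrix(0.2, 10, 2,
                                              dimnames = list(NULL, c("short", "long"))),
                                       scores = rep(50, 10)),
               "each side")

  withr::with_seed(12, {
    n_high <- 8; n_low <- 30
    eps <- rbind(
      cbind(short = rnorm(n_high, 0.20, 0.04),
            long = rnorm(n_high, 0.45, 0.05)),  # elevated group, long-heavy
      cbind(short = rnorm(n_low, 0.15, 0.04),
            long = rnorm(n_low, 0.25, 0.05)))
    scores <- c(rnorm(n_high, 78, 4), rnorm(n_low, 50, 8))
    scores[scores >= 70 & seq_along(scores) > n_high] <- 69
  })
  res <- clinical_split_analysis(eps, scores, cutoff = 70)
  expect_identical(res$n_high, 8L)
  long_row <- res$pairwise[res$pairwise$horizon == "long", ]
  expect_gt(long_row$mean_high - long_row$mean_low, 0)
  expect_lt(long_row$p_bonferroni, 0.05)
  expect_identical(nrow(res$anova), 3L)

  expect_equal(bonferroni(0.02, 1), 0.02)
  expect_equal(bonferroni(0.02, 3), 0.06)
  expect_equal(bonferroni(0.5, 3), 1)
})
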