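# Synthetic cohorts: subject tables and full choice datasets with the
# statistical structure of a three-group developmental study, so the whole
# pipeline can be exercised without any real data.

#' Cohort specification
#'
#' Describes a three-group cohort (children / early adolescents / late
#' adolescents, default sizes 26 / 38 / 33) of agents playing under the
#' winning model (`thompson+eps+eta`).  Per-group parameter distributions are
#' truncated normals; the defaults encode the designed structure: the
#' epsilon-greedy lapse is lower in the oldest group and higher in the long
#' horizon, while the novelty bonus and prior uncertainty carry no group
#' differences.  A continuous ADHD-like symptom score on a T-score scale
#' (mean 50, SD 10, so the clinical cutoff of 70 is meaningful) is positively
#' coupled to each subject's horizon-averaged epsilon with a target
#' correlation of 0.26.
#'
#' @param group_sizes Named integer vector (children, early, late).
#' @param age_mean,age_sd Per-group age distributions (years).
#' @param iq_mean,iq_sd IQ distribution (shared across groups).
#' @param param_means Named list; each entry is a length-3 vector of
#'   per-group means (children, early, late) for one winning-model parameter.
#' @param param_sds Named numeric vector of SDs for the same parameters.
#' @param target_r Target correlation between the symptom score and
#'   horizon-averaged epsilon; must lie in (-1, 1).
#' @param score_mean,score_sd Symptom score scale (T-score-like).
#' @param model Generating model label.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(children = 26L, early = 38L,
                                        late = 33L),
                        age_mean = c(9.32, 13.13, 17.18),
                        age_sd = c(0.27, 0.30, 0.29),
                        iq_mean = 100, iq_sd = 15,
                        param_means = list(
                          Q0       = c(5.0, 5.0, 5.0),
                          sigma0_s = c(2.0, 2.0, 2.0),
                          sigma0_l = c(2.0, 2.0, 2.0),
                          eps_s    = c(0.15, 0.15, 0.07),
                          eps_l    = c(0.30, 0.30, 0.15),
                          eta_s    = c(0.8, 0.8, 0.8),
                          eta_l    = c(0.8, 0.8, 0.8)),
                        param_sds = c(Q0 = 0.5, sigma0_s = 0.5,
                                      sigma0_l = 0.5, eps_s = 0.06,
                                      eps_l = 0.08, eta_s = 0.4,
                                      eta_l = 0.4),
                        target_r = 0.26, score_mean = 50, score_sd = 10,
                        model = "thompson+eps+eta") {
  stopifnot(all(group_sizes >= 1), length(group_sizes) == 3,
            abs(target_r) < 1, score_sd > 0)
  structure(list(group_sizes = group_sizes, age_mean = age_mean,
                 age_sd = age_sd, iq_mean = iq_mean, iq_sd = iq_sd,
                 param_means = param_means, param_sds = param_sds,
                 target_r = target_r, score_mean = score_mean,
                 score_sd = score_sd, model = model),
            class = "cohort_spec")
}

# Inverse-CDF truncated normal draw (seeding handled by the caller).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Generate a cohort subject table
#'
#' Draws per-subject true parameters (truncated to the fitting bounds), ages,
#' IQs, and a symptom score.  The score is `a + b * mean(eps_s, eps_l) +
#' noise`, with slope and noise variance calibrated against the realised
#' spread of epsilon so the population correlation matches `target_r` and
#' the score SD matches `score_sd`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @param bounds Parameter bounds (see [default_bounds()]).
#' @return Data frame: `subject_id`, `group`, `age`, `iq`, `symptom_score`,
#'   plus one column per true parameter.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L,
                            bounds = default_bounds()) {
  stopifnot(inherits(spec, "cohort_spec"))
  sizes <- spec$group_sizes
  n <- sum(sizes)
  group <- factor(rep(names(sizes), sizes), levels = names(sizes))
  gi <- as.integer(group)
  withr::with_seed(as.integer(seed), {
    age <- stats::rnorm(n, spec$age_mean[gi], spec$age_sd[gi])
    iq <- rtruncnorm(n, spec$iq_mean, spec$iq_sd, 70, 130)
    params <- lapply(names(spec$param_means), function(p) {
      b <- bounds[[p]]
      rtruncnorm(n, spec$param_means[[p]][gi], spec$param_sds[[p]],
                 b[1], b[2])
    })
    names(params) <- names(spec$param_means)
    eps_bar <- (params$eps_s + params$eps_l) / 2
    if (stats::sd(eps_bar) == 0 && spec$target_r != 0) {
      stop("epsilon has zero spread; target correlation infeasible",
           call. = FALSE)
    }
    slope <- if (spec$target_r == 0) 0 else {
      spec$target_r * spec$score_sd / stats::sd(eps_bar)
    }
    noise_sd <- spec$score_sd * sqrt(1 - spec$target_r^2)
    score <- spec$score_mean + slope * (eps_bar - mean(eps_bar)) +
      stats::rnorm(n, 0, noise_sd)
    out <- data.frame(subject_id = sprintf("sub%03d", seq_len(n)),
                      group = group, age = age, iq = iq,
                      symptom_score = score, stringsAsFactors = FALSE)
    for (p in names(params)) out[[p]] <- params[[p]]
  })
  out
}

#' Simulate full choice data for a cohort
#'
#' Each subject plays a fresh seeded session schedule under the generating
#' model with their own true parameters.
#'
#' @param cohort A [generate_cohort()] table.
#' @param task_cfg A [task_config()].
#' @param seed Integer seed.
#' @param model Generating model label (defaults to the winning model).
#' @return List with `choices` (all subjects' records) and `schedules`
#'   (named list keyed by `subject_id`).
#' @export
generate_cohort_data <- function(cohort, task_cfg = task_config(), seed = 1L,
                                 model = "thompson+eps+eta") {
  mspec <- model_from_label(model)
  seed <- as.integer(seed)
  schedules <- list()
  choices <- vector("list", nrow(cohort))
  pnames <- intersect(names(cohort), PARAM_NAMES)
  for (i in seq_len(nrow(cohort))) {
    sid <- cohort$subject_id[i]
    sched <- build_schedule(task_cfg, seed = seed + 13L * i)
    schedules[[sid]] <- sched
    params <- merge_params(unlist(cohort[i, pnames]))
    choices[[i]] <- simulate_agent(mspec, params, sched,
                                   seed = seed + 13L * i + 1L,
                                   subject_id = sid)
  }
  list(choices = do.call(rbind, choices), schedules = schedules)
}
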