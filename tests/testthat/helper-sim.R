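# Simulation fixtures built in code.

# Null design: two identical arms, used for the type-I-error experiment.
null_config <- function(n_per_arm = c(30L, 30L), max_weeks = 12L) {
  trial_sim_config(
    terms = list(
      diarrhea = list(onset = 0.12, grades = c(0.5, 0.3, 0.15, 0.04, 0.01),
                      mean_duration = 5),
      neutropenia = list(onset = 0.10, grades = c(0.3, 0.3, 0.25, 0.13, 0.02),
                         mean_duration = 7)
    ),
    n_per_arm = n_per_arm,
    arm_labels = c("A", "B"),
    max_weeks = max_weeks,
    dropout = 0.05,
    ongoing_prob = 0.5
  )
}

# A small random study for property tests: random size, length, hazards.
random_study <- function(seed, max_patients = 50L, max_weeks_cap = 30L) {
  set.seed(seed)
  n <- sample(4:max_patients, 1)
  n_a <- max(2L, rbinom(1, n, 0.5))
  n_b <- max(2L, n - n_a)
  weeks <- sample(4:max_weeks_cap, 1)
  n_terms <- sample(1:4, 1)
  terms <- setNames(
    lapply(seq_len(n_terms), function(i) {
      list(
        onset = list(runif(1, 0.02, 0.25), runif(1, 0.02, 0.25)),
        grades = {
          g <- runif(5); g / sum(g)
        },
        mean_duration = runif(1, 1, 20)
      )
    }),
    paste0("term", seq_len(n_terms))
  )
  cfg <- trial_sim_config(
    terms = terms, n_per_arm = c(n_a, n_b), arm_labels = c("A", "B"),
    max_weeks = weeks, dropout = runif(1, 0, 0.15),
    ongoing_prob = runif(1)
  )
  sim <- simulate_trial(cfg, seed = seed + 1000L)
  sim$episodes <- impute_end_dates(sim$episodes, sim$patients)
  sim$config <- cfg
  sim
}

# Monte-Carlo rejection rate of the permutation comparison.
rejection_rate <- function(config, n_trials, n_permutations = 999L,
                           alpha = 0.05, seed0 = 1L) {
  rejections <- 0L
  for (i in seq_len(n_trials)) {
    sim <- simulate_trial(config, seed = seed0 + i)
    eps <- impute_end_dates(sim$episodes, sim$patients)
    cmp <- suppressWarnings(compare_arms(
      sim$patients, eps, n_permutations = n_permutations,
      seed = seed0 + 100000L + i
    ))
    if (cmp$p_value <= alpha) rejections <- rejections + 1L
  }
  rejections / n_trials
}
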