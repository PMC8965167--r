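# Independent oracles used across the suite. These stay brute-force /
# closed-form on purpose: they must not share code with the implementation.

# Symmetric brute-force interval merging: repeatedly merge any two intervals
# within `gap_days` of each other until no pair merges.
oracle_merge_intervals <- function(admit, discharge, gap_days) {
  iv <- cbind(as.numeric(admit), as.numeric(discharge))
  repeat {
    n <- nrow(iv)
    merged <- FALSE
    for (i in seq_len(n)) {
      if (merged) break
      for (j in seq_len(n)) {
        if (i < j &&
            iv[i, 1] <= iv[j, 2] + gap_days &&
            iv[j, 1] <= iv[i, 2] + gap_days) {
          iv[i, ] <- c(min(iv[i, 1], iv[j, 1]), max(iv[i, 2], iv[j, 2]))
          iv <- iv[-j, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  iv[order(iv[, 1]), , drop = FALSE]
}

# Global k-medians optimum by exhaustive enumeration of all label
# assignments into at most k groups.
oracle_kmedians_objective <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    cl <- grid[r, ]
    obj <- 0
    for (g in unique(cl)) {
      xs <- x[cl == g, , drop = FALSE]
      med <- apply(xs, 2, stats::median)
      obj <- obj + sum(abs(sweep(xs, 2, med)))
    }
    if (obj < best) best <- obj
  }
  best
}

# Random per-person record set with controllable overlap structure.
random_record_set <- function(n_records, person_id = "p1") {
  admit <- sample.int(60, n_records, replace = TRUE)
  los <- sample.int(8, n_records, replace = TRUE) - 1L
  data.frame(person_id = person_id,
             admit = as.Date("2015-01-01") + admit,
             discharge = as.Date("2015-01-01") + admit + los,
             dx1 = "J18")
}

# A small cohort with balanced exposure classes and a known logistic truth;
# used by the model and margins tests.
sim_model_cohort <- function(n, beta_class5 = log(0.7), seed = 1) {
  units <- data.frame(unit_id = sprintf("u%d", 1:50),
                      ale_class = rep(1:5, each = 10))
  cfg <- cohort_config(
    n_respondents = n, class_probs = rep(0.2, 5),
    true_log_odds = list(
      y = list(intercept = -1.2, ale = c(0, 0.1, -0.1, 0.2, beta_class5),
               age = 0.02, female = -0.1,
               education = c(intermediate = -0.1, high = -0.2),
               smoking = c(former = 0.05, current = 0.2))),
    seed = seed)
  prepare_cohort(generate_cohort(units, units, cfg))
}
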