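test_that("cohort generation validates exposure and reproduces itself", {
  units <- data.frame(unit_id = c("a", "b"), ale_class = c(1L, 4L))
  cfg <- cohort_config(n_respondents = 200, seed = 5)
  d1 <- generate_cohort(units, units, cfg)
  d2 <- generate_cohort(units, units, cfg)
  expect_identical(d1, d2)
  expect_true(all(d1$age >= 16))
  expect_true(all(d1$followup_years >= 0.5))
  expect_true(all(d1$ale_class %in% c(1L, 4L)))

  no_class <- data.frame(unit_id = c("a", "b"), ale_class = c(1L, NA))
  expect_error(generate_cohort(units, no_class, cfg), "missing exposure")
})

test_that("outcome prevalence matches the encoded logistic model", {
  # intercept-only truth: plogis(intercept) = 0.27, n = 40,000
  units <- data.frame(unit_id = "u1", ale_class = 3L)
  cfg <- cohort_config(n_respondents = 40000,
                       true_log_odds = list(
                         obese = list(intercept = qlogis(0.27),
                                      ale = rep(0, 5))),
                       seed = 42)
  d <- generate_cohort(units, units, cfg)
  se <- sqrt(0.27 * 0.73 / 40000)
  expect_lt(abs(mean(d$obese) - 0.27), 3 * se)
})

test_that("null ALE effects leave outcomes independent of class", {
  units <- data.frame(unit_id = sprintf("u%d", 1:10),
                      ale_class = rep(1:5, 2))
  rejections <- 0L
  for (s in 1:20) {
    cfg <- cohort_config(n_respondents = 2000,
                         true_log_odds = list(
                           y = list(intercept = -1, ale = rep(0, 5))),
                         seed = s)
    d <- generate_cohort(units, units, cfg)
    p <- suppressWarnings(
      stats::chisq.test(table(d$ale_class, d$y))$p.value)
    if (p < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 1L)
})

test_that("length of stay follows the configured log-normal", {
  units <- data.frame(unit_id = "u1", ale_class = 1L)
  cfg <- cohort_config(n_respondents = 6000, followup_mean = 4.5,
                       true_log_odds = list(
                         hosp_latent = list(intercept = 2, ale = rep(0, 5))),
                       seed = 9)
  cohort <- generate_cohort(units, units, cfg)
  rc <- hospital_record_config(episode_rate = 0.6, p_split = 0,
                               p_day_case = 0, los_meanlog = log(5),
                               los_sdlog = 0.6, seed = 2)
  recs <- generate_hospital_records(cohort, rc)
  expect_gt(nrow(recs), 10000)
  los <- as.numeric(recs$discharge - recs$admit)
  expect_true(median(los) >= 4.5 && median(los) <= 5.5)
  # records live inside the follow-up window
  i <- match(recs$person_id, cohort$person_id)
  expect_true(all(recs$admit >= cohort$survey_date[i]))
  expect_true(all(recs$discharge <= cohort$followup_end[i] + 1))
})

test_that("record generation rejects invalid configurations", {
  expect_error(hospital_record_config(episode_rate = -1), "episode_rate")
  units <- data.frame(unit_id = "u1", ale_class = 1L)
  cohort <- generate_cohort(units, units,
                            cohort_config(n_respondents = 5, seed = 1))
  expect_error(generate_hospital_records(cohort,
                                         hospital_record_config()),
               "hosp_latent")
})

test_that("scenario presets encode the published cohort structure", {
  for (country in c("canada", "wales")) {
    sc <- scenario_preset(country, n = 4000, seed = 2)
    sim <- simulate_scenario(sc)
    expect_equal(nrow(sim$cohort), 4000)
    # respondent class shares near the published distribution
    ref <- reference_summary(country)
    shares <- ref$respondent_class_counts / sum(ref$respondent_class_counts)
    got <- tabulate(sim$cohort$ale_class, 5) / 4000
    expect_true(all(abs(got - shares) < 0.03))
    # roughly a quarter ever latently hospitalized
    expect_gt(mean(sim$cohort$hosp_latent), 0.18)
    expect_lt(mean(sim$cohort$hosp_latent), 0.32)
  }
})
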