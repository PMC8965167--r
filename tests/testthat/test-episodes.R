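rec <- function(person, admit, discharge, dx1 = "J18", ..., flag = "") {
  data.frame(person_id = person, admit = as.Date(admit),
             discharge = as.Date(discharge), dx1 = dx1,
             facility_flag = flag, ...)
}

test_that("single records become single episodes with date-difference LOS", {
  ep <- build_episodes(rec("p1", "2015-01-01", "2015-01-06"), "wales")
  expect_equal(nrow(ep), 1)
  expect_equal(ep$los_days, 5)
  expect_true(ep$all_cause)
})

test_that("Welsh person-spells merge strictly contiguous records", {
  r <- rbind(rec("p1", "2015-01-01", "2015-01-06"),
             rec("p1", "2015-01-06", "2015-01-10"))
  ep <- build_episodes(r, "wales")
  expect_equal(nrow(ep), 1)
  expect_equal(ep$start, as.Date("2015-01-01"))
  expect_equal(ep$end, as.Date("2015-01-10"))
  expect_equal(ep$los_days, 9)

  r2 <- rbind(rec("p1", "2015-01-01", "2015-01-06"),
              rec("p1", "2015-01-08", "2015-01-10"))
  expect_equal(nrow(build_episodes(r2, "wales")), 2)

  # same-day person-spell is a day case and is removed after merging
  ep3 <- build_episodes(rec("p1", "2015-03-03", "2015-03-03"), "wales")
  expect_equal(nrow(ep3), 0)
  expect_equal(attr(ep3, "summary")$day_cases_removed, 1)
})

test_that("Canadian episodes merge within 24 h after day-procedure removal", {
  r <- rbind(rec("p1", "2015-01-01", "2015-01-06"),
             rec("p1", "2015-01-07", "2015-01-09"),   # within 24 h: merges
             rec("p1", "2015-01-12", "2015-01-13"),   # > 24 h: separate
             rec("p1", "2015-02-01", "2015-02-01", flag = "A"))  # day proc
  ep <- build_episodes(r, "canada")
  expect_equal(nrow(ep), 2)
  expect_equal(ep$los_days, c(8, 1))
  expect_equal(attr(ep, "summary")$day_cases_removed, 1)

  expect_error(build_episodes(rec("p1", "2015-01-05", "2015-01-01"),
                              "canada"), "invalid record")
})

test_that("merging matches brute-force interval merging on random sets", {
  set.seed(1)
  for (trial in 1:200) {
    r <- random_record_set(sample(1:8, 1))
    for (regime in c("wales", "canada")) {
      gap <- if (regime == "canada") 1 else 0
      ep <- build_episodes(r, regime)
      iv <- oracle_merge_intervals(r$admit, r$discharge, gap)
      if (regime == "wales") iv <- iv[iv[, 1] != iv[, 2], , drop = FALSE]
      expect_equal(nrow(ep), nrow(iv))
      expect_equal(as.numeric(as.Date(ep$start)), iv[, 1])
      expect_equal(as.numeric(as.Date(ep$end)), iv[, 2])
    }
  }
})

test_that("merging is idempotent and monotone in the gap", {
  set.seed(2)
  for (trial in 1:20) {
    r <- random_record_set(sample(2:10, 1))
    ep <- build_episodes(r, "canada")
    # feed episodes back as records
    r2 <- data.frame(person_id = ep$person_id, admit = ep$start,
                     discharge = ep$end, dx1 = ep$primary_dx)
    ep2 <- build_episodes(r2, "canada")
    expect_equal(nrow(ep2), nrow(ep))
    expect_equal(ep2$start, ep$start)
    expect_equal(ep2$end, ep$end)
    # larger gap never increases the episode count
    n_by_gap <- vapply(c(0, 24, 48, 120), function(g)
      nrow(build_episodes(r, "canada", gap_hours = g)), numeric(1))
    expect_true(all(diff(n_by_gap) <= 0))
    expect_true(nrow(ep) <= nrow(r))
  }
})

test_that("cause flags use any position; pregnancy primary excludes", {
  r <- rec("p1", "2015-01-01", "2015-01-05", dx1 = "J18.9")
  ep <- build_episodes(r, "canada")
  expect_true(ep$respiratory)
  expect_false(ep$circulatory)
  expect_true(ep$all_cause)

  # childbirth as primary: excluded from all-cause and cause-specific
  r2 <- rec("p1", "2015-01-01", "2015-01-05", dx1 = "O80", dx2 = "I50")
  ep2 <- build_episodes(r2, "canada")
  expect_false(ep2$all_cause)
  expect_false(ep2$circulatory)

  # pregnancy code in secondary position does not exclude (default rule)
  r3 <- rec("p1", "2015-01-01", "2015-01-05", dx1 = "I21", dx2 = "O26")
  expect_true(build_episodes(r3, "canada")$all_cause)
  expect_false(build_episodes(r3, "canada",
                              pregnancy_rule = "any")$all_cause)

  # heart failure + T2D: circulatory, ENM and cardiometabolic all flag once
  r4 <- rec("p1", "2015-01-01", "2015-01-05", dx1 = "I50", dx2 = "E11")
  ep4 <- build_episodes(r4, "canada")
  expect_true(ep4$circulatory && ep4$enm && ep4$cardiometabolic)
  expect_equal(nrow(ep4), 1)
})

test_that("generator round trip: split records merge back to the truth", {
  units <- data.frame(unit_id = "u1", ale_class = 3L)
  cfg <- cohort_config(n_respondents = 300, followup_mean = 4,
                       true_log_odds = list(
                         hosp_latent = list(intercept = 0.5,
                                            ale = rep(0, 5))),
                       seed = 10)
  cohort <- generate_cohort(units, units, cfg)
  for (p_split in c(0, 1)) {
    for (dest in c("wales", "canada")) {
      rc <- hospital_record_config(episode_rate = 0.5, p_split = p_split,
                                   destination = dest, seed = 3)
      recs <- generate_hospital_records(cohort, rc)
      ep <- build_episodes(recs, dest)
      truth <- attr(recs, "true_episode_counts")
      expect_equal(nrow(ep), sum(truth))
      got <- table(ep$person_id)
      expect_true(all(truth[names(got)] == as.integer(got)))
      # with p_split = 1 every true episode is emitted as two records
      if (p_split == 1 && dest == "canada") {
        expect_equal(sum(recs$facility_flag != "A"), 2 * sum(truth))
      }
      # episode days never exceed the follow-up window
      days <- tapply(ep$los_days, ep$person_id, sum)
      fu <- cohort$followup_years[match(names(days), cohort$person_id)]
      expect_true(all(days <= fu * 365.25 + 1))
    }
  }
})
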