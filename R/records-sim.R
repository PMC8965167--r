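#' Configuration for the synthetic hospital-record generator
#'
#' Parameters controlling how latent hospitalization is realized as
#' discharge-abstract records: the episode intensity among latent-positive
#' persons, the proportion of day-case records, the probability that a true
#' episode is emitted as two contiguous records (a transfer the episode
#' builder must merge back), the log-normal length-of-stay distribution, and
#' the primary-diagnosis cause mix.
#'
#' @param episode_rate Expected inpatient episodes per person-year among
#'   persons with latent hospitalization (zero-truncated Poisson count).
#' @param p_day_case Target proportion of emitted records that are day cases
#'   (same-day records; flagged `"A"` for the Canada-style destination).
#' @param p_split Probability a true episode is emitted as two records that
#'   merge back under the destination regime.
#' @param los_meanlog,los_sdlog Log-normal parameters of length of stay in
#'   days; stays are rounded to whole days with a 1-day minimum.
#' @param cause_mix Named probability vector over primary-diagnosis groups
#'   (subset of `circulatory`, `enm`, `respiratory`, `cancer`, `pregnancy`,
#'   `other`); normalized to sum 1.
#' @param max_secondary Maximum number of secondary diagnoses (0-5 drawn
#'   uniformly).
#' @param destination `"wales"` (day cases are same-day records) or
#'   `"canada"` (day cases carry facility flag `"A"`).
#' @param seed Integer seed.
#' @return Object of class `hospital_record_config`.
#' @export
hospital_record_config <- function(episode_rate = 0.4, p_day_case = 0.15,
                                   p_split = 0.1,
                                   los_meanlog = log(5), los_sdlog = 1.15,
                                   cause_mix = c(circulatory = 0.08,
                                                 cardiometabolic = 0.06,
                                                 enm = 0.025,
                                                 respiratory = 0.05,
                                                 cancer = 0.055,
                                                 other = 0.73),
                                   max_secondary = 5,
                                   destination = c("wales", "canada"),
                                   seed = 1L) {
  destination <- match.arg(destination)
  if (episode_rate < 0) stop("invalid config: `episode_rate` must be >= 0")
  if (p_day_case < 0 || p_day_case >= 1 || p_split < 0 || p_split > 1)
    stop("invalid config: probabilities must lie in [0, 1]")
  if (any(cause_mix < 0)) stop("invalid config: `cause_mix` must be >= 0")
  cause_mix <- cause_mix / sum(cause_mix)
  structure(as.list(environment()), class = "hospital_record_config")
}

# zero-truncated Poisson draws (vectorized)
.rztpois <- function(lambda) {
  u <- stats::runif(length(lambda), stats::dpois(0, lambda), 1)
  pmax(stats::qpois(u, lambda), 1L)
}

# Sample an ICD-10 code from a cause group (3- or 4-character).
.sample_icd <- function(n, group) {
  if (n == 0) return(character(0))
  code3 <- switch(group,
    circulatory = sprintf("I%02d", sample(0:99, n, replace = TRUE)),
    cardiometabolic = {  # hypertensive/ischaemic/cerebrovascular/HF/T2D stems
      stems <- c(sprintf("I%02d", c(10:15, 20:25, 61:69, 50)),
                 sprintf("E%02d", 11:14))
      sample(stems, n, replace = TRUE)
    },
    enm = sprintf("E%02d", sample(0:88, n, replace = TRUE)),
    respiratory = sprintf("J%02d", sample(0:98, n, replace = TRUE)),
    cancer = {
      v <- sample(0:148, n, replace = TRUE)
      ifelse(v < 100, sprintf("C%02d", v), sprintf("D%02d", v - 100))
    },
    pregnancy = sprintf("O%02d", sample(0:99, n, replace = TRUE)),
    other = {  # chapters away from the tracked ranges
      l <- sample(c("F", "G", "K", "L", "M", "N", "S", "T"), n, replace = TRUE)
      sprintf("%s%02d", l, sample(0:99, n, replace = TRUE))
    })
  paste0(code3, sample(0:9, n, replace = TRUE))
}

#' Generate synthetic hospital discharge records
#'
#' Realizes the cohort's latent hospitalization (`hosp_latent`) as discharge
#' records. Each latent-positive respondent receives a zero-truncated
#' Poisson number of true inpatient episodes (intensity `episode_rate` per
#' follow-up year), placed inside the follow-up window and separated by more
#' than the merge gap so that episode construction recovers the emitted
#' truth exactly. With probability `p_split` an episode is emitted as two
#' contiguous records (a transfer). Additional day-case records are emitted
#' for randomly chosen respondents at the configured proportion. The number
#' of true episodes emitted per person is recorded in the
#' `true_episode_counts` attribute (named by `person_id`).
#'
#' @param cohort An [generate_cohort()] output containing `hosp_latent`.
#' @param config A [hospital_record_config()].
#' @return Data frame of class `ale_records`: `record_id`, `person_id`,
#'   `admit`, `discharge`, `dx1`..`dx6`, `facility_flag`.
#' @export
generate_hospital_records <- function(cohort, config) {
  if (!inherits(config, "hospital_record_config"))
    stop("invalid config: expected a `hospital_record_config`")
  if (nrow(cohort) == 0) stop("invalid input: empty cohort")
  if (is.null(cohort$hosp_latent))
    stop("invalid input: cohort lacks a `hosp_latent` outcome")
  if (any(cohort$followup_years <= 0))
    stop("invalid input: follow-up must be positive")
  set.seed(config$seed)
  gap_days <- 2L  # exceeds both merge gaps (0 and 24 h) at date resolution

  hosp <- which(cohort$hosp_latent & config$episode_rate > 0)
  true_counts <- stats::setNames(integer(nrow(cohort)), cohort$person_id)
  acc_person <- vector("list", length(hosp))
  acc_admit <- vector("list", length(hosp))
  acc_dis <- vector("list", length(hosp))
  hi <- 0L
  for (i in hosp) {
    hi <- hi + 1L
    fu_days <- as.integer(round(cohort$followup_years[i] * 365.25))
    m <- .rztpois(config$episode_rate * cohort$followup_years[i])
    los <- pmax(round(stats::rlnorm(m, config$los_meanlog, config$los_sdlog)),
                1L)
    # trim until the episodes (plus separating gaps) fit in the window
    while (m > 0 && sum(los) + (m + 1) * gap_days > fu_days) {
      m <- m - 1L
      los <- los[seq_len(m)]
    }
    if (m == 0) {  # window too short: emit one clipped episode
      m <- 1L
      los <- max(1L, fu_days - 2 * gap_days)
      if (los < 1) { true_counts[i] <- 0L; next }
    }
    # sequential placement; leftover window time spread randomly between
    # episodes (stick-breaking), gaps always > the merge threshold
    slack <- max(fu_days - sum(los) - (m + 1) * gap_days, 0)
    extra <- floor(diff(c(0, sort(stats::runif(m)))) * slack)
    starts <- integer(m)
    pos <- gap_days
    for (j in seq_len(m)) {
      pos <- pos + extra[j]
      starts[j] <- pos
      pos <- pos + los[j] + gap_days
    }
    true_counts[i] <- m
    acc_person[[hi]] <- rep.int(i, m)
    acc_admit[[hi]] <- as.numeric(cohort$survey_date[i]) + starts
    acc_dis[[hi]] <- as.numeric(cohort$survey_date[i]) + starts + los
  }
  recs <- data.frame(
    person_id = cohort$person_id[unlist(acc_person)],
    admit = as.Date(unlist(acc_admit), origin = "1970-01-01"),
    discharge = as.Date(unlist(acc_dis), origin = "1970-01-01"))

  # split a fraction of episodes into two contiguous records (transfers)
  if (nrow(recs) && config$p_split > 0) {
    split_it <- stats::runif(nrow(recs)) < config$p_split
    keep <- recs[!split_it, , drop = FALSE]
    sp <- recs[split_it, , drop = FALSE]
    if (nrow(sp)) {
      mid <- sp$admit + floor(stats::runif(nrow(sp)) *
                                as.numeric(sp$discharge - sp$admit + 1))
      mid <- pmin(pmax(mid, sp$admit), sp$discharge)
      first <- data.frame(person_id = sp$person_id, admit = sp$admit,
                          discharge = mid)
      second <- data.frame(person_id = sp$person_id, admit = mid,
                           discharge = sp$discharge)
      recs <- rbind(keep, first, second)
    }
  }
  recs$facility_flag <- rep("", nrow(recs))

  # day-case records: proportion p of all emitted records
  if (config$p_day_case > 0 && nrow(recs)) {
    n_dc <- round(config$p_day_case / (1 - config$p_day_case) * nrow(recs))
    if (n_dc > 0) {
      who <- sample.int(nrow(cohort), n_dc, replace = TRUE)
      day <- floor(stats::runif(n_dc) *
                     pmax(as.integer(round(cohort$followup_years[who] *
                                             365.25)) - 1, 1))
      d <- cohort$survey_date[who] + day
      recs <- rbind(recs,
                    data.frame(person_id = cohort$person_id[who],
                               admit = d, discharge = d,
                               facility_flag =
                                 if (config$destination == "canada") "A"
                                 else ""))
    }
  }

  if (nrow(recs)) {
    # diagnoses: primary from the cause mix, 0..max_secondary secondaries
    nr <- nrow(recs)
    grp <- sample(names(config$cause_mix), nr, replace = TRUE,
                  prob = config$cause_mix)
    dx <- matrix(NA_character_, nr, 6)
    for (g in unique(grp)) {
      sel <- grp == g
      dx[sel, 1] <- .sample_icd(sum(sel), g)
    }
    # secondary diagnoses: mostly incidental ("other") codes, so cause-
    # specific shares stay driven by the primary-diagnosis mix
    n_sec <- pmin(stats::rpois(nr, 1.5), min(config$max_secondary, 5))
    sec_groups <- unique(c(names(config$cause_mix), "other", "pregnancy"))
    sec_probs <- stats::setNames(rep(0.02, length(sec_groups)), sec_groups)
    sec_probs[["other"]] <- 1 - 0.02 * (length(sec_groups) - 1)
    for (j in 2:6) {
      need <- n_sec >= (j - 1)
      if (any(need)) {
        gg <- sample(sec_groups, sum(need), replace = TRUE, prob = sec_probs)
        val <- character(sum(need))
        for (g in unique(gg)) val[gg == g] <- .sample_icd(sum(gg == g), g)
        dx[need, j] <- val
      }
    }
    colnames(dx) <- paste0("dx", 1:6)
    recs <- cbind(recs, as.data.frame(dx))
    ord <- order(recs$person_id, recs$admit)
    recs <- recs[ord, , drop = FALSE]
    recs$record_id <- sprintf("H%06d", seq_len(nrow(recs)))
    rownames(recs) <- NULL
  } else {
    recs <- data.frame(person_id = character(0),
                       admit = as.Date(character(0)),
                       discharge = as.Date(character(0)),
                       facility_flag = character(0),
                       dx1 = character(0), dx2 = character(0),
                       dx3 = character(0), dx4 = character(0),
                       dx5 = character(0), dx6 = character(0),
                       record_id = character(0))
  }
  attr(recs, "true_episode_counts") <- true_counts
  class(recs) <- c("ale_records", "data.frame")
  recs
}
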