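#' Configuration for the synthetic cohort generator
#'
#' Encodes the respondent-level structure of a linked health-survey cohort:
#' demographics, 3-level education and smoking, BMI, follow-up time
#' (truncated normal, minimum half a year), and the true logistic models from
#' which binary outcomes are drawn. The `true_log_odds` element is a named
#' list, one entry per outcome column to generate; each entry is a list with
#' `intercept`, `ale` (length-5 log-odds vector, class 1 = reference = 0),
#' and optional `age`, `age2`, `female`, `education` (named: intermediate,
#' high), `smoking` (named: former, current), and `offset_log_fu` (logical:
#' add log follow-up years to the linear predictor, used for the latent
#' hospitalization indicator).
#'
#' @param n_respondents Cohort size.
#' @param age_mean,age_sd Age distribution (years), truncated at `age_min`.
#' @param age_min Minimum age (years); surveys of adults use 16.
#' @param p_female Proportion female.
#' @param education_probs,smoking_probs Named length-3 probability vectors
#'   (low/intermediate/high and never/former/current); normalized to sum 1.
#' @param bmi_mean,bmi_sd BMI distribution (kg/m2).
#' @param followup_mean,followup_sd,followup_min Follow-up years
#'   (truncated normal).
#' @param class_probs Optional length-5 probability vector over ALE classes;
#'   when given, respondents are assigned a class by these probabilities and
#'   then a uniformly chosen unit of that class; otherwise units are sampled
#'   uniformly.
#' @param true_log_odds See description.
#' @param survey_year Calendar year of survey response (dates are drawn
#'   uniformly within it).
#' @param seed Integer seed.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_respondents = 1000,
                          age_mean = 50, age_sd = 18, age_min = 16,
                          p_female = 0.52,
                          education_probs = c(low = 0.2, intermediate = 0.3,
                                              high = 0.5),
                          smoking_probs = c(never = 0.45, former = 0.35,
                                            current = 0.20),
                          bmi_mean = 27, bmi_sd = 5.5,
                          followup_mean = 4, followup_sd = 0.7,
                          followup_min = 0.5,
                          class_probs = NULL,
                          true_log_odds = list(),
                          survey_year = 2013, seed = 1L) {
  stopifnot(n_respondents >= 0, followup_mean > 0, followup_min > 0,
            p_female >= 0, p_female <= 1)
  education_probs <- education_probs / sum(education_probs)
  smoking_probs <- smoking_probs / sum(smoking_probs)
  if (!is.null(class_probs)) {
    if (length(class_probs) != 5 || any(class_probs < 0))
      stop("invalid config: `class_probs` must be 5 non-negative values")
    class_probs <- class_probs / sum(class_probs)
  }
  structure(as.list(environment()), class = "cohort_config")
}

.rtnorm <- function(n, mean, sd, lower) {
  # inverse-CDF truncated normal
  plo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(stats::runif(n, plo, 1), mean, sd)
}

#' Generate a synthetic survey cohort
#'
#' Draws respondents, assigns each to an areal unit (hence an ALE exposure
#' class), generates covariates, and draws each configured binary outcome
#' from its true logistic model. The latent hospitalization indicator (an
#' outcome named `hosp_latent` with `offset_log_fu = TRUE`) encodes whether a
#' respondent is ever hospitalized during follow-up; the record generator
#' realizes it as inpatient records.
#'
#' @param units Data frame with at least `unit_id` (e.g. the `units` element
#'   of [generate_geography()] output).
#' @param unit_ale_class Data frame `unit_id`, `ale_class` (1-5) or the
#'   `assignment` element of an [classify_units()] result.
#' @param config A [cohort_config()].
#' @return Data frame of class `ale_cohort`: `person_id`, `unit_id`,
#'   `ale_class`, `age`, `sex`, `education`, `smoking`, `bmi`,
#'   `followup_years`, `survey_date`, `followup_end`, plus one column per
#'   configured outcome.
#' @export
generate_cohort <- function(units, unit_ale_class, config) {
  if (!inherits(config, "cohort_config"))
    stop("invalid config: expected a `cohort_config`")
  if (inherits(unit_ale_class, "ale_classification"))
    unit_ale_class <- unit_ale_class$assignment
  uac <- as.data.frame(unit_ale_class)
  if (!all(units$unit_id %in% uac$unit_id) ||
      anyNA(uac$ale_class[match(units$unit_id, uac$unit_id)]))
    stop("missing exposure: some units have no ALE class")
  if (!all(uac$ale_class %in% 1:5))
    stop("missing exposure: ALE classes must be 1-5")
  n <- config$n_respondents
  set.seed(config$seed)
  if (n == 0 || nrow(units) == 0) return(.empty_cohort(config))

  cls_of_unit <- uac$ale_class[match(units$unit_id, uac$unit_id)]
  if (!is.null(config$class_probs)) {
    present <- sort(unique(cls_of_unit))
    p <- config$class_probs[present] / sum(config$class_probs[present])
    cls <- sample(present, n, replace = TRUE, prob = p)
    unit_idx <- vapply(cls, function(cc) {
      cand <- which(cls_of_unit == cc)
      cand[sample.int(length(cand), 1)]
    }, integer(1))
  } else {
    unit_idx <- sample.int(nrow(units), n, replace = TRUE)
    cls <- cls_of_unit[unit_idx]
  }

  age <- .rtnorm(n, config$age_mean, config$age_sd, config$age_min)
  sex <- ifelse(stats::runif(n) < config$p_female, "female", "male")
  education <- sample(names(config$education_probs), n, replace = TRUE,
                      prob = config$education_probs)
  smoking <- sample(names(config$smoking_probs), n, replace = TRUE,
                    prob = config$smoking_probs)
  bmi <- pmax(stats::rnorm(n, config$bmi_mean, config$bmi_sd), 13)
  fu <- .rtnorm(n, config$followup_mean, config$followup_sd,
                config$followup_min)
  survey_date <- as.Date(sprintf("%d-01-01", config$survey_year)) +
    sample.int(365, n, replace = TRUE) - 1L

  out <- data.frame(person_id = sprintf("R%06d", seq_len(n)),
                    unit_id = units$unit_id[unit_idx],
                    ale_class = as.integer(cls),
                    age = age, sex = sex, education = education,
                    smoking = smoking, bmi = bmi,
                    followup_years = fu, survey_date = survey_date,
                    followup_end = survey_date + round(fu * 365.25))
  for (nm in names(config$true_log_odds)) {
    out[[nm]] <- .draw_outcome(out, config$true_log_odds[[nm]])
  }
  class(out) <- c("ale_cohort", "data.frame")
  out
}

# Linear predictor of a configured true logistic model, on the cohort frame.
.true_eta <- function(d, m) {
  g <- function(x, default = 0) if (is.null(x)) default else x
  eta <- rep(g(m$intercept), nrow(d))
  ale <- g(m$ale, rep(0, 5))
  eta <- eta + ale[d$ale_class]
  eta <- eta + g(m$age) * d$age + g(m$age2) * d$age^2
  eta <- eta + g(m$female) * (d$sex == "female")
  if (!is.null(m$education))
    eta <- eta + ifelse(d$education == "intermediate",
                        g(m$education[["intermediate"]]),
                        ifelse(d$education == "high",
                               g(m$education[["high"]]), 0))
  if (!is.null(m$smoking))
    eta <- eta + ifelse(d$smoking == "former", g(m$smoking[["former"]]),
                        ifelse(d$smoking == "current",
                               g(m$smoking[["current"]]), 0))
  if (isTRUE(m$offset_log_fu)) eta <- eta + log(d$followup_years)
  eta
}

.draw_outcome <- function(d, m) {
  stats::runif(nrow(d)) < stats::plogis(.true_eta(d, m))
}

.empty_cohort <- function(config) {
  out <- data.frame(person_id = character(0), unit_id = character(0),
                    ale_class = integer(0), age = numeric(0),
                    sex = character(0), education = character(0),
                    smoking = character(0), bmi = numeric(0),
                    followup_years = numeric(0),
                    survey_date = as.Date(character(0)),
                    followup_end = as.Date(character(0)))
  for (nm in names(config$true_log_odds)) out[[nm]] <- logical(0)
  class(out) <- c("ale_cohort", "data.frame")
  out
}
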