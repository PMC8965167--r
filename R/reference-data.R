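#' Published cohort margins for Wales and Canada
#'
#' Marginal summary totals of the two linked survey-hospitalization cohorts
#' (Welsh Health Survey 2013-14 linked to PEDW with follow-up to 2017;
#' Canadian Community Health Survey 2007 linked to DAD with follow-up to
#' 2011) as released from the trusted research environments. Canadian
#' frequencies are disclosure-rounded to base 5 at source. These margins
#' are what the synthetic scenario presets emulate, and the denominators for
#' the derived descriptive statistics in [reference_descriptives()].
#'
#' @param country `"wales"` or `"canada"`.
#' @return A list: `n` (respondents), `total_py` (person-years),
#'   `hospitalized` (named counts of persons ever hospitalized per cause),
#'   `n_obese`, `unit_class_counts` and `respondent_class_counts`
#'   (ALE classes 1-5).
#' @export
reference_summary <- function(country = c("wales", "canada")) {
  country <- match.arg(country)
  if (country == "wales") {
    list(n = 9968L, total_py = 38561,
         hospitalized = c(all_cause = 2334L, circulatory = 666L, enm = 229L,
                          respiratory = 444L, cancer = 428L,
                          cardiometabolic = 559L),
         n_obese = 2358L,
         unit_class_counts = c(484L, 517L, 510L, 279L, 106L),
         respondent_class_counts = c(2838L, 2932L, 2700L, 1138L, 360L))
  } else {
    list(n = 40335L, total_py = 179203,
         hospitalized = c(all_cause = 10235L, circulatory = 2815L,
                          enm = 1035L, respiratory = 1500L, cancer = 1655L,
                          cardiometabolic = 2265L),
         n_obese = 10880L,
         unit_class_counts = c(20722L, 15327L, 13077L, 4541L, 2422L),
         respondent_class_counts = c(19670L, 11045L, 7095L, 1750L, 780L))
  }
}

#' Derived descriptive statistics from the published margins
#'
#' Recomputes, from the marginal totals in [reference_summary()], the
#' derived descriptive quantities: mean follow-up (total person-years over
#' respondents), percent ever hospitalized per cause, the share of
#' geographic units and of respondents in ALE class 1, and obesity
#' prevalence. Percentages are on the 0-100 scale.
#'
#' @param country `"wales"` or `"canada"`.
#' @return Named list of numeric values (unrounded; display rounding is the
#'   caller's concern).
#' @export
reference_descriptives <- function(country = c("wales", "canada")) {
  s <- reference_summary(country)
  list(mean_followup_years = s$total_py / s$n,
       pct_hospitalized = 100 * s$hospitalized / s$n,
       class1_unit_share = 100 * s$unit_class_counts[1] /
         sum(s$unit_class_counts),
       class1_respondent_share = 100 * s$respondent_class_counts[1] /
         sum(s$respondent_class_counts),
       obesity_pct = 100 * s$n_obese / s$n)
}
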