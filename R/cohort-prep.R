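#' Packaged education vocabularies
#'
#' The three-level harmonization of educational attainment differs by
#' country: for Wales, "no qualifications" is low; degree-level,
#' professional, foreign, or level-4+ vocational qualifications are high;
#' everything else is intermediate. For Canada, those without high school
#' graduation are low, high school graduates intermediate, and postgraduate
#' degree or diploma holders high. Mappings are user-extensible via the
#' `map` argument of [harmonize_education()].
#'
#' @param country `"wales"` or `"canada"`.
#' @return Named character vector raw label -> harmonized level.
#' @export
education_map <- function(country = c("wales", "canada")) {
  country <- match.arg(country)
  if (country == "wales") {
    c("no qualifications" = "low",
      "gcse" = "intermediate",
      "a level" = "intermediate",
      "apprenticeship" = "intermediate",
      "vocational level 1-3" = "intermediate",
      "other qualification" = "intermediate",
      "degree" = "high",
      "professional qualification" = "high",
      "foreign qualification" = "high",
      "vocational level 4 or higher" = "high")
  } else {
    c("without high school graduation" = "low",
      "high school graduation" = "intermediate",
      "some post-secondary" = "intermediate",
      "post-secondary certificate or diploma" = "intermediate",
      "postgraduate degree or diploma" = "high")
  }
}

#' Harmonize raw education labels to three levels
#'
#' @param raw_label Character vector of raw labels (matched case-insensitively
#'   after trimming).
#' @param country `"wales"` or `"canada"`; selects the packaged vocabulary.
#' @param map Optional replacement/extension mapping (named character vector,
#'   raw label -> `"low"`/`"intermediate"`/`"high"`).
#' @return Character vector in `{low, intermediate, high}`. Unknown labels
#'   raise an error; they are never silently imputed.
#' @export
harmonize_education <- function(raw_label, country = c("wales", "canada"),
                                map = NULL) {
  m <- if (is.null(map)) education_map(country) else map
  key <- tolower(trimws(raw_label))
  out <- unname(m[key])
  if (anyNA(out))
    stop("mapping error: unknown education label(s): ",
         paste(unique(raw_label[is.na(out)]), collapse = ", "))
  out
}

#' Derive baseline health flags
#'
#' Obesity is body mass index strictly exceeding 30 kg/m2 (missing BMI gives
#' missing obesity, excluded from obesity models downstream). "No
#' exercise/leisure-time physical activity" is a report of zero activity
#' occasions over the country-specific recall window (7 days for Wales, 3
#' months for Canada); the two definitions test different concepts of
#' physical activity and are carried as labelled metadata, never pooled.
#'
#' @param bmi Numeric vector, kg/m2 (NA allowed).
#' @param activity_report Numeric count of reported activity occasions over
#'   the country's recall window.
#' @param diabetes_report Logical (or 0/1) self-reported type 2 diabetes.
#' @param country `"wales"` or `"canada"`.
#' @return Data frame `obese`, `no_activity`, `t2d` with an
#'   `activity_definition` attribute describing the recall window.
#' @export
derive_baseline_flags <- function(bmi, activity_report, diabetes_report,
                                  country = c("wales", "canada")) {
  country <- match.arg(country)
  if (any(bmi < 0, na.rm = TRUE))
    stop("invalid value: negative BMI")
  out <- data.frame(obese = bmi > 30,
                    no_activity = activity_report == 0,
                    t2d = as.logical(diabetes_report))
  attr(out, "activity_definition") <- if (country == "wales")
    "no exercise in the 7 days before survey response"
  else "no leisure-time physical activity in the 3 months before survey response"
  out
}

#' Round counts to a disclosure-control base
#'
#' Nearest multiple of `base`, half away from zero — the convention used for
#' reporting frequencies from confidential microdata. Applied only at the
#' reporting layer; analysis inputs are never rounded, and rounded cell
#' counts may legitimately fail to sum to rounded totals.
#'
#' @param count Non-negative integer vector.
#' @param base Rounding base (default 5).
#' @return Rounded counts.
#' @export
disclosure_round <- function(count, base = 5) {
  if (any(count < 0)) stop("invalid value: negative count")
  base * floor(count / base + 0.5)
}

#' Prepare a cohort for modelling
#'
#' Adds `age_sq` and converts exposure and adjusters to factors with the
#' fixed reference levels the models assume: ALE class 1, education low,
#' smoking never, sex male.
#'
#' @param cohort A cohort data frame (e.g. from [generate_cohort()]).
#' @return The cohort with `age_sq` and factor columns; class `ale_cohort`.
#' @export
prepare_cohort <- function(cohort) {
  d <- as.data.frame(cohort)
  if (any(d$age < 16)) stop("invalid cohort: ages below 16")
  if (any(d$followup_years <= 0))
    stop("invalid cohort: non-positive follow-up")
  d$age_sq <- d$age^2
  d$ale_class <- factor(d$ale_class, levels = 1:5)
  d$sex <- factor(d$sex, levels = c("male", "female"))
  d$education <- factor(d$education,
                        levels = c("low", "intermediate", "high"))
  d$smoking <- factor(d$smoking, levels = c("never", "former", "current"))
  class(d) <- c("ale_cohort", "data.frame")
  d
}
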