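#' Person-years of observation
#'
#' @param cohort Data frame with `followup_years > 0` per respondent.
#' @return List: `total_py` (sum of follow-up years), `mean_fu`, `sd_fu`,
#'   `n`.
#' @export
person_years <- function(cohort) {
  fu <- cohort$followup_years
  if (is.null(fu) || any(fu <= 0))
    stop("invalid cohort: every respondent needs positive follow-up")
  list(total_py = sum(fu), mean_fu = sum(fu) / length(fu),
       sd_fu = stats::sd(fu), n = length(fu))
}

#' Descriptive hospitalization statistics
#'
#' For each cause group: the number and percent of cohort members ever
#' hospitalized with a qualifying episode, the crude episode rate per 100
#' person-years (aggregate episode count divided by the *whole cohort's*
#' person-time, times 100), and the mean and SD of length of stay over
#' qualifying episodes. Percentages and rates are stored at full precision;
#' the print method displays them to one decimal.
#'
#' @param cohort Cohort data frame (`person_id`, `followup_years`).
#' @param episodes An [build_episodes()] result (or any data frame with
#'   `person_id`, `los_days`, and logical cause columns).
#' @param causes Cause columns to summarize.
#' @return Data frame of class `utilization_summary`, one row per cause:
#'   `cause`, `n_hospitalized`, `pct_hospitalized`, `n_episodes`,
#'   `rate_per_100py`, `mean_los`, `sd_los`, plus `total_py` and `n_cohort`
#'   attributes.
#' @export
summarize_utilization <- function(cohort, episodes,
                                  causes = c("all_cause", "circulatory",
                                             "enm", "respiratory", "cancer",
                                             "cardiometabolic")) {
  py <- person_years(cohort)
  if (nrow(episodes) && !all(episodes$person_id %in% cohort$person_id))
    stop("orphan episode: episode person missing from cohort")
  rows <- lapply(causes, function(cc) {
    q <- episodes[episodes[[cc]], , drop = FALSE]
    data.frame(cause = cc,
               n_hospitalized = length(unique(q$person_id)),
               pct_hospitalized = 100 * length(unique(q$person_id)) / py$n,
               n_episodes = nrow(q),
               rate_per_100py = 100 * nrow(q) / py$total_py,
               mean_los = if (nrow(q)) mean(q$los_days) else NA_real_,
               sd_los = if (nrow(q) > 1) stats::sd(q$los_days) else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "total_py") <- py$total_py
  attr(out, "n_cohort") <- py$n
  class(out) <- c("utilization_summary", "data.frame")
  out
}

#' @export
print.utilization_summary <- function(x, ...) {
  cat("Hospital utilization over", round(attr(x, "total_py"), 0),
      "person-years (n =", attr(x, "n_cohort"), ")\n")
  d <- data.frame(cause = x$cause,
                  hospitalized = sprintf("%d (%.1f%%)", x$n_hospitalized,
                                         x$pct_hospitalized),
                  episodes = x$n_episodes,
                  rate_per_100py = sprintf("%.1f", x$rate_per_100py),
                  los = ifelse(is.na(x$mean_los), "-",
                               sprintf("%.1f (%.1f)", x$mean_los, x$sd_los)))
  print(d, row.names = FALSE)
  invisible(x)
}
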