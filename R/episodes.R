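#' Build inpatient episodes from hospital discharge records
#'
#' Turns raw discharge records into analysis-ready inpatient episodes under
#' one of two national conventions:
#'
#' * `regime = "wales"` (person-spells): strictly contiguous records for the
#'   same person — next admission on or before the current discharge date —
#'   merge into one spell; after merging, spells with same-day start and end
#'   are treated as day cases and removed.
#' * `regime = "canada"` (episodes of care): records flagged as day
#'   procedures (`facility_flag == "A"`) are removed first; remaining records
#'   within `gap_hours` (default 24 h, i.e. one day at date resolution) of
#'   each other merge into one episode.
#'
#' A merged episode spans the earliest admission to the latest discharge of
#' its member records; length of stay is the whole-day difference. Cause
#' flags are derived from all member diagnoses in any position; an episode
#' whose primary diagnosis (first position of its earliest record) lies in
#' O00-O99 is excluded from all-cause and cause-specific counts
#' (pregnancy/childbirth exclusion; set `pregnancy_rule = "any"` to exclude
#' on any diagnostic position).
#'
#' @param records Data frame with `person_id`, `admit`, `discharge` (Date or
#'   ISO-8601 character), diagnosis columns `dx1`, `dx2`, ... (position 1 =
#'   primary), and optionally `facility_flag`.
#' @param regime `"wales"` or `"canada"`.
#' @param gap_hours Merge gap; defaults to 0 for Wales and 24 for Canada.
#' @param taxonomy A [cause_taxonomy()].
#' @param pregnancy_rule `"primary"` (default) or `"any"`.
#' @return Data frame of class `ale_episodes`, one row per episode:
#'   `person_id`, `start`, `end`, `los_days`, `n_records`, `primary_dx`, and
#'   logical cause columns `all_cause`, `circulatory`, `enm`, `respiratory`,
#'   `cancer`, `cardiometabolic`. A `summary` attribute records counts of
#'   records in, day cases removed, and episodes out.
#' @export
build_episodes <- function(records, regime = c("wales", "canada"),
                           gap_hours = NULL, taxonomy = cause_taxonomy(),
                           pregnancy_rule = c("primary", "any")) {
  regime <- match.arg(regime)
  pregnancy_rule <- match.arg(pregnancy_rule)
  if (is.null(gap_hours)) gap_hours <- if (regime == "canada") 24 else 0
  gap_days <- gap_hours / 24

  records <- as.data.frame(records)
  records$admit <- as.Date(records$admit)
  records$discharge <- as.Date(records$discharge)
  if (anyNA(records$admit) || anyNA(records$discharge))
    stop("invalid record: unparseable admission/discharge date")
  if (any(records$admit > records$discharge))
    stop("invalid record: admission after discharge")
  dx_cols <- grep("^dx[0-9]+$", names(records), value = TRUE)
  dx_cols <- dx_cols[order(as.integer(sub("dx", "", dx_cols)))]
  if (!length(dx_cols)) stop("invalid record: no diagnosis columns (dx1...)")

  n_in <- nrow(records)
  n_daycase <- 0L
  if (regime == "canada" && "facility_flag" %in% names(records)) {
    dc <- !is.na(records$facility_flag) & records$facility_flag == "A"
    n_daycase <- sum(dc)
    records <- records[!dc, , drop = FALSE]
  }
  if (nrow(records) == 0) {
    return(.empty_episodes(n_in, n_daycase))
  }

  ord <- order(records$person_id, records$admit, records$discharge)
  records <- records[ord, , drop = FALSE]
  pid <- records$person_id
  ad <- as.numeric(records$admit)
  di <- as.numeric(records$discharge)
  grp <- match(pid, unique(pid))
  # running max discharge of *previous* records within person
  prev_end <- stats::ave(di, grp,
                         FUN = function(v) c(-Inf, utils::head(cummax(v), -1)))
  new_ep <- ad > prev_end + gap_days
  new_ep[!duplicated(grp)] <- TRUE
  ep_id <- cumsum(new_ep)

  ef <- factor(ep_id, levels = unique(ep_id))  # keeps episode order
  start <- as.Date(as.numeric(tapply(ad, ef, min)), origin = "1970-01-01")
  end <- as.Date(as.numeric(tapply(di, ef, max)), origin = "1970-01-01")
  ep_person <- pid[!duplicated(ep_id)]
  n_rec <- as.integer(table(ef))
  primary_dx <- records[[dx_cols[1]]][!duplicated(ep_id)]

  # cause membership of every diagnosis, aggregated per episode
  all_codes <- unlist(records[dx_cols], use.names = FALSE)
  code_ep <- rep(ep_id, times = length(dx_cols))
  keep <- !is.na(all_codes) & all_codes != ""
  all_codes <- all_codes[keep]; code_ep <- code_ep[keep]
  causes <- c("circulatory", "enm", "respiratory", "cancer",
              "cardiometabolic", "pregnancy")
  flag <- matrix(FALSE, length(unique(ep_id)), length(causes),
                 dimnames = list(NULL, causes))
  if (length(all_codes)) {
    cm <- classify_causes(all_codes, taxonomy)
    for (cc in causes) {
      if (cc %in% colnames(cm)) {
        agg <- rowsum(as.integer(cm[, cc]), code_ep)
        flag[as.integer(rownames(agg)), cc] <- agg[, 1] > 0
      }
    }
  }
  excluded <- if (pregnancy_rule == "primary")
    icd_in_range(primary_dx, taxonomy$pregnancy) else flag[, "pregnancy"]

  out <- data.frame(person_id = ep_person, start = start, end = end,
                    los_days = as.integer(end - start), n_records = n_rec,
                    primary_dx = primary_dx,
                    all_cause = !excluded,
                    circulatory = flag[, "circulatory"] & !excluded,
                    enm = flag[, "enm"] & !excluded,
                    respiratory = flag[, "respiratory"] & !excluded,
                    cancer = flag[, "cancer"] & !excluded,
                    cardiometabolic = flag[, "cardiometabolic"] & !excluded)
  rownames(out) <- NULL

  if (regime == "wales") {
    dc <- out$los_days == 0L & out$n_records >= 1L & out$start == out$end
    n_daycase <- sum(dc)
    out <- out[!dc, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "summary") <- list(records_in = n_in,
                               day_cases_removed = n_daycase,
                               episodes_out = nrow(out), regime = regime,
                               gap_hours = gap_hours)
  class(out) <- c("ale_episodes", "data.frame")
  out
}

.empty_episodes <- function(n_in = 0L, n_daycase = 0L) {
  out <- data.frame(person_id = character(0),
                    start = as.Date(character(0)),
                    end = as.Date(character(0)),
                    los_days = integer(0), n_records = integer(0),
                    primary_dx = character(0),
                    all_cause = logical(0), circulatory = logical(0),
                    enm = logical(0), respiratory = logical(0),
                    cancer = logical(0), cardiometabolic = logical(0))
  attr(out, "summary") <- list(records_in = n_in,
                               day_cases_removed = n_daycase,
                               episodes_out = 0L)
  class(out) <- c("ale_episodes", "data.frame")
  out
}
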