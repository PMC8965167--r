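#' Normalize ICD-10 diagnosis codes
#'
#' Strips dots and whitespace, uppercases, and splits each code into its
#' chapter letter, two-digit major number, and optional trailing subdigits.
#' Codes not matching the letter + two digits (+ optional digits) pattern are
#' rejected.
#'
#' @param code Character vector of ICD-10 codes (e.g. `"I21.9"`, `"e112"`).
#' @return Data frame with columns `code` (normalized), `letter`, `major`
#'   (integer 0-99), `minor` (character, `""` when absent).
#' @export
normalize_icd <- function(code) {
  if (length(code) == 0)
    return(data.frame(code = character(0), letter = character(0),
                      major = integer(0), minor = character(0)))
  raw <- code
  code <- toupper(gsub("[. ]", "", as.character(code)))
  ok <- grepl("^[A-Z][0-9]{2}[0-9]*$", code)
  if (any(!ok | is.na(ok)))
    stop("invalid code: ", paste(unique(raw[!ok | is.na(ok)]), collapse = ", "))
  data.frame(code = code,
             letter = substr(code, 1, 1),
             major = as.integer(substr(code, 2, 3)),
             minor = substring(code, 4))
}

# Total order over 3-character stems: letter-major lexicographic, as an
# integer (A00 = 0, ..., Z99 = 2599).
.icd_value <- function(letter, major) {
  (match(letter, LETTERS) - 1L) * 100L + major
}

#' Construct an ICD-10 code range
#'
#' A closed range over 3-character stems, ordered letter-first then by major
#' number (so `C00-D48` spans two chapters). Subdigits never exclude a code
#' whose 3-character stem lies in range.
#'
#' @param from,to Range endpoints, e.g. `"I00"`, `"I99"`.
#' @return Object of class `icd_range`.
#' @export
icd_range <- function(from, to = from) {
  a <- normalize_icd(from); b <- normalize_icd(to)
  lo <- .icd_value(a$letter, a$major)
  hi <- .icd_value(b$letter, b$major)
  if (lo > hi) stop("invalid range: ", from, "-", to)
  structure(list(from = a$code, to = b$code, lo = lo, hi = hi),
            class = "icd_range")
}

#' Test ICD-10 codes for range membership
#'
#' @param code Character vector of codes (normalized internally).
#' @param range An [icd_range()] or a list of them (membership in any).
#' @return Logical vector.
#' @export
icd_in_range <- function(code, range) {
  p <- normalize_icd(code)
  v <- .icd_value(p$letter, p$major)
  if (inherits(range, "icd_range")) range <- list(range)
  out <- rep(FALSE, length(v))
  for (r in range) out <- out | (v >= r$lo & v <= r$hi)
  out
}

#' The cause taxonomy for hospitalization grouping
#'
#' Named ICD-10 ranges used to flag episode causes: circulatory (I00-I99),
#' endocrine/nutritional/metabolic (E00-E88), respiratory (J00-J98), cancer
#' (C00-D48), and the cardiometabolic subset most plausibly related to
#' physical inactivity — hypertension (I10-I15), ischaemic heart disease
#' (I20-I25), cerebrovascular disease (I61-I69), heart failure (I50), and
#' type 2 diabetes (E11-E14; E10, type 1 diabetes, is deliberately excluded).
#' `pregnancy` (O00-O99) defines the pregnancy/childbirth exclusion from
#' all-cause counts.
#'
#' @return Named list of class `cause_taxonomy`; each element is a list of
#'   [icd_range()]s.
#' @export
cause_taxonomy <- function() {
  structure(list(
    circulatory = list(icd_range("I00", "I99")),
    enm = list(icd_range("E00", "E88")),
    respiratory = list(icd_range("J00", "J98")),
    cancer = list(icd_range("C00", "D48")),
    cardiometabolic = list(icd_range("I10", "I15"), icd_range("I20", "I25"),
                           icd_range("I61", "I69"), icd_range("I50"),
                           icd_range("E11", "E14")),
    pregnancy = list(icd_range("O00", "O99"))),
    class = "cause_taxonomy")
}

#' Classify diagnosis codes into cause groups
#'
#' @param code Character vector of ICD-10 codes.
#' @param taxonomy A [cause_taxonomy()].
#' @return Logical matrix, one row per code, one column per cause group.
#' @export
classify_causes <- function(code, taxonomy = cause_taxonomy()) {
  m <- vapply(taxonomy, function(rng) icd_in_range(code, rng),
              logical(length(code)))
  if (length(code) == 1) m <- matrix(m, nrow = 1,
                                     dimnames = list(NULL, names(taxonomy)))
  m
}
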