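#' Keyword search over a patient's clinical letters
#'
#' Flags a patient when the keyword (default the literal phrase
#' "geographic atrophy") appears in at least one clinical letter. Matching
#' is a case-insensitive substring match after internal-whitespace
#' normalisation; there is no stemming or negation detection. The earliest
#' matching letter's date is recorded and is later used to flag subsequent
#' scans.
#'
#' @param letters List of letters, each a list with `date` and `text`.
#' @param keyword Search phrase.
#' @return An `ehr_flag`: list with `matched` (logical) and `earliest_date`
#'   (`Date`, or `NA` when unmatched).
#' @examples
#' ehr <- keyword_search(list(list(date = as.Date("2020-01-01"),
#'                                 text = "Geographic Atrophy noted")))
#' ehr$matched
#' @export
keyword_search <- function(letters, keyword = "geographic atrophy") {
  norm <- function(s) tolower(gsub("\\s+", " ", s))
  key <- norm(keyword)
  dates <- as.Date(character(0))
  for (l in letters) {
    if (grepl(key, norm(l$text), fixed = TRUE)) {
      dates <- c(dates, as.Date(l$date))
    }
  }
  structure(
    list(matched = length(dates) > 0,
         earliest_date = if (length(dates)) min(dates) else as.Date(NA)),
    class = "ehr_flag"
  )
}

#' Flag scans acquired on or after the earliest keyword mention
#'
#' A scan is flagged when the patient matched the keyword search and the
#' scan date is on or after the earliest mention (same-day scans count as
#' subsequent: letters typically follow the visit that produced the scan).
#'
#' @param flag An `ehr_flag` from [keyword_search()].
#' @param scan_dates Vector of scan dates.
#' @return Logical vector, one element per scan.
#' @export
flag_scans <- function(flag, scan_dates) {
  scan_dates <- as.Date(scan_dates)
  if (!length(scan_dates)) return(logical(0))
  if (!isTRUE(flag$matched)) return(rep(FALSE, length(scan_dates)))
  scan_dates >= flag$earliest_date
}

#' Run the keyword search over a whole cohort
#'
#' @param cohort A `cohort`.
#' @param keyword Search phrase.
#' @return Data frame with `patient_id`, `matched`, `earliest_date`.
#' @export
ehr_search_cohort <- function(cohort, keyword = "geographic atrophy") {
  stopifnot(inherits(cohort, "cohort"))
  rows <- lapply(cohort$patients, function(p) {
    fl <- keyword_search(p$letters, keyword)
    data.frame(patient_id = p$patient_id, matched = fl$matched,
               earliest_date = fl$earliest_date, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
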