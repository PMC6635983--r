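#' The five intervention components of the 2^5 factorial design
#'
#' Short codes and display names for the five app components, each
#' delivered in an 'enhanced' (active) or 'minimal' (control) version.
#' Allocation is carried in the participant table as five 0/1 columns
#' named \code{mod_<code>}.
#'
#' @return Named character vector: codes \code{nf}, \code{cbr},
#'   \code{smf}, \code{ap}, \code{ic} mapped to display names.
#' @export
trial_modules <- function() {
  c(nf  = "Normative Feedback",
    cbr = "Cognitive Bias Re-training",
    smf = "Self-monitoring and Feedback",
    ap  = "Action Planning",
    ic  = "Identity Change")
}

alloc_cols <- function() paste0("mod_", names(trial_modules()))

required_cols <- function() {
  c("id", "age", alloc_cols(),
    "baseline_pwac", "baseline_audit",
    "followup_pwac", "followup_audit",
    "responded", "phase")
}

#' Validate a participant table
#'
#' Checks the schema and core invariants of a trial data frame: required
#' columns present, allocation columns 0/1, phase labels known, AUDIT in
#' range, and the responder definition (responded is true if and only if
#' the follow-up primary outcome is present).
#'
#' @param records Data frame of participant records.
#' @return The validated data frame, invisibly usable downstream.
#' @export
validate_records <- function(records) {
  if (!is.data.frame(records)) stop("'records' must be a data frame", call. = FALSE)
  missing_cols <- setdiff(required_cols(), names(records))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(records$id))
    stop("duplicated participant ids: ",
         paste(utils::head(unique(records$id[duplicated(records$id)]), 5L),
               collapse = ", "), call. = FALSE)
  for (col in alloc_cols()) {
    if (!all(records[[col]] %in% c(0L, 1L)))
      stop("allocation column '", col, "' must be 0/1", call. = FALSE)
  }
  bad_phase <- setdiff(unique(records$phase), c("original", "extended"))
  if (length(bad_phase))
    stop("unknown phase label(s): ", paste(bad_phase, collapse = ", "),
         call. = FALSE)
  audit_ok <- is.na(records$baseline_audit) |
    (records$baseline_audit >= 0 & records$baseline_audit <= 40)
  if (!all(audit_ok))
    stop("baseline_audit outside 0-40 for id(s): ",
         paste(utils::head(records$id[!audit_ok], 5L), collapse = ", "),
         call. = FALSE)
  resp <- as.logical(records$responded)
  mismatch <- resp != !is.na(records$followup_pwac)
  if (any(mismatch))
    stop("responder flag inconsistent with follow-up presence for id(s): ",
         paste(utils::head(records$id[mismatch], 5L), collapse = ", "),
         call. = FALSE)
  records$responded <- resp
  records
}

#' Read / write the participant CSV
#'
#' One row per participant; allocation as five 0/1 columns; missing
#' follow-up encoded as an empty field. A read-write-read round trip is
#' lossless for tables produced by [simulate_trial()] (consumption held to
#' 0.1 units, AUDIT integer).
#'
#' @param path File path.
#' @return \code{read_trial_csv} returns a validated data frame.
#' @export
read_trial_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  df$id <- as.character(df$id)
  df$responded <- as.logical(df$responded)
  validate_records(df)
}

#' @rdname read_trial_csv
#' @param records Participant data frame.
#' @param header_comment Optional comment line(s) written before the
#'   header, each prefixed with \code{#} (used to record the simulation
#'   seed).
#' @export
write_trial_csv <- function(records, path, header_comment = NULL) {
  records <- validate_records(records)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  utils::write.csv(records, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Apply the trial eligibility criteria
#'
#' Retains participants aged 18 or over with a baseline AUDIT score of 8
#' or above (indicative of excessive drinking). Further criteria —
#' UK residence, interest in reducing drinking, email provided — are
#' modelled as pre-validated logical columns (\code{uk_resident},
#' \code{wants_reduce}, \code{has_email}); when present they must be TRUE
#' for inclusion. Records missing age or AUDIT are rejected with their ids
#' named in a warning.
#'
#' @param records Participant data frame.
#' @return The eligible subset; attributes \code{n_removed} and
#'   \code{n_rejected} count exclusions and invalid records.
#' @export
filter_eligible <- function(records) {
  records <- validate_records(records)
  invalid <- is.na(records$age) | is.na(records$baseline_audit)
  if (any(invalid)) {
    warning("rejected ", sum(invalid),
            " record(s) with missing age or AUDIT, id(s): ",
            paste(utils::head(records$id[invalid], 10L), collapse = ", "),
            call. = FALSE)
    records <- records[!invalid, , drop = FALSE]
  }
  keep <- records$age >= 18 & records$baseline_audit >= 8
  for (flag in c("uk_resident", "wants_reduce", "has_email")) {
    if (flag %in% names(records)) keep <- keep & records[[flag]]
  }
  out <- records[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "n_rejected") <- sum(invalid)
  out
}

new_analysis_set <- function(outcome_kind, values, records) {
  structure(list(outcome_kind = outcome_kind, values = values,
                 records = records),
            class = "analysis_set")
}

#' @export
print.analysis_set <- function(x, ...) {
  cat(sprintf("Analysis set '%s': %d participants, mean value %.2f (SD %.2f)\n",
              x$outcome_kind, length(x$values),
              mean(x$values), stats::sd(x$values)))
  invisible(x)
}

#' Change-score analysis set (responders only)
#'
#' Computes follow-up minus baseline for the chosen outcome; negative
#' values indicate a reduction over time. All passed records must be
#' responders for that outcome (follow-up value present) — filter first
#' with [responders()].
#'
#' @param records Responder records.
#' @param outcome \code{"pwac"} (past-week alcohol consumption, units) or
#'   \code{"audit"} (full AUDIT score).
#' @return An \code{analysis_set} with \code{outcome_kind}
#'   \code{change_pwac} or \code{change_audit}.
#' @export
change_scores <- function(records, outcome = c("pwac", "audit")) {
  outcome <- match.arg(outcome)
  records <- validate_records(records)
  fu <- records[[paste0("followup_", outcome)]]
  bl <- records[[paste0("baseline_", outcome)]]
  if (any(is.na(fu)))
    stop("non-responders present for outcome '", outcome,
         "' (id(s): ",
         paste(utils::head(records$id[is.na(fu)], 5L), collapse = ", "),
         "); restrict to responders first", call. = FALSE)
  values <- fu - bl
  names(values) <- records$id
  new_analysis_set(paste0("change_", outcome), values, records)
}

#' Responders for a given outcome
#'
#' Subset of records with the follow-up value of the chosen outcome
#' present. A record with follow-up consumption but a missing follow-up
#' AUDIT counts as a responder for consumption analyses only.
#'
#' @inheritParams change_scores
#' @export
responders <- function(records, outcome = c("pwac", "audit")) {
  outcome <- match.arg(outcome)
  records <- validate_records(records)
  records[!is.na(records[[paste0("followup_", outcome)]]), , drop = FALSE]
}

#' Last-observation-carried-forward analysis set
#'
#' Builds consumption \emph{levels} (not changes): follow-up past-week
#' consumption for responders, the baseline measure carried forward for
#' non-responders. Membership is every record passed in, which preserves
#' the variability in the data that an intention-to-treat zero-change
#' assumption would suppress.
#'
#' @param records Participant records (responders and non-responders).
#' @return An \code{analysis_set} with \code{outcome_kind}
#'   \code{"locf_pwac"}.
#' @export
locf_set <- function(records) {
  records <- validate_records(records)
  if (any(is.na(records$baseline_pwac)))
    stop("missing baseline consumption for id(s): ",
         paste(utils::head(records$id[is.na(records$baseline_pwac)], 5L),
               collapse = ", "), call. = FALSE)
  values <- ifelse(records$responded, records$followup_pwac,
                   records$baseline_pwac)
  names(values) <- records$id
  new_analysis_set("locf_pwac", values, records)
}

#' Recruitment-phase accounting
#'
#' Counts participants and follow-up responders per recruitment phase and
#' overall, with response rates as percentages rounded to 1 decimal for
#' reporting.
#'
#' @param records Participant records with \code{phase} labels
#'   (\code{original} or \code{extended}).
#' @return Data frame with one row per phase plus an overall row; columns
#'   \code{phase}, \code{n}, \code{responders}, \code{response_rate_pct}.
#' @export
phase_accounting <- function(records) {
  records <- validate_records(records)
  phases <- intersect(c("original", "extended"), unique(records$phase))
  rows <- lapply(c(phases, "overall"), function(ph) {
    sub <- if (ph == "overall") records else records[records$phase == ph, ]
    n <- nrow(sub)
    r <- sum(sub$responded)
    data.frame(phase = ph, n = n, responders = r,
               response_rate_pct = if (n > 0) round(100 * r / n, 1) else 0.0)
  })
  do.call(rbind, rows)
}
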