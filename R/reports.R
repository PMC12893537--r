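# The in-memory representation of a spontaneous-report set: four relational
# tables keyed by primaryid (one row per report version in $demo; drug,
# event and outcome rows in the others). This mirrors the FAERS file layout
# and keeps every operation vectorizable.

#' Construct a report set
#'
#' @param demo One row per report version: `primaryid`, `caseid`,
#'   `report_date` (8-digit integer key), `report_date_partial`,
#'   `event_onset` (`Date`), `sex`, `age_years`, `age_group`, `reporter`,
#'   `country`.
#' @param drugs Drug rows: `primaryid`, `drug_seq`, `name_raw`,
#'   `name_standard`, `role` (PS/SS/C/I), `route`, `start_date` (`Date`).
#' @param events Event rows: `primaryid`, `pt` (lower-case preferred term).
#' @param outcomes Outcome rows: `primaryid`, `outcome`.
#' @param quality Named list of ingestion quality counts.
#' @return A `faers_reports` object.
#' @export
faers_reports <- function(demo, drugs = NULL, events = NULL, outcomes = NULL,
                          quality = list()) {
  need <- c("primaryid", "caseid")
  if (!all(need %in% names(demo))) {
    pv_stop("demo must contain primaryid and caseid", "pv_config_error")
  }
  if (anyDuplicated(demo$primaryid)) {
    pv_stop("duplicate primaryid in demo", "pv_format_error")
  }
  defaults <- list(report_date = NA_integer_, report_date_partial = FALSE,
                   event_onset = as.Date(NA), sex = "unknown",
                   age_years = NA_real_, reporter = "unknown",
                   country = "unknown")
  for (nm in names(defaults)) {
    if (is.null(demo[[nm]])) demo[[nm]] <- defaults[[nm]]
  }
  demo$age_group <- age_group_of(demo$age_years)
  empty <- function(cols) {
    as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  }
  drugs <- drugs %||% empty(c("primaryid", "drug_seq", "name_raw",
                              "name_standard", "role", "route", "start_date"))
  events <- events %||% empty(c("primaryid", "pt"))
  outcomes <- outcomes %||% empty(c("primaryid", "outcome"))
  if (is.null(drugs$start_date)) drugs$start_date <- as.Date(NA)
  if (!inherits(drugs$start_date, "Date")) {
    drugs$start_date <- as.Date(as.character(drugs$start_date))
  }
  if (!inherits(demo$event_onset, "Date")) {
    demo$event_onset <- as.Date(as.character(demo$event_onset))
  }
  if (is.null(drugs$route)) drugs$route <- rep("other", nrow(drugs))
  if (is.null(drugs$name_standard)) drugs$name_standard <- trimlower(drugs$name_raw)
  if (is.null(demo$route)) {
    # report-level route: route of the first primary-suspect entry
    # (first drug row as fallback), "other" when no drug rows exist
    if (nrow(drugs)) {
      o <- order(drugs$primaryid, drugs$role != "PS", drugs$drug_seq)
      first <- drugs[o, , drop = FALSE]
      first <- first[!duplicated(first$primaryid), , drop = FALSE]
      demo$route <- first$route[match(demo$primaryid, first$primaryid)]
      demo$route[is.na(demo$route)] <- "other"
    } else {
      demo$route <- rep("other", nrow(demo))
    }
  }
  rownames(demo) <- rownames(drugs) <- rownames(events) <- rownames(outcomes) <- NULL
  structure(list(demo = demo, drugs = drugs, events = events,
                 outcomes = outcomes),
            quality = quality, class = "faers_reports")
}

#' @export
print.faers_reports <- function(x, ...) {
  cat(sprintf(
    "<faers_reports> %d report(s), %d case(s); %d drug row(s), %d event row(s), %d outcome row(s)\n",
    nrow(x$demo), length(unique(x$demo$caseid)), nrow(x$drugs),
    nrow(x$events), nrow(x$outcomes)))
  q <- attr(x, "quality")
  if (length(q)) {
    cat("quality log:",
        paste(sprintf("%s=%s", names(q), unlist(q)), collapse = ", "), "\n")
  }
  invisible(x)
}

n_reports <- function(x) nrow(x$demo)

# keep a subset of reports by primaryid, preserving demo order
reports_filter <- function(x, ids) {
  demo <- x$demo[x$demo$primaryid %in% ids, , drop = FALSE]
  keep <- demo$primaryid
  out <- faers_reports(
    demo,
    x$drugs[x$drugs$primaryid %in% keep, , drop = FALSE],
    x$events[x$events$primaryid %in% keep, , drop = FALSE],
    x$outcomes[x$outcomes$primaryid %in% keep, , drop = FALSE],
    quality = attr(x, "quality") %||% list()
  )
  out
}

#' Deduplicate report versions to one record per case
#'
#' FAERS carries every submitted version of a case; only the most recent
#' version by report date is retained. Ties on date are broken by the
#' larger `primaryid` (monotone with FAERS id issuance). The result is
#' sorted by `caseid`, so output order is deterministic, and the operation
#' is idempotent.
#'
#' @param x A `faers_reports` object.
#' @return A `faers_reports` object with exactly one record per `caseid`.
#' @export
deduplicate_reports <- function(x) {
  stopifnot(inherits(x, "faers_reports"))
  d <- x$demo
  if (nrow(d) == 0L) return(x)
  key <- ifelse(is.na(d$report_date), -1L, d$report_date)
  pid_num <- suppressWarnings(as.numeric(d$primaryid))
  pid_ord <- if (!anyNA(pid_num)) pid_num else xtfrm(d$primaryid)
  o <- order(d$caseid, -key, -pid_ord)
  survivors <- d$primaryid[o][!duplicated(d$caseid[o])]
  out <- reports_filter(x, survivors)
  out$demo <- out$demo[order(out$demo$caseid), , drop = FALSE]
  rownames(out$demo) <- NULL
  out
}

#' Select reports with a given drug as primary suspect
#'
#' @param x A deduplicated `faers_reports` object.
#' @param drug Standardized drug name.
#' @return The subset of reports containing at least one entry for `drug`
#'   with role code PS. An unknown drug yields a warning and an empty set.
#' @export
select_primary_suspect <- function(x, drug) {
  stopifnot(inherits(x, "faers_reports"))
  dr <- x$drugs
  if (!any(dr$name_standard == drug)) {
    warning(sprintf("drug '%s' not present in the report set", drug))
    return(reports_filter(x, character(0)))
  }
  ids <- unique(dr$primaryid[dr$name_standard == drug & dr$role == "PS"])
  reports_filter(x, ids)
}
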