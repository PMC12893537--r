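# Stratified, exclusion, comparator, demographic and time-to-onset
# analyses. Strata are self-contained: each stratum's 2x2 tables are built
# against that stratum's own background, so stratum tables sum cell-by-cell
# to the pooled table.

#' Partition a report set into strata
#'
#' @param x A deduplicated `faers_reports` object.
#' @param by `"age_group"` (levels <18, 18-65, >=65, unknown) or `"sex"`
#'   (female, male, unknown).
#' @return Named list of `faers_reports` subsets; the levels partition the
#'   input (unknown is a level).
#' @export
stratify_reports <- function(x, by = c("age_group", "sex")) {
  stopifnot(inherits(x, "faers_reports"))
  by <- match.arg(by)
  levels <- if (by == "age_group") age_group_levels else sex_levels
  value <- x$demo[[by]]
  out <- lapply(levels, function(l) reports_filter(x, x$demo$primaryid[value == l]))
  names(out) <- levels
  out
}

drug_classes_in_report <- function(x, dictionary, exclude_drug = NULL) {
  dr <- x$drugs
  if (!is.null(exclude_drug)) {
    dr <- dr[dr$name_standard != exclude_drug, , drop = FALSE]
  }
  cls <- map_with_default(dr$name_standard, dictionary$class_of, "none")
  data.frame(primaryid = dr$primaryid, class = cls, stringsAsFactors = FALSE)
}

#' Concomitant drug-class profile for selected events
#'
#' Among the target drug's primary-suspect reports mentioning each event,
#' counts the reports with at least one concomitant drug (any entry other
#' than the target itself, regardless of role code) in each anticoagulant
#' or antiplatelet class. Class rows are not mutually exclusive; the
#' none-of-the-classes row is exclusive of all class rows. Percentages are
#' rounded to one decimal.
#'
#' @param x A deduplicated `faers_reports` object.
#' @param target_drug Standardized drug name.
#' @param pts Character vector of PTs to profile.
#' @param dictionary A `drug_dictionary`.
#' @return Long data frame: `event`, `n_reports`, `class`, `count`,
#'   `percent`.
#' @export
concomitant_profile <- function(x, target_drug, pts, dictionary) {
  xt <- select_primary_suspect(x, target_drug)
  cls <- drug_classes_in_report(xt, dictionary, exclude_drug = target_drug)
  cls <- cls[cls$class %in% anticoagulant_classes, , drop = FALSE]
  pts <- trimlower(pts)
  rows <- lapply(pts, function(p) {
    ids <- unique(xt$events$primaryid[xt$events$pt == p])
    n <- length(ids)
    counts <- vapply(anticoagulant_classes, function(k) {
      length(unique(cls$primaryid[cls$class == k & cls$primaryid %in% ids]))
    }, integer(1))
    none <- n - length(unique(cls$primaryid[cls$primaryid %in% ids]))
    data.frame(event = p, n_reports = n,
               class = c(anticoagulant_classes, "none"),
               count = c(counts, none),
               percent = if (n > 0) round(100 * c(counts, none) / n, 1) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Disproportionality scan excluding concomitant antithrombotics
#'
#' Drops every report -- target and background alike -- containing any
#' drug of class heparin/LMWH, warfarin, DOAC, other anticoagulant or
#' antiplatelet other than the target drug itself, then reruns the full
#' contingency and scoring chain on the remainder.
#'
#' @inheritParams concomitant_profile
#' @param vocab Optional `meddra_vocab` (required for SOC level).
#' @param level `"PT"` or `"SOC"`.
#' @param thresholds A [signal_thresholds()] object.
#' @return A `signal_scan` object with an `n_excluded` element.
#' @export
exclusion_analysis <- function(x, target_drug, dictionary, vocab = NULL,
                               level = c("PT", "SOC"),
                               thresholds = signal_thresholds()) {
  level <- match.arg(level)
  cls <- drug_classes_in_report(x, dictionary, exclude_drug = target_drug)
  drop_ids <- unique(cls$primaryid[cls$class %in% anticoagulant_classes])
  keep <- setdiff(x$demo$primaryid, drop_ids)
  if (length(keep) == 0L) {
    warning("all reports contain concomitant antithrombotics; nothing left")
  }
  x2 <- reports_filter(x, keep)
  scan <- signal_scan(x2, target_drug, vocab, level, thresholds)
  scan$n_excluded <- length(drop_ids)
  scan
}

#' Comparative disproportionality across several drugs
#'
#' Runs the identical primary-suspect filter, contingency and scoring
#' chain for each comparator against the same dataset and thresholds; all
#' comparators share one gamma-Poisson prior fitted on the full cell set.
#'
#' @param x A deduplicated `faers_reports` object.
#' @param drugs Character vector of standardized drug names.
#' @param vocab Optional `meddra_vocab`.
#' @param level `"PT"` or `"SOC"`.
#' @param thresholds A [signal_thresholds()] object.
#' @param pts Optional PT subset to restrict the output to.
#' @return Long data frame keyed by `(drug, event)` with the per-scan
#'   score columns; the individual `signal_scan` objects are in
#'   `attr(, "scans")`.
#' @export
comparator_analysis <- function(x, drugs, vocab = NULL,
                                level = c("PT", "SOC"),
                                thresholds = signal_thresholds(),
                                pts = NULL) {
  level <- match.arg(level)
  hyper <- fit_mgps(drug_event_counts(x, vocab, level))
  scans <- lapply(drugs, function(d) {
    signal_scan(x, d, vocab, level, thresholds, hyper = hyper)
  })
  names(scans) <- drugs
  rows <- lapply(drugs, function(d) {
    s <- scans[[d]]$scores
    if (nrow(s) == 0L) return(NULL)
    cbind(drug = d, s, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(drug = character(0), event = character(0))
  }
  if (!is.null(pts)) out <- out[out$event %in% trimlower(pts), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scans") <- scans
  out
}

tto_bin_levels <- c("0-30", "31-60", "61-90", "91-120", "121-150",
                    "151-180", "181-360", ">360", "unknown")

tto_bin_of <- function(days) {
  out <- cut(days, breaks = c(-1, 30, 60, 90, 120, 150, 180, 360, Inf),
             labels = tto_bin_levels[1:8])
  out <- as.character(out)
  out[is.na(out)] <- "unknown"
  out
}

#' Time-to-onset analysis
#'
#' Computes, per report, the whole-day interval from the therapy start
#' date of the first primary-suspect drug entry to the event onset date
#' (same-day onset counts as 0 days). Negative intervals are excluded and
#' counted; partial or missing dates yield an unknown bin. Bins follow the
#' conventional 30-day grid with inclusive upper bounds (day 30 falls in
#' 0-30, day 31 in 31-60).
#'
#' @param x A `faers_reports` object (typically already restricted to the
#'   target drug's primary-suspect reports).
#' @param target_drug Optional: restrict the therapy-start lookup to this
#'   drug's PS entries.
#' @return An `onset_summary` object: per-report `tto` table, bin counts
#'   with percentages over all reports, median and quartiles over valid
#'   intervals, and counts of valid / unknown / negative intervals.
#' @export
onset_analysis <- function(x, target_drug = NULL) {
  stopifnot(inherits(x, "faers_reports"))
  dr <- x$drugs[x$drugs$role == "PS", , drop = FALSE]
  if (!is.null(target_drug)) {
    dr <- dr[dr$name_standard == target_drug, , drop = FALSE]
  }
  dr <- dr[order(dr$primaryid, dr$drug_seq), , drop = FALSE]
  dr <- dr[!duplicated(dr$primaryid), , drop = FALSE]
  start <- dr$start_date[match(x$demo$primaryid, dr$primaryid)]
  tto <- as.integer(x$demo$event_onset - start)
  n_negative <- sum(!is.na(tto) & tto < 0)
  tto[!is.na(tto) & tto < 0] <- NA_integer_
  bins <- tto_bin_of(tto)
  counts <- table(factor(bins, levels = tto_bin_levels))
  qs <- if (any(!is.na(tto))) {
    stats::quantile(tto, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  } else {
    rep(NA_real_, 3)
  }
  structure(list(
    tto = data.frame(primaryid = x$demo$primaryid, tto_days = tto,
                     bin = bins, stringsAsFactors = FALSE),
    counts = data.frame(bin = tto_bin_levels, n = as.integer(counts),
                        percent = round(100 * as.integer(counts) /
                                          max(1L, nrow(x$demo)), 2)),
    n_reports = nrow(x$demo), n_valid = sum(!is.na(tto)),
    n_negative = n_negative,
    q1 = qs[1], median = qs[2], q3 = qs[3]),
    class = "onset_summary")
}

#' @export
print.onset_summary <- function(x, ...) {
  cat(sprintf("Time to onset: %d of %d report(s) with a valid interval (%d negative excluded)\n",
              x$n_valid, x$n_reports, x$n_negative))
  cat(sprintf("median %.2f days (IQR %.2f-%.2f)\n", x$median, x$q1, x$q3))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

count_pct <- function(values, levels, denom) {
  n <- table(factor(values, levels = levels))
  data.frame(level = levels, n = as.integer(n),
             percent = round(100 * as.integer(n) / max(1L, denom), 2),
             stringsAsFactors = FALSE)
}

#' Demographic and clinical summary of a report set
#'
#' n (%) per level for sex, age group, reporter type, country, route and
#' outcomes, plus median (quartile) summaries for age and time to onset.
#' Report-level fields use the report count as denominator; outcome
#' percentages use the total number of outcome mentions (a report may
#' carry several outcomes).
#'
#' @param x A `faers_reports` object.
#' @return A `demographics_summary` object (a named list of data frames
#'   plus the continuous summaries).
#' @export
report_demographics <- function(x) {
  stopifnot(inherits(x, "faers_reports"))
  d <- x$demo
  n <- nrow(d)
  by_n <- function(df) df[order(-df$n), , drop = FALSE]
  countries <- unique(d$country)
  out_mentions <- nrow(x$outcomes)
  age_q <- if (any(!is.na(d$age_years))) {
    stats::quantile(d$age_years, c(0.25, 0.5, 0.75), na.rm = TRUE,
                    names = FALSE)
  } else rep(NA_real_, 3)
  onset <- onset_analysis(x)
  structure(list(
    n_reports = n,
    sex = count_pct(d$sex, sex_levels, n),
    age_group = count_pct(d$age_group, age_group_levels, n),
    reporter = by_n(count_pct(d$reporter, reporter_levels, n)),
    country = by_n(count_pct(d$country, countries, n)),
    route = by_n(count_pct(d$route, route_levels, n)),
    outcomes = by_n(count_pct(x$outcomes$outcome, outcome_levels,
                              out_mentions)),
    outcome_mentions = out_mentions,
    age = c(q1 = age_q[1], median = age_q[2], q3 = age_q[3]),
    tto = c(q1 = onset$q1, median = onset$median, q3 = onset$q3),
    tto_bins = onset$counts),
    class = "demographics_summary")
}

#' @export
print.demographics_summary <- function(x, ...) {
  cat(sprintf("Report set of %d report(s); %d outcome mention(s)\n",
              x$n_reports, x$outcome_mentions))
  cat(sprintf("age median %.1f (%.1f-%.1f); time to onset median %.1f (%.1f-%.1f) days\n",
              x$age["median"], x$age["q1"], x$age["q3"],
              x$tto["median"], x$tto["q1"], x$tto["q3"]))
  for (nm in c("sex", "age_group", "reporter", "route", "outcomes")) {
    cat("--", nm, "--\n")
    print(x[[nm]], row.names = FALSE)
  }
  invisible(x)
}

#' Export a demographics summary as CSV
#'
#' @param x A `demographics_summary` object.
#' @param path Output CSV path.
#' @return Invisibly, the long-format data frame written.
#' @export
export_demographics <- function(x, path) {
  blocks <- c("sex", "age_group", "reporter", "country", "route", "outcomes")
  rows <- lapply(blocks, function(b) cbind(variable = b, x[[b]]))
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
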