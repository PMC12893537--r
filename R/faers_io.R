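# Reading and writing the FAERS quarterly ASCII dialect: dollar-delimited
# text with one header line per file, file names DEMOyyQq / DRUGyyQq /
# REACyyQq / OUTCyyQq / THERyyQq. The writer emits exactly the dialect the
# reader consumes, so synthetic data can be round-tripped through the same
# ingestion path as downloaded data.

faers_schemas <- list(
  DEMO = c("primaryid", "caseid", "fda_dt", "event_dt", "age", "age_cod",
           "sex", "occp_cod", "occr_country"),
  DRUG = c("primaryid", "drug_seq", "role_cod", "drugname", "route"),
  REAC = c("primaryid", "pt"),
  OUTC = c("primaryid", "outc_cod"),
  THER = c("primaryid", "dsg_drug_seq", "start_dt")
)

faers_table_of <- function(path) {
  nm <- toupper(basename(path))
  hit <- regmatches(nm, regexpr("^(DEMO|DRUG|REAC|OUTC|THER)", nm))
  if (length(hit) == 0L) {
    pv_stop(sprintf("cannot infer FAERS table from file name '%s'", basename(path)),
            "pv_config_error")
  }
  hit
}

# age unit codes -> multiplier to years
age_unit_factors <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52,
                      DY = 1 / 365.25, HR = 1 / 8766)

sex_map <- c(F = "female", M = "male")
occp_map <- c(CN = "Consumer", MD = "Physician", PH = "Pharmacist",
              OT = "Other health-professional", LW = "Lawyer",
              RN = "Registered Nurse")
outc_map <- c(HO = "hospitalization", OT = "other_serious", DE = "death",
              LT = "life_threatening", DS = "disability",
              RI = "required_intervention", CA = "congenital_anomaly")
role_map <- c(PS = "PS", SS = "SS", C = "C", I = "I")
route_map <- c(sc = "subcutaneous", subcutaneous = "subcutaneous",
               iv = "intravenous", intravenous = "intravenous",
               po = "oral", oral = "oral",
               transplacental = "transplacental",
               im = "intramuscular", intramuscular = "intramuscular")

#' Read one dollar-delimited FAERS ASCII table
#'
#' Splits every non-header line on the dollar sign. Lines whose field count
#' does not match the header are rejected and counted, never silently
#' dropped.
#'
#' @param path Path to the file.
#' @param table Table name (`"DEMO"`, `"DRUG"`, `"REAC"`, `"OUTC"`,
#'   `"THER"`); inferred from the file name when `NULL`.
#' @return A data frame of raw text fields with attribute
#'   `"malformed_lines"` (integer count of rejected lines).
#' @export
read_faers_table <- function(path, table = NULL) {
  table <- table %||% faers_table_of(path)
  if (!table %in% names(faers_schemas)) {
    pv_stop(sprintf("unknown FAERS table '%s'", table), "pv_config_error")
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    pv_stop(sprintf("file '%s' has no header line", path), "pv_format_error")
  }
  header <- strsplit(lines[1L], "$", fixed = TRUE)[[1L]]
  schema <- faers_schemas[[table]]
  if (!all(schema %in% header)) {
    pv_stop(sprintf("file '%s' is missing required %s columns: %s", path,
                    table, paste(setdiff(schema, header), collapse = ", ")),
            "pv_format_error")
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "$", fixed = TRUE)
  # a trailing empty field is dropped by strsplit; restore arity
  lens <- lengths(parts)
  short1 <- lens == length(header) - 1L & endsWith(body, "$")
  parts[short1] <- lapply(parts[short1], function(p) c(p, ""))
  lens <- lengths(parts)
  good <- lens == length(header)
  n_bad <- sum(!good)
  if (any(good)) {
    mat <- matrix(unlist(parts[good], use.names = FALSE),
                  ncol = length(header), byrow = TRUE)
    df <- as.data.frame(mat, stringsAsFactors = FALSE)
    names(df) <- header
    df <- df[schema]
  } else {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(schema)),
                                        schema))
  }
  attr(df, "malformed_lines") <- n_bad
  df
}

collect_faers_files <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "^(DEMO|DRUG|REAC|OUTC|THER).*\\.txt$",
                        full.names = TRUE, ignore.case = TRUE)
  }
  if (length(paths) == 0L) {
    pv_stop("no FAERS ASCII files found", "pv_config_error")
  }
  split(paths, vapply(paths, faers_table_of, character(1)))
}

#' Read FAERS-style ASCII tables into a report set
#'
#' Parses the quarterly ASCII tables (several quarters may be supplied at
#' once), joins them on `primaryid`, and normalizes demographic fields:
#' ages are converted to years from the FAERS unit codes, age groups are
#' assigned at the <18 / 18-65 / >=65 cut points, and sex, route, reporter
#' and outcome codes are mapped to their label sets with anything
#' unrecognized collapsing to the catch-all level. Implausible ages
#' (negative or above 130 years) are treated as missing. Reports with no
#' event rows are dropped. All of these are tallied in the quality log
#' (`attr(x, "quality")`).
#'
#' @param paths Character vector of file paths, or a single directory.
#' @param dictionary Optional [load_drug_dictionary()] object used to
#'   standardize drug names; without one, names are lower-cased and
#'   trimmed.
#' @return A `faers_reports` object.
#' @seealso [write_faers_ascii()], [deduplicate_reports()]
#' @export
read_faers_ascii <- function(paths, dictionary = NULL) {
  files <- collect_faers_files(paths)
  if (!"DEMO" %in% names(files)) {
    pv_stop("no DEMO file supplied", "pv_config_error")
  }
  quality <- c(malformed_lines = 0L, implausible_ages = 0L,
               partial_dates = 0L, reports_without_events = 0L)
  read_all <- function(table) {
    if (!table %in% names(files)) {
      return(as.data.frame(stats::setNames(
        rep(list(character(0)), length(faers_schemas[[table]])),
        faers_schemas[[table]])))
    }
    pieces <- lapply(files[[table]], read_faers_table, table = table)
    quality["malformed_lines"] <<- quality["malformed_lines"] +
      sum(vapply(pieces, attr, integer(1), which = "malformed_lines"))
    do.call(rbind, pieces)
  }
  demo_raw <- read_all("DEMO")
  drug_raw <- read_all("DRUG")
  reac_raw <- read_all("REAC")
  outc_raw <- read_all("OUTC")
  ther_raw <- read_all("THER")

  fda <- parse_faers_date(demo_raw$fda_dt)
  onset <- parse_faers_date(demo_raw$event_dt)
  quality["partial_dates"] <- sum(fda$partial) + sum(onset$partial)

  age_val <- suppressWarnings(as.numeric(demo_raw$age))
  age_fac <- map_with_default(toupper(trimws(demo_raw$age_cod)),
                              age_unit_factors, NA_real_)
  age_years <- age_val * age_fac
  implausible <- !is.na(age_years) & (age_years < 0 | age_years > 130)
  quality["implausible_ages"] <- sum(implausible)
  age_years[implausible] <- NA_real_

  demo <- data.frame(
    primaryid = trimws(demo_raw$primaryid),
    caseid = trimws(demo_raw$caseid),
    report_date = fda$key,
    report_date_partial = fda$partial,
    event_onset = onset$date,
    sex = map_with_default(toupper(trimws(demo_raw$sex)), sex_map, "unknown"),
    age_years = age_years,
    age_group = age_group_of(age_years),
    reporter = map_with_default(toupper(trimws(demo_raw$occp_cod)),
                                occp_map, "unknown"),
    country = ifelse(nzchar(trimws(demo_raw$occr_country)),
                     trimws(demo_raw$occr_country), "unknown"),
    stringsAsFactors = FALSE
  )

  ther_key <- paste(trimws(ther_raw$primaryid), trimws(ther_raw$dsg_drug_seq))
  start <- parse_faers_date(ther_raw$start_dt)
  quality["partial_dates"] <- quality["partial_dates"] + sum(start$partial)
  start_lookup <- start$date[!duplicated(ther_key)]
  names(start_lookup) <- ther_key[!duplicated(ther_key)]

  name_raw <- trimws(drug_raw$drugname)
  if (is.null(dictionary)) {
    name_standard <- trimlower(name_raw)
  } else {
    name_standard <- classify_drug(dictionary, name_raw)$name_standard
  }
  drug_key <- paste(trimws(drug_raw$primaryid), trimws(drug_raw$drug_seq))
  drugs <- data.frame(
    primaryid = trimws(drug_raw$primaryid),
    drug_seq = suppressWarnings(as.integer(trimws(drug_raw$drug_seq))),
    name_raw = name_raw,
    name_standard = name_standard,
    role = map_with_default(toupper(trimws(drug_raw$role_cod)), role_map, "C"),
    route = map_with_default(trimlower(drug_raw$route), route_map, "other"),
    start_date = as.Date(unname(start_lookup[drug_key]), origin = "1970-01-01"),
    stringsAsFactors = FALSE
  )

  events <- data.frame(primaryid = trimws(reac_raw$primaryid),
                       pt = trimlower(reac_raw$pt),
                       stringsAsFactors = FALSE)
  events <- events[nzchar(events$pt), , drop = FALSE]

  outcomes <- data.frame(
    primaryid = trimws(outc_raw$primaryid),
    outcome = map_with_default(toupper(trimws(outc_raw$outc_cod)),
                               outc_map, "other_serious"),
    stringsAsFactors = FALSE
  )
  outcomes <- outcomes[nzchar(trimws(outc_raw$outc_cod)), , drop = FALSE]

  # spontaneous reports must carry at least one event
  has_event <- demo$primaryid %in% events$primaryid
  quality["reports_without_events"] <- sum(!has_event)
  demo <- demo[has_event, , drop = FALSE]

  faers_reports(demo, drugs, events, outcomes, quality = as.list(quality))
}

rev_map <- function(map) stats::setNames(names(map), unname(map))

#' Write a report set to FAERS-style ASCII files
#'
#' Emits the five dollar-delimited tables (`DEMO`, `DRUG`, `REAC`, `OUTC`,
#' `THER`) in the dialect [read_faers_ascii()] consumes; re-reading the
#' files reproduces the records field for field (for fully dated records).
#'
#' @param x A `faers_reports` object.
#' @param dir Output directory (created if absent).
#' @param quarter Quarter tag appended to the file names, e.g. `"24Q3"`.
#' @return Invisibly, the paths written.
#' @export
write_faers_ascii <- function(x, dir, quarter = "24Q3") {
  stopifnot(inherits(x, "faers_reports"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- x$demo
  sex_rev <- c(female = "F", male = "M", unknown = "")
  occp_rev <- c(rev_map(occp_map), unknown = "")
  outc_rev <- rev_map(outc_map)
  route_rev <- c(subcutaneous = "SC", intravenous = "IV", oral = "PO",
                 transplacental = "TRANSPLACENTAL", intramuscular = "IM",
                 other = "OT")
  fmt_num <- function(v) ifelse(is.na(v), "", sprintf("%.15g", v))
  demo_out <- cbind(
    d$primaryid, d$caseid,
    ifelse(is.na(d$report_date), "", sprintf("%08d", d$report_date)),
    ifelse(is.na(d$event_onset), "", date_to_key(d$event_onset)),
    fmt_num(d$age_years), ifelse(is.na(d$age_years), "", "YR"),
    unname(sex_rev[d$sex]), unname(occp_rev[d$reporter]),
    ifelse(d$country == "unknown", "", d$country)
  )
  dr <- x$drugs
  drug_out <- cbind(dr$primaryid, as.character(dr$drug_seq), dr$role,
                    dr$name_raw, unname(route_rev[dr$route]))
  reac_out <- cbind(x$events$primaryid, x$events$pt)
  outc_out <- cbind(x$outcomes$primaryid,
                    unname(outc_rev[x$outcomes$outcome]))
  has_start <- !is.na(dr$start_date)
  ther_out <- cbind(dr$primaryid[has_start],
                    as.character(dr$drug_seq[has_start]),
                    date_to_key(dr$start_date[has_start]))
  tables <- list(DEMO = demo_out, DRUG = drug_out, REAC = reac_out,
                 OUTC = outc_out, THER = ther_out)
  paths <- character(0)
  for (nm in names(tables)) {
    path <- file.path(dir, paste0(nm, quarter, ".txt"))
    header <- paste(faers_schemas[[nm]], collapse = "$")
    body <- apply(tables[[nm]], 1L, paste, collapse = "$")
    writeLines(c(header, body), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Write the ingestion quality log as CSV
#'
#' @param x A `faers_reports` object.
#' @param path Output CSV path.
#' @return Invisibly, the quality log as a data frame.
#' @export
write_quality_log <- function(x, path) {
  q <- attr(x, "quality") %||% list()
  df <- data.frame(metric = names(q), count = unlist(q, use.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
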