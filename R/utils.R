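# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

trimlower <- function(x) tolower(trimws(as.character(x)))

pv_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "pv_error", "error", "condition")))
}

# FAERS dates are 8-digit yyyymmdd integers. 6-digit (yyyymm) and 4-digit
# (yyyy) partial dates are padded with 01 so they still order correctly for
# deduplication, but are flagged partial and treated as missing wherever an
# actual day-level interval is computed (time to onset).
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[!is.na(x) & x == ""] <- NA_character_
  n <- nchar(x)
  n[is.na(x)] <- 0L
  padded <- x
  padded[n == 4L] <- paste0(x[n == 4L], "0101")
  padded[n == 6L] <- paste0(x[n == 6L], "01")
  padded[!(n %in% c(4L, 6L, 8L))] <- NA_character_
  key <- suppressWarnings(as.integer(padded))
  partial <- n %in% c(4L, 6L) & !is.na(key)
  date <- as.Date(rep(NA_integer_, length(x)), origin = "1970-01-01")
  full <- n == 8L & !is.na(key)
  date[full] <- as.Date(padded[full], format = "%Y%m%d")
  # invalid calendar dates (e.g. month 13) fail as.Date; drop their key too
  bad <- full & is.na(date)
  key[bad] <- NA_integer_
  data.frame(key = key, date = date, partial = partial & !is.na(key))
}

date_to_key <- function(d) {
  out <- rep(NA_character_, length(d))
  ok <- !is.na(d)
  out[ok] <- format(d[ok], "%Y%m%d")
  out
}

# age groups per the usual spontaneous-report cut points
age_group_of <- function(age_years) {
  out <- rep("unknown", length(age_years))
  ok <- !is.na(age_years)
  out[ok & age_years < 18] <- "<18"
  out[ok & age_years >= 18 & age_years < 65] <- "18-65"
  out[ok & age_years >= 65] <- ">=65"
  out
}

age_group_levels <- c("<18", "18-65", ">=65", "unknown")
sex_levels <- c("female", "male", "unknown")
route_levels <- c("subcutaneous", "intravenous", "oral", "transplacental",
                  "intramuscular", "other")
reporter_levels <- c("Consumer", "Physician", "Pharmacist",
                     "Other health-professional", "Lawyer",
                     "Registered Nurse", "unknown")
outcome_levels <- c("hospitalization", "other_serious", "death",
                    "life_threatening", "disability",
                    "required_intervention", "congenital_anomaly")
drug_class_levels <- c("heparin_lmwh", "warfarin", "doac",
                       "other_anticoagulant", "antiplatelet", "none")
anticoagulant_classes <- drug_class_levels[1:5]

map_with_default <- function(x, map, default) {
  out <- unname(map[x])
  out[is.na(out)] <- default
  out
}
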