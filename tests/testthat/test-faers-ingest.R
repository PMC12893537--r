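# Ingestion of the dollar-delimited ASCII dialect, deduplication and
# primary-suspect selection.

write_lines_tmp <- function(lines, name, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, name)
  writeLines(lines, path)
  path
}

test_that("parser splits on the dollar sign and counts malformed lines", {
  dir <- withr::local_tempdir()
  demo <- write_lines_tmp(c(
    "primaryid$caseid$fda_dt$event_dt$age$age_cod$sex$occp_cod$occr_country",
    "11$1$20200101$20200101$65$YR$F$MD$US",
    "21$2$20200202$$40$YR$M$CN$FR"), "DEMO20Q1.txt", dir)
  tab <- read_faers_table(demo)
  expect_equal(nrow(tab), 2L)
  expect_named(tab, c("primaryid", "caseid", "fda_dt", "event_dt", "age",
                      "age_cod", "sex", "occp_cod", "occr_country"))
  expect_equal(attr(tab, "malformed_lines"), 0L)

  drug <- write_lines_tmp(c(
    "primaryid$drug_seq$role_cod$drugname$route",
    "11$1$PS$fondaparinux$SC",
    "21$1$PS$warfarin"), "DRUG20Q1.txt", dir)
  tab2 <- read_faers_table(drug)
  expect_equal(nrow(tab2), 1L)
  expect_equal(attr(tab2, "malformed_lines"), 1L)

  empty <- write_lines_tmp(character(0), "REAC20Q1.txt", dir)
  expect_error(read_faers_table(empty), class = "pv_format_error")
  foo <- write_lines_tmp("a$b", "FOO20Q1.txt", dir)
  expect_error(read_faers_table(foo), class = "pv_config_error")
})

test_that("a fixture quarter assembles into reports with hand-counted lists", {
  dir <- withr::local_tempdir()
  write_lines_tmp(c(
    "primaryid$caseid$fda_dt$event_dt$age$age_cod$sex$occp_cod$occr_country",
    "11$1$20200101$20200103$65$YR$F$MD$US",
    "21$2$20200102$$40$YR$M$CN$FR",
    "31$3$20200103$$7.5$DEC$F$PH$",
    "41$4$20200104$$18$MON$$OT$US",
    "51$5$20200105$$150$YR$M$MD$US"), "DEMO20Q1.txt", dir)
  write_lines_tmp(c(
    "primaryid$drug_seq$role_cod$drugname$route",
    "11$1$PS$fondaparinux$SC",
    "11$2$C$aspirin$PO",
    "21$1$PS$warfarin$PO",
    "31$1$PS$fondaparinux$SC",
    "31$2$SS$heparin$IV",
    "31$3$C$metformin$PO",
    "41$1$PS$enoxaparin$SC",
    "51$1$XX$fondaparinux$SC"), "DRUG20Q1.txt", dir)
  write_lines_tmp(c(
    "primaryid$pt",
    "11$Haematoma",
    "11$anaemia",
    "21$haemorrhage",
    "31$haematoma",
    "31$haematoma",
    "41$rash",
    "51$epistaxis"), "REAC20Q1.txt", dir)
  x <- read_faers_ascii(dir)
  expect_s3_class(x, "faers_reports")
  expect_equal(nrow(x$demo), 5L)
  n_drugs <- table(x$drugs$primaryid)
  expect_equal(as.integer(n_drugs[c("11", "21", "31", "41", "51")]),
               c(2L, 1L, 3L, 1L, 1L))
  n_events <- table(x$events$primaryid)
  expect_equal(as.integer(n_events[c("11", "21", "31", "41", "51")]),
               c(2L, 1L, 2L, 1L, 1L))
  # PT case folding
  expect_true(all(x$events$pt == tolower(x$events$pt)))
  # unrecognized role code collapses to concomitant
  expect_equal(x$drugs$role[x$drugs$primaryid == "51"], "C")
})

test_that("ages convert from FAERS unit codes and map to age groups", {
  dir <- withr::local_tempdir()
  write_lines_tmp(c(
    "primaryid$caseid$fda_dt$event_dt$age$age_cod$sex$occp_cod$occr_country",
    "11$1$20200101$$65$YR$F$MD$US",
    "21$2$20200101$$7.5$DEC$M$MD$US",
    "31$3$20200101$$18$MON$F$MD$US",
    "41$4$20200101$$150$YR$M$MD$US",
    "51$5$20200101$$-4$YR$M$MD$US"), "DEMO20Q1.txt", dir)
  write_lines_tmp(c("primaryid$pt", "11$p", "21$p", "31$p", "41$p", "51$p"),
                  "REAC20Q1.txt", dir)
  x <- read_faers_ascii(dir)
  ages <- x$demo$age_years[match(c("11", "21", "31", "41", "51"),
                                 x$demo$primaryid)]
  expect_equal(ages, c(65, 75, 1.5, NA, NA))
  groups <- x$demo$age_group[match(c("11", "21", "31"), x$demo$primaryid)]
  expect_equal(groups, c(">=65", ">=65", "<18"))
  expect_equal(attr(x, "quality")$implausible_ages, 2L)
})

test_that("deduplication keeps the latest version with a deterministic tie-break", {
  x <- mk_reports(
    rpt("101", case = "1", date = 20200101L, pts = "p",
        drugs = list(d("x"))),
    rpt("102", case = "1", date = 20200301L, pts = "q",
        drugs = list(d("x"))),
    rpt("100", case = "2", date = 20200101L, pts = "p",
        drugs = list(d("y"))),
    rpt("200", case = "2", date = 20200101L, pts = "q",
        drugs = list(d("y"))))
  dd <- deduplicate_reports(x)
  expect_equal(sort(dd$demo$primaryid), c("102", "200"))
  # exactly one record per case, partition sums conserved
  expect_equal(length(unique(dd$demo$caseid)),
               length(unique(x$demo$caseid)))
  # idempotence
  expect_identical(deduplicate_reports(dd)$demo, dd$demo)
})

test_that("primary-suspect selection is exact on role and drug", {
  specs <- c(
    list(rpt("s1", pts = "p", drugs = list(d("fondaparinux", "SS")))),
    list(rpt("s2", pts = "p", drugs = c(list(d("fondaparinux", "PS")),
                                        lapply(1:5, function(i)
                                          d(paste0("c", i), "C"))))),
    lapply(3:5, function(i) rpt(paste0("s", i), pts = "p",
                                drugs = list(d("fondaparinux", "PS")))),
    lapply(6:10, function(i) rpt(paste0("s", i), pts = "p",
                                 drugs = list(d("other", "PS")))))
  x <- do.call(mk_reports, specs)
  sel <- select_primary_suspect(x, "fondaparinux")
  expect_equal(nrow(sel$demo), 4L)
  expect_false("s1" %in% sel$demo$primaryid)
  expect_true("s2" %in% sel$demo$primaryid)
  expect_warning(empty <- select_primary_suspect(x, "absent-drug"),
                 "not present")
  expect_equal(nrow(empty$demo), 0L)
})

test_that("writing and re-reading the ASCII dialect round-trips a report set", {
  cfg <- synthetic_config(n_reports = 150, duplicate_rate = 0.2)
  x <- generate_reports(cfg, seed = 7)
  dir <- withr::local_tempdir()
  write_faers_ascii(x, dir, quarter = "24Q1")
  y <- read_faers_ascii(dir)
  expect_equal(nrow(y$demo), nrow(x$demo))
  ord <- function(df, cols) {
    df <- df[do.call(order, df[cols]), sort(names(df)), drop = FALSE]
    rownames(df) <- NULL
    df
  }
  expect_equal(ord(y$demo, c("primaryid")), ord(x$demo, c("primaryid")))
  expect_equal(ord(y$drugs, c("primaryid", "drug_seq")),
               ord(x$drugs, c("primaryid", "drug_seq")))
  expect_equal(ord(y$events, c("primaryid", "pt")),
               ord(x$events, c("primaryid", "pt")))
  expect_equal(ord(y$outcomes, c("primaryid", "outcome")),
               ord(x$outcomes, c("primaryid", "outcome")))
  # deduplication removes exactly the injected duplicate versions
  expect_equal(nrow(deduplicate_reports(y)$demo), 150L)
})
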