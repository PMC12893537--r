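# Stratified, exclusion, comparator, onset and demographic analyses.

test_that("age stratification maps boundary ages to the stated levels", {
  x <- mk_reports(
    rpt("1", age = 10, pts = "p", drugs = list(d("x"))),
    rpt("2", age = 30, pts = "p", drugs = list(d("x"))),
    rpt("3", age = 70, pts = "p", drugs = list(d("x"))),
    rpt("4", age = NA, pts = "p", drugs = list(d("x"))),
    rpt("5", age = 65, pts = "p", drugs = list(d("x"))))
  strata <- stratify_reports(x, "age_group")
  expect_equal(strata[["<18"]]$demo$primaryid, "1")
  expect_equal(strata[["18-65"]]$demo$primaryid, "2")
  expect_setequal(strata[[">=65"]]$demo$primaryid, c("3", "5"))
  expect_equal(strata[["unknown"]]$demo$primaryid, "4")
  expect_equal(sum(vapply(strata, function(s) nrow(s$demo), 0L)),
               nrow(x$demo))
})

test_that("concomitant profile counts classes non-exclusively with a none row", {
  dict <- toy_dict()
  x <- mk_reports(
    rpt("1", pts = "haematoma", drugs = list(d("fondaparinux"))),
    rpt("2", pts = "haematoma", drugs = list(d("fondaparinux"),
                                             d("heparin", "C"))),
    rpt("3", pts = "haematoma", drugs = list(d("fondaparinux"),
                                             d("warfarin", "C"),
                                             d("aspirin", "C"))),
    rpt("4", pts = "haematoma", drugs = list(d("fondaparinux"),
                                             d("metformin", "C"))),
    rpt("5", pts = "rash", drugs = list(d("fondaparinux"))))
  prof <- concomitant_profile(x, "fondaparinux", "haematoma", dict)
  get <- function(cl) prof[prof$class == cl, ]
  expect_equal(get("heparin_lmwh")$count, 1L)
  expect_equal(get("heparin_lmwh")$percent, 25.0)
  # report 3 counts once in each of two class rows
  expect_equal(get("warfarin")$count, 1L)
  expect_equal(get("antiplatelet")$count, 1L)
  # none row excludes any report with a classed concomitant
  expect_equal(get("none")$count, 2L)
  expect_equal(get("none")$percent, 50.0)
  expect_true(all(prof$n_reports == 4L))
  # absent PT gives a zero row
  zero <- concomitant_profile(x, "fondaparinux", "absent pt", dict)
  expect_true(all(zero$count == 0L))
})

test_that("exclusion analysis drops antithrombotic co-reports and recounts", {
  dict <- toy_dict()
  mk8 <- function() mk_reports(
    rpt("1", pts = "haematoma", drugs = list(d("fondaparinux"))),
    rpt("2", pts = "haematoma", drugs = list(d("fondaparinux"),
                                             d("heparin", "C"))),
    rpt("3", pts = "rash", drugs = list(d("fondaparinux"))),
    rpt("4", pts = "haematoma", drugs = list(d("metformin"))),
    rpt("5", pts = "haematoma", drugs = list(d("metformin"),
                                             d("aspirin", "C"))),
    rpt("6", pts = "rash", drugs = list(d("metformin"))),
    rpt("7", pts = "nausea", drugs = list(d("metformin"))),
    rpt("8", pts = "nausea", drugs = list(d("lisinopril"))))
  x <- mk8()
  ex <- exclusion_analysis(x, "fondaparinux", dict,
                           thresholds = signal_thresholds(min_cases = 1))
  expect_equal(ex$n_excluded, 2L)
  expect_equal(ex$n_reports, 6L)
  # brute-force recount on the six remaining reports
  keep <- setdiff(x$demo$primaryid, c("2", "5"))
  want <- brute_tables(pvsignal:::reports_filter(x, keep), "fondaparinux")
  got <- ex$tables
  expect_equal(got$event, want$event)
  expect_equal(as.numeric(got$a), as.numeric(want$a))
  expect_equal(as.numeric(got$d), as.numeric(want$d))
  # with no antithrombotic concomitants anywhere, exclusion is the identity
  x2 <- mk_reports(
    rpt("1", pts = "haematoma", drugs = list(d("fondaparinux"))),
    rpt("2", pts = "rash", drugs = list(d("metformin"))),
    rpt("3", pts = "haematoma", drugs = list(d("metformin"))))
  ex2 <- exclusion_analysis(x2, "fondaparinux", dict,
                            thresholds = signal_thresholds(min_cases = 1))
  main2 <- signal_scan(x2, "fondaparinux",
                       thresholds = signal_thresholds(min_cases = 1))
  expect_equal(ex2$scores, main2$scores)
  expect_equal(ex2$n_excluded, 0L)
})

test_that("comparator analysis with only the target reproduces the main scan", {
  x <- random_reports(40, seed = 23)
  main <- signal_scan(x, "x")
  cmp <- comparator_analysis(x, "x")
  expect_equal(cmp$event, main$scores$event)
  expect_equal(cmp$ror, main$scores$ror)
  expect_equal(cmp$ebgm, main$scores$ebgm, tolerance = 1e-6)
})

test_that("an injected signal flags only the drug that carries it", {
  cfg <- synthetic_config(
    n_reports = 8000,
    signals = list(list(drug = "fondaparinux", pt = "pt_150", rho = 12)))
  x <- deduplicate_reports(generate_reports(cfg, seed = 99))
  cmp <- comparator_analysis(x, c("fondaparinux", "warfarin"),
                             vocab = catalog_vocabulary(cfg),
                             pts = "pt_150")
  f_row <- cmp[cmp$drug == "fondaparinux", ]
  w_row <- cmp[cmp$drug == "warfarin", ]
  expect_true(f_row$signal)
  expect_true(nrow(w_row) == 0L || !w_row$signal)
})

test_that("time-to-onset intervals, exclusions and bins follow the rules", {
  x <- mk_reports(
    rpt("1", drugs = list(d("x", start = as.Date("2020-01-01"))),
        pts = "p", onset = as.Date("2020-01-06")),
    rpt("2", drugs = list(d("x", start = as.Date("2020-01-10"))),
        pts = "p", onset = as.Date("2020-01-05")),
    rpt("3", drugs = list(d("x", start = as.Date("2020-01-01"))),
        pts = "p", onset = as.Date("2020-01-31")),
    rpt("4", drugs = list(d("x", start = as.Date("2020-01-01"))),
        pts = "p", onset = as.Date("2020-02-01")),
    rpt("5", drugs = list(d("x", start = as.Date("2020-01-01"))),
        pts = "p"),
    rpt("6", drugs = list(d("x", start = as.Date("2020-01-01"))),
        pts = "p", onset = as.Date("2020-01-01")))
  res <- onset_analysis(x, "x")
  tto <- stats::setNames(res$tto$tto_days, res$tto$primaryid)
  expect_equal(unname(tto["1"]), 5L)
  expect_true(is.na(tto["2"]))      # negative interval excluded
  expect_equal(res$n_negative, 1L)
  expect_equal(unname(tto["6"]), 0L)  # same-day onset counts as 0 days
  bins <- stats::setNames(res$tto$bin, res$tto$primaryid)
  expect_equal(unname(bins[c("1", "3", "4", "5", "6")]),
               c("0-30", "0-30", "31-60", "unknown", "0-30"))
  counts <- stats::setNames(res$counts$n, res$counts$bin)
  expect_equal(unname(counts["0-30"]), 3L)
  expect_equal(unname(counts["31-60"]), 1L)
  expect_equal(unname(counts["unknown"]), 2L)
  expect_equal(sum(res$counts$n), nrow(x$demo))
})

test_that("demographic summaries use report and mention denominators", {
  x <- mk_reports(
    rpt("1", sex = "female", age = 70, outcomes = c("hospitalization",
                                                    "death")),
    rpt("2", sex = "female", age = 40, outcomes = "hospitalization"),
    rpt("3", sex = "male", age = NA, outcomes = character(0)),
    rpt("4", sex = "unknown", age = 10, outcomes = "death"))
  dem <- report_demographics(x)
  sex <- stats::setNames(dem$sex$percent, dem$sex$level)
  expect_equal(unname(sex["female"]), 50)
  # outcome percentages are over the 4 mentions, not the 4 reports
  out <- stats::setNames(dem$outcomes$percent, dem$outcomes$level)
  expect_equal(unname(out["hospitalization"]), 50)
  expect_equal(unname(out["death"]), 50)
  expect_equal(dem$outcome_mentions, 4L)
  # exclusive categorizations sum to 100 within rounding
  for (block in list(dem$sex, dem$age_group, dem$reporter, dem$route)) {
    expect_equal(sum(block$percent), 100, tolerance = 0.1)
  }
  # an all-unknown-sex set is 100% unknown
  y <- mk_reports(rpt("1"), rpt("2"))
  dy <- report_demographics(y)
  expect_equal(dy$sex$percent[dy$sex$level == "unknown"], 100)
})
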