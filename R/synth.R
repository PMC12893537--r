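# Synthetic spontaneous-report generator with known ground truth. Reports
# are drawn report-by-report from a fully specified generative model:
# a primary-suspect drug, optional concomitants, a zero-truncated-Poisson
# number of event draws from the PT catalog (re-weighted by any injected
# signal multiplier for the PS drug and uniqued within the report),
# demographics with configurable missingness, therapy/onset dates with an
# exponential time-to-onset, and duplicate case versions. Because PT
# draws are with-replacement-then-unique, the per-report inclusion
# probability of a PT is exactly 1 - (1 - pi)^k, which makes every
# expected contingency cell available in closed form (expected_tables).

#' Default drug catalog for the synthetic generator
#'
#' An anticoagulant-heavy market basket: the target pentasaccharide, the
#' major comparator classes (heparins, warfarin, DOACs, antiplatelets)
#' and a background of unrelated drugs. `prob` is the marginal chance of
#' being the primary-suspect drug of a report.
#'
#' @return Data frame with columns `name`, `class`, `prob`.
#' @export
default_drug_catalog <- function() {
  data.frame(
    name = c("fondaparinux", "enoxaparin", "heparin", "warfarin",
             "apixaban", "rivaroxaban", "dabigatran", "edoxaban",
             "aspirin", "clopidogrel", "metformin", "lisinopril",
             "atorvastatin", "omeprazole"),
    class = c("other_anticoagulant", "heparin_lmwh", "heparin_lmwh",
              "warfarin", "doac", "doac", "doac", "doac", "antiplatelet",
              "antiplatelet", "none", "none", "none", "none"),
    prob = c(0.08, 0.10, 0.08, 0.10, 0.09, 0.09, 0.05, 0.03, 0.12, 0.08,
             0.06, 0.05, 0.04, 0.03),
    stringsAsFactors = FALSE)
}

#' PT catalog built from the bundled toy vocabulary
#'
#' Takes the named PTs of the toy vocabulary and pads them with numbered
#' filler terms cycled over the same SOC list until `n_pt` terms exist.
#' Baseline reporting probabilities follow a deterministic Zipf-like
#' decay and are normalized to sum to one.
#'
#' @param n_pt Total number of PTs (default 250).
#' @return Data frame with columns `pt`, `soc`, `prob`.
#' @export
synthetic_pt_catalog <- function(n_pt = 250L) {
  vocab <- load_vocabulary(pv_example("toy_meddra.tsv"))
  pts <- names(vocab$pt_to_soc)
  socs <- unname(vocab$pt_to_soc)
  n_extra <- max(0L, n_pt - length(pts))
  if (n_extra > 0L) {
    extra_pt <- sprintf("pt_%03d", seq_len(n_extra))
    extra_soc <- rep_len(vocab$soc_list, n_extra)
    pts <- c(pts, extra_pt)
    socs <- c(socs, extra_soc)
  }
  prob <- 1 / (seq_along(pts) + 9)
  data.frame(pt = pts, soc = socs, prob = prob / sum(prob),
             stringsAsFactors = FALSE)
}

#' Configuration of the synthetic report generator
#'
#' The demographic defaults emulate the marginal composition of a large
#' anticoagulant safety cohort: predominantly female, elderly-skewed,
#' subcutaneously dosed, with roughly a third of ages, onsets and regions
#' missing; time to onset is exponential with a 5-day median.
#'
#' @param n_reports Number of unique cases to generate.
#' @param drug_catalog Data frame `name`, `class`, `prob` (marginal PS
#'   probability; normalized internally).
#' @param pt_catalog Data frame `pt`, `soc`, `prob` (baseline reporting
#'   probability; normalized internally).
#' @param signals List of signal specifications, each a list
#'   `list(drug =, pt =, rho =)`: the PT-selection probability for
#'   reports whose PS drug is `drug` is multiplied by `rho` (> 0;
#'   `rho = 1` is the null) and renormalized.
#' @param sex_probs,age_group_probs,reporter_probs,country_probs,route_probs
#'   Named level probabilities (normalized internally; the unknown level
#'   carries the missing mass).
#' @param outcome_probs Per-outcome independent mention probabilities.
#' @param events_lambda Rate of the zero-truncated Poisson event-draw
#'   count per report (must give mean >= 1).
#' @param drugs_per_report_probs Categorical distribution of the number
#'   of drug entries per report (1, 2, ...).
#' @param tto_mean_days Mean of the exponential time-to-onset, in days.
#' @param onset_missing_prob Probability that the onset date is missing.
#' @param duplicate_rate Fraction of cases emitted with an extra,
#'   earlier-dated version under the same case id.
#' @param date_window Character length-2, the therapy-start window.
#' @return A validated `synthetic_config` object.
#' @export
synthetic_config <- function(n_reports = 50000L,
                             drug_catalog = default_drug_catalog(),
                             pt_catalog = synthetic_pt_catalog(),
                             signals = list(),
                             sex_probs = c(female = 0.4872, male = 0.3497,
                                           unknown = 0.1631),
                             age_group_probs = c("<18" = 0.0054,
                                                 "18-65" = 0.2726,
                                                 ">=65" = 0.3924,
                                                 unknown = 0.3296),
                             reporter_probs = c(Consumer = 0.4591,
                                                Physician = 0.3315,
                                                Pharmacist = 0.0907,
                                                "Other health-professional" = 0.0900,
                                                unknown = 0.0273,
                                                Lawyer = 0.0007,
                                                "Registered Nurse" = 0.0007),
                             country_probs = c(other = 0.6621, US = 0.1284,
                                               FR = 0.0871, IE = 0.0527,
                                               IT = 0.0340, DE = 0.0168,
                                               JP = 0.0102, GB = 0.0088),
                             route_probs = c(subcutaneous = 0.7234,
                                             other = 0.2350,
                                             intravenous = 0.0318,
                                             oral = 0.0038,
                                             transplacental = 0.0035,
                                             intramuscular = 0.0026),
                             outcome_probs = c(hospitalization = 0.489,
                                               other_serious = 0.346,
                                               death = 0.176,
                                               life_threatening = 0.113,
                                               disability = 0.035,
                                               required_intervention = 0.006,
                                               congenital_anomaly = 0.003),
                             events_lambda = 2.87,
                             drugs_per_report_probs = c(0.45, 0.30, 0.17, 0.08),
                             tto_mean_days = 5 / log(2),
                             onset_missing_prob = 0.33,
                             duplicate_rate = 0.10,
                             date_window = c("2004-01-01", "2024-06-30")) {
  cfg <- list(n_reports = as.integer(n_reports), drug_catalog = drug_catalog,
              pt_catalog = pt_catalog, signals = signals,
              sex_probs = sex_probs, age_group_probs = age_group_probs,
              reporter_probs = reporter_probs, country_probs = country_probs,
              route_probs = route_probs, outcome_probs = outcome_probs,
              events_lambda = events_lambda,
              drugs_per_report_probs = drugs_per_report_probs,
              tto_mean_days = tto_mean_days,
              onset_missing_prob = onset_missing_prob,
              duplicate_rate = duplicate_rate,
              date_window = as.Date(date_window))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_reports < 1L) pv_stop("n_reports must be >= 1", "pv_config_error")
  if (nrow(cfg$drug_catalog) == 0L || nrow(cfg$pt_catalog) == 0L) {
    pv_stop("drug and PT catalogs must be non-empty", "pv_config_error")
  }
  probs <- c(cfg$drug_catalog$prob, cfg$pt_catalog$prob, cfg$sex_probs,
             cfg$age_group_probs, cfg$reporter_probs, cfg$country_probs,
             cfg$route_probs, cfg$outcome_probs, cfg$drugs_per_report_probs,
             cfg$onset_missing_prob, cfg$duplicate_rate)
  if (any(!is.finite(probs)) || any(probs < 0)) {
    pv_stop("all probabilities must be finite and non-negative",
            "pv_config_error")
  }
  if (any(cfg$outcome_probs > 1) || cfg$onset_missing_prob > 1 ||
      cfg$duplicate_rate > 1) {
    pv_stop("per-report probabilities must be <= 1", "pv_config_error")
  }
  if (cfg$events_lambda <= 0 || cfg$tto_mean_days <= 0) {
    pv_stop("events_lambda and tto_mean_days must be positive",
            "pv_config_error")
  }
  for (s in cfg$signals) {
    if (!all(c("drug", "pt", "rho") %in% names(s))) {
      pv_stop("each signal needs drug, pt and rho", "pv_config_error")
    }
    if (!s$drug %in% cfg$drug_catalog$name) {
      pv_stop(sprintf("signal drug '%s' not in the drug catalog", s$drug),
              "pv_config_error")
    }
    if (!s$pt %in% cfg$pt_catalog$pt) {
      pv_stop(sprintf("signal PT '%s' not in the PT catalog", s$pt),
              "pv_config_error")
    }
    if (s$rho <= 0) pv_stop("signal rho must be > 0", "pv_config_error")
  }
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("<synthetic_config> %d report(s), %d drug(s), %d PT(s), %d signal(s), duplicate rate %.2f\n",
              x$n_reports, nrow(x$drug_catalog), nrow(x$pt_catalog),
              length(x$signals), x$duplicate_rate))
  invisible(x)
}

#' Vocabulary implied by a synthetic configuration
#'
#' @param config A `synthetic_config`.
#' @return A `meddra_vocab` mapping the catalog's PTs to their SOCs.
#' @export
catalog_vocabulary <- function(config) {
  structure(list(pt_to_soc = stats::setNames(config$pt_catalog$soc,
                                             trimlower(config$pt_catalog$pt)),
                 soc_list = unique(config$pt_catalog$soc)),
            class = "meddra_vocab")
}

# PT selection weights for a given PS drug: baseline probabilities times
# the signal multipliers for that drug, renormalized
signal_weights <- function(config, drug) {
  w <- config$pt_catalog$prob
  for (s in config$signals) {
    if (s$drug == drug) {
      w[config$pt_catalog$pt == s$pt] <- w[config$pt_catalog$pt == s$pt] * s$rho
    }
  }
  w / sum(w)
}

# zero-truncated Poisson draws via inverse CDF
rztpois <- function(n, lambda) {
  u <- stats::runif(n, stats::dpois(0, lambda), 1)
  stats::qpois(u, lambda)
}

ztpois_pmf <- function(lambda, kmax) {
  k <- seq_len(kmax)
  p <- stats::dpois(k, lambda) / (1 - stats::dpois(0, lambda))
  p / sum(p)
}

#' Generate a synthetic FAERS-style report set
#'
#' Fully reproducible from `seed`: the same configuration and seed yield
#' an identical report set (and byte-identical ASCII files via
#' [write_faers_ascii()]). Draws follow a fixed stage order -- PS drugs,
#' drug counts, concomitants, event counts, events, demographics, dates,
#' duplicate versions -- under a single seed.
#'
#' @param config A [synthetic_config()] object.
#' @param seed Integer seed.
#' @return A `faers_reports` object containing `n_reports` cases plus any
#'   injected duplicate versions; deduplication recovers exactly the
#'   cases.
#' @export
generate_reports <- function(config, seed) {
  validate_synthetic_config(config)
  set.seed(seed)
  n <- config$n_reports
  dc <- config$drug_catalog
  ptc <- config$pt_catalog
  nd <- nrow(dc)
  dprob <- dc$prob / sum(dc$prob)

  caseid <- sprintf("%d", 1000000L + seq_len(n))
  primaryid <- paste0(caseid, "2")          # version 2 = current

  ## stage 1: primary-suspect drug
  ps_idx <- sample.int(nd, n, replace = TRUE, prob = dprob)

  ## stage 2: drug count and concomitants
  m <- sample.int(length(config$drugs_per_report_probs), n, replace = TRUE,
                  prob = config$drugs_per_report_probs)
  extra <- m - 1L
  rep_row <- rep.int(seq_len(n), extra)
  con_idx <- sample.int(nd, sum(extra), replace = TRUE, prob = dprob)
  keep <- con_idx != ps_idx[rep_row]
  keep <- keep & !duplicated(paste(rep_row, con_idx))
  rep_row <- rep_row[keep]
  con_idx <- con_idx[keep]

  ## stage 3: events (draws uniqued within report)
  k <- rztpois(n, config$events_lambda)
  ev_rep <- integer(0)
  ev_pt <- integer(0)
  for (d in seq_len(nd)) {
    rows <- which(ps_idx == d)
    if (!length(rows)) next
    w <- signal_weights(config, dc$name[d])
    tot <- sum(k[rows])
    draws <- sample.int(nrow(ptc), tot, replace = TRUE, prob = w)
    ev_rep <- c(ev_rep, rep.int(rows, k[rows]))
    ev_pt <- c(ev_pt, draws)
  }
  ev <- unique(data.frame(row = ev_rep, pt = ev_pt))
  ev <- ev[order(ev$row, ev$pt), , drop = FALSE]

  ## stage 4: demographics
  draw_level <- function(probs) {
    names(probs)[sample.int(length(probs), n, replace = TRUE,
                            prob = probs / sum(probs))]
  }
  sex <- draw_level(config$sex_probs)
  agegrp <- draw_level(config$age_group_probs)
  age <- rep(NA_real_, n)
  lt18 <- agegrp == "<18"; mid <- agegrp == "18-65"; ge65 <- agegrp == ">=65"
  age[lt18] <- round(stats::runif(sum(lt18), 1, 17.99), 1)
  age[mid] <- round(stats::runif(sum(mid), 18, 64.99), 1)
  age[ge65] <- round(stats::runif(sum(ge65), 65, 95), 1)
  reporter <- draw_level(config$reporter_probs)
  country <- draw_level(config$country_probs)
  route <- draw_level(config$route_probs)
  out_mat <- matrix(stats::runif(n * length(config$outcome_probs)) <
                      rep(config$outcome_probs, each = n), nrow = n)
  colnames(out_mat) <- names(config$outcome_probs)

  ## stage 5: dates
  win <- as.integer(config$date_window)
  start <- as.Date(sample(win[1]:win[2], n, replace = TRUE),
                   origin = "1970-01-01")
  tto <- floor(stats::rexp(n, rate = 1 / config$tto_mean_days))
  onset <- start + tto
  onset[stats::runif(n) < config$onset_missing_prob] <- NA
  fda <- onset
  fda[is.na(fda)] <- start[is.na(fda)]
  fda <- fda + sample.int(300L, n, replace = TRUE)
  report_key <- as.integer(format(fda, "%Y%m%d"))

  demo <- data.frame(
    primaryid = primaryid, caseid = caseid, report_date = report_key,
    report_date_partial = FALSE, event_onset = onset, sex = sex,
    age_years = age, reporter = reporter, country = country,
    route = route, stringsAsFactors = FALSE)

  drugs <- rbind(
    data.frame(primaryid = primaryid, drug_seq = 1L,
               name_raw = dc$name[ps_idx], name_standard = dc$name[ps_idx],
               role = "PS", route = route, start_date = start,
               stringsAsFactors = FALSE),
    data.frame(primaryid = primaryid[rep_row],
               drug_seq = as.integer(1L + stats::ave(rep_row, rep_row,
                                                     FUN = seq_along)),
               name_raw = dc$name[con_idx], name_standard = dc$name[con_idx],
               role = "C", route = "other",
               start_date = as.Date(NA), stringsAsFactors = FALSE))
  drugs <- drugs[order(drugs$primaryid, drugs$drug_seq), , drop = FALSE]

  events <- data.frame(primaryid = primaryid[ev$row], pt = ptc$pt[ev$pt],
                       stringsAsFactors = FALSE)
  oc_idx <- which(out_mat, arr.ind = TRUE)
  outcomes <- data.frame(primaryid = primaryid[oc_idx[, 1]],
                         outcome = colnames(out_mat)[oc_idx[, 2]],
                         stringsAsFactors = FALSE)
  outcomes <- outcomes[order(outcomes$primaryid, outcomes$outcome), ,
                       drop = FALSE]

  ## stage 6: duplicate earlier versions (perturb only report date and id)
  dup <- stats::runif(n) < config$duplicate_rate
  if (any(dup)) {
    lag <- sample(30:180, sum(dup), replace = TRUE)
    fda1 <- fda[dup] - lag
    demo_dup <- demo[dup, , drop = FALSE]
    demo_dup$primaryid <- paste0(caseid[dup], "1")
    demo_dup$report_date <- as.integer(format(fda1, "%Y%m%d"))
    demo <- rbind(demo, demo_dup)
    dup_ids <- stats::setNames(paste0(caseid, "1"), primaryid)
    clone <- function(df) {
      sub <- df[df$primaryid %in% primaryid[dup], , drop = FALSE]
      sub$primaryid <- unname(dup_ids[sub$primaryid])
      sub
    }
    drugs <- rbind(drugs, clone(drugs))
    events <- rbind(events, clone(events))
    outcomes <- rbind(outcomes, clone(outcomes))
  }
  faers_reports(demo, drugs, events, outcomes,
                quality = list(generated = n, duplicates = sum(dup)))
}

#' Closed-form expected contingency tables for a configuration
#'
#' Because each report draws `K` events with replacement (zero-truncated
#' Poisson) and keeps the distinct ones, the probability that PT `p`
#' appears on a report with PS drug `d` is exactly
#' `q(d,p) = sum_k P(K = k) (1 - (1 - w(d,p))^k)` with `w` the
#' signal-adjusted selection weights. Expected cells follow by linearity
#' over the `n` unique reports (duplicate versions are removed by
#' deduplication and do not enter). This is the oracle against which the
#' estimators' bias is checked.
#'
#' @param config A `synthetic_config` object.
#' @return Data frame with columns `drug`, `event`, `a`, `b`, `c`, `d`,
#'   `N` (expected, real-valued) and `ror` (the induced reporting odds
#'   ratio implied by the expected cells).
#' @export
expected_tables <- function(config) {
  validate_synthetic_config(config)
  n <- config$n_reports
  dc <- config$drug_catalog
  ptc <- config$pt_catalog
  dprob <- dc$prob / sum(dc$prob)
  kmax <- max(10L, stats::qpois(1 - 1e-12, config$events_lambda))
  pk <- ztpois_pmf(config$events_lambda, kmax)
  k <- seq_len(kmax)
  # q[d, p]: inclusion probability of PT p on a report with PS drug d
  q <- t(vapply(seq_len(nrow(dc)), function(d) {
    w <- signal_weights(config, dc$name[d])
    vapply(w, function(wp) sum(pk * (1 - (1 - wp)^k)), numeric(1))
  }, numeric(nrow(ptc))))
  exp_a <- n * dprob * q                       # drug x pt expected pairs
  margin_drug <- rowSums(exp_a)
  margin_event <- colSums(exp_a)
  Ntot <- sum(exp_a)
  grid <- expand.grid(drug = dc$name, event = ptc$pt,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  a <- as.vector(exp_a)
  b <- rep(margin_drug, times = nrow(ptc)) - a
  cc <- rep(margin_event, each = nrow(dc)) - a
  d <- Ntot - a - b - cc
  data.frame(drug = grid$drug, event = grid$event, a = a, b = b, c = cc,
             d = d, N = Ntot, ror = (a * d) / (b * cc))
}
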