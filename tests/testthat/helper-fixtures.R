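# Fixture builders and independent oracles used across the suite.

`%|%` <- function(a, b) if (is.null(a)) b else a

# Build a faers_reports object from compact per-report specifications:
#   rpt(id, drugs = list(d("fondaparinux", "PS")), pts = c("haematoma"), ...)
d <- function(name, role = "PS", start = as.Date(NA)) {
  list(name = name, role = role, start = start)
}

rpt <- function(id, case = id, date = NA_integer_, pts = character(0),
                drugs = list(), age = NA_real_, sex = "unknown",
                onset = as.Date(NA), reporter = "unknown",
                country = "unknown", outcomes = character(0)) {
  list(id = as.character(id), case = as.character(case), date = date,
       pts = pts, drugs = drugs, age = age, sex = sex, onset = onset,
       reporter = reporter, country = country, outcomes = outcomes)
}

mk_reports <- function(...) {
  specs <- list(...)
  demo <- do.call(rbind, lapply(specs, function(s) data.frame(
    primaryid = s$id, caseid = s$case, report_date = s$date,
    report_date_partial = FALSE, event_onset = s$onset, sex = s$sex,
    age_years = s$age, reporter = s$reporter, country = s$country,
    stringsAsFactors = FALSE)))
  drugs <- do.call(rbind, lapply(specs, function(s) {
    if (!length(s$drugs)) return(NULL)
    data.frame(primaryid = s$id,
               drug_seq = seq_along(s$drugs),
               name_raw = vapply(s$drugs, `[[`, "", "name"),
               name_standard = vapply(s$drugs, `[[`, "", "name"),
               role = vapply(s$drugs, `[[`, "", "role"),
               route = "other",
               start_date = as.Date(vapply(s$drugs, function(x)
                 as.character(x$start), ""), origin = "1970-01-01"),
               stringsAsFactors = FALSE)
  }))
  events <- do.call(rbind, lapply(specs, function(s) {
    if (!length(s$pts)) return(NULL)
    data.frame(primaryid = s$id, pt = tolower(s$pts),
               stringsAsFactors = FALSE)
  }))
  outcomes <- do.call(rbind, lapply(specs, function(s) {
    if (!length(s$outcomes)) return(NULL)
    data.frame(primaryid = s$id, outcome = s$outcomes,
               stringsAsFactors = FALSE)
  }))
  faers_reports(demo, drugs, events, outcomes)
}

toy_vocab <- function() load_vocabulary(pv_example("toy_meddra.tsv"))
toy_dict <- function() load_drug_dictionary(pv_example("toy_drugs.tsv"))

# Brute-force contingency oracle: quadruple-loop pair counter, independent
# of the vectorized implementation.
brute_tables <- function(reports, target, vocab = NULL, level = "PT") {
  ids <- reports$demo$primaryid
  tids <- character(0)
  for (id in ids) {
    dr <- reports$drugs[reports$drugs$primaryid == id, ]
    if (any(dr$name_standard == target & dr$role == "PS")) tids <- c(tids, id)
  }
  pair_id <- character(0); pair_ev <- character(0)
  for (id in ids) {
    pts <- unique(reports$events$pt[reports$events$primaryid == id])
    labs <- if (level == "SOC") unique(map_pt_to_soc(vocab, pts)) else pts
    for (l in labs) {
      pair_id <- c(pair_id, id); pair_ev <- c(pair_ev, l)
    }
  }
  N <- length(pair_id)
  out <- NULL
  for (ev in unique(pair_ev)) {
    a <- b <- cc <- dd <- 0L
    for (i in seq_len(N)) {
      is_t <- pair_id[i] %in% tids
      is_e <- pair_ev[i] == ev
      if (is_t && is_e) a <- a + 1L
      else if (is_t) b <- b + 1L
      else if (is_e) cc <- cc + 1L
      else dd <- dd + 1L
    }
    if (a >= 1L) {
      out <- rbind(out, data.frame(event = ev, a = a, b = b, c = cc, d = dd,
                                   N = N, stringsAsFactors = FALSE))
    }
  }
  out[order(-out$a, out$event), , drop = FALSE]
}

# hand-coded gamma density (not stats::dgamma) for quadrature oracles
gamma_dens <- function(x, shape, rate) {
  exp(shape * log(rate) + (shape - 1) * log(x) - rate * x - lgamma(shape))
}

# quantile by numeric CDF inversion: integrate the density, invert by
# root finding
gamma_quantile_oracle <- function(p, shape, rate) {
  cdf <- function(x) stats::integrate(gamma_dens, 0, x, shape = shape,
                                      rate = rate, rel.tol = 1e-12)$value
  mean_g <- shape / rate
  sd_g <- sqrt(shape) / rate
  stats::uniroot(function(x) cdf(x) - p,
                 lower = max(1e-12, mean_g - 12 * sd_g),
                 upper = mean_g + 12 * sd_g, tol = 1e-12)$root
}

# hand-coded negative-binomial marginal of a Poisson-gamma cell
nb_marginal_oracle <- function(n, E, alpha, beta) {
  exp(lgamma(alpha + n) - lgamma(alpha) - lfactorial(n) +
        alpha * log(beta / (beta + E)) + n * log(E / (beta + E)))
}

# quadrature oracle for the posterior geometric mean and 5% quantile of
# the two-component gamma mixture posterior
ebgm_oracle <- function(a, E, theta) {
  a1 <- theta[1]; b1 <- theta[2]; a2 <- theta[3]; b2 <- theta[4]
  p <- theta[5]
  m1 <- p * nb_marginal_oracle(a, E, a1, b1)
  m2 <- (1 - p) * nb_marginal_oracle(a, E, a2, b2)
  w1 <- m1 / (m1 + m2); w2 <- 1 - w1
  dens <- function(x) w1 * gamma_dens(x, a1 + a, b1 + E) +
    w2 * gamma_dens(x, a2 + a, b2 + E)
  elog <- stats::integrate(function(x) log(x) * dens(x), 0, Inf,
                           rel.tol = 1e-12)$value
  cdf <- function(x) stats::integrate(dens, 0, x, rel.tol = 1e-12)$value
  q05 <- stats::uniroot(function(x) cdf(x) - 0.05, lower = 1e-10,
                        upper = (a + a2) / E + 10, tol = 1e-12)$root
  list(ebgm = exp(elog), eb05 = q05)
}

# random small report sets for property-style checks
random_reports <- function(n, seed, drugs = c("x", "y", "z"),
                           pts = c("p", "q", "r", "s")) {
  set.seed(seed)
  specs <- lapply(seq_len(n), function(i) {
    nd <- sample(1:2, 1)
    dl <- lapply(seq_len(nd), function(j) {
      d(sample(drugs, 1), role = if (j == 1) "PS" else sample(c("C", "SS"), 1))
    })
    rpt(sprintf("%03d", i), pts = sample(pts, sample(1:3, 1)), drugs = dl,
        sex = sample(c("female", "male", "unknown"), 1),
        age = sample(c(NA, 10, 40, 80), 1))
  })
  do.call(mk_reports, specs)
}
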