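# Drug-event 2x2 contingency construction. The counting unit is the unique
# (report, event-label) pair: a report contributes at most 1 to any event
# label even when a PT repeats, and at SOC level at most 1 per SOC. For a
# target drug and event label:
#   a = pairs from target-PS reports with the label
#   a+b = all pairs from target-PS reports
#   a+c = all pairs with the label
#   N = all pairs in the deduplicated dataset.
# The background is all other drugs' pairs in the same dataset.

event_pairs <- function(x, vocab = NULL, level = c("PT", "SOC")) {
  level <- match.arg(level)
  ev <- x$events[, c("primaryid", "pt")]
  if (level == "SOC") {
    if (is.null(vocab)) {
      pv_stop("SOC-level counting requires a vocabulary", "pv_config_error")
    }
    ev$event <- map_pt_to_soc(vocab, ev$pt)
  } else {
    ev$event <- ev$pt
  }
  unique(ev[, c("primaryid", "event")])
}

#' Build drug-event 2x2 contingency tables
#'
#' One table per event label (PT or SOC) with at least one target-drug
#' pair. "Target" membership of a pair means its report lists the target
#' drug with role code PS. At SOC level, PTs absent from the vocabulary
#' accumulate under the `"unmapped"` label.
#'
#' @param reports A deduplicated `faers_reports` object (the full dataset,
#'   target and background together).
#' @param target_drug Standardized drug name.
#' @param vocab A `meddra_vocab` object (required for `level = "SOC"`).
#' @param level `"PT"` or `"SOC"`.
#' @return A data frame of class `contingency_set` with columns `event`,
#'   `level`, `a`, `b`, `c`, `d`, `N`, sorted by decreasing `a`.
#' @export
build_contingency <- function(reports, target_drug, vocab = NULL,
                              level = c("PT", "SOC")) {
  stopifnot(inherits(reports, "faers_reports"))
  level <- match.arg(level)
  ev <- event_pairs(reports, vocab, level)
  dr <- reports$drugs
  tids <- unique(dr$primaryid[dr$name_standard == target_drug &
                                dr$role == "PS"])
  empty <- data.frame(event = character(0), level = character(0),
                      a = integer(0), b = integer(0), c = integer(0),
                      d = integer(0), N = integer(0))
  if (length(tids) == 0L) {
    warning(sprintf("target drug '%s' has no primary-suspect reports",
                    target_drug))
    return(structure(empty, class = c("contingency_set", "data.frame"),
                     target = target_drug, level = level))
  }
  N <- nrow(ev)
  in_t <- ev$primaryid %in% tids
  ab <- sum(in_t)
  m_all <- table(ev$event)
  a_tab <- table(ev$event[in_t])
  events <- names(a_tab)
  a <- as.integer(a_tab)
  m_e <- as.integer(m_all[events])
  out <- data.frame(event = events, level = level, a = a, b = ab - a,
                    c = m_e - a, d = N - ab - (m_e - a), N = N,
                    stringsAsFactors = FALSE)
  out <- out[out$a >= 1L, , drop = FALSE]
  out <- out[order(-out$a, out$event), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("contingency_set", "data.frame"),
            target = target_drug, level = level,
            counting = "(report, event-label) pairs")
}

#' Observed and expected counts for every drug-event pair
#'
#' For each (primary-suspect drug, event label) combination with positive
#' margins, returns the observed pair count `a` and the independence
#' expectation `E = (a+b)(a+c)/N`. This is the input the gamma-Poisson
#' shrinker is fitted on; zero-count cells are included so the prior sees
#' the full cell distribution.
#'
#' @inheritParams build_contingency
#' @return Data frame with columns `drug`, `event`, `a`, `E`,
#'   `margin_drug`, `margin_event`, `N`.
#' @export
drug_event_counts <- function(reports, vocab = NULL, level = c("PT", "SOC")) {
  stopifnot(inherits(reports, "faers_reports"))
  level <- match.arg(level)
  ev <- event_pairs(reports, vocab, level)
  dr <- reports$drugs
  ps <- unique(dr[dr$role == "PS", c("primaryid", "name_standard")])
  if (nrow(ps) == 0L || nrow(ev) == 0L) {
    return(data.frame(drug = character(0), event = character(0),
                      a = integer(0), E = numeric(0),
                      margin_drug = integer(0), margin_event = integer(0),
                      N = integer(0)))
  }
  N <- nrow(ev)
  # pairs per report, then per-drug margins over that report's pairs
  ppr <- table(ev$primaryid)
  margin_drug_tab <- tapply(as.integer(ppr[ps$primaryid]), ps$name_standard,
                            sum)
  tri <- merge(ps, ev, by = "primaryid")
  a_tab <- table(factor(tri$name_standard), factor(tri$event))
  m_event_tab <- table(ev$event)
  # expand.grid varies the first factor fastest, matching table()'s
  # column-major layout, so the flattened counts line up directly
  grid <- expand.grid(drug = rownames(a_tab), event = colnames(a_tab),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$a <- as.integer(a_tab)
  grid$margin_drug <- as.integer(margin_drug_tab[grid$drug])
  grid$margin_event <- as.integer(m_event_tab[grid$event])
  grid$E <- grid$margin_drug * grid$margin_event / N
  grid$N <- N
  grid <- grid[grid$margin_drug > 0 & grid$margin_event > 0, , drop = FALSE]
  rownames(grid) <- NULL
  grid[, c("drug", "event", "a", "E", "margin_drug", "margin_event", "N")]
}

#' Export contingency tables as CSV
#'
#' @param tables A `contingency_set` data frame.
#' @param path Output CSV path.
#' @return Invisibly, `tables`.
#' @export
export_contingency <- function(tables, path) {
  utils::write.csv(tables[, c("event", "level", "a", "b", "c", "d")],
                   path, row.names = FALSE)
  invisible(tables)
}
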