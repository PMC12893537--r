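# The central scoring surface: signal_scan() runs contingency construction
# and all four disproportionality statistics for one target drug against
# the background of the same deduplicated report set, applies the joint
# thresholds, and returns a classed object.

#' Disproportionality signal scan for one drug
#'
#' Builds the drug-event 2x2 tables at PT or SOC level, computes ROR, PRR,
#' Pearson chi-square, the BCPNN information component and the
#' gamma-Poisson shrinker scores for every event label, and applies the
#' joint signal thresholds. The shrinker hyperparameters are fitted on the
#' full drug-event cell set of the dataset unless supplied.
#'
#' @param reports A deduplicated `faers_reports` object containing target
#'   and background reports.
#' @param target_drug Standardized drug name.
#' @param vocab A `meddra_vocab` object (required for SOC level).
#' @param level `"PT"` or `"SOC"`.
#' @param thresholds A [signal_thresholds()] object.
#' @param hyper Optional pre-fitted [fit_mgps()] object (reused across
#'   comparator scans so all drugs share one prior).
#' @return A `signal_scan` object; `as.data.frame()` returns the score
#'   table.
#' @examples
#' cfg <- synthetic_config(n_reports = 2000,
#'   signals = list(list(drug = "fondaparinux", pt = "haematoma", rho = 8)))
#' reps <- deduplicate_reports(generate_reports(cfg, seed = 1))
#' scan <- signal_scan(reps, "fondaparinux", catalog_vocabulary(cfg))
#' head(as.data.frame(scan))
#' @export
signal_scan <- function(reports, target_drug, vocab = NULL,
                        level = c("PT", "SOC"),
                        thresholds = signal_thresholds(), hyper = NULL) {
  level <- match.arg(level)
  tables <- build_contingency(reports, target_drug, vocab, level)
  if (is.null(hyper)) {
    hyper <- fit_mgps(drug_event_counts(reports, vocab, level))
  }
  if (nrow(tables) == 0L) {
    scores <- data.frame(event = character(0))
  } else {
    E <- (tables$a + tables$b) * (tables$a + tables$c) / tables$N
    r <- ror(tables)
    p <- prr(tables)
    chi2 <- chi_square(tables)
    ic <- bcpnn_ic(tables$a, E)
    eb <- ebgm_scores(tables$a, E, hyper)
    scores <- data.frame(
      event = tables$event, level = level,
      a = tables$a, b = tables$b, c = tables$c, d = tables$d, N = tables$N,
      E = E,
      ror = r$est, ror_low = r$low, ror_high = r$high,
      prr = p$est, prr_low = p$low, prr_high = p$high,
      chi2 = chi2, ic = ic$ic, ic025 = ic$ic025,
      ebgm = eb$ebgm, eb05 = eb$eb05, corrected = r$corrected,
      stringsAsFactors = FALSE)
    scores <- evaluate_signal(scores, thresholds)
  }
  structure(list(scores = scores, tables = tables, hyper = hyper,
                 target = target_drug, level = level,
                 thresholds = thresholds,
                 n_reports = n_reports(reports),
                 n_pairs = if (nrow(tables)) tables$N[1] else 0L),
            class = "signal_scan")
}

#' @export
as.data.frame.signal_scan <- function(x, ...) x$scores

fmt_ci <- function(est, lo, hi) sprintf("%.2f (%.2f, %.2f)", est, lo, hi)

#' @export
print.signal_scan <- function(x, n = 10L, ...) {
  cat(sprintf("<signal_scan> drug '%s' at %s level: %d report(s), %d pair(s), %d event label(s), %d signal(s)\n",
              x$target, x$level, x$n_reports, x$n_pairs, nrow(x$scores),
              sum(x$scores$signal %||% logical(0))))
  s <- x$scores
  if (nrow(s)) {
    show <- utils::head(s[order(-s$signal, -s$a), ], n)
    disp <- data.frame(event = show$event, cases = show$a,
                       ROR = fmt_ci(show$ror, show$ror_low, show$ror_high),
                       PRR = fmt_ci(show$prr, show$prr_low, show$prr_high),
                       chisq = round(show$chi2, 2),
                       IC = sprintf("%.2f (%.2f)", show$ic, show$ic025),
                       EBGM = sprintf("%.2f (%.2f)", show$ebgm, show$eb05),
                       signal = show$signal)
    print(disp, row.names = FALSE)
    if (nrow(s) > n) cat(sprintf("... %d more event label(s)\n", nrow(s) - n))
  }
  invisible(x)
}

#' @export
summary.signal_scan <- function(object, ...) {
  s <- object$scores
  out <- list(
    target = object$target, level = object$level,
    n_reports = object$n_reports, n_pairs = object$n_pairs,
    n_events = nrow(s),
    n_eligible = sum(s$a >= object$thresholds$min_cases),
    flags = c(ror = sum(s$sig_ror %||% 0), prr = sum(s$sig_prr %||% 0),
              ic = sum(s$sig_ic %||% 0), ebgm = sum(s$sig_ebgm %||% 0),
              combined = sum(s$signal %||% 0)))
  class(out) <- "summary.signal_scan"
  out
}

#' @export
print.summary.signal_scan <- function(x, ...) {
  cat(sprintf("Signal scan of '%s' (%s level)\n", x$target, x$level))
  cat(sprintf("  reports: %d   pairs: %d   event labels: %d (eligible: %d)\n",
              x$n_reports, x$n_pairs, x$n_events, x$n_eligible))
  cat(sprintf("  flagged  ROR: %d  PRR+chi2: %d  IC025: %d  EB05: %d  combined: %d\n",
              x$flags["ror"], x$flags["prr"], x$flags["ic"],
              x$flags["ebgm"], x$flags["combined"]))
  invisible(x)
}

#' @export
plot.signal_scan <- function(x, ...) {
  s <- x$scores
  if (!nrow(s)) {
    warning("nothing to plot")
    return(invisible(x))
  }
  graphics::plot(s$ic, log10(s$chi2 + 1),
                 cex = 0.5 + sqrt(s$a) / max(1, sqrt(max(s$a))) * 2,
                 pch = 21, bg = ifelse(s$signal, "firebrick", "grey70"),
                 xlab = "information component (bits)",
                 ylab = "log10(chi-square + 1)",
                 main = sprintf("%s (%s level)", x$target, x$level), ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Export a score table in the conventional column layout
#'
#' Writes `event, cases, ROR (CI), PRR (CI), chisq, IC (IC025),
#' EBGM (EBGM05), flags` as comma-separated values.
#'
#' @param scan A `signal_scan` object (or its score data frame).
#' @param path Output CSV path.
#' @return Invisibly, the formatted data frame.
#' @export
export_signal_table <- function(scan, path) {
  s <- if (inherits(scan, "signal_scan")) scan$scores else scan
  out <- data.frame(
    event = s$event, cases = s$a,
    ror_ci = fmt_ci(s$ror, s$ror_low, s$ror_high),
    prr_ci = fmt_ci(s$prr, s$prr_low, s$prr_high),
    chisq = round(s$chi2, 2),
    ic_ic025 = sprintf("%.2f (%.2f)", s$ic, s$ic025),
    ebgm_eb05 = sprintf("%.2f (%.2f)", s$ebgm, s$eb05),
    sig_ror = s$sig_ror, sig_prr = s$sig_prr, sig_ic = s$sig_ic,
    sig_ebgm = s$sig_ebgm, signal = s$signal)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
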