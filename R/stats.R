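# The four disproportionality statistics. All functions are vectorized
# over tables and accept either four count vectors or a data frame with
# columns a, b, c, d (as produced by build_contingency).

unpack_cells <- function(a, b, c, d) {
  if (is.data.frame(a)) {
    df <- a
    stopifnot(all(c("a", "b", "c", "d") %in% names(df)))
    list(a = df$a, b = df$b, c = df$c, d = df$d)
  } else {
    list(a = a, b = b, c = c, d = d)
  }
}

#' Reporting odds ratio with Woolf confidence interval
#'
#' `ROR = ad / bc`, with the 95% interval
#' `exp(ln ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. Tables with any zero
#' cell receive the Haldane-Anscombe correction (+0.5 to every cell) and
#' are flagged `corrected`.
#'
#' @param a,b,c,d Cell counts, or a data frame with those columns as `a`.
#' @param conf Confidence level (default 0.95).
#' @return Data frame with columns `est`, `low`, `high`, `corrected`.
#' @export
ror <- function(a, b = NULL, c = NULL, d = NULL, conf = 0.95) {
  x <- unpack_cells(a, b, c, d)
  corrected <- x$a == 0 | x$b == 0 | x$c == 0 | x$d == 0
  off <- ifelse(corrected, 0.5, 0)
  aa <- x$a + off; bb <- x$b + off; cc <- x$c + off; dd <- x$d + off
  est <- (aa * dd) / (bb * cc)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  data.frame(est = est, low = exp(log(est) - z * se),
             high = exp(log(est) + z * se), corrected = corrected)
}

#' Proportional reporting ratio with confidence interval
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`, with standard error
#' `sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))` on the log scale. Zero cells are
#' handled as in [ror()].
#'
#' @inheritParams ror
#' @return Data frame with columns `est`, `low`, `high`, `corrected`.
#' @export
prr <- function(a, b = NULL, c = NULL, d = NULL, conf = 0.95) {
  x <- unpack_cells(a, b, c, d)
  corrected <- x$a == 0 | x$b == 0 | x$c == 0 | x$d == 0
  off <- ifelse(corrected, 0.5, 0)
  aa <- x$a + off; bb <- x$b + off; cc <- x$c + off; dd <- x$d + off
  est <- (aa / (aa + bb)) / (cc / (cc + dd))
  se <- sqrt(1 / aa - 1 / (aa + bb) + 1 / cc - 1 / (cc + dd))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  data.frame(est = est, low = exp(log(est) - z * se),
             high = exp(log(est) + z * se), corrected = corrected)
}

#' Pearson chi-square for a 2x2 table
#'
#' `N (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]`; with `yates = TRUE` the
#' discrepancy `|ad - bc|` is reduced by `N/2` (floored at zero). A zero
#' margin makes the statistic undefined; it is returned as 0 with a
#' warning.
#'
#' @inheritParams ror
#' @param yates Apply Yates continuity correction?
#' @return Numeric vector of chi-square statistics.
#' @export
chi_square <- function(a, b = NULL, c = NULL, d = NULL, yates = FALSE) {
  x <- unpack_cells(a, b, c, d)
  a <- as.numeric(x$a); b <- as.numeric(x$b)
  c <- as.numeric(x$c); d <- as.numeric(x$d)
  N <- a + b + c + d
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  disc <- abs(a * d - b * c)
  if (yates) disc <- pmax(0, disc - N / 2)
  out <- numeric(length(a))
  zero <- denom == 0
  if (any(zero)) warning("zero margin: chi-square undefined, returned as 0")
  out[!zero] <- N[!zero] * disc[!zero]^2 / denom[!zero]
  out
}

#' BCPNN information component with lower credibility bound
#'
#' The information component is the base-2 log of the shrunk
#' observed-to-expected ratio, `IC = log2((a + 0.5) / (E + 0.5))` with
#' `E = (a+b)(a+c)/N`. Its lower 95% credibility bound `IC025` is the
#' base-2 log of the 2.5% quantile of a Gamma(shape `a + 0.5`, rate
#' `E + 0.5`) posterior. `a = 0` is allowed (the pair is shrunk toward the
#' null).
#'
#' @param a Observed pair count, or a data frame with columns `a` and `E`.
#' @param E Expected count under independence.
#' @return Data frame with columns `ic` and `ic025`.
#' @export
bcpnn_ic <- function(a, E = NULL) {
  if (is.data.frame(a)) { E <- a$E; a <- a$a }
  shape <- a + 0.5
  rate <- E + 0.5
  data.frame(ic = log2(shape / rate),
             ic025 = log2(stats::qgamma(0.025, shape = shape, rate = rate)))
}

#' Joint signal-detection thresholds
#'
#' The default criteria are the standard pharmacovigilance rules: ROR
#' lower 95% CI bound > 1; PRR >= 2 with chi-square >= 4; IC025 > 0;
#' EB05 > 1; and at least `min_cases` reports for the pair. With
#' `combine = "all"` a pair is a signal only when every enabled rule
#' fires.
#'
#' @param min_cases Minimum pair count (default 3).
#' @param ror,prr,ic,ebgm Enable the respective rule.
#' @param combine `"all"` (conjunction, the default) or `"any"`.
#' @return A `signal_thresholds` object.
#' @export
signal_thresholds <- function(min_cases = 3L, ror = TRUE, prr = TRUE,
                              ic = TRUE, ebgm = TRUE,
                              combine = c("all", "any")) {
  stopifnot(min_cases >= 1L)
  structure(list(min_cases = as.integer(min_cases), ror = ror, prr = prr,
                 ic = ic, ebgm = ebgm, combine = match.arg(combine)),
            class = "signal_thresholds")
}

#' Apply signal criteria to a score table
#'
#' Adds the per-algorithm flags (`sig_ror`, `sig_prr`, `sig_ic`,
#' `sig_ebgm`) and the combined `signal` flag. Inequalities are strict
#' exactly as stated in the rules (e.g. a ROR CI lower bound of exactly 1
#' does not fire). Pairs with fewer than `min_cases` reports are
#' unconditionally non-signals.
#'
#' @param scores Data frame with columns `a`, `ror_low`, `prr`, `chi2`,
#'   `ic025`, `eb05`.
#' @param thresholds A [signal_thresholds()] object.
#' @return `scores` with flag columns appended.
#' @export
evaluate_signal <- function(scores, thresholds = signal_thresholds()) {
  stopifnot(inherits(thresholds, "signal_thresholds"))
  scores$sig_ror <- scores$ror_low > 1
  scores$sig_prr <- scores$prr >= 2 & scores$chi2 >= 4
  scores$sig_ic <- scores$ic025 > 0
  scores$sig_ebgm <- scores$eb05 > 1
  flags <- cbind(if (thresholds$ror) scores$sig_ror,
                 if (thresholds$prr) scores$sig_prr,
                 if (thresholds$ic) scores$sig_ic,
                 if (thresholds$ebgm) scores$sig_ebgm)
  combined <- if (is.null(flags)) {
    rep(TRUE, nrow(scores))
  } else if (thresholds$combine == "all") {
    rowSums(flags) == ncol(flags)
  } else {
    rowSums(flags) > 0
  }
  scores$signal <- combined & scores$a >= thresholds$min_cases
  scores
}

#' Reconstruct a 2x2 table from its published summary statistics
#'
#' Given a published case count `a`, the ROR and PRR point estimates and
#' the ROR 95% confidence interval, the remaining cells have a closed
#' form: `ROR/PRR = d(a+b) / [b(c+d)]` pins `b = a(PRR - 1)/(ROR - PRR)`
#' and the ratio `d/c = ROR * b / a`, while the Woolf interval width
#' supplies the absolute scale through
#' `1/b + 1/c + 1/d = [ln(high/low) / (2z)]^2 - 1/a`. Useful for checking
#' the internal consistency of published disproportionality tables.
#'
#' @param a Case count (the a cell).
#' @param ror_est,prr_est Published point estimates (must satisfy
#'   `ror_est > prr_est > 1`).
#' @param ror_ci Length-2 vector, the published ROR confidence bounds.
#' @param conf Confidence level of `ror_ci` (default 0.95).
#' @return One-row data frame with columns `a`, `b`, `c`, `d`, `N`.
#' @export
reconstruct_2x2 <- function(a, ror_est, prr_est, ror_ci, conf = 0.95) {
  stopifnot(length(ror_ci) == 2L, a > 0)
  if (!(ror_est > prr_est && prr_est > 1)) {
    pv_stop("reconstruction requires ROR > PRR > 1", "pv_config_error")
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  b <- a * (prr_est - 1) / (ror_est - prr_est)
  r <- ror_est * b / a                       # d / c
  s2 <- (log(ror_ci[2] / ror_ci[1]) / (2 * z))^2
  inv_cd <- s2 - 1 / a - 1 / b               # 1/c + 1/d
  if (inv_cd <= 0) {
    pv_stop("published CI is too narrow to be consistent with a and b",
            "pv_config_error")
  }
  cc <- (1 + 1 / r) / inv_cd
  dd <- r * cc
  data.frame(a = a, b = b, c = cc, d = dd, N = a + b + cc + dd)
}
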