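# The four disproportionality statistics and the joint thresholds.

test_that("ROR and PRR reproduce closed-form worked examples", {
  expect_equal(ror(10, 10, 10, 10)$est, 1)
  expect_true(ror(10, 10, 10, 10)$low < 1 && ror(10, 10, 10, 10)$high > 1)
  r <- ror(5, 5, 5, 45)
  expect_equal(r$est, 9)
  expect_equal(r$low, 1.92, tolerance = 0.005)
  expect_equal(r$high, 42.24, tolerance = 0.005)
  expect_equal(prr(10, 10, 10, 10)$est, 1)
  expect_equal(prr(5, 5, 5, 45)$est, 5)
  # zero cells receive the Haldane-Anscombe correction and are flagged
  z <- ror(0, 5, 5, 45)
  expect_true(z$corrected)
  expect_equal(z$est, (0.5 * 45.5) / (5.5 * 5.5))
})

test_that("ROR dominates PRR exactly when the table is disproportionate", {
  set.seed(42)
  for (i in 1:200) {
    cells <- sample(1:50, 4, replace = TRUE)
    r <- ror(cells[1], cells[2], cells[3], cells[4])$est
    p <- prr(cells[1], cells[2], cells[3], cells[4])$est
    expect_equal(sign(r - 1), sign(p - 1))
    if (r > 1) expect_gte(r, p)
    if (abs(r - 1) < 1e-12) expect_equal(p, 1)
  }
})

test_that("Pearson chi-square matches examples and the expected-count oracle", {
  expect_equal(chi_square(10, 10, 10, 10), 0)
  expect_equal(chi_square(20, 10, 10, 20), 6.6667, tolerance = 1e-4)
  expect_equal(chi_square(20, 10, 10, 20, yates = TRUE), 5.4)
  # oracle: sum (O - E)^2 / E over the four cells, all tables with cells 1..6
  oracle <- function(a, b, c, d) {
    N <- a + b + c + d
    O <- c(a, b, c, d)
    E <- c((a + b) * (a + c), (a + b) * (b + d),
           (c + d) * (a + c), (c + d) * (b + d)) / N
    sum((O - E)^2 / E)
  }
  grid <- expand.grid(a = 1:6, b = 1:6, c = 1:6, d = 1:6)
  got <- chi_square(grid$a, grid$b, grid$c, grid$d)
  want <- mapply(oracle, grid$a, grid$b, grid$c, grid$d)
  expect_equal(got, unname(want), tolerance = 1e-10)
  # symmetry under transposition and joint row/column swap
  expect_equal(chi_square(7, 3, 2, 9), chi_square(7, 2, 3, 9))
  expect_equal(chi_square(7, 3, 2, 9), chi_square(9, 2, 3, 7))
  expect_warning(z <- chi_square(0, 0, 3, 4), "zero margin")
  expect_equal(z, 0)
})

test_that("information component follows the shrunk log2 ratio and gamma quantile", {
  # observed equals expected: E = (a+b)(a+c)/N = 10
  expect_equal(bcpnn_ic(10, 10)$ic, 0)
  ic <- bcpnn_ic(3, 0.5)
  expect_equal(ic$ic, log2(3.5 / 1.0), tolerance = 1e-12)
  # quantile oracle: numeric integration of the gamma CDF, inverted
  for (case in list(c(3, 0.5), c(10, 2), c(50, 60))) {
    got <- bcpnn_ic(case[1], case[2])$ic025
    want <- log2(gamma_quantile_oracle(0.025, case[1] + 0.5, case[2] + 0.5))
    expect_equal(got, want, tolerance = 1e-8)
  }
  # monotone in the observed count at fixed E
  ics <- bcpnn_ic(0:20, rep(5, 21))
  expect_true(all(diff(ics$ic) > 0))
  expect_true(all(diff(ics$ic025) > 0))
})

test_that("EBGM matches the quadrature oracle and shrinks sensibly", {
  theta <- c(0.2, 0.1, 2.0, 4.0, 1 / 3)
  got <- ebgm_scores(5, 1, theta)
  want <- ebgm_oracle(5, 1, theta)
  expect_equal(got$ebgm, want$ebgm, tolerance = 1e-6)
  expect_equal(got$eb05, want$eb05, tolerance = 1e-6)
  # a = 0 is shrunk below the null
  z <- ebgm_scores(0, 2, theta)
  expect_lt(z$ebgm, 1)
  expect_lt(z$eb05, z$ebgm)
  # shrinkage ordering for an elevated pair
  s <- ebgm_scores(20, 4, theta)
  expect_lt(s$eb05, s$ebgm)
  expect_lt(s$ebgm, 20 / 4)
  # monotone in a at fixed E
  m <- ebgm_scores(1:30, rep(3, 30), theta)
  expect_true(all(diff(m$ebgm) > 0))
})

test_that("joint thresholds follow the stated rules with strict boundaries", {
  base <- data.frame(a = 10, ror_low = 5.56, prr = 5.26, chi2 = 7197.64,
                     ic025 = 2.33, eb05 = 5.05)
  ev <- evaluate_signal(base)
  expect_true(all(unlist(ev[c("sig_ror", "sig_prr", "sig_ic", "sig_ebgm",
                              "signal")])))
  # fewer than three cases is unconditionally a non-signal
  few <- base; few$a <- 2
  expect_false(evaluate_signal(few)$signal)
  # boundary: ROR CI lower bound of exactly 1 does not fire
  bd <- base; bd$ror_low <- 1.0
  expect_false(evaluate_signal(bd)$sig_ror)
  expect_false(evaluate_signal(bd)$signal)
  # PRR rule is a conjunction with its chi-square
  pc <- base; pc$chi2 <- 3.9
  expect_false(evaluate_signal(pc)$sig_prr)
  # "any" combination
  any_th <- signal_thresholds(combine = "any")
  expect_true(evaluate_signal(bd, any_th)$signal)
})

test_that("published-table reconstruction inverts the summary statistics", {
  tab <- reconstruct_2x2(a = 582, ror_est = 66.78, prr_est = 64.95,
                         ror_ci = c(60.99, 73.12))
  # the reconstructed table reproduces its own inputs
  expect_equal(ror(tab)$est, 66.78, tolerance = 1e-6)
  expect_equal(prr(tab)$est, 64.95, tolerance = 1e-6)
  expect_equal(ror(tab)$low, 60.99, tolerance = 1e-4)
  expect_equal(ror(tab)$high, 73.12, tolerance = 1e-4)
  expect_error(reconstruct_2x2(10, 2, 3, c(1, 4)), class = "pv_config_error")
})
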