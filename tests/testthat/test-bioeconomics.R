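test_that("harvest follows the exponential-mortality law", {
  expect_identical(harvest(1.0, 0.023, 0), 0)
  expect_identical(harvest(0, 0.023, 100), 0)
  expect_equal(harvest(0.3, 0.023, 18), 0.3 * (1 - exp(-0.414)))
  expect_equal(harvest(0.3, 0.023, 18), 0.1016997, tolerance = 1e-6)
  expect_error(harvest(-0.1, 0.023, 1), class = "fisherygame_domain_error")
  expect_error(harvest(0.3, 0.023, -1), class = "fisherygame_domain_error")
})

test_that("harvest is increasing and concave in effort and bounded by the stock", {
  f <- seq(0, 500, by = 5)
  for (Bp in c(0.05, 0.3, 1)) {
    h <- harvest(Bp, 0.023, f)
    expect_true(all(diff(h) > 0))
    expect_true(all(diff(diff(h)) < 0))
    expect_true(all(h < Bp))
  }
})

test_that("monopoly effort maximizes single-agent season profit", {
  econ <- default_econ()
  f_T <- monopoly_effort(econ, 0.3)
  expect_equal(f_T, 390.3929840, tolerance = 1e-8)
  # numeric maximization oracle
  opt <- optimize(oracle_profit, c(0, 2000), maximum = TRUE,
                  B_prime = 0.3, P = econ$P, q = econ$q,
                  c_prime = econ$c_prime)
  expect_equal(f_T, opt$maximum, tolerance = 1e-4)
  # profit at f_T beats a dense grid of alternatives
  grid <- seq(0, 1500, by = 1)
  expect_true(all(
    oracle_profit(f_T, 0.3, econ$P, econ$q, econ$c_prime) >=
      oracle_profit(grid, 0.3, econ$P, econ$q, econ$c_prime)))
})

test_that("monopoly effort inverts the first-order condition exactly", {
  f0 <- 123.4
  Bp <- 0.5
  econ <- bioeconomic_params(c_prime = Bp * 23 * 0.023 * exp(-0.023 * f0))
  expect_equal(monopoly_effort(econ, Bp), f0, tolerance = 1e-9)
})

test_that("non-viable stocks signal instead of returning an effort", {
  econ <- default_econ()
  B_lo <- econ$c_prime / (econ$P * econ$q)  # viability threshold
  expect_warning(out <- monopoly_effort(econ, B_lo / 2),
                 class = "fisherygame_not_viable")
  expect_true(is.na(out))
  expect_false(viable_fishery(econ, B_lo / 2))
  expect_true(viable_fishery(econ, 2 * B_lo))
})

test_that("base payoffs reproduce the case-study values at B' = 0.3", {
  bp <- base_payoffs(default_econ(), 0.3)
  expect_equal(bp$Pi_CC, 2.338733436, tolerance = 1e-8)
  expect_equal(bp$Pi_CN, 0.3177408699, tolerance = 1e-8)
  expect_equal(bp$Pi_NC, 6.573581705, tolerance = 1e-8)
  expect_identical(bp$Pi_NN, 0)
  expect_true(bp$viable)
  expect_false(bp$degenerate)
})

test_that("mixed-encounter revenue is conserved and rent fully dissipates", {
  econ <- default_econ()
  draws <- random_scenarios(1e4, seed = 7)
  bp <- base_payoffs(econ, draws$B_prime)
  ok <- bp$viable & !bp$degenerate
  rho <- econ$c_prime / (bp$B_prime * econ$P * econ$q)
  total_revenue <- bp$B_prime * (1 - rho) * econ$P
  resid <- bp$Pi_CN[ok] + bp$Pi_NC[ok] + econ$c_prime * bp$f_T[ok] -
    total_revenue[ok]
  expect_true(sum(ok) > 9000)
  expect_lt(max(abs(resid)), 1e-12)
  expect_true(all(bp$Pi_NN[ok] == 0))
  # cooperative profit positive, cheater's mixed payoff at least the
  # cooperator's whenever fishing is worthwhile
  expect_true(all(bp$Pi_CC[ok] > 0))
  expect_true(all(bp$Pi_NC[ok] >= bp$Pi_CN[ok]))
})

test_that("a regulated effort above the monopoly effort clips the cheater", {
  # choose cost so that f_T = 10 < f* = 18
  Bp <- 0.4
  econ <- bioeconomic_params(
    c_prime = Bp * 23 * 0.023 * exp(-0.023 * 10), f_star = 18)
  bp <- base_payoffs(econ, Bp)
  expect_true(bp$degenerate)
  expect_identical(bp$Pi_NC, 0)
  expect_equal(bp$Pi_CN, bp$Pi_CC)
  # boundary case f* = f_T: cheater contributes nothing and earns nothing
  econ2 <- bioeconomic_params(
    c_prime = Bp * 23 * 0.023 * exp(-0.023 * 18), f_star = 18)
  bp2 <- base_payoffs(econ2, Bp)
  expect_true(bp2$degenerate)
  expect_identical(bp2$Pi_NC, 0)
})

test_that("normalization divides by carrying capacity and payoffs are homogeneous", {
  ns <- normalize_stock(c = 20, B = 300, K = 1000)
  expect_equal(ns$c_prime, 0.02)
  expect_equal(ns$B_prime, 0.3)
  ns0 <- normalize_stock(c = 0, B = 1000, K = 1000)
  expect_equal(ns0$c_prime, 0)
  expect_equal(ns0$B_prime, 1)
  expect_error(normalize_stock(c = 1, B = 1100, K = 1000),
               class = "fisherygame_domain_error")

  # scaling (c, B, K) by lambda leaves normalized payoffs unchanged, and
  # normalized payoffs are 1/K of the raw first-principles payoffs
  set.seed(42)
  for (i in 1:25) {
    K <- runif(1, 100, 1e5)
    B <- runif(1, 0.05, 1) * K
    cost <- runif(1, 1e-6, 5e-4) * K
    lambda <- runif(1, 0.1, 50)
    n1 <- normalize_stock(cost, B, K)
    n2 <- normalize_stock(lambda * cost, lambda * B, lambda * K)
    expect_equal(n1, n2, tolerance = 1e-12)
    econ <- bioeconomic_params(c_prime = n1$c_prime, K = K)
    bp <- base_payoffs(econ, n1$B_prime)
    if (!bp$viable || bp$degenerate) next
    raw <- oracle_raw_payoffs(cost, B, K, P = 23, q = 0.023, f_star = 18)
    expect_equal(bp$Pi_CC, raw$CC / K, tolerance = 1e-10)
    expect_equal(bp$Pi_CN, raw$CN / K, tolerance = 1e-10)
    expect_equal(bp$Pi_NC, raw$NC / K, tolerance = 1e-10)
  }
})
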