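# Independent oracles the tests check the package against. These are
# written from the model's economics directly — season profit as revenue
# minus cost — not from the package's payoff expressions, so agreement is
# informative.

# Single-agent season profit at total effort f (per unit carrying
# capacity): the quantity the unrestricted agent maximizes.
oracle_profit <- function(f, B_prime, P, q, c_prime) {
  B_prime * (1 - exp(-q * f)) * P - c_prime * f
}

# Raw (un-normalized) payoffs computed from first principles with a raw
# cost c, raw biomass B and carrying capacity K: total harvest revenue is
# split in proportion to effort, each agent pays its own cost. Used for
# the homogeneity / normalization-invariance checks.
oracle_raw_payoffs <- function(c, B, K, P, q, f_star) {
  f_T <- log(B * P * q / c) / q               # raw first-order condition
  H_rev <- function(f) B * (1 - exp(-q * f)) * P
  list(
    CC = H_rev(f_star) - c * f_star,
    CN = (f_star / f_T) * H_rev(f_T) - c * f_star,
    NC = ((f_T - f_star) / f_T) * H_rev(f_T) - c * (f_T - f_star),
    NN = 0)
}

# Frequency at which the two strategies are equally fit, found by brute
# force on the fitness difference rather than by the closed form.
oracle_equal_fitness <- function(m, interval = c(1e-9, 1 - 1e-9)) {
  g <- function(x) {
    (x * m$pi_CC + (1 - x) * m$pi_CN) - (x * m$pi_NC + (1 - x) * m$pi_NN)
  }
  stats::uniroot(g, interval, tol = 1e-12)$root
}

default_econ <- function() bioeconomic_params()

# Long-run target frequency implied by an outcome label, for the
# classifier-vs-dynamics cross-check.
predicted_limit <- function(label, x_bar, x0) {
  switch(label,
         cooperative_dominance = 1,
         noncooperative_dominance = 0,
         cooperative_coexistence = x_bar,
         noncooperative_coexistence = x_bar,
         bistability = if (x0 < x_bar) 0 else if (x0 > x_bar) 1
                       else NA_real_,
         NA_real_)
}
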