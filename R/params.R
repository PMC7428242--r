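# Parameter containers. All user-facing constructors validate on entry so
# that downstream algebra (logs of revenue/cost ratios, penalty fractions)
# never sees an out-of-domain value.

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    rlang::abort(sprintf("`%s` must be supplied.", name),
                 class = "fisherygame_domain_error")
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    rlang::abort(sprintf("`%s` must be a single finite number.", name),
                 class = "fisherygame_domain_error")
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    rlang::abort(sprintf(
      "`%s` = %g is outside its domain %s%g, %g%s.",
      name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"),
      class = "fisherygame_domain_error")
  }
  invisible(x)
}

#' Bioeconomic constants of the fishery
#'
#' Fixed economic and gear parameters of the harvest model. Defaults are the
#' Laguna shrimp fyke-net fishery values: price 23 (Brazilian reais per kg),
#' catchability 0.023 per fishing unit, normalized unit cost `c' = c/K` of
#' 2e-5 reais per effort unit per kg of carrying capacity, and a regulated
#' effort of 18 nets per fisher.
#'
#' @param P Market price per unit biomass (currency/kg); positive.
#' @param q Catchability: fraction of the available stock taken per unit of
#'   effort; in (0, 1).
#' @param c_prime Cost of one effort unit per unit of carrying capacity
#'   (currency/(effort x kg)); positive. Obtain it from a raw cost `c` and a
#'   carrying capacity `K` with [normalize_stock()].
#' @param f_star Regulated fishing effort (fishing units, e.g. nets);
#'   positive.
#' @param K Carrying capacity (kg). Optional; only needed to normalize raw
#'   costs and stock sizes.
#'
#' @return An object of class `bioeconomic_params`.
#' @seealso [stock_state()], [social_params()], [fishery_game()]
#' @examples
#' bioeconomic_params()
#' bioeconomic_params(P = 30, f_star = 12)
#' @export
bioeconomic_params <- function(P = 23, q = 0.023, c_prime = 2e-5,
                               f_star = 18, K = NULL) {
  check_number(P, "P", lower = 0, strict_lower = TRUE)
  check_number(q, "q", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(c_prime, "c_prime", lower = 0, strict_lower = TRUE)
  check_number(f_star, "f_star", lower = 0, strict_lower = TRUE)
  check_number(K, "K", lower = 0, strict_lower = TRUE, allow_null = TRUE)
  structure(list(P = P, q = q, c_prime = c_prime, f_star = f_star, K = K),
            class = "bioeconomic_params")
}

#' State of the fish stock for one game
#'
#' @param B_prime Relative stock size `B' = B/K`, in (0, 1].
#' @param r Intrinsic growth rate of the stock per season; non-negative
#'   (the bundled scenarios explore 0 to 2).
#'
#' @return An object of class `stock_state`.
#' @examples
#' stock_state(B_prime = 0.3, r = 1.0)
#' @export
stock_state <- function(B_prime, r) {
  check_number(B_prime, "B_prime", lower = 0, upper = 1, strict_lower = TRUE)
  check_number(r, "r", lower = 0)
  structure(list(B_prime = B_prime, r = r), class = "stock_state")
}

#' Social parameters of the two fisher populations
#'
#' Control perception `alpha` is the perceived certainty of being punished
#' for a violation; risk tolerance `b` is the (inverse) ability to bear
#' stock uncertainty: `b` near 0 means high tolerance (favours cooperation),
#' `b` near 1 low tolerance. Population 1 holds the cooperative strategy,
#' population 2 the non-cooperative one; all bundled scenarios are symmetric
#' so the population-2 values default to the population-1 values.
#'
#' @param alpha1,alpha2 Control perception of each population, in \[0, 1\].
#' @param b1,b2 Risk tolerance of each population, in \[0, 1\].
#'
#' @return An object of class `social_params`.
#' @examples
#' social_params()                      # alpha = 1, b = 0.3 (symmetric)
#' social_params(alpha1 = 0.8, b1 = 0.7)
#' @export
social_params <- function(alpha1 = 1, b1 = 0.3, alpha2 = alpha1, b2 = b1) {
  check_number(alpha1, "alpha1", lower = 0, upper = 1)
  check_number(alpha2, "alpha2", lower = 0, upper = 1)
  check_number(b1, "b1", lower = 0, upper = 1)
  check_number(b2, "b2", lower = 0, upper = 1)
  structure(list(alpha1 = alpha1, alpha2 = alpha2, b1 = b1, b2 = b2),
            class = "social_params")
}

#' Scenario configuration for parameter sweeps
#'
#' Bundles the social and economic parameters with the (r, B') grid over
#' which outcomes are mapped. Default grids cover growth rates 0 to 2 and
#' relative stock sizes 0.01 to 1, both in steps of 0.01 — fine enough to
#' localize outcome boundaries to about one cell before bisection refines
#' them.
#'
#' @param social A [social_params()] object.
#' @param econ A [bioeconomic_params()] object.
#' @param r_grid Sorted vector of growth rates, all non-negative.
#' @param B_grid Sorted vector of relative stock sizes in (0, 1].
#'
#' @return An object of class `scenario_config`.
#' @seealso [sweep_scenario()], [boundary_r()], [frequency_curves()],
#'   [scenario_preset()]
#' @export
scenario_config <- function(social = social_params(),
                            econ = bioeconomic_params(),
                            r_grid = seq(0, 2, by = 0.01),
                            B_grid = seq(0.01, 1, by = 0.01)) {
  stopifnot(inherits(social, "social_params"),
            inherits(econ, "bioeconomic_params"))
  for (nm in c("r_grid", "B_grid")) {
    g <- get(nm)
    if (!is.numeric(g) || length(g) == 0L || anyNA(g)) {
      rlang::abort(sprintf("`%s` must be a non-empty numeric vector.", nm),
                   class = "fisherygame_domain_error")
    }
    if (is.unsorted(g, strictly = TRUE)) {
      rlang::abort(sprintf("`%s` must be strictly increasing.", nm),
                   class = "fisherygame_domain_error")
    }
  }
  if (min(r_grid) < 0) {
    rlang::abort("`r_grid` values must be non-negative.",
                 class = "fisherygame_domain_error")
  }
  if (min(B_grid) <= 0 || max(B_grid) > 1) {
    rlang::abort("`B_grid` values must lie in (0, 1].",
                 class = "fisherygame_domain_error")
  }
  structure(list(social = social, econ = econ,
                 r_grid = as.numeric(r_grid), B_grid = as.numeric(B_grid)),
            class = "scenario_config")
}

#' @export
print.bioeconomic_params <- function(x, ...) {
  cat("<bioeconomic_params>\n")
  cat(sprintf("  P = %g  q = %g  c' = %g  f* = %g%s\n",
              x$P, x$q, x$c_prime, x$f_star,
              if (is.null(x$K)) "" else sprintf("  K = %g", x$K)))
  invisible(x)
}

#' @export
print.social_params <- function(x, ...) {
  cat("<social_params>\n")
  cat(sprintf("  cooperators:     alpha = %g  b = %g\n", x$alpha1, x$b1))
  cat(sprintf("  non-cooperators: alpha = %g  b = %g\n", x$alpha2, x$b2))
  invisible(x)
}

#' @export
print.stock_state <- function(x, ...) {
  cat(sprintf("<stock_state> B' = %g, r = %g\n", x$B_prime, x$r))
  invisible(x)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  r grid: %d points in [%g, %g]\n",
              length(x$r_grid), min(x$r_grid), max(x$r_grid)))
  cat(sprintf("  B' grid: %d points in [%g, %g]\n",
              length(x$B_grid), min(x$B_grid), max(x$B_grid)))
  print(x$social)
  print(x$econ)
  invisible(x)
}
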