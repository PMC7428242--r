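# Scenario machinery: (r, B') outcome grids, equilibrium-frequency curves,
# and bisection of outcome boundaries along the growth-rate axis.

#' Sweep a scenario over the (r, B') grid
#'
#' Classifies the game at every grid cell of the scenario: base payoffs,
#' behaviour penalty, penalized matrix, outcome label and interior
#' equilibrium. Fully deterministic — identical configs give bit-identical
#' tables.
#'
#' @param config A [scenario_config()] object.
#' @param delta_override Optional fixed penalty for both populations;
#'   `0.5` removes the control and risk effects from the model.
#' @return A tibble of class `outcome_sweep`, one row per grid cell, with
#'   the scenario attached as attribute `scenario`. [autoplot()] renders
#'   it as a phase diagram.
#' @examples
#' cfg <- scenario_preset("high_tolerance_high_control",
#'                        r_grid = seq(0, 2, by = 0.1),
#'                        B_grid = seq(0.1, 1, by = 0.1))
#' sweep_scenario(cfg) |> dplyr::count(label)
#' @export
sweep_scenario <- function(config, delta_override = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  grid <- tidyr::expand_grid(r = config$r_grid, B_prime = config$B_grid)
  grid$alpha1 <- config$social$alpha1
  grid$alpha2 <- config$social$alpha2
  grid$b1 <- config$social$b1
  grid$b2 <- config$social$b2
  out <- classify_games(grid, econ = config$econ,
                        delta_override = delta_override)
  structure(out, scenario = config,
            class = c("outcome_sweep", class(out)))
}

boundary_kinds <- list(
  dominance = list(
    from = "cooperative_dominance",
    to = c("cooperative_coexistence", "noncooperative_coexistence")),
  half_equilibrium = list(
    from = "cooperative_coexistence",
    to = "noncooperative_coexistence"))

match_transition <- function(from, to) {
  for (kind in names(boundary_kinds)) {
    k <- boundary_kinds[[kind]]
    if (from %in% k$from && to %in% k$to) return(kind)
  }
  rlang::abort(sprintf("No growth-rate boundary is defined between '%s' and '%s'.",
                       from, to),
               class = "fisherygame_domain_error")
}

# Sign functions whose roots (in r) are the outcome boundaries at one B'.
# dominance:        pi_CC(r) - pi_NC(r) = 0 (cooperation stops resisting
#                   invasion; pi_CN > 0 whenever viable, so the dominance
#                   region is bounded by this condition alone)
# half_equilibrium: x_bar(r) - 0.5 = 0 within the coexistence window,
#                   whose lower edge is the dominance boundary (x_bar -> 1
#                   there).
# Sentinels: -Inf when the transition lies below the growth-rate range
# (the 'from' region is already absent at its lower end), +Inf when it
# lies above it (the 'from' region persists through the upper end); NA
# when fishing is not viable at this stock size.
boundary_root <- function(kind, social, econ, B_prime, r_range,
                          tol = 1e-6) {
  if (!viable_fishery(econ, B_prime)) return(NA_real_)
  bp <- base_payoffs(econ, B_prime)
  g_dom <- function(r) {
    behaviour_penalty(social$alpha1, social$b1, r) * bp$Pi_CC -
      (1 - behaviour_penalty(social$alpha2, social$b2, r)) * bp$Pi_NC
  }
  r_lo <- r_range[1]; r_hi <- r_range[2]
  dom_root <- function() {
    if (g_dom(r_lo) <= 0) return(-Inf)
    if (g_dom(r_hi) > 0) return(Inf)
    stats::uniroot(g_dom, c(r_lo, r_hi), tol = tol)$root
  }
  if (kind == "dominance") return(dom_root())
  # half_equilibrium: bracket below by the dominance boundary if present
  g_half <- function(r) {
    d_C <- behaviour_penalty(social$alpha1, social$b1, r)
    d_N <- behaviour_penalty(social$alpha2, social$b2, r)
    pi_CC <- d_C * bp$Pi_CC; pi_CN <- d_C * bp$Pi_CN
    pi_NC <- (1 - d_N) * bp$Pi_NC
    (-pi_CN) / (pi_CC - pi_CN - pi_NC) - 0.5
  }
  lo <- dom_root()
  if (is.infinite(lo) && lo > 0) return(Inf)  # dominance through the range
  lo <- if (is.finite(lo)) min(lo + tol * 1e-3, r_hi) else r_lo
  if (g_half(lo) <= 0) return(-Inf)
  if (g_half(r_hi) > 0) return(Inf)
  stats::uniroot(g_half, c(lo, r_hi), tol = tol)$root
}

#' Critical growth rate of an outcome transition
#'
#' Locates, by bisection to `tol`, the growth rate at which the outcome
#' label changes along the r-axis for one or more relative stock sizes.
#' Two transitions are defined: cooperative dominance to coexistence
#' (where the penalized cooperator payoff stops exceeding the cheater's,
#' `delta_C Pi_CC = (1 - delta_N) Pi_NC`) and cooperative to
#' non-cooperative coexistence (where the interior equilibrium crosses one
#' half). `NA` with a classed warning marks columns where the transition
#' does not occur within the growth-rate range.
#'
#' @param config A [scenario_config()] object; its `r_grid` range brackets
#'   the search and its `B_grid` supplies the columns when `B_prime` is
#'   `NULL`.
#' @param from,to Outcome labels adjacent along r (see above).
#' @param B_prime Optional stock-size column(s); defaults to the config's
#'   grid.
#' @param tol Bisection tolerance on r.
#' @return A tibble with columns `B_prime` and `r_star`.
#' @examples
#' cfg <- scenario_preset("high_tolerance_high_control")
#' boundary_r(cfg, "cooperative_dominance", "cooperative_coexistence",
#'            B_prime = 0.3)
#' @export
boundary_r <- function(config, from, to, B_prime = NULL, tol = 1e-6) {
  stopifnot(inherits(config, "scenario_config"))
  kind <- match_transition(from, to)
  cols <- B_prime %||% config$B_grid
  r_range <- range(config$r_grid)
  r_star <- vapply(cols, function(b) {
    boundary_root(kind, config$social, config$econ, b, r_range, tol = tol)
  }, numeric(1))
  r_star[!is.finite(r_star)] <- NA_real_
  if (anyNA(r_star)) {
    rlang::warn("Transition absent within the growth-rate range for some stock sizes (NA returned).",
                class = "fisherygame_no_boundary")
  }
  tibble::tibble(B_prime = cols, r_star = r_star)
}

#' Growth-rate thresholds aggregated over the whole stock-size grid
#'
#' Reads the outcome map across the full B' band the way the phase
#' diagrams are read: `r_dominance` is the largest growth rate up to which
#' *every* viable stock size yields cooperative dominance (the minimum of
#' the per-B' dominance boundaries), and `r_all_noncooperative` the
#' smallest growth rate beyond which *every* viable stock size yields
#' non-cooperative coexistence (the maximum of the per-B' equilibrium
#' crossings) — equivalently the largest r at which any cell is still
#' cooperative-dominant or cooperative-coexistent.
#'
#' @inheritParams boundary_r
#' @return A one-row tibble with columns `r_dominance` and
#'   `r_all_noncooperative` (either may be `NA` when the region is empty
#'   or unbounded on the grid).
#' @examples
#' band_thresholds(scenario_preset("low_tolerance_high_control"))
#' @export
band_thresholds <- function(config, tol = 1e-6) {
  stopifnot(inherits(config, "scenario_config"))
  viable <- viable_fishery(config$econ, config$B_grid)
  cols <- config$B_grid[viable]
  r_range <- range(config$r_grid)
  dom <- vapply(cols, function(b) {
    boundary_root("dominance", config$social, config$econ, b, r_range,
                  tol = tol)
  }, numeric(1))
  half <- vapply(cols, function(b) {
    boundary_root("half_equilibrium", config$social, config$econ, b,
                  r_range, tol = tol)
  }, numeric(1))
  # A column whose dominance region is already absent at the low end of
  # the range makes the all-dominance region empty (NA); one where
  # dominance persists through the range is bounded by the range itself.
  r_dom <- if (any(dom == -Inf)) NA_real_
           else min(pmin(dom, r_range[2]))
  # A column still cooperative at the top of the range makes the
  # all-noncooperative region empty; one noncooperative throughout
  # imposes no constraint beyond the low end.
  r_nc <- if (any(half == Inf)) NA_real_
          else max(pmax(half, r_range[1]))
  tibble::tibble(r_dominance = r_dom, r_all_noncooperative = r_nc)
}

#' Equilibrium cooperator frequency as a function of growth rate
#'
#' For each relative stock size in the grid, the long-run cooperator
#' frequency at every growth rate: 1 where cooperation dominates, the
#' interior equilibrium where the strategies coexist, and `NA` elsewhere
#' (gaps in the curve).
#'
#' @inheritParams sweep_scenario
#' @return A tibble of class `frequency_curves` with columns `B_prime`,
#'   `r`, `label` and `x_C_eq`. [autoplot()] draws one line per stock
#'   size.
#' @examples
#' cfg <- scenario_preset("high_tolerance_high_control",
#'                        B_grid = c(0.2, 0.5, 1.0))
#' frequency_curves(cfg)
#' @export
frequency_curves <- function(config, delta_override = NULL) {
  sw <- sweep_scenario(config, delta_override = delta_override)
  out <- dplyr::mutate(
    tibble::as_tibble(sw),
    x_C_eq = dplyr::case_when(
      label == "cooperative_dominance" ~ 1,
      label %in% c("cooperative_coexistence",
                   "noncooperative_coexistence") ~ x_bar,
      .default = NA_real_))
  out <- out[, c("B_prime", "r", "label", "x_C_eq")]
  structure(out, scenario = config,
            class = c("frequency_curves", class(out)))
}
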