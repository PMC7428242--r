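# Outcome classification for the 2x2 fishery game and the interior
# (coexistence) equilibrium frequency.

outcome_levels <- c("cooperative_dominance", "cooperative_coexistence",
                    "noncooperative_coexistence", "noncooperative_dominance",
                    "bistability", "no_fishing", "degenerate")

# Vectorized classification core shared by classify_outcome() and
# classify_games(). Interior equilibrium is reported only where it is a
# dynamical fixed point (coexistence: stable; bistability: unstable).
classify_impl <- function(pi_CC, pi_CN, pi_NC, pi_NN, viable,
                          tol = 1e-12) {
  d1 <- pi_CC - pi_NC   # does cooperation resist cheater invasion?
  d2 <- pi_CN - pi_NN   # can cooperation invade cheaters?
  den <- pi_CC - pi_CN - pi_NC + pi_NN
  x_bar <- ifelse(viable & den != 0, (pi_NN - pi_CN) / den, NA_real_)
  tie <- viable & (abs(d1) <= tol | abs(d2) <= tol)
  label <- dplyr::case_when(
    !viable ~ "no_fishing",
    tie ~ "degenerate",
    d1 > 0 & d2 > 0 ~ "cooperative_dominance",
    d1 < 0 & d2 < 0 ~ "noncooperative_dominance",
    d1 > 0 & d2 < 0 ~ "bistability",
    x_bar > 0.5 ~ "cooperative_coexistence",
    .default = "noncooperative_coexistence")
  interior <- label %in% c("cooperative_coexistence",
                           "noncooperative_coexistence", "bistability")
  list(label = label, x_bar = ifelse(interior, x_bar, NA_real_),
       tie = tie, boundary_half = viable & !tie & !is.na(x_bar) &
         x_bar == 0.5 & d1 < 0 & d2 > 0)
}

#' Interior equilibrium frequency of cooperators
#'
#' The cooperator frequency at which the two strategies have equal
#' fitness: `x_bar = (pi_NN - pi_CN) / (pi_CC - pi_CN - pi_NC + pi_NN)`.
#' It is the interior fixed point of the replicator dynamics — stable
#' under coexistence, unstable under bistability.
#'
#' @param matrix A [payoff_matrix()] (or [fishery_game()]) object.
#' @return The equilibrium frequency, or `NA` (with a classed warning)
#'   when the fitness difference is constant in frequency and no interior
#'   equilibrium exists.
#' @examples
#' g <- fishery_game(stock_state(0.3, 1.0), social_params(0.8, 0.7))
#' interior_equilibrium(g)
#' @export
interior_equilibrium <- function(matrix) {
  stopifnot(inherits(matrix, "payoff_matrix"))
  den <- matrix$pi_CC - matrix$pi_CN - matrix$pi_NC + matrix$pi_NN
  if (!is.finite(den) || den == 0) {
    rlang::warn("Payoff matrix has no interior equilibrium (degenerate fitness difference).",
                class = "fisherygame_no_interior_equilibrium")
    return(NA_real_)
  }
  (matrix$pi_NN - matrix$pi_CN) / den
}

#' Classify the outcome of one fishery game
#'
#' Applies the standard sign conditions for 2x2 evolutionary games: with
#' `pi_CC > pi_NC` cooperation resists invasion, with `pi_CN > pi_NN` it
#' can invade. The four sign patterns give cooperative dominance,
#' non-cooperative dominance, bistability, or coexistence; coexistence is
#' sub-labelled cooperative when the equilibrium cooperator frequency
#' exceeds one half and non-cooperative otherwise. Non-viable fisheries
#' are labelled `no_fishing` before any payoff comparison (their payoffs
#' are undefined).
#'
#' Payoffs equal within `tol` sit on a classification boundary; such games
#' are labelled `degenerate` and a classed warning
#' (`fisherygame_degenerate_game`) is raised rather than silently binning
#' them. An equilibrium exactly at one half is labelled
#' `noncooperative_coexistence` (the cooperative label requires a strictly
#' higher frequency) and flagged with a warning.
#'
#' @param matrix A [payoff_matrix()] or [fishery_game()] object.
#' @param viable Viability flag; defaults to the matrix's own.
#' @param tol Absolute tolerance for payoff ties.
#' @return A one-row tibble of class `game_outcome` with columns `label`
#'   and `x_bar` (`NA` unless the outcome is coexistence or bistability).
#' @examples
#' g <- fishery_game(stock_state(0.3, 0.5), social_params(1, 0.3))
#' classify_outcome(g)
#' @export
classify_outcome <- function(matrix, viable = matrix$viable, tol = 1e-12) {
  stopifnot(inherits(matrix, "payoff_matrix"))
  res <- classify_impl(matrix$pi_CC, matrix$pi_CN, matrix$pi_NC,
                       matrix$pi_NN, viable = isTRUE(viable), tol = tol)
  if (res$tie) {
    rlang::warn("Payoffs tie within tolerance; game lies on a classification boundary.",
                class = "fisherygame_degenerate_game")
  }
  if (res$boundary_half) {
    rlang::warn("Interior equilibrium is exactly 0.5; labelled noncooperative_coexistence.",
                class = "fisherygame_half_equilibrium")
  }
  out <- tibble::tibble(label = res$label, x_bar = res$x_bar)
  class(out) <- c("game_outcome", class(out))
  out
}

#' Classify a table of fishery games
#'
#' Vectorized pipeline used by [sweep_scenario()]: for every row of
#' `data`, builds base payoffs, the behaviour penalty, the penalized
#' matrix, and the outcome label. Rows below the viability threshold are
#' labelled `no_fishing`.
#'
#' @param data A data frame with columns `r` and `B_prime`, and either
#'   social columns `alpha1`, `b1` (optionally `alpha2`, `b2`; symmetric
#'   defaults apply) or none if `delta_override` is given.
#' @param econ A [bioeconomic_params()] object.
#' @param delta_override Optional fixed penalty for both populations,
#'   bypassing the social columns.
#' @param tol Payoff-tie tolerance passed to the classifier.
#' @return The input tibble augmented with `delta_C`, `delta_N`, `viable`,
#'   `pi_CC`, `pi_CN`, `pi_NC`, `pi_NN`, `label`, `x_bar`.
#' @examples
#' library(tibble)
#' tibble(r = c(0.5, 2), B_prime = 0.3, alpha1 = 1, b1 = 0.3) |>
#'   classify_games()
#' @export
classify_games <- function(data, econ = bioeconomic_params(),
                           delta_override = NULL, tol = 1e-12) {
  stopifnot(is.data.frame(data))
  if (!all(c("r", "B_prime") %in% names(data))) {
    rlang::abort("`data` must have columns `r` and `B_prime`.",
                 class = "fisherygame_domain_error")
  }
  check_number(delta_override, "delta_override", lower = 0, upper = 1,
               allow_null = TRUE)
  data <- tibble::as_tibble(data)
  if (is.null(delta_override)) {
    if (!all(c("alpha1", "b1") %in% names(data))) {
      rlang::abort("`data` needs `alpha1` and `b1` columns (or a `delta_override`).",
                   class = "fisherygame_domain_error")
    }
    if (!"alpha2" %in% names(data)) data$alpha2 <- data$alpha1
    if (!"b2" %in% names(data)) data$b2 <- data$b1
    d_C <- behaviour_penalty(data$alpha1, data$b1, data$r)
    d_N <- behaviour_penalty(data$alpha2, data$b2, data$r)
  } else {
    d_C <- d_N <- rep(delta_override, nrow(data))
  }
  bp <- base_payoffs(econ, data$B_prime)
  pi_CC <- d_C * bp$Pi_CC
  pi_CN <- d_C * bp$Pi_CN
  pi_NC <- (1 - d_N) * bp$Pi_NC
  pi_NN <- ifelse(bp$viable, 0, NA_real_)
  cls <- classify_impl(pi_CC, pi_CN, pi_NC, pi_NN, bp$viable, tol = tol)
  dplyr::mutate(data,
                delta_C = d_C, delta_N = d_N, viable = bp$viable,
                pi_CC = pi_CC, pi_CN = pi_CN, pi_NC = pi_NC, pi_NN = pi_NN,
                label = factor(cls$label, levels = outcome_levels),
                x_bar = cls$x_bar)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a payoff matrix into one row per encounter
#'
#' @param x A [payoff_matrix()] or [fishery_game()] object.
#' @param ... Unused.
#' @return A tibble with columns `focal`, `opponent`, `payoff`.
#' @export
tidy.payoff_matrix <- function(x, ...) {
  tibble::tibble(
    focal = c("C", "C", "N", "N"),
    opponent = c("C", "N", "C", "N"),
    payoff = c(x$pi_CC, x$pi_CN, x$pi_NC, x$pi_NN))
}

#' One-row summary of a payoff matrix and its game outcome
#'
#' @param x A [payoff_matrix()] or [fishery_game()] object.
#' @param ... Unused.
#' @return A one-row tibble with the payoffs, penalties, viability,
#'   outcome label and interior equilibrium (plus `B_prime` and `r` for
#'   [fishery_game()] objects).
#' @export
glance.payoff_matrix <- function(x, ...) {
  cls <- classify_impl(x$pi_CC, x$pi_CN, x$pi_NC, x$pi_NN, x$viable)
  tibble::tibble(
    pi_CC = x$pi_CC, pi_CN = x$pi_CN, pi_NC = x$pi_NC, pi_NN = x$pi_NN,
    delta_C = x$delta_C, delta_N = x$delta_N, viable = x$viable,
    label = cls$label, x_bar = cls$x_bar)
}

#' @rdname glance.payoff_matrix
#' @export
glance.fishery_game <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(B_prime = x$stock$B_prime, r = x$stock$r),
    glance.payoff_matrix(x))
}
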