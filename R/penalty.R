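# The social behaviour penalty and its application to the payoff matrix.

#' Behaviour penalty combining control perception, risk tolerance and
#' stock growth
#'
#' `delta = alpha / (1 + b r)`. The penalty scales cooperator payoffs by
#' `delta` and cheater payoffs by `1 - delta`: a value of 1 penalizes
#' cheaters maximally, 0 penalizes cooperators maximally. Fast stock growth
#' (`r` large) and low risk tolerance (`b` near 1) both erode the penalty
#' on cheating — a quickly recovering stock weakens the sense that the
#' restriction matters — while a strong perception of enforcement (`alpha`
#' near 1) strengthens it.
#'
#' @param alpha Control perception in \[0, 1\]. Vectorized.
#' @param b Risk tolerance in \[0, 1\] (0 = high tolerance). Vectorized.
#' @param r Stock growth rate, non-negative. Vectorized.
#' @return `delta` in \[0, alpha\].
#' @examples
#' behaviour_penalty(0.8, 0.7, 1.0)  # 0.8 / 1.7
#' @export
behaviour_penalty <- function(alpha, b, r) {
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha > 1)) {
    rlang::abort("`alpha` must lie in [0, 1].",
                 class = "fisherygame_domain_error")
  }
  if (any(!is.finite(b)) || any(b < 0) || any(b > 1)) {
    rlang::abort("`b` must lie in [0, 1].",
                 class = "fisherygame_domain_error")
  }
  if (any(!is.finite(r)) || any(r < 0)) {
    rlang::abort("`r` must be finite and non-negative.",
                 class = "fisherygame_domain_error")
  }
  alpha / (1 + b * r)
}

#' Apply the behaviour penalty to base payoffs
#'
#' Scales cooperator payoffs by `delta_C` and cheater payoffs by
#' `1 - delta_N`. The two populations may perceive control and bear risk
#' differently, hence the two penalty values; in the symmetric case they
#' coincide. The cheater-cheater payoff stays exactly zero (rent
#' dissipation) under any penalty.
#'
#' @param base A one-row tibble from [base_payoffs()], or any list with
#'   elements `Pi_CC`, `Pi_CN`, `Pi_NC` (and optionally `viable`,
#'   `degenerate`).
#' @param delta_C Penalty applied to the cooperative population, in
#'   \[0, 1\].
#' @param delta_N Penalty applied to the non-cooperative population;
#'   defaults to `delta_C`.
#' @return A `payoff_matrix` object.
#' @examples
#' bp <- base_payoffs(bioeconomic_params(), 0.3)
#' penalized_matrix(bp, delta_C = 0.5)
#' @export
penalized_matrix <- function(base, delta_C, delta_N = delta_C) {
  check_number(delta_C, "delta_C", lower = 0, upper = 1)
  check_number(delta_N, "delta_N", lower = 0, upper = 1)
  if (is.data.frame(base) && nrow(base) != 1L) {
    rlang::abort("`base` must contain exactly one set of payoffs.",
                 class = "fisherygame_domain_error")
  }
  viable <- if (!is.null(base$viable)) isTRUE(all(base$viable)) else TRUE
  payoff_matrix(
    pi_CC = if (viable) delta_C * base$Pi_CC else NA_real_,
    pi_CN = if (viable) delta_C * base$Pi_CN else NA_real_,
    pi_NC = if (viable) (1 - delta_N) * base$Pi_NC else NA_real_,
    pi_NN = if (viable) 0 else NA_real_,
    delta_C = delta_C, delta_N = delta_N, viable = viable,
    degenerate_encounter = isTRUE(all(base$degenerate %||% FALSE)))
}

#' Construct a penalized payoff matrix
#'
#' Low-level constructor; most users build matrices from parameters with
#' [fishery_game()] or [penalized_matrix()].
#'
#' @param pi_CC,pi_CN,pi_NC,pi_NN Penalized payoffs (row player's payoff
#'   against the column strategy; C = cooperator, N = non-cooperator).
#' @param delta_C,delta_N Penalty values used, if known.
#' @param viable Whether fishing is economically viable.
#' @param degenerate_encounter Whether the mixed encounter was clipped
#'   (`f* >= f_T`).
#' @return An object of class `payoff_matrix`.
#' @export
payoff_matrix <- function(pi_CC, pi_CN, pi_NC, pi_NN = 0,
                          delta_C = NA_real_, delta_N = delta_C,
                          viable = TRUE, degenerate_encounter = FALSE) {
  structure(list(pi_CC = pi_CC, pi_CN = pi_CN, pi_NC = pi_NC,
                 pi_NN = pi_NN, delta_C = delta_C, delta_N = delta_N,
                 viable = isTRUE(viable),
                 degenerate_encounter = isTRUE(degenerate_encounter)),
            class = "payoff_matrix")
}

#' Build the penalized game for one fishery state
#'
#' Convenience wrapper chaining [base_payoffs()], [behaviour_penalty()] and
#' [penalized_matrix()] for a single `(B', r)` state: the one-game
#' counterpart of [sweep_scenario()].
#'
#' @param stock A [stock_state()] object.
#' @param social A [social_params()] object.
#' @param econ A [bioeconomic_params()] object.
#' @param delta_override Optional fixed penalty replacing the computed
#'   `delta` for both populations. `delta_override = 0.5` removes the
#'   control and risk effects entirely, scaling both roles equally.
#' @return A `fishery_game` object (a [payoff_matrix()] carrying the
#'   generating parameters).
#' @examples
#' g <- fishery_game(stock_state(0.3, 1.0), social_params(0.8, 0.7))
#' g
#' glance(g)
#' @export
fishery_game <- function(stock, social = social_params(),
                         econ = bioeconomic_params(),
                         delta_override = NULL) {
  stopifnot(inherits(stock, "stock_state"),
            inherits(social, "social_params"),
            inherits(econ, "bioeconomic_params"))
  check_number(delta_override, "delta_override", lower = 0, upper = 1,
               allow_null = TRUE)
  base <- base_payoffs(econ, stock$B_prime)
  if (is.null(delta_override)) {
    d_C <- behaviour_penalty(social$alpha1, social$b1, stock$r)
    d_N <- behaviour_penalty(social$alpha2, social$b2, stock$r)
  } else {
    d_C <- d_N <- delta_override
  }
  m <- penalized_matrix(base, delta_C = d_C, delta_N = d_N)
  m$stock <- stock
  m$social <- social
  m$econ <- econ
  m$base <- base
  class(m) <- c("fishery_game", class(m))
  m
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat("<payoff_matrix>")
  if (!x$viable) {
    cat(" (fishing not viable)\n")
    return(invisible(x))
  }
  cat("\n            vs C        vs N\n")
  cat(sprintf("  C  %10.5f  %10.5f\n", x$pi_CC, x$pi_CN))
  cat(sprintf("  N  %10.5f  %10.5f\n", x$pi_NC, x$pi_NN))
  if (!is.na(x$delta_C)) {
    cat(sprintf("  delta_C = %.6g, delta_N = %.6g\n", x$delta_C, x$delta_N))
  }
  invisible(x)
}

#' @export
print.fishery_game <- function(x, ...) {
  cat(sprintf("<fishery_game> B' = %g, r = %g\n",
              x$stock$B_prime, x$stock$r))
  NextMethod()
}
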