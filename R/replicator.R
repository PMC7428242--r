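# Continuous-time replicator dynamics on the cooperator-frequency simplex.
# The state is one-dimensional (x_N = 1 - x_C), so trajectories are
# monotone between fixed points and every run ends at a boundary or at the
# interior equilibrium.

clip01 <- function(x) pmin(1, pmax(0, x))

#' Strategy fitnesses at a given population composition
#'
#' Expected payoff of each strategy against a population with cooperator
#' frequency `x_C`: `fit_C = x_C pi_CC + (1 - x_C) pi_CN` and
#' `fit_N = x_C pi_NC + (1 - x_C) pi_NN`. Both are linear in `x_C` and
#' cross at the interior equilibrium.
#'
#' @param x_C Cooperator frequency in \[0, 1\]. Vectorized.
#' @param matrix A [payoff_matrix()] or [fishery_game()] object.
#' @return A tibble with columns `x_C`, `fit_C`, `fit_N`.
#' @export
replicator_fitness <- function(x_C, matrix) {
  stopifnot(inherits(matrix, "payoff_matrix"))
  if (any(!is.finite(x_C)) || any(x_C < 0) || any(x_C > 1)) {
    rlang::abort("`x_C` must lie in [0, 1].",
                 class = "fisherygame_domain_error")
  }
  tibble::tibble(
    x_C = x_C,
    fit_C = x_C * matrix$pi_CC + (1 - x_C) * matrix$pi_CN,
    fit_N = x_C * matrix$pi_NC + (1 - x_C) * matrix$pi_NN)
}

#' Right-hand side of the replicator equation
#'
#' `dx_C/dt = x_C (1 - x_C) (fit_C(x) - fit_N(x))`: the cooperator
#' frequency grows when cooperators are fitter than cheaters. Zero at both
#' boundaries and at the interior equilibrium.
#'
#' @inheritParams replicator_fitness
#' @return Numeric vector of rates of change.
#' @export
replicator_rhs <- function(x_C, matrix) {
  fit <- replicator_fitness(x_C, matrix)
  x_C * (1 - x_C) * (fit$fit_C - fit$fit_N)
}

#' Integrate the replicator dynamics
#'
#' Integrates `dx_C/dt` from `x0` with an adaptive stiff-capable solver
#' (`deSolve::lsodar`), stopping early once `|dx_C/dt|` falls below
#' `conv_tol` (a root condition), i.e. once the trajectory has effectively
#' reached a fixed point. Frequencies are clipped to \[0, 1\] against
#' round-off and snapped to the boundary when within 1e-12 of it. Time is
#' measured in generations (fishing seasons).
#'
#' @param matrix A [payoff_matrix()] or [fishery_game()] object with
#'   finite payoffs.
#' @param x0 Initial cooperator frequency in \[0, 1\].
#' @param horizon Maximum number of generations to integrate.
#' @param conv_tol Convergence threshold on `|dx_C/dt|`.
#' @param n_out Number of time points reported in the trajectory (the
#'   solver's internal stepping is adaptive and unrelated).
#' @param rtol,atol Solver error tolerances.
#' @return A tibble of class `replicator_trajectory` with columns `time`
#'   and `x_C`, and attributes `x_final`, `converged` and `matrix`.
#'   [glance()] summarises them.
#' @examples
#' g <- fishery_game(stock_state(0.3, 1.0), social_params(0.8, 0.7))
#' traj <- replicator_integrate(g, x0 = 0.10)
#' glance(traj)
#' @export
replicator_integrate <- function(matrix, x0 = 0.5, horizon = 1e4,
                                 conv_tol = 1e-10, n_out = 201,
                                 rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(matrix, "payoff_matrix"))
  check_number(x0, "x0", lower = 0, upper = 1)
  check_number(horizon, "horizon", lower = 0, strict_lower = TRUE)
  payoffs <- c(matrix$pi_CC, matrix$pi_CN, matrix$pi_NC, matrix$pi_NN)
  if (any(!is.finite(payoffs))) {
    rlang::abort("Payoff matrix must be finite to integrate (is the fishery viable?).",
                 class = "fisherygame_integration_error")
  }

  snap <- function(x) {
    x <- clip01(x)
    x[x < 1e-12] <- 0
    x[x > 1 - 1e-12] <- 1
    x
  }

  # plain-arithmetic right-hand side (identical algebra to
  # replicator_rhs(), without per-call tibble construction)
  a <- matrix$pi_CC; b <- matrix$pi_CN; cc <- matrix$pi_NC
  d <- matrix$pi_NN
  rhs <- function(x) {
    x <- clip01(x)
    x * (1 - x) * (x * a + (1 - x) * b - x * cc - (1 - x) * d)
  }

  if (abs(rhs(snap(x0))) <= conv_tol) {
    traj <- tibble::tibble(time = 0, x_C = snap(x0))
    return(new_trajectory(traj, x_final = snap(x0), converged = TRUE,
                          matrix = matrix, x0 = x0))
  }

  times <- unique(c(0, seq(0, horizon, length.out = max(2L, n_out))))
  sol <- deSolve::lsodar(
    y = c(x_C = x0), times = times,
    func = function(t, y, p) list(rhs(y)),
    rootfunc = function(t, y, p) abs(rhs(y)) - conv_tol,
    rtol = rtol, atol = atol)
  converged <- !is.null(attr(sol, "troot")) && length(attr(sol, "troot")) > 0
  traj <- tibble::tibble(time = sol[, "time"], x_C = snap(sol[, "x_C"]))
  new_trajectory(traj, x_final = traj$x_C[nrow(traj)],
                 converged = converged, matrix = matrix, x0 = x0)
}

new_trajectory <- function(traj, x_final, converged, matrix, x0,
                           subclass = character()) {
  structure(traj,
            x_final = x_final, converged = converged, matrix = matrix,
            x0 = x0,
            class = c(subclass, "replicator_trajectory", class(traj)))
}

#' Simulate an invasion attempt by the cooperative strategy
#'
#' Starts the replicator dynamics from a small cooperator frequency
#' (default 10% invaders in a 90% non-cooperative resident population) in
#' the game defined by the given parameters, and reports whether
#' cooperation fixates, stabilizes at an interior frequency, or is
#' repelled. The default stock state (`B' = 0.3`, `r = 1`) is the bundled
#' case-study invasion setting.
#'
#' @param social A [social_params()] object.
#' @param stock A [stock_state()] object.
#' @param econ A [bioeconomic_params()] object.
#' @param x0 Initial (invader) cooperator frequency.
#' @param ... Passed to [replicator_integrate()].
#' @return A `replicator_trajectory` with an extra attribute `invasion`
#'   in `c("fixates", "coexists", "repelled", "absent")`; see
#'   [glance.replicator_trajectory()].
#' @examples
#' run_invasion(social_params(1, 0.3)) |> glance()     # cooperation fixates
#' run_invasion(social_params(0.8, 0.7)) |> glance()   # stabilizes low
#' @export
run_invasion <- function(social = social_params(),
                         stock = stock_state(B_prime = 0.3, r = 1.0),
                         econ = bioeconomic_params(),
                         x0 = 0.10, ...) {
  game <- fishery_game(stock, social, econ)
  traj <- replicator_integrate(game, x0 = x0, ...)
  xf <- attr(traj, "x_final")
  # convergence triggers on |dx/dt|, which can stop a fixating
  # trajectory a hair short of the boundary
  invasion <- if (x0 == 0) {
    "absent"
  } else if (xf >= 1 - 1e-6) {
    "fixates"
  } else if (xf <= 1e-6) {
    "repelled"
  } else {
    "coexists"
  }
  attr(traj, "invasion") <- invasion
  class(traj) <- c("invasion_trajectory", class(traj))
  traj
}

#' @export
print.replicator_trajectory <- function(x, ...) {
  cat(sprintf(
    "<replicator_trajectory> x0 = %g -> x_final = %.6g (%s, %d points)\n",
    attr(x, "x0"), attr(x, "x_final"),
    if (attr(x, "converged")) "converged" else "horizon reached", nrow(x)))
  NextMethod()
}

#' Tidy and summarise replicator trajectories
#'
#' `tidy()` returns the `(time, x_C)` table (with the cheater frequency
#' added for convenience); `glance()` a one-row summary with the terminal
#' frequency and convergence flag.
#'
#' @param x A `replicator_trajectory`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.replicator_trajectory <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$x_N <- 1 - out$x_C
  out
}

#' @rdname tidy.replicator_trajectory
#' @export
glance.replicator_trajectory <- function(x, ...) {
  out <- tibble::tibble(
    x0 = attr(x, "x0"),
    x_final = attr(x, "x_final"),
    converged = attr(x, "converged"),
    time_final = x$time[nrow(x)])
  inv <- attr(x, "invasion")
  if (!is.null(inv)) out$invasion <- inv
  out
}

#' Export a trajectory to CSV with a JSON metadata sidecar
#'
#' Writes the `(time, x_C)` table to `path` and, alongside it, a
#' `<path>.json` manifest recording the generating parameters and terminal
#' state. Numbers round-trip exactly (shortest-representation formatting).
#'
#' @param traj A `replicator_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "replicator_trajectory"))
  readr::write_csv(tibble::as_tibble(traj)[, c("time", "x_C")], path)
  m <- attr(traj, "matrix")
  meta <- list(
    package = "fisherygame",
    version = as.character(utils::packageVersion("fisherygame")),
    x0 = attr(traj, "x0"), x_final = attr(traj, "x_final"),
    converged = attr(traj, "converged"),
    payoffs = list(pi_CC = m$pi_CC, pi_CN = m$pi_CN,
                   pi_NC = m$pi_NC, pi_NN = m$pi_NN),
    invasion = attr(traj, "invasion"))
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
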