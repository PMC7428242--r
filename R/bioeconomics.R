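# Normalized Gordon-style season economics: an exponential harvest law,
# the cheater's profit-maximizing total effort, and the unpenalized season
# payoffs for each encounter type. Everything here is expressed per unit of
# carrying capacity, so stock enters as B' = B/K and cost as c' = c/K.

#' Season harvest as a fraction of carrying capacity
#'
#' Exponential-mortality harvest law for one fishing season of unit length
#' with negligible natural mortality: `H = B' (1 - exp(-q f))`. Fishing
#' mortality is proportional to effort through the catchability `q`.
#'
#' @param B_prime Relative stock size (>= 0). Vectorized.
#' @param q Catchability, positive.
#' @param f Fishing effort in fishing units (>= 0). Vectorized.
#'
#' @return Harvested biomass per unit carrying capacity; always strictly
#'   less than `B_prime` for finite effort.
#' @examples
#' harvest(0.3, 0.023, 18)
#' @export
harvest <- function(B_prime, q, f) {
  if (any(!is.finite(B_prime)) || any(B_prime < 0)) {
    rlang::abort("`B_prime` must be finite and non-negative.",
                 class = "fisherygame_domain_error")
  }
  check_number(q, "q", lower = 0, strict_lower = TRUE)
  if (any(!is.finite(f)) || any(f < 0)) {
    rlang::abort("`f` must be finite and non-negative.",
                 class = "fisherygame_domain_error")
  }
  B_prime * (1 - exp(-q * f))
}

#' Is fishing economically viable?
#'
#' Fishing is viable when the first unit of effort earns more than it
#' costs, i.e. `c' < B' P q`. Below this threshold every rational agent
#' stays ashore and the game outcome is "no fishing".
#'
#' @param params A [bioeconomic_params()] object.
#' @param B_prime Relative stock size(s).
#' @return Logical vector.
#' @export
viable_fishery <- function(params, B_prime) {
  stopifnot(inherits(params, "bioeconomic_params"))
  params$c_prime < B_prime * params$P * params$q
}

#' Profit-maximizing total effort of an unrestricted agent
#'
#' The effort `f_T = log(B' P q / c') / q` that maximizes single-agent
#' season profit `B'(1 - exp(-q f)) P - c' f`; it solves the first-order
#' condition `B' P q exp(-q f) = c'`. This is the total effort a cheater
#' drives the fishery to. For non-viable stocks (`c' >= B' P q`) there is
#' no positive profitable effort and `NA` is returned with a classed
#' warning.
#'
#' @inheritParams viable_fishery
#' @return Numeric vector of efforts (fishing units); `NA` where fishing
#'   is not viable.
#' @examples
#' monopoly_effort(bioeconomic_params(), 0.3)
#' @export
monopoly_effort <- function(params, B_prime) {
  stopifnot(inherits(params, "bioeconomic_params"))
  if (any(!is.finite(B_prime)) || any(B_prime <= 0)) {
    rlang::abort("`B_prime` must be finite and positive.",
                 class = "fisherygame_domain_error")
  }
  ok <- viable_fishery(params, B_prime)
  out <- rep(NA_real_, length(B_prime))
  out[ok] <- log(B_prime[ok] * params$P * params$q / params$c_prime) /
    params$q
  if (any(!ok)) {
    rlang::warn(
      "Fishing not viable (c' >= B' P q) for some stock sizes; returning NA.",
      class = "fisherygame_not_viable")
  }
  out
}

#' Unpenalized season payoffs for each encounter type
#'
#' Computes the four per-encounter season profits (per unit carrying
#' capacity) before the behaviour penalty is applied. With
#' `rho = c'/(B' P q)` (cost-revenue ratio at the margin), `L = log(rho)`
#' (negative when viable) and total unrestricted effort `f_T = -L/q`:
#'
#' * `Pi_CC`: two cooperators, each fishing the regulated effort `f*`:
#'   `B'(1 - exp(-q f*)) P - c' f*`.
#' * `Pi_CN`: a cooperator meeting a cheater. The cheater drives total
#'   effort to `f_T`; the cooperator keeps the share `f*/f_T` of the total
#'   harvest revenue `B'(1 - rho) P` and pays its own cost:
#'   `(c' - B' P q) f*/L - c' f*`.
#' * `Pi_NC`: the cheater in that encounter: complementary revenue share
#'   `(L + q f*)/L` times total revenue, minus the cheater's cost
#'   `c' (f_T - f*)`.
#' * `Pi_NN`: two cheaters race for the stock and dissipate the rent
#'   entirely: exactly 0.
#'
#' The two mixed-encounter shares sum to one, so
#' `Pi_CN + Pi_NC + c' f_T = B'(1 - rho) P` holds to machine precision
#' (revenue conservation).
#'
#' When the stock is so low that `c' >= B' P q`, fishing is not viable:
#' payoffs are `NA` and `viable` is `FALSE`. When `f* >= f_T` the cheater's
#' residual effort would be negative; it is clipped to zero, the encounter
#' is evaluated at total effort `f*` (the cooperator's own effort), giving
#' `Pi_CN = Pi_CC` and `Pi_NC = 0`, and `degenerate` is `TRUE`.
#'
#' @inheritParams viable_fishery
#' @return A tibble with one row per element of `B_prime` and columns
#'   `B_prime`, `viable`, `degenerate`, `f_T`, `Pi_CC`, `Pi_CN`, `Pi_NC`,
#'   `Pi_NN`.
#' @examples
#' base_payoffs(bioeconomic_params(), 0.3)
#' @export
base_payoffs <- function(params, B_prime) {
  stopifnot(inherits(params, "bioeconomic_params"))
  if (any(!is.finite(B_prime)) || any(B_prime <= 0) || any(B_prime > 1)) {
    rlang::abort("`B_prime` must lie in (0, 1].",
                 class = "fisherygame_domain_error")
  }
  P <- params$P; q <- params$q; cp <- params$c_prime; fs <- params$f_star
  viable <- viable_fishery(params, B_prime)

  rho <- cp / (B_prime * P * q)
  L <- ifelse(viable, log(rho), NA_real_)
  f_T <- -L / q
  degenerate <- viable & fs >= f_T

  Pi_CC <- ifelse(viable, B_prime * (1 - exp(-q * fs)) * P - cp * fs,
                  NA_real_)
  Pi_CN <- ifelse(viable, (cp - B_prime * P * q) * fs / L - cp * fs,
                  NA_real_)
  Pi_NC <- ifelse(viable,
                  ((L + q * fs) / L) * B_prime * (1 - rho) * P -
                    cp * (f_T - fs),
                  NA_real_)
  # cheater effort clipped at 0: encounter evaluated at total effort f*
  Pi_CN <- ifelse(degenerate, Pi_CC, Pi_CN)
  Pi_NC <- ifelse(degenerate, 0, Pi_NC)

  tibble::tibble(
    B_prime = B_prime, viable = viable, degenerate = degenerate,
    f_T = f_T, Pi_CC = Pi_CC, Pi_CN = Pi_CN, Pi_NC = Pi_NC,
    Pi_NN = ifelse(viable, 0, NA_real_))
}

#' Normalize raw cost and stock size by carrying capacity
#'
#' Converts a raw per-unit effort cost `c` (currency/effort) and a raw
#' stock biomass `B` (kg) into the dimension-reduced quantities used
#' throughout the model: `c' = c/K` and `B' = B/K`. The payoff algebra is
#' homogeneous of degree one in `(c, B, K)`, so results expressed per unit
#' carrying capacity are independent of `K`.
#'
#' @param c Raw cost of one effort unit (>= 0). Vectorized.
#' @param B Raw stock biomass, `0 <= B <= K`. Vectorized.
#' @param K Carrying capacity, positive.
#' @return A tibble with columns `c_prime` and `B_prime`.
#' @examples
#' normalize_stock(c = 20, B = 300, K = 1000)
#' @export
normalize_stock <- function(c, B, K) {
  check_number(K, "K", lower = 0, strict_lower = TRUE)
  if (any(!is.finite(c)) || any(c < 0)) {
    rlang::abort("`c` must be finite and non-negative.",
                 class = "fisherygame_domain_error")
  }
  if (any(!is.finite(B)) || any(B < 0) || any(B > K)) {
    rlang::abort("`B` must lie in [0, K].",
                 class = "fisherygame_domain_error")
  }
  tibble::tibble(c_prime = c / K, B_prime = B / K)
}
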