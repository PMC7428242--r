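---
title: "Methods: a penalized evolutionary game for effort-restricted fisheries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a penalized evolutionary game for effort-restricted fisheries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fisherygame)
library(dplyr)
```

## The problem

In an effort-restricted small-scale fishery, each fisher chooses between
two strategies: *cooperate* — fish only the regulated effort $f^*$ — or
*cheat* — fish as much as individual profit maximization dictates. The
package models this conflict as an evolutionary game between two fisher
populations with fixed strategies, asks which strategy spreads across
fishing seasons (generations), and maps how the answer depends on the
stock's growth rate, its current size, and two social levers: how certain
fishers are that violations are punished (control perception) and how
well they bear stock uncertainty (risk tolerance). The bundled default
parameters describe a shrimp fyke-net fishery in Laguna, southern Brazil,
where the proposed fishing agreement allows $f^* = 18$ nets per fisher.

## The bioeconomic season model

The stock, a single species in logistic growth, enters the season at
biomass $B$ out of a carrying capacity $K$; everything is expressed per
unit of carrying capacity through $B' = B/K$ and a normalized effort cost
$c' = c/K$, making results independent of the absolute stock scale (the
payoff algebra is homogeneous of degree one in $(c, B, K)$, a property
the test suite checks on random draws).

A season of unit length with negligible natural mortality removes

$$H = B'\,\bigl(1 - e^{-q f}\bigr),$$

where $q$ is catchability and $f$ total effort. Season profit per unit
carrying capacity at price $P$ is $B'(1 - e^{-qf})P - c'f$. An
unrestricted agent pushes effort to the first-order condition
$B'Pq\,e^{-qf} = c'$, i.e. the profit-maximizing total effort

$$f_T = \frac{1}{q}\,\ln\!\frac{B'Pq}{c'},$$

defined whenever fishing is *viable*, $c' < B'Pq$: below that threshold
the first unit of effort already costs more than it earns and the game is
classified as a no-fishing situation before any payoff is evaluated (the
payoff expressions contain logarithms that are undefined there).

### Encounter payoffs

With $\rho = c'/(B'Pq)$ and $L = \ln\rho$ (negative when viable), the
four unpenalized encounter payoffs are:

* **Both cooperate** ($\Pi_{CC}$): each fishes $f^*$; the focal fisher
  earns $B'(1 - e^{-qf^*})P - c'f^*$. The printed expression evaluates
  the focal fisher's season at its own effort $f^*$; whether the partner's
  simultaneous effort should deplete the shared harvest (total effort
  $2f^*$) is left open by the model's sources, and the package follows
  the stated formula.
* **Cooperator meets cheater** ($\Pi_{CN}$, $\Pi_{NC}$): the cheater
  drives total effort to $f_T$, contributing $f_T - f^*$ on top of the
  cooperator's $f^*$. Total harvest revenue $B'(1-\rho)P$ is split in
  proportion to effort, and each pays its own cost:
  $\Pi_{CN} = (f^*/f_T)\,B'(1-\rho)P - c'f^*$ (equivalently
  $(c' - B'Pq)f^*/L - c'f^*$) and
  $\Pi_{NC} = \bigl((L + qf^*)/L\bigr)\,B'(1-\rho)P - c'(f_T - f^*)$.
  The proportional split is the unique reading under which the two
  shares sum to one, so revenue conservation
  $\Pi_{CN} + \Pi_{NC} + c'f_T = B'(1-\rho)P$ holds to machine
  precision; the suite enforces it at $10^{-12}$ over $10^4$ random
  draws.
* **Both cheat** ($\Pi_{NN} = 0$): a fishing race dissipates the rent
  entirely.

If the regulation already allows more effort than the profit maximum
($f^* \ge f_T$), the cheater's residual effort would be negative; it is
clipped at zero and the encounter is evaluated at total effort $f^*$,
giving $\Pi_{CN} = \Pi_{CC}$ and $\Pi_{NC} = 0$. The model's sources are
silent on this corner; clipping is the only economically meaningful
choice, and such games are flagged `degenerate = TRUE`. None of the
bundled scenarios reach it ($f_T \ge 242$ effort units across the default
grid, against $f^* = 18$).

## The behaviour penalty

Social context enters as a single multiplier

$$\delta = \frac{\alpha}{1 + b\,r}, \qquad 0 \le \delta \le \alpha \le 1,$$

combining control perception $\alpha$, risk tolerance $b$ (0 = high
tolerance) and stock growth $r$: cooperator payoffs are scaled by
$\delta$, cheater payoffs by $1 - \delta$. Fast-recovering stocks and
low risk tolerance both erode the penalty on cheating; strong perceived
enforcement strengthens it. The two populations may differ, so the
package applies $\delta_C = \delta(\alpha_1, b_1, r)$ to cooperators and
$1 - \delta_N$ with $\delta_N = \delta(\alpha_2, b_2, r)$ to cheaters —
the only reading that uses all four social parameters and collapses to
the single-$\delta$ form in the symmetric scenarios, which are the only
ones the bundled presets exercise. Setting `delta_override = 0.5`
removes the social terms altogether (both roles scaled equally); the
test suite uses this switch to confirm that the unpenalized game is
non-cooperative everywhere.

Risk-tolerance conventions deserve a note: the model's verbal convention
("tolerance is high when $b$ is near zero") and the numeric scenario
values (high tolerance $b = 0.3$, low tolerance $b = 0.7$) are taken
from the case study's scenario definitions; the numbers are treated as
authoritative.

## Classification and dynamics

With penalized payoffs $\pi'$, the standard 2x2 sign conditions apply:
$\pi'_{CC} > \pi'_{NC}$ means cooperation resists invasion,
$\pi'_{CN} > \pi'_{NN}$ means it can invade. The four sign patterns give
cooperative dominance, non-cooperative dominance, bistability, and
coexistence; coexistence is sub-labelled by the interior equilibrium

$$\bar x = \frac{\pi'_{NN} - \pi'_{CN}}
               {\pi'_{CC} - \pi'_{CN} - \pi'_{NC} + \pi'_{NN}},$$

cooperative when $\bar x > 0.5$, non-cooperative otherwise. Because
$\Pi_{CN} > 0$ strictly whenever fishing is viable (average revenue per
unit effort exceeds marginal cost below the profit maximum), the
fishery's own payoff structure can only produce cooperative dominance or
coexistence; bistability and cheater dominance are reachable only with
hand-built matrices, and the classifier and integrator are tested on
those too.

Numerical choices:

* **Tie handling.** Payoff comparisons use strict inequalities with an
  absolute tolerance of $10^{-12}$; ties within tolerance raise a classed
  warning and the label `degenerate` rather than being silently binned
  (ties occur only on measure-zero parameter boundaries).
* **$\bar x = 0.5$ exactly** is labelled non-cooperative (the cooperative
  label requires a strictly higher frequency) and flagged.
* **Viability before payoffs.** `no_fishing` is decided from
  $c' \ge B'Pq$ before any comparison.

Frequencies evolve by the replicator equation
$\dot x_C = x_C(1 - x_C)\,[\mathrm{fit}_C(x) - \mathrm{fit}_N(x)]$ with
$\mathrm{fit}_C = x_C\pi'_{CC} + (1-x_C)\pi'_{CN}$ and
$\mathrm{fit}_N = x_C\pi'_{NC} + (1-x_C)\pi'_{NN}$. The dynamics are
one-dimensional and smooth, so the package integrates them with
`deSolve::lsodar` (adaptive step, `rtol` $10^{-10}$, `atol` $10^{-12}$)
and stops at the root of $|\dot x_C| - \text{tol}$ with a convergence
tolerance of $10^{-10}$ by default ($10^{-12}$ in the strictest tests),
up to a horizon of $10^4$ generations. An adaptive solver was preferred
over a fixed-step scheme because absorption into a boundary is an
exponential approach whose natural step grows without bound; accuracy is
instead guaranteed by the solver tolerances, and the suite checks that
tightening `rtol` tenfold moves the terminal state by less than
$10^{-8}$. Frequencies are clipped to $[0,1]$ against round-off and
snapped to a boundary within $10^{-12}$ of it. Generations map
one-to-one to integration time units.

The central structural test cross-checks the two routes to the same
prediction: on 200 seeded random scenarios (plus synthetic bistable and
dominant matrices), the label from the sign conditions must agree with
the long-run replicator limit from starts at 0.1, 0.5 and 0.9 to within
$10^{-6}$, and the closed-form $\bar x$ must agree with a brute-force
root of the fitness difference.

## Scenario sweeps and thresholds

`sweep_scenario()` classifies every cell of an $(r, B')$ grid; the
default grids run $r$ from 0 to 2 and $B'$ from 0.01 to 1, both in steps
of 0.01 (201 x 100 cells). The resolution is a package choice — fine
enough to localize boundaries to one cell, coarse enough that a full
sweep takes well under a second — and boundaries are then refined by
bisection to $10^{-6}$ in `boundary_r()`: the dominance edge solves
$\delta_C\Pi_{CC} = (1-\delta_N)\Pi_{NC}$, the coexistence sub-label
edge solves $\bar x(r) = 0.5$ bracketed inside the coexistence window
(at the dominance edge $\bar x \to 1$).

The case-study threshold statements are band aggregates over the whole
stock-size axis, and `band_thresholds()` reports them both ways the map
can be read: `r_dominance`, the largest growth rate at which *every*
viable stock size still yields cooperative dominance (the minimum of the
per-$B'$ edges), and `r_all_noncooperative`, the smallest growth rate
beyond which *every* viable stock size yields non-cooperative
coexistence (the maximum of the per-$B'$ crossings). The strict
"every cell" reading is sensitive to the $B' \to 0$ edge of the grid,
where the cooperative-coexistence band stretches to noticeably higher
growth rates than in the bulk ($B' \gtrsim 0.1$) of the map; per-$B'$
boundaries from `boundary_r()` are the right tool when a specific stock
level is of interest.

```{r thresholds}
cfg <- scenario_preset("high_tolerance_high_control")
band_thresholds(cfg)
boundary_r(cfg, "cooperative_coexistence", "noncooperative_coexistence",
           B_prime = c(0.1, 0.3, 1.0))
```

## What the random-scenario generator does and does not emulate

`random_scenarios()` draws the social parameters uniformly on $[0,1]$,
growth rate uniformly on $[0,2]$ and relative stock size uniformly on
$(0,1]$, with the case-study economics held fixed. That is exactly the
parameter space the sensitivity analysis explores, so property tests run
on these draws probe the full modelled domain. It does *not* emulate
real-fishery data in any richer sense: no observation noise, no temporal
variation in $\alpha$, $b$ or prices, no within-season stock depletion,
no multi-species interactions, and no finite-population stochasticity.
Passing tests therefore certify the internal consistency of the model
and its implementation over its stated domain — not the model's fit to
any particular fishery.

## Known limitations

* The mixed-encounter split and the $f^* \ge f_T$ corner are
  reconstructions constrained by revenue conservation, as described
  above; alternative readings of the cooperator-cooperator encounter
  (total effort $2f^*$) would lower $\Pi_{CC}$ and shift every boundary.
* Social parameters are exogenous constants per scenario; there is no
  learning or state dependence.
* The replicator dynamics are deterministic and infinite-population;
  absorption times, not just limits, would differ under finite-population
  (Moran) dynamics, which are out of scope.
* Threshold statements aggregated over the full stock-size band are
  dominated by the smallest stock sizes on the grid (see above); both
  aggregate and per-$B'$ readings are exposed so users can choose
  deliberately.
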