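---
title: "Methods: coupled energy-oxygen budgets and optimal activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled energy-oxygen budgets and optimal activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finscope)
```

## The model

`finscope` simulates the thermal performance of a fish (or other
water-breathing ectotherm) from two coupled instantaneous budgets evaluated
at a body weight $w$ (g), temperature $T$ (°C) and behavioural activity
fraction $\tau \in [0,1]$.

**Energy budget.** Net energy gain (g y⁻¹) is assimilated intake minus
standard and activity metabolism:

$$P(w,T,\tau) = (1-\beta-\phi_e)\, f\, h\, c(T)\, w^q
  \;-\; c(T)\, k\, w^n \;-\; \tau\, c(T)\, k_a\, w ,$$

with the feeding level a Holling type-II response to encountered food
$\tau\gamma\Theta w^p$ against digestive capacity $h\,c(T)\,w^q$:

$$f(w,T,\tau) = \frac{\tau\gamma\Theta w^p}{\tau\gamma\Theta w^p + h c(T) w^q}.$$

Only enzymatically driven rates (maximum consumption, standard and active
metabolism) carry the Arrhenius factor
$c(T)=\exp\!\big(E_a (T-T_0)/(b\,T\,T_0)\big)$ (Kelvin inside, $b$ the
Boltzmann constant, $c(T_0{=}15°C)=1$); ecological rates respond to
temperature only through the behavioural optimization below.

**Oxygen budget.** The aerobic scope is supply minus demand,

$$P_{O_2} = S_{O_2}(T)\, w^n - \omega\, c(T)\big(\beta f h w^q + k w^n +
\tau k_a w\big),$$

where supply combines a flexible dome in temperature with a saturating
dependence on ambient dissolved oxygen:

$$S_{O_2}(T) = \lambda(T)\Big(1 - e^{(C(T)-C_{crit})\log 0.5/(C_{50}-C_{crit})}\Big),
\qquad
\lambda(T) = \zeta\, x^{\eta} e^{\eta(1-x)},\;
x = \tfrac{T_{max}-T}{T_{max}-T_{opt}},$$

and ambient oxygen declines with warming as $l\,e^{-0.01851 (T-5)}$
(saltwater at 35 PSU; $l$ is the concentration at 5 °C). $\lambda$ vanishes
at the lethal temperature $T_{max}$ and peaks at $T_{opt}$; $\eta \approx 3$
gives a pronounced dome (maximum oxygen supply, MOS, declining well below
$T_{max}$), $\eta \approx 0.1$ a MOS that rises almost to $T_{max}$.

**Behaviour.** The fish chooses its activity by Gilliam's rule — maximize
net energy gain over mortality,
$\tau^* = \arg\max_\tau P(w,T,\tau)/M(w,\tau)$ with
$M(w,\tau) = (\rho + \mu\tau) w^{q-1}$ — subject to a non-negative aerobic
scope. Because oxygen demand is strictly increasing in $\tau$, the
feasibility cap $\tau_{max}$ is the unique root of $P_{O_2}(\tau)=0$ (or 1
when scope remains at full activity). `optimal_activity()` reports the
unconstrained optimum, the cap, the realized $\tau^* = \min$ of the two, and
an oxygen-limitation flag.

**Life history.** Surplus energy is split between growth and reproduction
by a maturation reaction norm (MRN), a logistic share
$\psi(w) = 1/(1+e^{-c_{mrn}(w-w^*)})$ (a sloped variant shifts the midpoint
linearly with age). Growth integrates $dw/dt = (1-\psi) P(w,T,\tau^*(w))$,
survival accumulates as $S(t)=\exp(-\int_0^t M\,ds)$, and fitness is the
lifetime reproductive output
$R_0 = \int \psi\, P\, S\, dt$ (negative instantaneous contributions
clipped at zero: starving fish shrink, they do not unproduce offspring).
The intercept $w^*$ is calibrated by maximizing $R_0$ at the reference
temperature and baseline food, then held fixed across temperatures —
mimicking a norm evolved under historical conditions.

## Symbols and naming

Several conventional symbols collide across sub-models; the package renames
them once:

| quantity | conventional symbol | here |
|---|---|---|
| egestion + excretion fraction | $\phi$ | `phi_e` |
| allocation to reproduction | $\phi(w,w^*)$ | `psi` / [allocation()] |
| MRN steepness | $c$ | `c_mrn` |
| Arrhenius factor | $c(T)$ | `arrhenius_factor()` |

## Parameters that matter

The four `fish_preset()` bundles cross two trait strategies with two MOS
regimes. The slow strategy (k = 1, k_a = 4, n = 0.88, h = 30, ρ = 0.1,
μ = 6, ζ = 0.5) minimizes mortality and metabolism at the expense of
production; the fast strategy (k = 1.5, k_a = 2, n = 0.75, h = 60, ρ = 1,
μ = 1, ζ = 1) maximizes production at higher exposure. Shared values:
β = 0.15, φ_e = 0.25, γΘ = 60 (food variations 2/3 and 4/3 of baseline),
p = q = 0.8, E_a = 0.52 eV, T₀ = 15 °C, T_max = 26 °C, c_mrn = 0.5 g⁻¹,
flat MRN, C_crit = 2 and C_50 = 4 mg L⁻¹. Dome presets use η = 3,
T_opt = 20 °C; nodome presets η = 0.1, T_opt = 25 °C.

Two oxygen constants are free choices of the package rather than preset
trait values:

* `l = 10` mg L⁻¹, ambient dissolved O₂ at 5 °C — approximate seawater
  saturation at 35 PSU.
* `omega = 0.01` g O₂ per g of mass metabolized. Only the ratio ζ/ω is
  identifiable (the sign of the scope depends on λ/ω alone), so ω is
  calibrated, with ζ fixed at its preset values, to realize the
  oxygen-limitation regime the scenarios are built around: for a 10 g fish
  under a dome-shaped MOS,
  activity is oxygen-limited at the extremes of the 5–26 °C range (below
  ≈7 °C and above ≈24 °C) but not in the interior window, and without
  doming the scope exceeds the demand of full activity (τ = 1) at the
  reference temperature and is never limiting below T_max. On a ladder of
  candidates (0.005–0.02) ω = 0.01 is the unique value satisfying all of
  these conditions; it implies a generous factorial aerobic scope, which is
  a direct consequence of holding ζ at its preset values.

## The MOS curve: normalization and exponential coefficient

Two formulation details of $\lambda(T)$ are deliberate:

* the exponential coefficient is $\eta$, which makes $T_{opt}$ the exact
  stationary point of the dome — the defining property of "temperature of
  maximum oxygen supply". (`mos_level(exp_coef =)` exposes the coefficient
  for sensitivity checks, e.g. re-using a metabolic exponent there, at the
  cost of shifting the true peak.)
* $\lambda$ is normalized by $e^{\eta}$ so that $\lambda(T_{opt}) = \zeta$
  exactly, matching ζ's role as the supply level; `normalize = FALSE`
  drops the factor. Relative-to-maximum curves are identical in both modes;
  absolute feasibility is governed by ζ/ω either way.

Ambient oxygen below C_crit yields zero (not negative) supply.

## Oxygen demand at realized activity

The demand side charges the activity cost at the realized level,
$\tau k_a w$, so that the feasibility constraint responds to behaviour; the
maximal-demand form (full $k_a w$ regardless of $\tau$) is recovered at
$\tau = 1$ and available via `oxygen_budget(demand = "maximal")`. SDA burns
oxygen on realized intake ($\beta f h w^q$, no extra Arrhenius factor
beyond the global $\omega c(T)$).

## Numerical choices

* **Activity optimizer**: dense grid on [0, 1] (2001 points by default)
  refined by golden-section search to 1e-8; ties resolve to the smallest τ
  (risk-averse). The oxygen cap is bracketed root-finding to 1e-10. When no
  feasible activity yields $P > 0$, the realized activity maximizes $P$
  itself — maximizing a negative ratio would reward dying fast — which is
  continuous with the profitable regime.
* **Growth integration**: `deSolve::lsoda` at relative tolerance 1e-8 on
  states (w, cumulative hazard, accumulated R₀). Re-optimizing τ inside the
  right-hand side dominates the cost, so τ*(w) and the associated rates are
  precomputed on a 2001-point log-spaced weight grid per (T, food) and
  interpolated; within the cache the per-weight optimum uses a dense
  vectorized τ grid with parabolic refinement of the argmax (accuracy
  ~grid², equivalent to the golden-section path at a fraction of the cost).
* **Floors and degeneracy**: starving fish may shrink but not below a 0.01 g
  floor; if resting metabolism already exceeds oxygen supply at the initial
  weight (e.g. at T_max, where λ = 0) the trajectory is flagged degenerate
  with S = 0 and R₀ = 0. Temperatures above T_max are an error.
* **Calibration**: w* is scanned on a log grid from 1 g up to the
  energy-limited asymptote (the largest weight at which any activity yields
  P > 0), then refined by golden-section in log space to 1e-3 relative.
  Integration horizon 100 y; R₀ changes by less than 1e-3 between 50 y and
  100 y horizons for all presets, as survival decay dominates.

## The calibrated reaction norms: a caveat

With the preset parameter values the R₀ landscape is sharply asymmetric
between strategies. For the slow strategy R₀ at 15 °C peaks at
w* ≈ 74 g, giving an asymptotic length of ≈ 21 cm. For the fast strategy
the preset trait values make intake (∝ 60 w^0.8) outgrow metabolic costs
(1.5 w^0.75 + 2τw) until w ~ 10⁵ g while mortality declines as w^-0.2, so
R₀ increases with w* almost to the energy ceiling and the calibrated
intercept lands near 4×10⁴ g. The two presets therefore do **not** describe
species of a common adult size once their norms are calibrated; analyses
that require a matched size (e.g. contrasting strategies at ~270 g) should
set `w_star` explicitly in `grow()`/`lifetime_fitness()` rather than rely
on `calibrate_wstar()`.

## What the presets emulate — and what passing tests show

The presets are synthetic study conditions, not fitted organisms: a
deterministic physiology on idealized grids (temperatures 5–26 °C, food at
2/3, 1, 4/3 of baseline, diagnostic sizes 1.25, 10 and 80 g). Passing the
test suite shows that the budgets, the constrained optimization and the
life-history integrals behave as the theory prescribes — monotonicities,
anchor points, closed-form limits, and agreement with independently coded
oracles — under these idealized conditions. It does not validate the model
against any measured fish: there is no individual variability, no
stochastic environment, no seasonality, no anaerobic metabolism or oxygen
debt, and no evolutionary response of traits or of the reaction-norm slope.

The unit suite runs the model at reduced problem sizes chosen for
precision-per-second (coarse temperature grids of 3–14 points, horizons of
20–150 y, brute-force oracles at 10⁴–10⁵ grid points); these sizes are
stated in the tests themselves and are the package's own choice of
diagnostic resolution.

## Known limitations

* Behaviour is myopic (Gilliam's rule): no state-dependent dynamic
  programming over future conditions.
* The sloped MRN option is a simple linear age-offset of the logistic
  midpoint; it is provided as a convenience, not a calibrated alternative.
* R₀ is in units of allocated energy (g, survival-weighted), not offspring
  counts; only comparisons across temperatures and scenarios are
  meaningful.
* Oxygen enters only through the aggregated supply curve; there is no
  mechanistic gill or circulatory sub-model, and no hypoxia dynamics beyond
  the fixed ambient-O₂ decline with temperature.
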