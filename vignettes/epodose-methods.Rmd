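---
title: "Model, discretization and controller design in epodose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, discretization and controller design in epodose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The control problem

Hemodialysis patients produce too little endogenous erythropoietin (EPO) and
are chronically anemic; clinicians dose recombinant EPO to hold hemoglobin
(Hgb) inside a 10–12 g/dl window. The difficulty is a ~2-week dead time: EPO
acts on marrow progenitors that only reach circulation after their full
maturation, so naive dose protocols overshoot and cycle. `epodose` treats
dosing as a receding-horizon optimal control problem on a mechanistic model of
erythropoiesis, assuming a continuously programmable pump with
piecewise-constant rates.

## The state model

Five age-structured population classes describe the erythroid lineage —
BFU-E, CFU-E, erythroblasts, marrow reticulocytes, and circulating
erythrocytes. Class $i$ carries a density $y_i(t,x)$ over a maturity interval
$\Omega_i$ (days); the marrow intervals are fixed at $[0,3]$, $[3,8]$,
$[8,13]$, $[13,15.5]$, and the erythrocyte class spans $[0,\bar x_5]$ where
the RBC lifespan $\bar x_5$ is patient-specific (37.7–115.8 days in
hemodialysis patients). Each class obeys a transport equation

$$\partial_t y_i + v_i(E)\,\partial_x y_i = \kappa_i(x;E)\,y_i,$$

with unit maturation velocity everywhere except the marrow-reticulocyte
class, whose velocity $\nu(E)$ rises with EPO (early release under
stimulation), and with net growth rates

* $\kappa_1=\beta_1$, $\kappa_3=\beta_3$ (proliferation),
* $\kappa_2=\beta_2-\alpha_2(E)$ where the CFU-E apoptosis rate
  $\alpha_2(E)=\mu_1/(1+e^{\mu_2E-\mu_3})$ falls with EPO — the main control
  channel,
* $\kappa_4=-\alpha_4$,
* $\kappa_5=-\alpha_5(x;E)$ where
  $\alpha_5=\alpha_5^0+\chi_{\hat\Omega_5}(x)\,H(\tau_E-E)\,
  \min(\mu_8/E^{\mu_9},\mu_{10})$
  adds neocytolysis: selective destruction of young circulating cells
  (ages in `neo_window`, default $[0,14]$ d) when EPO falls below the
  threshold $\tau_E = 80$.

Boundary influx couples the classes: $g_1=S_0$ (committed stem-cell influx),
$g_{i}=y_{i-1}(t,\bar x_{i-1})$ for $i=2,3$, $g_4=y_3(t,\bar x_3)/\nu(E)$ and
$g_5=\nu(E)\,y_4(t,\bar x_4)$, so cell throughput is conserved across the
velocity change. The observables are the total RBC count
$P(t)=\int_{\Omega_5}y_5\,dx$ and
$\mathrm{Hgb}=P\cdot\mathrm{MCH}/(c_\mathsf{tbv}\cdot 10^{10})$ g/dl with
MCH = 29 pg.

### Pharmacokinetics and units

Administration at piecewise-constant rates $u_j$ (U/day) drives a
one-compartment elimination model
$\dot E^\mathrm{ex}=u(t)/V-\lambda E^\mathrm{ex}$ with
$\lambda=\log 2/T_{1/2}$, solved in closed form; total EPO is
$E=E^\mathrm{end}+E^\mathrm{ex}\ge E_\mathrm{min}>0$. The package carries $E$
in U/l, so the distribution volume is the blood volume in liters,
$V=c_\mathsf{tbv}/1000$. This is the only unit convention under which a
1000 U/day cap (steady state $\approx 87$ U/l above baseline) is commensurate
with the neocytolysis threshold $\tau_E=80$ and endogenous levels of 20–300 —
i.e. under which exogenous dosing can cross the threshold at all.

### Regularization

$\alpha_5$ is discontinuous in $E$ at $\tau_E$ and kinked at the min. For
gradient-based optimization both are smoothed with the C² polynomial
Heaviside $H^\varepsilon$ (exact 0/1 plateaus, transition band of width
$\varepsilon$) and the induced smooth min
$F^\varepsilon(s,\tau)=(s-\tau)H^\varepsilon(\tau-s)+\tau$. The two smoothed
quantities live on different scales: the threshold argument $\tau_E-E$ is an
EPO concentration (natural width `epsilon` = 1 U/l), while the min acts on
mortality rates of order 0.05–0.4/day. A single shared width would either
degenerate the min (at $\varepsilon=1$, $F^\varepsilon\approx\mu_{10}$
everywhere, distorting the steady-state dose response several-fold) or
un-smooth the threshold. The package therefore carries a second width
`epsilon_R` (default 0.02/day) for the rate-scale min. Both regularizations
recover the exact non-smooth rates outside their bands, which the tests
check, along with pointwise convergence as the widths shrink.

## Discretization

Each class is normalized to $\xi\in[0,1]$ via $h(\xi)=\underline x+w\xi$ and
expanded in shifted Legendre polynomials
$e_j(\xi)=L_j(2\xi-1)/\sqrt w$, $j=0,\dots,N-1$ ($N=15$ by default),
orthogonal under $\langle f,g\rangle_w = w\int_0^1fg\,d\xi$ with
$\|e_j\|_w^2=1/(2j+1)$. The inflow boundary condition is imposed weakly
through the discrete delta representer $\tilde\delta_N$ satisfying
$\langle\tilde\delta_N,\varphi\rangle_w=\varphi(0)$ on the span; the
Galerkin operator per class is

$$A_N(E)\varphi = -\tfrac{v(E)}{w}\varphi'
  + \mathcal P_N\!\big(\kappa(h(\cdot);E)\,\varphi\big)
  - \tilde\delta_N\,\varphi(0),$$

yielding one dense $N\times N$ system of ODEs per class, driven by the
influx vector $d=(e_j(0)/\|e_j\|_w^2)_j$. For the marrow classes the
reaction coefficient is constant in maturity and the projection term is a
scalar multiple of the identity; only the erythrocyte class needs a
projection matrix for the age-windowed neocytolysis indicator, assembled
once by Gauss–Legendre quadrature split at the window edge (all integrands
are then polynomial-times-smooth and the rule order makes them effectively
exact; no quadrature rule is prescribed by the underlying scheme, so this is
the package's choice). The total population reduces to
$P_N = \sqrt{w_5}\,\tilde y_{5,0}$ because only the constant basis function
has non-zero integral — an identity the tests verify against quadrature of
the reconstructed density.

Time stepping is implicit Euler with the classes solved consecutively
1→5 within each step, the EPO concentration evaluated at the step end (a
convention the package fixes; the scheme is first-order regardless, as the
Richardson test confirms). The equations are scaled by $10^8$ cells
internally; all public observables are unscaled. The plant integrates at
$\Delta t = 0.01$ d. Spectral accuracy in maturity is verified against the
analytic BFU-E equilibrium $S_0e^{\beta_1 x}$ (relative $L^2$ error below
$10^{-6}$ at $N=15$, with super-polynomial decay over $N\in\{4,8,12,15\}$).

## The cost functional and its weights

On a horizon of $M$ control intervals of length $\Delta_t$,

$$J(u)=\tfrac12\sum_j\gamma_j|u_j|^2
 +\tfrac{\sigma_\Omega}2\int\big(r\,(P_N-P^d)\big)^2dt
 +\tfrac{\sigma_f}2\big(r\,(P_N(t_f)-P^d)\big)^2,$$

with $r=2\,\mathrm{MCH}/(c_\mathsf{tbv}10^{10})$, so $r(P-P^d)$ is twice the
Hgb deviation in g/dl, and $\sigma_\Omega=10^4/(M\Delta_t)$, $\sigma_f=10^3$,
$\gamma_j=c_\gamma\Delta_t/(M\Delta_t)$. Measuring the deviation on the
$r$-scale (rather than raw cell counts) is what makes the three terms
commensurate: with it, $c_\gamma$ spanning 0.01–100 moves the controller
from dose-insensitive to dose-dominated, the regime the method is designed
to explore; on the raw scale the tracking term would exceed the control term
by ~14 orders of magnitude and $c_\gamma$ would be inert. The terminal
weight keeps its $\sigma_f/\sigma_\Omega = M\Delta_t/10$ ratio to the
tracking weight. $c_\gamma$ is the only individualized tuning constant; for
longer constant-rate periods it is multiplied by the days per period so
control effort is penalized alike across update frequencies. The desired
population is $P^d$ at 10.5 g/dl — deliberately in the lower half of the
10–12 g/dl window because Hgb cannot be actively pulled down after an
overshoot.

## Gradient: discretize-then-optimize

The gradient of $J$ is computed as the exact gradient of the fully
discretized cost (not a discretization of the continuous adjoint): one
forward sweep stores the per-step states, one backward sweep solves the
transposed per-class systems in reverse order 5→2 within each step, and the
chain rule through $\partial E/\partial u$ (available in closed form; the
exogenous kinetics are linear in the rates, so this sensitivity is
control-independent and the PK Hessian is zero) assembles the gradient. The
discrete adjoint of the BFU-E class never enters — that class is autonomous
— and is skipped. Discretize-then-optimize guarantees agreement with finite
differences of the implemented cost to solver precision; the acceptance test
demands $10^{-5}$ over random admissible controls and the implementation
delivers ~$10^{-8}$.

## The open-loop solver

Projected BFGS with Armijo line search under the box $[0,u_\mathrm{max}]$:
controls are rescaled by $u_\mathrm{max}$ for conditioning; variables within
a small distance of a bound with an outward gradient are frozen per
iteration (ε-active sets); the inverse-Hessian approximation is
Shanno-scaled at its first update and reset only when a direction fails the
descent test; backtracking uses quadratic interpolation with safeguards,
sufficient-decrease parameter $10^{-4}$, at most 40 backtracks. Termination
is on the projected-gradient norm relative to its starting value (the
dead-time part of the tracking residual keeps $|J|$ large even at the
optimum, so cost-relative tests are uninformative here). The problem is
non-convex — distinct local minima with nearly identical tracking quality
exist, differing mainly in how the early-horizon dose burst is distributed —
which is immaterial for the receding-horizon loop since only the first
interval is applied and the loop re-plans daily.

## The NMPC loop

At each decision time the open-loop problem is solved on a shifted horizon
from the measured plant state (perfect measurement is assumed, including
post-event states), the first rate is applied, and the plant advances.
Three engineering choices matter for practicality:

* **Warm starts.** The next solve starts from the previous optimum shifted
  by one interval (last value padded) *and* inherits its final
  inverse-Hessian approximation, index-shifted the same way. Re-learning
  curvature from scratch each day costs ~5× more iterations for identical
  closed-loop behavior.
* **Prediction grid.** The controller's internal forward model integrates at
  `pred_dt` = 0.05 d while the plant uses 0.01 d. The optimizer needs only
  control-grade accuracy from its predictions; the induced plant–model
  mismatch is far below the tracking tolerance.
* **Inner tolerance.** The closed loop solves to a projected-gradient
  reduction of $10^{-3}$ (cap 60 iterations) rather than the $10^{-6}$
  default of `solve_open_loop()` — dose differences below ~1 U/day have no
  visible effect on Hgb.

The horizon rule follows the marrow dead time: 4 weeks of prediction for
periods of 1 or 7 days, 6 weeks for 14 or 21, 8 weeks for 28, so the horizon
always spans the ~2-week maturation delay with at least two decision
intervals.

Scenario events model reality intruding on the loop: bleeds (the circulating
class is scaled down to a target Hgb at the start of the event day — marrow
classes are untouched, since hemorrhage removes blood, not marrow; the
controller learns of it only through the next measurement), missed doses
(actuator outputs zero), and dosing errors (an override rate is applied
verbatim, possibly above the cap).

## Synthetic patients

No clinical parameter sets ship with the package; `generate_patient()`
replaces them. Its defaults are the study conditions:

* `E_end` by profile — high (200–300 U/l, above the neocytolysis threshold),
  near-threshold (60–80), low (20–60); RBC lifespan uniform on the published
  37.7–115.8 d range; blood volume 4–6.5 l; EPO half-life 0.25–0.4 d.
* Sigmoid midpoints are placed relative to the patient's own endogenous
  level (α₂ at `E_end` + 30–50, ν at `E_end` + 40–60), as individualized
  estimates would put them — this keeps every profile responsive to
  exogenous EPO within the admissible concentration range.
* Sigmoid amplitudes (μ₁ ≈ 0.15–0.3, slopes ≈ 0.02–0.035) are sized so the
  steady-state dose response is physiologic: maintenance doses for a
  10.5 g/dl target fall in the tens to hundreds of U/day and sustained
  dosing at the 1000 U/day cap reaches steady Hgb of roughly 15–30 g/dl.
  (Steeper response curves are mathematically admissible but collapse all
  control action into a sliver of the dose box and correspond to no real
  dose-response data.)

Calibration is the substitute ground truth: the uncontrolled steady state
(fixed-point of the scheme at $E=E^\mathrm{end}$) must be anemic
(Hgb ∈ [7, 9.5] g/dl; `S0` is rescaled exactly, by linearity, to a sampled
target in [7.5, 9.2]), and sustained maximum-rate dosing must clear
12 g/dl; violations are errors, never silent adjustments. The default
five-patient cohort (fixed seeds 1–5; profiles high/near/near/low/low) also
carries a per-patient `c_gamma` recommendation: the maintenance dose $u^*$
is found by bisection on the steady-state dose response, and patients with
$u^* > 300$ U/day get $c_\gamma=0.01$ instead of 0.1 — with the common value
the control penalty visibly biases their equilibrium below the setpoint,
which is precisely why the underlying method leaves $c_\gamma$ as the
individualized knob.

What the generator does **not** emulate: parameter drift over time,
measurement noise, plant–model mismatch, iron-limited response, and
inter-parameter correlations estimated from data. Passing tests therefore
demonstrate internal consistency of model, discretization and controller
under idealized observation — not clinical performance.

## Numerical choices and degenerate inputs

* Quadrature: Gauss–Legendre of order ≥ max(N+2, 24) per smooth panel,
  subdivided at indicator edges.
* The closed-form PK is evaluated with all exponents non-positive, so
  arbitrarily long horizons cannot overflow; the plant updates the exogenous
  level recursively per interval.
* $\mu_8/E^{\mu_9}$ is evaluated in log space.
* Singular per-class systems (possible only for contrived parameter
  combinations) raise errors naming the class.
* Bleed targets above the current Hgb, rates outside $[0,u_\mathrm{max}]$,
  and non-conforming configuration files are rejected with explicit
  messages before any computation.
* Problem sizes used by the shipped checks: $N=15$ basis functions, 168-day
  closed loops with daily updates for the setpoint targets, a 112-day
  horizon for the $c_\gamma$ dose sweep, and full-length 168-day runs for
  the period comparison (longer periods are cheaper, not dearer, since they
  involve fewer decisions).

## Known limitations

Single-compartment PK only (no subcutaneous absorption); continuous pumps
are hypothetical — thrice-weekly dosing at dialysis visits is not modelled;
no robustness to parameter misestimation (the loop assumes the true model);
the oscillation metrics compare update frequencies on one plant realization,
not distributions. The open-loop problem's non-convexity means reported
optima are local; diagnostics (cost history, projected-gradient norm, KKT
residuals) are returned so users can judge solve quality.
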