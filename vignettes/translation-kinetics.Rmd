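---
title: "Kinetic models of microRNA action on translation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic models of microRNA action on translation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtrans)
```

# The models

`mirtrans` implements the two Nissan–Parker mass-action models of protein
translation and the dominant-system asymptotics that make their transient
behaviour interpretable.

**Linear cycle.** The simplest description is a closed three-step cycle
over the small ribosomal subunit: free 40S binds the mRNA initiation site
(rate $k_1$), scans to the start codon (rate $k_2$), and completes
elongation/termination, releasing the 40S and one protein (rate $k_3$).
With $k_3 \gg k_1, k_2$ the dynamics splits into a fast elongation scale
$\sim 1/k_3$ and a slow initiation scale, giving the closed forms
$$\mathit{Prsynth} = [40S]_0\,\frac{k_1 k_2}{k_1 + k_2}, \qquad
  t_{\mathrm{rel}} = \frac{1}{k_1 + k_2}.$$
Neither involves $k_3$: inhibiting a fast, non-limiting step is invisible
in both observables. The dense eigen-solution of the $3\times3$ rate
matrix (`linear_eigen_solution()`) serves as the exact reference; the
closed forms agree with it to a few percent once $k_3/\max(k_1,k_2)
\gtrsim 100$.

**Non-linear recycling model.** Six species (free 40S, 60S, eIF4F;
mRNA-bound 40S; the start-codon complex AUG; translating 80S) and four
irreversible reactions:
$$\begin{aligned}
  &R1:\; 40S + eIF4F \xrightarrow{k_1} mRNA{:}40S, \quad
   R2:\; mRNA{:}40S \xrightarrow{k_2} AUG + eIF4F,\\
  &R3:\; AUG + 60S \xrightarrow{k_3} 80S, \quad
   R4:\; 80S \xrightarrow{k_4} 40S + 60S \;(+\text{protein}).
\end{aligned}$$
Three pools are conserved ($[40S]$-containing species, $[60S]+[80S]$,
$[eIF4F]+[mRNA{:}40S]$); the vector field satisfies these identities
exactly, and every integration is checked against them. All quantities
are in relative, unitless model units; no attempt is made to calibrate
them to experimental minutes or hours.

During transients the "protein synthesis rate" is not pinned down by the
scheme — one protein is completed per R3–R4 turn — so `nonlinear_rhs()`
exposes both conventions ($k_4[80S]$, the default, and
$k_3[AUG][60S]$); at steady state all definitions coincide, and every
steady-state claim in the package is definition-invariant.

# Steady state and the regime ratio

At steady state all four fluxes equal a common rate $w$. Writing
$x = [60S]_s/[60S]_0$ closes the system into one scalar equation on
$(0,1]$, solved by bracketed bisection to $10^{-12}$
(`steady_state_exact()`). Neglecting terms of smaller order under the
standard parameter orderings reduces it to a cubic,
$$\alpha x(1-x) + (1-x-\delta)\,x(x+\beta-1) + \gamma(1-x)(x+\beta-1)=0,$$
with $\alpha = k_2/(k_1[60S]_0)$, $\gamma = k_4/(k_3[60S]_0)$,
$\delta = [40S]_0/[60S]_0$ and the **regime ratio**
$$\beta = \frac{k_2\,[eIF4F]_0}{k_4\,[60S]_0},$$
the ratio of the maximal initiation flux to the maximal
subunit-recycling flux. The cubic has one root near zero ($x_0$, the
efficient-initiation branch, $\beta > 1$: nearly all 60S engaged,
recycling limits synthesis), one order-one root ($x_1$, the
inefficient branch, $\beta < 1$: eIF4F limits synthesis) and one always
negative companion; positivity of the back-substituted $[eIF4F]_s$ and
$[40S]_s$ always selects exactly one. The steady rate is, to leading
order, $\min(k_2[eIF4F]_0,\; k_4[60S]_0)$, and inhibiting $k_4$ (or
$k_2$) flips the regime at the threshold solving $\beta = 1$
(`critical_thresholds()`).

```{r}
p <- fixture("default")       # k1 = k2 = 2, k3 = 5, k4 = 1, pools 100/25/6
c(beta = beta(p), regime = classify_regime(p))
```

Near the boundary ($|\beta - 1| < 0.05$ by default) results carry a
boundary flag and the asymptotic machinery falls back to numerics: the
reduced formulas assume a clear separation of the two recycling fluxes.

# Staged relaxation and gluing

Switched on from the all-free state, the $\beta > 1$ system relaxes in
three stages, each with its own dominant system; `glue()` assembles them
into a single `piecewise_solution`:

1. **Stage 1 (quasiequilibrium).** eIF4F and mRNA:40S equilibrate on the
   fast scale $1/(k_1[40S]_0)$, AUG on $1/(k_3[60S]_0)$, while assembled
   ribosomes accumulate at the initiation-limited rate. The
   implementation tracks the *cumulative fill* $G(t) = [AUG]+[80S]$,
   whose reduced ODE has a two-logarithm closed-form time
   parametrization; the split of $G$ between AUG and 80S follows from
   flux balance (a quadratic). This one closed form covers stage 1 *and*
   its prolongation after $t'$ (when $[80S]$ stops being negligible),
   and ends at $t_a$, where the free 60S pool is exhausted down to
   $[60S] = [AUG]$.
2. **Stage 2 (quasi-steady state).** Both reaction cycles are internally
   balanced; $A = [40S]+[AUG]$ is conserved and $[40S]$ obeys a single
   ODE whose flux saturation makes the descent linear then exponential.
   The package evaluates the *exact* time integral of the reduced ODE
   (again a two-logarithm closed form) and also exposes the textbook
   piecewise linear/exponential constants (`stage2_closed_form()`,
   `Stage2Params`): slope $K_1 = k_2 m_{qe} - k_4[60S]_0$ with the
   quasiequilibrium occupancy $m_{qe}$ evaluated mid-descent (using the
   full pool $[eIF4F]_0$ instead overestimates the drain by a few
   percent, which accumulates over the stage), rate $K_2 = k_1[eIF4F]_0$,
   and plateau $[40S]_{s2} = k_4[60S]_0/(k_1[eIF4F]_0)$.
3. **Stage 3.** With the R3–R4 cycle frozen at its steady flux, $[40S]$
   and $[mRNA{:}40S]$ relax along the pseudo-linear R1–R2 chain. The
   closed-form linear-chain solution is accurate only near the fixed
   point (the pseudo-rate $k_1[eIF4F]$ changes severalfold on the way
   down), so the stage trajectory integrates the reduced two-species
   dominant system, while the chain constants — amplitude $B$ and
   relaxation time $1/|\lambda_{\mathrm{slow}}|$ of the chain Jacobian —
   are exposed as the analytic product.

Transition-time estimates $t'$, $t''$ (end of stage 1, where
$[60S] = 10\,[AUG]$) and $t'''$ (end of stage 2, where
$[40S] = 10\,[eIF4F]$) are closed-form inversions of the fill and
descent solutions. "Much bigger/smaller" is one order of magnitude
throughout, configurable where it appears. The numeric counterparts —
ratio-crossing events detected on an integrated trajectory
(`detect_crossings()`) — are the oracle the estimates are tested
against (factor-2 agreement required; in practice they agree to a few
percent).

For $\beta < 1$ the quasiequilibrium (stage-1-type) solution describes
the whole relaxation; its fill fixed point reproduces the exact steady
state to $\sim$1–2% (the residual comes from treating the small AUG
pool as part of the fill outflow). For very weak initiation capacity
($k_1[eIF4F]_0 \le k_4$, the A-cap situation, flagged strictly at a
factor 10), the staged closed forms above do not apply and
`acap_regime()` returns a numerically derived piecewise description
with stage windows from the ordering crossings.

**Accuracy metric.** Agreement between the glued solution and the full
numerics is measured per species as relative error on log-spaced samples
inside each stage window, excluding a 10% (log-scale) buffer at each
edge — the hand-off zones are transition regions by construction — and
with an absolute floor of 1% of the largest conserved pool: below that
scale no agreement is claimed (a log-scale concentration plot cannot
resolve it either). Under this metric the glued solution tracks the
numerics within 25% for the moderately separated efficient set
($k_4 = 0.1$) and within 15% for the strongly separated set
($k_1{=}1, k_2{=}5, k_3{=}50, k_4{=}0.01$), and the acceptance tests
pin those bounds.

# Relaxation time and inhibition scans

The operational relaxation time is the latest time at which *any*
species differs from its final steady value by more than 10% of that
value; species with near-zero steady values (below $10^{-6}$ of the
largest pool) are compared on an absolute band instead, to avoid
division blow-ups. `measure_relaxation()` integrates with an
automatically extended horizon until the measurement is stable.

`inhibition_scan()` mimics microRNA action on one step by scaling
$k_1 \ldots k_4$ (or the eIF4F pool) by factors in $(0,1]$: the steady
rate comes from the exact solver, the relaxation time from a fresh
integration from the all-free state. The four canonical experimental
settings cross cap structure (wild-type vs A-cap, $k_1 = 0.01$) with
initiation regime ($\beta = 0.48$ vs $\beta = 7.2$); the two linear-model
settings are $k_1 = k_2$ (wild type) and $k_1 = k_2/100$ (A-cap; the
factor 100 gives clear margin over the order-of-magnitude convention).
These parameter sets *are* the study conditions; they are fixed in
`fixture()`/`signature_setting()` and not tuned elsewhere.

# The qualitative classifier

The published signature tables use a closed, qualitative vocabulary
("decreases after threshold", "goes up and down", ...) with no numeric
definitions, so the classifier necessarily involves calibrated
thresholds. Design choices (`signature_thresholds()`, calibrated once
against the canonical settings and then frozen):

* **Rate labels** are read off fold-decreases at reference inhibition
  depths interpolated in log-log space: flat below 1.25-fold at
  100$\times$ inhibition is "no change"; an early-onset proportional
  decline (1.2-fold by $10^{0.25}\times$, 1.6-fold by
  $10^{0.5}\times$) is "decreases"; late declines split by their depth
  at 100$\times$ inhibition into "decreases after threshold"
  ($\ge$20-fold: the regime flipped early), "slightly decreases after
  strong inhibition" (4–20-fold) and "decreases slightly" (1.25–4).
* **Time labels** are assessed only over the inhibition range in which
  the targeted step keeps its position in the rate hierarchy that the
  staged analysis assumes (e.g. $k_3[60S]_0$ stays well above the other
  effective rates, $k_2$ stays above $k_4$); driving a fast step below
  the recycling rate changes the dominant system itself, which the
  tables treat as beyond the physiological range. Conditions already
  violated at baseline (the A-cap settings) are not imposed. Within the
  window: an interior peak $\ge$1.2-fold followed by a $\ge$8% fall is
  "goes up and down"; a sustained rise $\ge$2-fold at the deep end is
  "increases" ($\ge$10-fold: "drastically"); otherwise "no change"
  (below 2-fold for the non-linear tables, 1.4 for the linear one,
  whose vocabulary has an explicit "slightly" grade).
* Near-threshold shapes set a `low_confidence` flag rather than being
  resolved silently.

Under these frozen settings the computed tables reproduce all 12 linear
and all 32 non-linear published cells. Several margins are thin — the
A-cap/efficient $k_1$ peak is 1.27-fold against the 1.2 threshold, the
inefficient A-cap $k_4$ dip is 13% against 8% — which is an honest
reflection of how qualitative the source vocabulary is; the thresholds
are exposed precisely so this sensitivity can be examined.

`mechanism_lookup()` inverts the reference table: observations that are
entirely "no change" return the never-limiting mechanism ($k_3$)
*together with* the no-effect hypothesis — the two are explicitly
indistinguishable.

# Numerical choices

* Integration: `deSolve::lsoda` (adaptive, stiff-capable),
  `rtol = 1e-8`, `atol = 1e-10`, dense output on a log-friendly grid;
  conservation residuals $\le 10^{-6}$ asserted on every trajectory;
  concentrations clipped at zero inside the right-hand side (the
  positivity contract allows excursions to $-10^{-9}$).
* Root finding: bracketed `uniroot` on the physical branch (monotone by
  construction; the admissible domain is $x \in (\max(0, 1-\beta), 1]$).
* Eigen problems: dense `eigen()`; defective monomolecular matrices fall
  back to numerical propagation with a warning, never to silent rate
  perturbation.
* Degenerate inputs: zero-rate networks, boundary $\beta = 1$,
  non-separated cycles (complex eigenvalues, limiting-step outputs
  refused), vanishing eIF4F pools (tested down to $10^{-5}$; below
  that $1 - x$ reaches float-noise scale).

Test problem sizes: eigen-oracle sweeps use 200 random linear and 500
random non-linear parameter sets; scan-based table checks use 41
log-spaced factors per mechanism over four decades; trajectory oracles
use 1200–3000 output points. The full suite runs in about a minute on
one CPU.

# Known limitations

* The staged approximation is phase-accurate to a few percent in the
  transition times; pointwise errors concentrate at the steep hand-off
  regions and are assessed with the buffered metric above, not at the
  switch points themselves.
* The single-stage ($\beta<1$) closed form carries a $\sim$2% bias in
  its terminal state; use `steady_state_exact()` for steady-state
  quantities.
* $k_1$-insensitivity of the steady rate is asymmetric in the
  inefficient regime: a ten-fold *decrease* of $k_1$ moves the rate by
  $\sim$10% (eIF4F sequestration), while a ten-fold increase moves it
  by under 1%.
* The classifier's vocabulary mapping is calibrated to the canonical
  settings; applying it to parameter sets with different orderings will
  work mechanically but the windows and thresholds were not designed
  for them.
* SBML support covers the two mass-action models of this package, not
  arbitrary documents; validation is structural, not XSD-schema-based.
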