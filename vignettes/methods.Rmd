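---
title: "Rational social distancing, healthcare thresholds, and costly intervention: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rational social distancing, healthcare thresholds, and costly intervention: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(epictrl)
```

# The model

`epictrl` implements a three-level hierarchy: an SIR epidemic, rational
individuals choosing how much to socially distance, and a government
choosing how strongly to incentivise them.

## Epidemic layer

The epidemic follows the rescaled SIR equations

$$\dot s = -k\,s\,i, \qquad \dot i = k\,s\,i - i,$$

with recovery rate 1, so time is measured in units of the mean infectious
period. The recovered fraction $r = 1-s-i$ is implicit. The single driver
is the population behaviour $k(t)$, the population-averaged
infectiousness, whose undisturbed value is $\kappa^\* > 1$ (the basic
reproduction number). Initial conditions are $s(0) = 1-i_0$,
$i(0)=i_0$ with a tiny seed ($i_0 = 3\times10^{-8}$ in the shipped
scenarios, $\kappa^\* = 4$).

## Individual layer

A representative individual tracks the probabilities
$\psi_s,\psi_i$ of being susceptible/infectious, which evolve against the
population's infection level $i(t)$ under the individual's own behaviour
$\kappa(t)$. The individual maximises the discounted utility with running
term

$$u = f^{-t}\left[-\alpha(i)\,\psi_i - \beta(\kappa-\kappa^\*)^2
      + (\kappa-\kappa^\*)\,\varepsilon(t)\right],$$

truncated at a horizon $t_f$ with a closed-form salvage term
$U_f = -f^{-t_f}\alpha(0)\psi_{i,f}/(1+\ln f)$ that prices the epidemic
tail under a perfect vaccine arriving at $t_f$ (so the "log" is the
natural logarithm and the undiscounted limit $f=1$ is finite). Units are
chosen so the distancing-cost coefficient is $\beta = 1$.

The infection cost $\alpha(i)$ is either constant or rises around a
healthcare capacity threshold,

$$\alpha(i) = \alpha_0 + \tfrac{\alpha_1-\alpha_0}{2}
  \left(\tanh[(i-i_{hc})\sigma]+1\right),$$

modelling congested care: once the infected fraction approaches $i_{hc}$,
each infection costs more. Note $\alpha(0)$ slightly exceeds $\alpha_0$
when $i_{hc}\sigma$ is small; with $\sigma = 300$ the relative excess
$(1-\tanh(i_{hc}\sigma))/2$ is $2.5\times10^{-3}$ at $i_{hc}=0.01$ and
$0.14$ at $i_{hc}=0.003$.

Pontryagin's principle yields costates $v_s, v_i$ (the economic values of
being susceptible/infectious),

$$\dot v_s = (v_s-v_i)\kappa i, \qquad
  \dot v_i = f^{-t}\alpha(i) + v_i,$$

with $v_s(t_f)=0$, $v_i(t_f) = -f^{-t_f}\alpha(0)/(1+\ln f)$, and the
pointwise rule
$\kappa = \max\{0,\ \kappa^\* + [\varepsilon - f^t(v_s-v_i)\psi_s i]/(2\beta)\}$.
The mean-field Nash equilibrium imposes self-consistency
$k=\kappa$, $\psi_s=s$, $\psi_i=i$: `solve_nash()` iterates forward state
integration, backward costate integration, and a damped/accelerated
control update until the sup-norm gap between the behaviour and its own
best-response candidate is below `1e-6 * kappa_star`.

## Utilitarian optimum

`solve_utilitarian()` maximises the aggregate utility directly. The only
structural change is the population costate equation

$$\dot v_i = f^{-t}\left[\alpha(i) + \alpha'(i)i\right]
  + (v_s-v_i)k s + v_i,$$

whose extra term $(v_s-v_i)ks$ prices onward transmission — the
externality a self-interested individual ignores. The utilitarian value
weakly dominates the Nash value, and feeding the utilitarian behaviour to
`verify_nash_fixed_point()` exposes the profitable defection that makes
it unstable without enforcement or incentives.

## Government layer

The government maximises

$$V = \int_0^{t_f} f_g^{-t}\left[-\alpha_g(i)i - \beta_g(k-\kappa^\*)^2
  - \gamma_g\,\varepsilon\,(k-\kappa^\*)\right]dt + V_f$$

over the incentive field $\varepsilon(t)$, with the population's Nash
response embedded through its optimality rule. $\gamma_g$ is the shadow
cost of public funds: $\gamma_g=0$ means running the incentive scheme is
free, $\gamma_g>0$ makes intervention itself costly. The government
costates $\lambda_s,\lambda_i$ follow the printed adjoint system (see
`government_costates()`), in which the individual value fields $v_s,v_i$
are treated as exogenous functions of time — the standard simplification
for this nested problem — and the candidate intervention is

$$\varepsilon = \frac{i s\left[f^t(\beta_g+\gamma_g)(v_s-v_i)
  - f_g^t(\lambda_s-\lambda_i)\right]}{\beta_g + 2\gamma_g}.$$

`solve_government()` runs the nested sweep: each outer iteration
re-equilibrates the population at the current $\varepsilon$ (inner solves
warm-started from the previous outer iterate), integrates the government
costates backward, and mixes in the candidate.

# Numerical design

**Grid and integrators.** All states, costates and controls live on one
uniform grid (default $t_f=100$, $n=5001$, so $dt=0.02$). Integration is
fixed-step classical RK4 — bit-reproducible and with matching forward and
backward passes, which a forward–backward sweep requires. Half-step
values of tabulated paths use 4-point cubic interpolation (quadratic at
the edges) so smooth problems retain high order; with $dt=0.02$ the
uncontrolled peak changes by under $10^{-6}$ when the step is halved, and
converged objectives move by less than $10^{-6}$ relative. Objectives use
composite Simpson quadrature (the grid always has an even number of
intervals), whose $O(dt^4)$ error keeps objective values stable to
$10^{-8}$ relative under refinement on fixed trajectories. If the
terminal infected fraction exceeds $10^{-8}$, the horizon is extended by
50% (same step) and the problem re-solved warm-started, so the salvage
approximation stays accurate. Peaks reported in summaries are refined by
a local quadratic fit around the argmax node. Negative undershoots of
$s,i$ below $-10^{-12}$ are an error; smaller ones are clamped to zero
with a warning. The epidemic duration metric counts grid nodes with
$i > 10^{-4}$ (the threshold is configurable).

**Fixed-point driver.** The control updates are damped
($\omega = 0.1$ inner, $0.05$ outer by default) with safeguarded Anderson
acceleration over a five-step residual history: accelerated steps that
inflate the residual beyond `accept_factor` are rejected, the iteration
reverts and takes a damped step, and acceleration pauses for a cooldown.
The damped step size adapts towards the stability edge (growing on
sustained progress, halving after three consecutive rises). If the
iteration stalls, a Jacobian-free Newton–Krylov polish takes over:
GMRES on finite-difference directional derivatives of the sweep map, a
trust-region cap on the step, and a residual line search. Newton handles
the regimes where the sweep map has eigenvalues at or beyond the unit
circle, which genuinely occur here (see below).

**Equilibrium multiplicity and folds.** Under a strong
activity-subsidising intervention the incentivised Nash equilibrium is
not unique: a low-peak equilibrium (the one a decentralizing government
targets) coexists with a high-activity one, and the low-peak branch can
terminate at a fold. We verified numerically that past the fold no
nearby fixed point exists (Picard, Anderson and uncapped Newton all
bottom out at a residual of order $10^{-2}$). The solvers therefore
track branches deliberately: inner warm starts are committed only on
accepted outer steps, outer steps whose equilibrium leaps away from the
tracked branch are rejected, and Newton steps are capped. A consequence
worth knowing: for matched preferences and constant infection cost the
decentralized utilitarian optimum sits essentially at this fold, so with
$\gamma_g > 0$ the nested sweep has no convergent path on the
interventionist branch — the costly-intervention variant of that
scenario is reported flagged as non-converged rather than silently
wrong. Cost-free intervention ($\gamma_g = 0$) is solved exactly.

**Government starts.** The outer sweep's starting point selects the
branch. The default start solves the *coordinated* problem in the
government's own preferences (what it would impose if it could dictate
behaviour) and decentralizes it through the individuals' optimality rule
— exact for $\gamma_g = 0$. For threshold costs the coordinated problem
is itself non-convex and its sweep map stiff (the tanh derivative enters
the costates with magnitude $(\alpha_1-\alpha_0)\sigma/2$), so it is
seeded by a coarse direct transcription (L-BFGS-B over ~60 control
nodes) and finished with Newton–Krylov; the threshold-tracking local
optimum is reached from a constructed hold-at-threshold path (grow
freely to $i_{hc}$, hold $i$ with $k = 1/s$ until herd immunity, then
relax). `branch_scan()` runs both seeds plus bidirectional continuation
in $\alpha_{g1}$, deduplicates converged optima by sup-norm distance of
their $\varepsilon$ paths ($>10^{-2}$), selects the maximiser of $V$,
and reports the switch where the selected branch changes: the objective
crosses continuously there while the peak of infections jumps.

**The bound $\kappa \ge 0$.** The candidate behaviour is clipped before
relaxation mixing, so iterates are feasible at all times. The
intervention rule above is derived for interior behaviour; where the
bound binds it need not vanish at the optimum. `solve_government()`
exposes both treatments: `bound_handling = "printed"` applies the rule
pointwise everywhere (the equations as derived), `"project"` freezes
$\varepsilon$ at bound-active nodes, which is what lets the outer
residual vanish when the optimal behaviour saturates the bound; scans
use the projected variant, and the stationarity diagnostics mask
bound-active nodes accordingly.

**Verification.** Three independent checks ship with the package and run
in the test suite: (i) `direct_transcription()` maximises the same
objectives by simulate-then-quadrature over a coarse piecewise-linear
control with L-BFGS-B and multiple seeded restarts — no costates
anywhere — and must agree with the sweep objectives to $10^{-3}$
relative (objective values, not pointwise controls, since a coarse
control cannot match a fine path); (ii) `pontryagin_residual()` checks
pointwise Hamiltonian stationarity by central finite differences along
converged paths (scaled residual below $10^{-5}$, sign condition at the
bound); (iii) `verify_nash_fixed_point()` recomputes the individual best
response against a solution and measures the defection gap (below
$10^{-4}$ at equilibria; large and profitable at the utilitarian
optimum). Backward integrations are additionally cross-checked against
`deSolve::lsoda` on spline-interpolated paths in the unit tests, and
constant-behaviour runs against the analytic final-size relation
(`final_size_root()`, bracketed to $10^{-12}$).

# Parameters that matter

| parameter | meaning | default | notes |
|---|---|---|---|
| `kappa_star` | baseline infectiousness (R0) | 4 | dimensionless |
| `i0` | initial infected fraction | 3e-8 | seeds the epidemic |
| `f`, `f_g` | discount rates | 1 | discount time `1/log f`; 1 = none |
| `beta`, `beta_g` | distancing cost weight | 1 | unit choice |
| `alpha0`, `alpha1` | infection cost below/above threshold | 100 / varied | in units of the distancing cost |
| `i_hc` | healthcare threshold | 0.1 or 0.01 | fraction infected |
| `sigma` | threshold steepness | 300 | per unit `i` |
| `gamma_g` | shadow cost of intervening | 0 or 0.5 | 0 = cost-free incentives |
| `tf`, `n` | horizon and grid nodes | 100, 5001 | `dt = 0.02`; horizon auto-extends |

Problem sizes used by the shipped tests and the acceptance script:
single solves run on the default grid ($n = 5001$); parameter scans use
$n$ between 2001 and 4001 nodes, 6–11 scan points, and coarse
transcriptions of 20–80 control nodes. These sizes were chosen so that
the refinement invariants above hold with margin while a full scan
remains a desk-scale computation.

# What passing tests do and do not show

The model is deliberately stylised: a single well-mixed population, no
demographic or transmission noise, no reinfection or waning immunity, no
vaccine before the horizon, no compartment-specific distancing costs,
and rational, identical agents with perfect information. Tests passing
on this model validate the mathematics and the numerics — the epidemic
integrator against analytic limits, the equilibria against independent
optimizers and defection checks, the policy switch as a robust
*qualitative* structure — but say nothing about forecasting real
epidemics. The package's value is in mapping how rational behaviour,
care capacity, and the cost of governing interact; its numbers inherit
every idealisation listed above.

# Known limitations

- The government adjoints follow the printed nested-sweep formulation,
  which treats the individual value fields as exogenous when
  differentiating; its stationary points satisfy that system exactly,
  but are not guaranteed to be exact maximisers of $V$ when
  $\gamma_g > 0$ (for $\gamma_g = 0$ the decentralization argument makes
  them exact).
- Costly intervention on the interventionist branch of the matched
  constant-cost scenario is numerically inaccessible (fold, see above);
  the solver reports rather than hides this.
- Sweep convergence tolerances are sup-norm on control candidates; the
  outer tolerance cannot be pushed below the noise floor set by the
  inner tolerance (defaults keep a factor ~50 between them).
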