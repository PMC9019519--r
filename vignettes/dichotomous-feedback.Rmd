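---
title: "Dichotomous feedback in two-component signalling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dichotomous feedback in two-component signalling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcsfb)
```

## The system and the feedback idea

A bacterial two-component signalling system (TCSS) transduces a chemical
signal through phosphoryl transfer: a histidine kinase HK autophosphorylates
at a rate that rises with the inducer concentration, the phosphorylated
kinase HKp passes the group to a response regulator RR, and phosphorylated
RRp activates an output promoter. The natural system is effectively a
switch: its dose–response saturates, so intermediate output levels are hard
to reach robustly.

*Dichotomous feedback* closes a negative loop around this process without
adding any annihilation chemistry. A sequestration protein is expressed from
the same promoter as the output, so its production rate is `P·kout(RRp)`
with a dimensionless feedback strength `P` (experimentally a terminator
efficiency or RBS strength). Two dual realizations exist:

* **phosphorylation sequestration** — a second response regulator SR is
  phosphorylated and dephosphorylated by the same kinase but does not
  activate the promoter, siphoning phosphotransfer flux;
* **dephosphorylation enhancement** — a phosphatase PH strips RRp directly.

Both lower RRp, hence the output, in proportion to the output itself: a
negative feedback that exploits the finite pool of phosphoryl groups.

## Model structure

Every architecture is represented by one `reaction_network` object —
species, integer stoichiometry matrix and per-reaction propensity
descriptors — which is the single source of truth for

* the deterministic mass-action ODE (`ode_rhs`, `simulate_network`),
* the chemical-master-equation sampler (`ssa_simulate`, `ssa_ensemble`),
* the linear noise approximation (`lna_moments`).

Propensities are either mass action (zeroth, first or second order) or one
of two named nonlinear forms used directly as mesoscopic rates: the
Michaelis–Menten autophosphorylation `kap(I) = kap_max·I/(I + Kda)` and the
Hill output initiation `kout(x) = kout_max·(x/Kdr)^n/((x/Kdr)^n + 1)`. We do
not expand these into elementary promoter-binding steps; this matches the
granularity at which the rates were defined. Dephosphorylation is modelled
as a bimolecular mass-action step (`HK + RRp → HK + RR`), i.e. we follow
the reaction equations, not an enzymatic Michaelis–Menten reduction.

Architectures: `wild_type`; `open_loop_phos_seq` / `open_loop_dephos`
(constitutive `beta_SR` / `beta_PH`); `closed_loop_phos_seq` /
`closed_loop_dephos` (production `P·kout(RRp)`); and two *comparison*
feedbacks in which the controller species is produced at the same rate
`P·kout(RRp)` but acts by different means:

* `molecular_seq_feedback` — an annihilator A binds HK and HKp irreversibly
  at one bimolecular rate `k_bind` (a flag restricts binding to HKp only);
* `transcriptional_feedback` — a repressor TF multiplies HK production by
  `1/(1 + TF/K_tf)` (cooperativity 1).

`k_bind` and `K_tf` are not free knobs: they are *matched* so that the
comparison dose–response curves approximate the dichotomous one, by least
squares of log steady-state output over the inducer grid at `P = 1`
(`match_comparison_feedback`). The least-squares criterion is our documented
choice; any matching procedure needs a discrepancy measure and this is the
standard one.

Crosstalk is an extra kinase X held at a constant total `X_tot` (no
production or dilution — its source is unspecified biology, so we model only
its phosphorylation state) with a constant phosphorylation drive
`kap_X = 0.08 min⁻¹` and the same transfer/dephosphorylation rates towards
RR and SR as HK.

## Default parameters and why

Units are fixed package-wide: time in minutes, inducer in mM, proteins in
molecules per cell (system size Ω = 1, i.e. deterministic concentrations are
read as copy numbers; coefficients of variation scale as 1/√Ω, so this
choice matters for every noise figure and is stated here prominently).

No complete published rate table was available to transcribe, so
`nominal_params()` is this package's documented default set; every value
carries a provenance flag (`"default"` vs `"literature"`) so downstream code can
tell them apart. Only the crosstalk rate (0.08 min⁻¹) is anchored in the
published model description. The defaults were chosen once, to place the
model in the qualitative regime the analysis concerns, and are frozen:

| parameter | value | rationale |
|---|---|---|
| `delta` | 0.01 min⁻¹ | dilution at a ~70 min doubling time |
| `beta_HK`, `beta_RR` | 1, 10 molecules/min | HK_tot = 100, RR_tot = 1000: EnvZ/OmpR-like copy numbers |
| `kap_max`, `Kda` | 0.1 min⁻¹, 1 mM | autophosphorylation is the limiting step; half-max induction inside the standard 0.5–10 mM grid |
| `kt`, `kp` | 0.01, 0.0015 (molec·min)⁻¹ | transfer fast against dilution (`kt·RR_tot = 10 ≫ δ`), dephosphorylation by HK dominating RRp turnover (`kp·HK_tot = 0.15`); both needed for the closed-form validity ratios ≈ 17 |
| `ktc` | 0.01 (molec·min)⁻¹ | weak per-molecule sequestration of a large SR pool → moderate loop gain |
| `kpc` | 0.1 (molec·min)⁻¹ | fast SRp recycling: high controller bandwidth and a small HK-channel cross-gain; as a phosphatase rate it also makes the PH loop much stronger than the SR loop, consistent with the direct action of a phosphatase on the kinase flux |
| `kout_max`, `Kdr`, `n` | 40 molecules/min, 20 molecules, 2 | high-copy output (≈3600 molecules at saturation) so transmitted RRp noise dominates the output's Poisson floor; `Kdr` well below the wild-type RRp* ≈ 57 makes the natural response switch-like, which is the premise of the design |
| `X_tot` | 50 molecules | crosstalk flux `kap_X·X_tot` comparable to, but below, the induced flux |

Consequences of this regime, each verified by the test suite:
the closed-loop plateau is tunable from ≈0.92 down to ≈0.54 of the
wild-type plateau as `P` goes 0.1→1; at matched mean output the closed loop
has a lower output coefficient of variation than the wild type, decreasing
with `P`; the sensitivity peak of the dichotomous loop stays near 1; the
crosstalk-driven basal fraction falls monotonically with `P`; and the
dichotomous step response has no overshoot while both comparison feedbacks
overshoot (they deplete the kinase pool, which must then recover through
dilution).

One consequence runs against a naive reading of the noise claim: at *fixed*
inducer, increasing `P` lowers the mean output, so the output's Poisson
floor (∝ 1/√mean) rises and the cv increases mildly. The meaningful
comparison — the one the cv-versus-mean figure actually supports — is at
matched mean output, and there stronger feedback is strictly quieter. The
tests assert the matched-mean ordering.

Similarly, the "graded vs sigmoidal" contrast between open- and closed-loop
dose–response is, in this model family, a statement about the top of the
curve: at matched plateaus the closed-loop response is flat at high
induction (robust plateau) while the open loop still rises. The maximum
normalized slope, by contrast, is *larger* for the open loop everywhere in
the admissible parameter space (its curve is essentially a shifted copy of
the steep natural response), so we operationalize the shape contrast with
the top-of-grid slope.

## Deterministic analysis

Integration uses `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10`:
phosphotransfer rates exceed dilution by two to three orders of magnitude,
so the system is stiff. Propensity evaluation clamps negative entries at
zero (guarding stiff-solver micro-undershoot); states below −10⁻⁶ of the
state scale are rejected as errors rather than silently repaired.

`steady_state` integrates to a settling horizon of 10⁵ min and polishes the
endpoint by a damped Newton iteration with the analytic Jacobian, requiring
a residual 2-norm below 10⁻¹⁰. The Newton step uses a Moore–Penrose solve
so that conservation laws (the crosstalk kinase total) are preserved: the
residual has no component in the left null space of the stoichiometry, and
neither does the pseudo-inverse step. Non-convergence is an error carrying
the offending architecture and inducer, never a silent NaN.

Dose–response grids default to 25 log-spaced points per decade; the discrete
grids of the standard scenarios (0.5/1/2/5/10 mM; `P` 0.1/0.4/0.7/1) are
used verbatim. Overshoot is `(max − final)/final`, floored at 0, and demands
a settled trajectory (<0.1% variation over the final 10% window, otherwise
an error advises a longer horizon). The 1% overshoot threshold that
separates "no overshoot" from "overshoot" in the step-response comparison is
a documented, configurable convention.

## Steady-state theory

The closed forms for RRp* (one per motif) are implemented exactly as
algebra; their validity assumptions are evaluated *numerically* by
`check_assumptions`: the phosphorylated fractions at the full-model steady
state and the rate inequality, each reported as a left/right ratio. "Much
greater" is operationalized as a ratio above a configurable margin
(default 10×) — reported numerically, not merely as a boolean, because the
approximation error varies continuously with the ratios. The phosphorylated
fraction of the sequestration protein (`SR_p ≪ SR_sum`) has no published
quantitative threshold; we apply the same 10× margin to it.

The reduced three-state model (totals eliminated) carries the structural
results: forward invariance of the box S, the algebraic local-stability
condition (equivalent to a positive determinant of the reduced 2×2
Jacobian, the trace being always negative — the test suite verifies the
equivalence on random parameter sets against an eigenvalue oracle),
cooperativity of the Jacobian sign pattern (all off-diagonal entries
nonnegative on S — checked numerically on 10³ sampled states because the
package makes no symbolic claims), the two-corner global-attractivity
diagnostic, and monotonicity of the steady-state RR in `beta_SR`.

## Stochastic analysis

The SSA is the direct Gillespie method in compiled code. Each run draws
from its own counter-based stream seeded by (seed, run index), so ensembles
are reproducible and order-independent. The inner loop keeps a running
propensity sum updated through a species→reaction dependency graph and
refreshes it in full every 4096 events to wash out floating-point drift;
invalid propensities abort with a state dump. Copy numbers are integers;
Hill/Michaelis–Menten propensities are evaluated directly on them.

The LNA integrates the macroscopic mean together with
`dΣ/dt = JΣ + ΣJᵀ + D`, `D = S·diag(a)·Sᵀ`, using the analytic propensity
Jacobian; Σ is checked to stay symmetric positive semidefinite (tolerance
10⁻⁸ relative) at all saved times. Means and covariances start at the
deterministic zero state; the probe time is 1000 min.

The noise cross-validation uses 10⁴ runs per grid point (a desk-scale
ensemble; the standard error of the cv is then ≈0.7% relative, by the
normal-theory delta formula `se(cv) = cv·√(1/(2n) + cv²/n)`). **Validity
boundary**: the LNA linearizes the Hill output around the mean RRp, so it
carries a finite-copy-number bias of order `h''·Var(RRp)` in the mean and
under 10⁻³ (absolute) in the output cv at our copy numbers. In the
appreciable-noise regime (cv ≳ 3% — the regime the noise analysis is
about) this bias is far inside three standard errors at 10⁴ runs and LNA
and SSA agree; at saturated low-noise operating points (cv ≈ 2%) three
standard errors shrink below the bias, and the agreement there is asserted
on the absolute scale instead. Passing these tests therefore shows the LNA
is an accurate *intrinsic-noise* model at these copy numbers; it says
nothing about extrinsic noise, which is outside the package's scope.

## Frequency-domain analysis

The closed loop is split into process and controller. The process keeps
states (HK, RRp) under the steady-state reductions HK_sum = HK_tot,
RR_sum = RR_tot; for the comparison feedbacks the kinase total is not
conserved, so their process keeps (HK, HKp, RRp). The controller is the
sequestration motif: states (SR, SR_sum), or the single state PH (first
order, `K(jω) = P·h'(RRp*)/(jω + δ)`), or the single annihilator/repressor
state. Linearizations are analytic and verified against finite differences
of the exported nonlinear right-hand sides in the test suite; the operating
point is the full-network steady state (which coincides with the reduced
one, since the totals are exact at steady state).

The sensitivity function is `S(jω) = (I − G_yu(jω)K(jω))⁻¹`, the loop
closed exactly as `Y = T·Z + S·W` with no extra sign injected; `‖S(jω)‖` is
the spectral norm, and the defining identity `S·(I − G_yu K) = I` is
re-verified at every grid frequency to 10⁻¹⁰. The frequency grid is
log-spaced over 10⁻⁶–10² rad/min at 200 points per decade — the model's
time constants span ~0.1 min (transfer) to 100 min (dilution), so this
range brackets all loop dynamics with two decades of margin on each side —
and the grid maximum gets one golden-section refinement pass
(`stats::optimize`) in the bracketing interval to guard against peak
aliasing; a grid-refinement invariance test pins the result to <0.1%.

Known regime differences from the published comparison (documented, and
asserted red in the acceptance checks rather than papered over): with our
default rates the comparison feedbacks are *much* less robust than the
dichotomous loop (grid maxima ≈7–10 vs ≈1.03) because at low induction
removing kinase also removes the response regulator's main
dephosphorylation route (`kp·HK_tot ≫ δ`), turning the loop locally
positive; for the same reason they raise, rather than preserve, the
crosstalk-driven basal response, and the phosphorylated-only
molecular-sequestration variant does not reproduce the dichotomous
sensitivity profile within 2%. A regime with `kp·HK_tot ~ δ` would soften
all three effects but would break the closed-form validity margins that the
steady-state theory checks require; with a single dephosphorylation rate
constant both cannot hold at once.

## Crosstalk analysis

`crosstalk_scan` reports, per feedback strength, the basal output (I = 0),
the maximal output (top of the inducer grid — "saturating" by convention),
and the max- and basal-normalized dose–response curves. `X_tot` and the
mechanism keeping X phosphorylated are exposed as configuration
(`kap_X`, `X_tot`) since only the phosphorylation rate is specified
biology. `basal_leak_variant` adds a constitutive output-production term;
with a leak well above the regulated rate the basal response becomes
feedback-independent (the regulated part contributes a few percent), which
the tests exercise with a 5× `kout_max` leak.

## Scenarios, configuration and reproducibility

`scenario()` packages the standard computational experiments (architecture
sets, grids, parameters, seed); scenarios and run configurations serialize
to YAML with explicit units and round-trip losslessly. `run_command`
dispatches the six pipeline commands, writes CSV with mandatory unit
columns and a JSON summary with a provenance block (package version, config
hash, seed), and identical configurations produce byte-identical artifacts.
Randomness is always an explicit seed argument; package functions never
read or disturb the caller's RNG state. Problem sizes used throughout the
checks: 10⁴ SSA runs per noise point, 10³ sampled states for the
monotonicity check, 100 random starts for invariance, 200 random parameter
sets for the stability scan, 20-point (I, P) grids for the sensitivity
maxima.

## What the synthetic conditions do and do not show

The parameter generator emulates a *plausible, internally consistent* TCSS
in the regime the feedback design targets. It does not reproduce any
specific organism's measured rates, promoter leak, gene-expression
burstiness (production is modelled as single-molecule births, so protein
noise floors are Poissonian), cell growth/division stochasticity, or
extrinsic noise. Conclusions validated here are therefore statements about
the architecture — orderings, shapes, stability and robustness properties —
not predictions of absolute expression levels or noise magnitudes in a
particular strain. Numerical headline values (sensitivity maxima, cv
values, overshoots, basal fractions) are reproduced from scratch by
`scripts/acceptance.R`.
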