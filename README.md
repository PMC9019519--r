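# tcsfb — dichotomous feedback in two-component signalling systems

`tcsfb` models, analyses and simulates **dichotomous feedback**: negative
feedback built by sequestering a signalling pathway's own phosphotransfer
flux rather than by annihilating molecules. The testbed is the bacterial
two-component signalling system (TCSS): a histidine kinase HK
autophosphorylates in response to an inducer and passes the phosphoryl group
to a response regulator RR, whose phosphorylated form RRp activates an
output promoter. The loop is closed by expressing a *sequestration protein*
from that same output promoter — either a second response regulator SR that
competes for the phosphorylated kinase (phosphorylation sequestration) or a
phosphatase PH that strips RRp (dephosphorylation enhancement) — with a
tunable feedback strength P ∈ [0, 1].

The package is aimed at synthetic-biology modellers and control theorists
who want to study this controller architecture quantitatively: how it shapes
the dose–response, attenuates intrinsic noise, behaves in the frequency
domain, and suppresses crosstalk from a rogue kinase.

## The model

The core network follows mass-action kinetics with two lumped nonlinearities,

- autophosphorylation: `kap(I) = kap_max · I/(I + Kda)` (Michaelis–Menten in
  the inducer, mM),
- output initiation: `kout(RRp) = kout_max · (RRp/Kdr)^n / ((RRp/Kdr)^n + 1)`
  (Hill activation),

with phosphotransfer `HKp + RR → HK + RRp` (rate `kt`), dephosphorylation
`HK + RRp → HK + RR` (`kp`), the analogous SR reactions (`ktc`, `kpc`),
production `∅ → βX` and first-order dilution `δ` for every protein. Closing
the loop replaces the constant SR (or PH) production by `P · kout(RRp)`.

On top of this single network description the package provides:

- deterministic simulation (stiff ODE), steady states, dose–response and
  step-response/overshoot analysis (`simulate_network`, `steady_state`,
  `dose_response`, `overshoot`);
- closed-form steady-state approximations for both sequestration motifs with
  numerical validity diagnostics, e.g.
  `RRp* = (kap/kp) · kt·RRtot/(kt·RRtot + ktc·SRtot + δ) · kp·HKtot/(kp·HKtot + δ)`
  (`rrp_star_phos_seq`, `rrp_star_dephos`, `check_assumptions`,
  `resource_steady_state`);
- structural theory for the reduced three-state model: forward invariance of
  the box `0 ≤ HK ≤ HKtot, 0 ≤ RR ≤ RRtot, 0 ≤ SR ≤ SRtot`, an algebraic
  local-stability condition, cooperativity (monotone-systems) checks and the
  corner-trajectory global-attractivity diagnostic
  (`local_stability_condition`, `monotone_structure_check`,
  `corner_convergence`, `beta_sr_scan`);
- intrinsic-noise analysis by the linear noise approximation (mean ODE plus
  Lyapunov covariance equation) and an exact direct-method Gillespie
  simulator in compiled code (`lna_moments`, `ssa_simulate`, `ssa_ensemble`,
  `cv_vs_mean_curve`);
- frequency-domain robustness: the closed loop is split into process
  (the TCSS, states HK and RRp) and controller (the sequestration motif),
  linearized at the operating point, and the sensitivity function
  `S(jω) = (I − G_yu K)⁻¹` is evaluated on a log frequency grid with its
  grid maximum (`linearize_process`, `linearize_controller`,
  `sensitivity_response`, `sensitivity_grid_max`);
- comparison feedbacks (molecular sequestration of the kinase;
  transcriptional repression of kinase production) matched to the
  dichotomous dose–response by least squares (`match_comparison_feedback`),
  and crosstalk experiments with an extra kinase X
  (`crosstalk_scan`, `basal_leak_variant`).

All analyses run on a documented default parameter set
(`nominal_params()`, minutes / mM / molecules; each value carries a
provenance flag) and named scenarios (`scenario()`).

## Worked example

```r
library(tcsfb)
p <- nominal_params()

# wild-type steady state at saturating inducer (10 mM)
steady_state(build_network("wild_type", p, I = 10))
#>     HK    HKp     RR    RRp Output
#>   99.0    1.0  943.3   56.7 3557.7

# closed-loop plateaus are tunable by the feedback strength
for (P in c(0.1, 0.4, 0.7, 1)) {
  p$P <- P
  out <- steady_state(build_network("closed_loop_phos_seq", p, I = 10))["Output"]
  cat(sprintf("P = %.1f  output plateau = %.0f molecules\n", P, out))
}
#> P = 0.1  output plateau = 3270 molecules
#> P = 0.4  output plateau = 2609 molecules
#> P = 0.7  output plateau = 2197 molecules
#> P = 1.0  output plateau = 1919 molecules

# closed-form steady state against the full model, with validity ratios
check_assumptions(nominal_params(), I = 10, motif = "phos_seq")
#> <approx_report> approx 56.76 vs full 56.72 (rel. err. 0.000662); valid: TRUE
#>   assumption ratios (require > 10 ):
#>     rr_frac    17.6
#>     rate_ineq  17.4

# robustness of the dichotomous feedback at I = 2 mM, P = 1
p1 <- nominal_params(); p1$P <- 1
proc <- linearize_process("closed_loop_phos_seq", p1, I = 2)
fr <- sensitivity_response(proc, linearize_controller(proc))
cat(sprintf("||S||_Hinf = %.3f at omega = %.3g rad/min\n", fr$hinf, fr$omega_at_hinf))
#> ||S||_Hinf = 1.028 at omega = 0.1 rad/min
```

The wild type saturates (switch-like response); closing the loop buys
graded, robust intermediate expression levels: the plateau drops smoothly
with P while the sensitivity peak stays close to 1 (disturbances are not
amplified; the textbook design target is a peak ≤ 1.2).

A thin command-line wrapper over the same machinery lives at
`inst/cli/tcsfb.R`:

```sh
Rscript inst/cli/tcsfb.R --command dose_response --scenario tunability \
  --seed 1 --out-csv curves.csv --out-json summary.json
```

## Vignette

`vignettes/dichotomous-feedback.Rmd` documents the model and its
assumptions, the default parameter set and the reasoning behind every
value, the numerical methods (stiff integration, Newton polishing, the LNA,
the SSA kernel, the frequency grid) and the known limitations of the
analysis.
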