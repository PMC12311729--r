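---
title: "Models and methods in edxkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in edxkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edxkin)
```

## The scientific problem

Extradiol ring-cleaving dioxygenases (EDX) are non-heme Fe(II) enzymes
that open a catechol ring adjacent to the diol, producing a muconic
semialdehyde. The biosynthetic family member modeled here, L-DOPA
2,3-dioxygenase, acts on L-DOPA and on lignin-derived catechols such as
3,4-dihydroxyhydrocinnamic acid (DHHCA). Catalysis proceeds through a
one-electron oxidation of the bound catechol(ate) to a semiquinone
radical, which either recombines productively with iron-bound superoxide
(eventually yielding the ring-cleaved product) or quenches
nonproductively, inactivating the enzyme. Electron-withdrawing ring
substituents (Br, CN, NO2) lower the catecholic pKa, raise the oxidation
potential, slow productive turnover, and tilt the branch toward
inactivation — which is why a quantitative treatment needs transient
kinetics, steady-state kinetics, pKa determination, and redox summaries
side by side.

## The single-turnover mechanism

`build_scheme1()` constructs a fixed ten-step mass-action network over
twelve species. Under single-turnover conditions (enzyme in tenfold
excess over substrate) each substrate molecule traverses the pathway
once:

| # | step | constants | default status |
|---|------|-----------|----------------|
| 1 | `SA <-> SB` | `k1`, `km1` | `k1` ratio-linked to `km1` |
| 2 | `E + SA <-> ES` | `k2`, `km2` | fixed (competent path) |
| 3 | `E + SB <-> ES` | `k3`, `km3` | fixed_slow |
| 4 | `ES + O2 -> ESO2` | `k4` | fixed_fast |
| 5 | `ESO2 -> ESQ` | `k5` | fixed |
| 6 | `ESQ -> EI` | `k6` | free |
| 7 | `ESQ -> ESQX` | `k7` | free |
| 8 | `EI -> EP` | `k8` | fixed |
| 9 | `EP -> E + P` | `k9` | fixed |
| 10 | `P <-> PX` | `k10`, `km10` | fixed |

Conventions, chosen once and frozen:

* **Units.** Concentrations in μM, time in s, first-order constants in
  s⁻¹, second-order constants in μM⁻¹ s⁻¹; extinction coefficients are
  stored in M⁻¹ cm⁻¹ and reconciled with μM concentrations by an explicit
  factor of 10⁻⁶ in the observable.
* **Charge states.** `SA` is always the more protonated form, `SB` its
  conjugate base. The solution equilibrium is pinned to the
  Henderson–Hasselbalch ratio: `k1/km1 = [SB]/[SA] = 10^(pH − pKa)`,
  re-derived after every parameter update so the constraint can never
  drift. The initial substrate pool is split across `SA`/`SB` at the same
  equilibrium fractions (the substrate equilibrates in solution long
  before mixing).
* **Step numbering.** Only the branch constants `k6`/`k7` (and the
  charge-state pair `k1`/`km1`) carry mechanistic meaning by name; the
  rest of the numbering is this package's convention.
* **Binding-competent state.** Which charge state forms `ES` is
  genuinely undetermined by a single trace: fitting software drives one
  of the two binding pathways to zero, but which one depends on
  assumptions, not data. Both paths are therefore present in the network,
  `binding_state` selects the competent one (the other is `fixed_slow`),
  and the default (`"SA"`) is a convention, not a claim.
* **Status sentinels.** `fixed_fast` resolves to 1×10⁹ and `fixed_slow`
  to 1×10⁻¹², the conventional sentinels for "much faster/slower than
  anything observable". They make the ODE system stiff across ~21 orders
  of magnitude in rate, which is why the integrator below is stiff by
  default.

Remaining defaults (`km1` = 100 s⁻¹, `k2` = 1 μM⁻¹s⁻¹, `km2` = 1 s⁻¹,
`k5` = 1 s⁻¹, `k8` = 0.15 s⁻¹, `k9` = 2 s⁻¹, `k10` = `km10` = 0.05 s⁻¹)
were chosen once as physically reasonable magnitudes that reproduce the
qualitative single-turnover phenotype of a slowly oxidized catechol — a
sharp semiquinone transient within the first few seconds, a UV-silent
gap, product absorbance accumulating between 10 and 20 s, and a slow
late drift from the `P <-> PX` equilibrium — while keeping protonation
and binding fast relative to the chemistry. They are all overridable via
`rate_spec`. The free branch constants default to `k6` = 0.55 s⁻¹ and
`k7` = 0.3 s⁻¹, the regime in which productive decay is only ~1.8× faster
than inactivation.

## Integration

`simulate_mechanism()` integrates the mass-action ODEs with
`deSolve::lsoda` and an analytic Jacobian assembled from the reaction
structure (for step *j* with net flux *v_j*, `dy = S v` with `S` the net
stoichiometry matrix; the Jacobian chains `dv/dy` through `S`).
Tolerances default to rtol = 10⁻⁸ and atol = 10⁻¹² μM, tight enough that
enzyme and substrate conservation hold to better than 10⁻⁶ relative
through a full turnover even with `fixed_fast` steps present. Solver
failures abort with the attempted step sizes; trial points that fail
during fitting are rejected by returning large residuals instead of
crashing the optimizer.

## The observable

The absorbance map is
`A(t) = 1e-6 · l · (a·([ESQ] − [ESQ_X]) + b·([EP] + [P])) − c`,
with `a` the semiquinone extinction coefficient (fittable), `b` the
product extinction coefficient — always determined independently from
endpoint experiments and **never** free in a fit — and `c` a y-axis
offset. Subtracting the quenched semiquinone (`literal_mode = TRUE`, the
default) is the expression conventionally used with this mechanism, even
though the quenched species is usually described as spectroscopically
silent; the physically motivated alternative that simply drops the
`ESQ_X` term is available as `literal_mode = FALSE`. The choice is an
explicit flag, never silent, because the two differ measurably at long
times once inactivation is significant. The stopped-flow pathlength is
not generally knowable from a trace; it defaults to 1 cm and is
configurable everywhere it enters.

## Transient fitting and FitSpace contours

`fit_mechanism()` minimizes the squared residual over the fit window
with Levenberg–Marquardt (trust-region) iterations (`minpack.lm`).
Rate constants and `a` are log-transformed so positivity is structural
rather than enforced by hard walls — necessary when fixed constants span
10⁻¹²–10⁹ — while the offset `c` is fitted untransformed. The default
window `c(0.8, 45)` s excludes the first 800 ms, where real traces of
slowly oxidized substrates contain additional low-intensity features
that are not part of the model; the window is configurable. Convergence
reporting is honest: a maximum-iteration exit is flagged as not
converged.

`fit_space()` quantifies uniqueness: for a pair of parameters it scans a
grid (default 21×21 nodes, log-spaced spanning a factor of 5 either side
of the best fit, center node pinned to the best-fit value), re-optimizes
all remaining free parameters at each node, and reports
`sse_ratio = SSE_min/SSE_node`. The confidence region is
`{sse_ratio ≥ threshold}` with threshold 0.83, i.e. fits whose SSE
exceeds the minimum by no more than ~20%; per-parameter intervals are
the projections of the region. Whether the threshold is applied to raw
SSE or to a reduced chi-square is immaterial when the noise is uniform
(the two differ by a constant factor that cancels in the ratio), so the
ratio is computed on SSE. Implementation details that matter: nodes are
visited in serpentine order and each inner fit is warm-started from its
neighbor (continuity of the profile surface); when the only remaining
free parameters are the observable's `a` and `c`, which enter the
prediction linearly, the inner re-optimization collapses to one
simulation plus closed-form linear least squares; an empty region above
the threshold is reported with a warning, never silently clipped; and if
any node undercuts the nominal minimum (solver slack), ratios are
computed against the smallest SSE seen so that they stay in (0, 1].

## Steady-state analysis

Initial rates are extracted from progress curves by an explicit,
logged rule: absorbance is converted to product concentration through
the product extinction coefficient, and the earliest window of ≥ 8
points with linear-fit R² ≥ 0.995 is expanded point-by-point until R²
would drop; the slope of the last accepted window (×60 for s → min) is
the rate. A zero-variance (flat) signal is linear by convention with
rate 0. The thresholds are arguments, because "the linear region" of a
progress curve is otherwise in the eye of the operator.

Rates are normalized to `y = rate/E0` (min⁻¹) before fitting, and the
hyperbola is fitted in both parameterizations: traditional
(`kcat`, `KM`) and the specificity-constant form
`y = kSP·x/(1 + (kSP/kcat)·x)`, which extracts `kSP` directly as a
fitted parameter (`KM = kcat/kSP` follows). The latter is implemented in
its dimensionally consistent algebraic form. Both routes end with a
polish step that profiles out the linear amplitude and solves the 1-D
stationarity condition by root-finding, so the two fitted curves agree
to rounding error (~10⁻¹¹) rather than to the optimizer's relative
stopping tolerance (~10⁻⁷) — this is what makes the parameterization
equivalence a testable invariant instead of an approximation. `kcat` is
reported in s⁻¹, `kSP = 60·kcat/KM` in μM⁻¹·min⁻¹ with the conventional
×10² display scale in reports, and data whose largest concentration lies
below the fitted `KM` are flagged as extrapolated.

Dissolved O2 is mapped linearly from gas percentage with 100% O2 =
1300 μM at 22 °C (hence 21% → 273 μM); the anchor is a saturation
convention, so any other temperature requires an explicit user-supplied
constant rather than a hidden extrapolation. Endpoint extinction
coefficients come from a through-origin fit of endpoint absorbance
against `1e-6·c·l`, with a warning on non-monotone series.

## pKa determination

The microplate pipeline mirrors standard practice: subtract the buffer
blank per pH; shift each spectrum so A(600 nm) = 0 (600 nm lies outside
the absorption bands of these catechols and serves as a per-well
baseline); difference each spectrum against the most acidic reference
buffer (3.0 by default, 4.0 exposed as an alternative so both runs can
be reported); pick the reporting wavelengths as the maximum positive and
maximum negative difference in the highest-pH column (first maximum on
ties); and fit the two-state model

A(pH) = [St] · (ε_HA + ε_A·10^(pH−pKa)) / (1 + 10^(pH−pKa))

by nonlinear least squares. `ε_HA`/`ε_A` are effective absorptivities of
the acid and base forms at the chosen wavelength (for difference data,
the minima and maxima of the difference curve); starting values come
from the plateau means and the half-amplitude crossing. Two response
modes are supported: the difference at the positive wavelength
(`"single"`, default) and the total absorbance difference
`|Δ(λ+)| + |Δ(λ−)|` per pH (`"total"`). Degenerate inputs are refused
with diagnostics: flat series (no transition), pH-independent spectra
(no usable wavelength), fitted pKa outside the scanned range (warning).

Hammett regression is ordinary least squares of pKa on substituent σ
constants; the package ships the standard Hansch values for H, Br, CN
and NO2 (σ_para 0.00/0.23/0.66/0.78, σ_meta 0.00/0.39/0.56/0.71; Hansch,
Leo & Taft, *Chem. Rev.* 1991, 91, 165) and accepts user-supplied
values. Voltammetric summaries are pure arithmetic
(`E1/2 = (Epa+Epc)/2`, `ΔEp = Epa−Epc`, `Ipa/Ipc`), with a missing
cathodic peak propagating as undefined rather than zero. Relative
substrate-property tables report percentages of a reference compound by
default; because "normalized to the reference" can also mean an offset,
a difference mode is provided and the choice is recorded on the output.
Active-site cavity volumes appearing in such tables are user-supplied
annotations — computing them is out of scope.

## Synthetic data: what it emulates and what it does not

The generators produce every input the pipeline consumes, with ground
truth recorded as an attribute (and exportable as a JSON sidecar):

* `gen_stopped_flow()` — single-turnover traces at the default study
  conditions (5.6 μM substrate, 56 μM enzyme, ~1000 μM O2, pH 7.35,
  380 nm, 14 °C), sampled on a 500-point log-spaced grid from 2 ms to
  45 s so both the early transient and the slow rise are resolved, with
  homoscedastic Gaussian noise (default σ = 0.002 AU, a nominal
  instrument-like value — the true noise of real instruments varies) and
  15 replicates, mirroring the averaging of replicate shots.
* `gen_mm_rates()` — hyperbolic rate tables with relative Gaussian
  noise.
* `gen_titration()` — two-Gaussian-band spectra (acid band at 280 nm,
  base band at 350 nm by default) mixing with Henderson–Hasselbalch
  fractions over pH 3–12.5, on the 210–600 nm / 2 nm grid, with a smooth
  nonzero blank and independent noise on compound and blank reads.
* `gen_endpoint_series()` — Beer–Lambert endpoint series.

Identical seeds give bit-identical outputs. The generators deliberately
omit several features of real data: mixing dead-time artifacts and the
sub-800-ms spectral features (the excluded window is emulated only by
the fit window), photobleaching and baseline drift, wavelength-dependent
instrument response, and buffer-specific systematic shifts between pH
series. Passing recovery tests on these synthetics therefore
demonstrates correctness of the estimation machinery under the stated
noise model — not robustness to every instrument pathology.

## Problem sizes and numerical choices in the test suite

The suite runs at desk scale, chosen to exercise every code path with
comfortable margins: 500-point traces with 15 replicates for the
headline transient-recovery study (20 replicate experiments, median
recovery of `k6`, `k7`, their ratio, and the semiquinone ε), 20
replicate titration plates per tabulated pKa, 21×21 FitSpace grids, and
50-seed Monte-Carlo checks for the scalar estimators. Oracles are
independent of the code paths they check: matrix exponentials for linear
networks, closed-form first-order kinetics, an analytic SSE ellipse for
the profile engine, a separately integrated progress curve for
initial-rate extraction, and brute-force Henderson–Hasselbalch
arithmetic.

## Known limitations

* No global multi-experiment fitting (e.g. simultaneous wavelengths or
  pH series) and no Bayesian posterior sampling; uncertainty beyond
  standard errors comes only from the profile-SSE contours.
* No thermodynamic-cycle consistency enforcement and no temperature
  dependence of rate constants.
* Steady-state analysis treats catechol and O2 saturation curves
  independently; there is no bisubstrate ternary-complex rate law, and
  no substrate- or product-inhibition terms.
* Raw voltammogram processing (baseline correction, peak picking) is out
  of scope; peak potentials are inputs.
* The mechanism's non-branch rate constants are conventions calibrated
  to a phenotype, not measurements; conclusions should rest on the
  constants actually constrained by the data (`k6`, `k7`, `a`), which is
  exactly what the FitSpace contours are for.
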