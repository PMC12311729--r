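# edxkin

Quantitative characterization of catecholic substrates of extradiol
ring-cleaving dioxygenases (EDX), built around the biosynthetic enzyme
L-DOPA 2,3-dioxygenase and lignin-derived catechols such as
3,4-dihydroxyhydrocinnamic acid (DHHCA) and its 6-substituted (Br, CN,
NO2) derivatives.

EDX enzymes cleave a catechol ring next to the diol to give a muconic
semialdehyde, but electron-poor substrates are slow to oxidize: the
semiquinone radical intermediate lingers, and its nonproductive quenching
inactivates the enzyme. Characterizing a candidate substrate therefore
combines several measurements, all of which this package implements as a
tested pipeline for enzymologists working on ring-cleaving dioxygenases:

* **Pre-steady-state (stopped-flow) mechanism fitting.** A mass-action
  reaction network for single-turnover conditions: solution charge-state
  equilibrium of the substrate (`S_A <-> S_B`, pinned to the
  Henderson–Hasselbalch ratio `[S_B]/[S_A] = 10^(pH − pKa)`), binding of
  one competent charge state, rapid irreversible O2 binding, semiquinone
  (ESQ) formation, and the branch point

  `ESQ -> EI` (productive, `k6`)  vs  `ESQ -> ESQ_X` (inactivation, `k7`),

  followed by a lumped UV-silent step to the enzyme–product complex,
  product release, and a `P <-> P_X` equilibrium with a silent product
  form. Traces are predicted through the observable
  `A = 1e-6·l·(a·([ESQ]−[ESQ_X]) + b·([EP]+[P])) − c` and fitted by
  trust-region least squares on log-transformed parameters, with
  FitSpace-style 2-D confidence contours: pairs of parameters are scanned
  on a grid, all remaining free parameters are re-optimized at each node,
  and the confidence region is `SSE_min/SSE ≥ 0.83` (fits at most ~20%
  above the minimum SSE).
* **Steady-state Michaelis–Menten analysis** in both parameterizations —
  the traditional `y = kcat·x/(KM + x)` and the specificity-constant form
  `y = kSP·x/(1 + (kSP/kcat)·x)` with `y = rate/E0` — including the
  specificity constant `kSP = kcat/KM` (μM⁻¹·min⁻¹), O2 as the varied
  substrate (gas % → μM at 22 °C), initial-rate extraction from progress
  curves, and endpoint extinction-coefficient determination.
* **Spectrophotometric pKa determination** from microplate titrations
  (210–600 nm, pH 3–12.5): blank subtraction, 600-nm baseline
  normalization, difference spectra against a reference buffer,
  wavelength selection, and the two-state fit
  `A(pH) = [St]·(ε_HA + ε_A·10^(pH−pKa))/(1 + 10^(pH−pKa))`.
* **Hammett linear free-energy regression** of pKa against built-in
  Hansch σ constants, **voltammetric summaries** (`E1/2 = (Epa+Epc)/2`,
  `ΔEp = Epa−Epc`), protein ε280 from sequence composition, and relative
  substrate-property tables.
* **Synthetic-data generators** for every input (stopped-flow traces,
  rate tables, titration plates, endpoint series) with recorded ground
  truth, so the whole pipeline is testable without instrument data.

## Worked example

```r
library(edxkin)

## 1. Simulate a single-turnover stopped-flow experiment (15 replicate
##    shots, 5.6 uM substrate, 56 uM enzyme, ~1000 uM O2, 380 nm)
traces <- gen_stopped_flow(seed = 1)
avg <- average_traces(traces)
avg
#> Kinetic trace: 500 points, 0-45 s, 380 nm, pH 7.35, mean of 15 shots

## 2. Fit the inactivation-branch mechanism to the averaged trace
mech <- build_scheme1(pka = 7.51, ph = 7.35, e0 = 56, s0 = 5.6, o2_0 = 1000)
obs  <- observable_model(a = 38950, b = 33256)
prob <- fit_problem(mech, obs, avg, free = c("k6", "k7", "a"),
                    window = c(0.8, 45))
fit_mechanism(prob, start = c(k6 = 1, k7 = 0.5, a = 30000))
#> Transient least-squares fit (201 points, SSE 5.0323e-05)
#>         k6         k7          a
#> 5.5234e-01 3.0009e-01 3.9098e+04

## 3. Steady-state Michaelis-Menten analysis of a synthetic rate table
d <- gen_mm_rates(kcat = 2.1, km = 922, e0 = 0.5,
                  s_grid = c(50, 100, 200, 400, 800, 1600, 3200, 6000),
                  noise_rel = 0.05, seed = 1)
fit_mm_traditional(d)
#> Michaelis-Menten fit (traditional form)
#>   kcat = 2.167 +/- 0.052 s^-1
#>   KM   = 969.8 +/- 68 uM
#>   kSP  = 0.134 uM^-1 min^-1 (13.4 on the x10^2 scale)

## 4. pKa from a synthetic microplate titration
plate <- gen_titration(pka = 7.51, seed = 1)
titration_pka(plate)
#> Titration fit: pKa = 7.515 +/- 0.019 (eps_HA -2.308e-05, eps_A 0.004356 AU/uM)

## 5. Hammett correlation of the bundled pKa series
ref <- merge(edx_reference("pka_values"), hammett_sigma(), by = "substituent")
h <- hammett_regression(ref$pka, ref$sigma_para)
round(c(rho = h$rho, r_squared = h$r_squared), 4)
#>       rho r_squared
#>   -2.3364    0.9807
```

The transient fit recovers the generating branch rates (`k6` 0.55 s⁻¹,
`k7` 0.30 s⁻¹ — productive decay only ~1.8× faster than inactivation,
i.e. heavy single-turnover inactivation) and the semiquinone extinction
coefficient (39,098 vs a generating 38,950 M⁻¹cm⁻¹) from noisy replicate
traces. The steady-state fit returns `kcat`, `KM` and `kSP` with `kSP`
also shown on the conventional ×10² μM⁻¹·min⁻¹ display scale, and the
Hammett slope ρ < 0 quantifies how electron-withdrawing 6-substituents
acidify the catechol.

A thin command-line interface over the same functions is installed at
`inst/cli/edxkin` with subcommands `generate`, `fit-transient`, `fit-mm`,
`fit-pka`, `hammett`, `cv-summary` and `profile-table`; every run writes
its resolved configuration next to its outputs.

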