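---
title: "Modelling growth-decoupled fed-batch cultivations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling growth-decoupled fed-batch cultivations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedbatchkit)
```

## The problem

Constitutive expression systems in *Komagataella phaffii* couple product
formation to growth: the specific production rate is q_p = α·μ, so
product only accumulates while biomass does. Stress- and
starvation-responsive promoters invert this: they are repressed while
substrate is plentiful and induced when the specific substrate uptake
rate q_S drops to maintenance levels. Exploiting them requires a
different process design — grow first, then hold the culture in a
*pseudo-starving* state with a minimal constant feed — and a different
set of quantitative tools. This package collects those tools: release
kinetics for flask-scale carbon limitation, feed-profile design,
a macroscopic simulator, black-box stoichiometry, KPI estimation, and
elemental-balance data reconciliation.

## Slow-release kinetics

Flask-scale carbon limitation is implemented with silicone-matrix discs
that release glycerol following the Ritger–Peppas power law
M(t) = k·tⁿ (M in mg, t in h). We fit k and n by nonlinear least
squares **on the original scale**, using the log–log linearization only
for starting values: the scatter of HPLC-measured cumulative masses is
approximately additive in mg, so an original-scale residual standard
error is the meaningful fit statistic (and the one practitioners
report). For disc geometry the exponent classifies the mechanism:
n ≤ 0.5 Fickian diffusion, 0.5 < n < 1 anomalous transport (diffusion
plus matrix erosion), n ≥ 1 case-II. The boundary at exactly 0.5 is
assigned to Fickian by convention.

Culture-level predictions assume every mg released is consumed
immediately (the culture is severely carbon limited) and biomass is
approximately constant, giving a window-averaged
q_S = ΔM/(1000·X_total·Δt) and μ = q_S·Y_X/S. The default 24 h
averaging window is a choice: the released mass grows sub-linearly, so
the average depends on the window, and the first day of feeding is the
window such predictions are typically quoted for. With a 3-disc model
k ≈ 5.13, n ≈ 0.65 and 0.29 g DCW this yields q_S ≈ 0.0058 g g⁻¹ h⁻¹
and μ ≈ 0.003 h⁻¹, the regime the bioreactor pseudo-starving feed
reproduces. Discs are assumed to act independently, so k scales
linearly with their number (`scale_beads`).

## Feed design

Two feed laws cover the strategies:

* **Exponential (constant μ).** From the biomass balance with yield
  Y_X/S and maintenance m_S,
  F(t) = (μ_set/Y_X/S + m_S)·X₀V₀·e^(μ_set·t)/S_feed. The default
  m_S = 0 matches the common practice of converting between μ and q_S
  by yield alone; it is configurable for organisms or regimes where
  maintenance matters.
* **Constant (pseudo-starving).** F = q_S,set·X_total/S_feed, sized to
  the biomass present at induction start. As biomass slowly grows, the
  delivered q_S drifts below the set-point proportionally; the
  guarantee we test is that q_S stays within 10% of the set-point while
  total biomass has moved less than 10%.

`build_schedule` assembles three named strategies: `FB-mu` (batch + one
exponential phase to a DCW target), `PS` (batch + growth at 0.15 h⁻¹ to
70 g/L + a single pseudo-starving induction at q_S 0.005 g g⁻¹ h⁻¹) and
`3-PS` (three growth/induction cycles to 40, 60, 80 g/L with 24 h
inductions).

The feed glycerol concentration (default 400 g/L) and the batch medium
(40 g/L glycerol, 2 L, 0.5 g/L inoculum) are rig-specific quantities
that are not universal constants; they are surfaced in every config and
function signature. With these defaults the batch ends near 24 g/L DCW,
a typical starting point for the feeding phase of this organism on a
4% glycerol batch.

## The simulator

State variables are V (L), total biomass XV (g), dissolved substrate SV
(g) and total product PV (AU); concentrations are derived. The balances
are

dV/dt = F,  d(XV)/dt = μ·XV,  d(SV)/dt = F·S_feed − q_S·XV,
d(PV)/dt = q_p·XV,

with Monod kinetics μ = μ_max·S/(K_S + S) and q_S = μ/Y_X/S + m_S.
During feeding the residual substrate settles at the quasi-steady
concentration where consumption equals supply, so the realized μ is
feed-determined — the standard fed-batch limit — while Monod governs the
batch phase and transitions. μ_max = 0.20 h⁻¹ and K_S = 0.1 g/L are
defaults of convenience (glycerol-grown *K. phaffii* grows at
0.15–0.20 h⁻¹; K_S only sets how sharply the quasi-steady state is
approached) and are configurable.

Product kinetics come in the two regulatory modes. Growth-coupled:
q_p = α·μ with α = Y_P/X. Starvation-induced:
q_p = q_p,max·e^(−t_ind/τ) while q_S is below a repression threshold
q_S,rep, and zero otherwise; the induction clock t_ind starts when
uptake falls through the threshold and resets whenever a growth phase
raises it again, so repeated starvation cycles re-induce. The transient
decay reflects the observation that starvation-promoter activity fades
over tens of hours even though the limitation persists.

Default induced-kinetics parameters were calibrated once from the
endpoint scale of a single pseudo-starving induction at 70 g/L DCW:
with the production integral q_p,max·τ·XV matching a ~26–27 kAU final
titer in ~2.7 L and the titer curve flattening at 24–30 h, q_p,max =
12.5 AU g⁻¹ h⁻¹ and τ = 12 h. The repression threshold q_S,rep =
0.02 g g⁻¹ h⁻¹ sits between the pseudo-starving uptake (0.005) and the
slowest growth-phase uptake (~0.044). Two known divergences from real
cultures: (i) a slow constant-μ fed-batch of a starvation-regulated
strain shows partial activation at the growth-to-feed transition, which
a sharp threshold cannot produce; (ii) in three-cycle schedules the
third induction is observed to attenuate, for which no mechanism is
available, so it is not modelled. Evaporation, sampling withdrawals and
base addition volumes are ignored.

Off-gas is attached at every output step from black-box stoichiometry
(below), so OUR, CER and RQ are consistent with the instantaneous μ and
q_S by construction, and carbon closes along the whole trajectory to
within integration error (< 1%, tested by independent trapezoidal
integration of CER·V).

Integration uses `deSolve` (lsoda/lsodar) with root functions for phase
termination (substrate depletion at 0.01 g/L residual for batch, DCW
targets for growth phases, durations for inductions). Tolerances
default to 1e-8; tightening them changes endpoint states by < 0.1%.

## Black-box stoichiometry

For growth on glycerol (γ_S = 4.667 e⁻/C-mol) with ammonia as nitrogen
source, per C-mol of substrate consumed the carbon balance gives CO₂ =
1 − Y (Y the C-mol biomass yield) and the electron balance gives O₂ =
(γ_S − Y·γ_X)/4. Two biomass presets ship: generic yeast CH1.8O0.5N0.2
(γ_X = 4.20, 24.63 g/C-mol, the default) and a glycerol-grown
*K. phaffii* composition CH1.785O0.572N0.166 taken from published
elemental analyses; ash is taken as zero. RQ decreases monotonically
with yield and approaches the combustion limit 4/γ_S = 6/7 ≈ 0.857 as
Y → 0.

The secreted product is quantified in lipolytic activity units (1 AU =
1 µmol p-nitrophenol released min⁻¹), which carry no elemental
information, so product carbon is neglected in all balances. The bias
is visible and small: computed RQ runs ~0.01–0.03 below typical
measured values for these cultivations.

## Rates, yields and KPIs

`estimate_rates` takes μ as the least-squares slope of ln(X·V) versus
time and q_S as (glycerol fed − Δ(S·V)) divided by the trapezoidal
biomass-time integral. `compute_kpis` adds Y_X/S = μ/q_S, Y_P/X, Y_P/S,
q_p = ΔP_total/∫XV dt, volumetric productivity Q_v =
ΔP_total/(V_end·Δt), and the titer convention
titer (kAU) = activity (AU/mL) × V (L), which keeps titer/activity
ratios equal to the vessel volume. Phase windows are closed-open
[t0, t1), closed by the last sample at or before t1. Zero denominators
yield `NA` flags, not errors. The identity Y_X/S = μ/q_S is exact in
the quasi-steady limit; on simulator output a < 1% bias remains from
the transient while the residual substrate pool fills at feed start,
and our tests assert it at that tolerance.

Note that a specific production rate depends on its time base: computed
over an induction phase only, q_p is several-fold higher than over the
whole process. Both are legitimate; `compute_kpis` computes whatever
window it is given, and comparison tables should state the window.

The p-nitrophenyl butyrate assay conversion
activity = (dA405/dt)/(ε·path)·dilution requires the molar
absorptivity ε of p-nitrophenol under the actual assay pH and buffer;
because ε varies steeply with pH around its pKa, no default is baked
in. The dilution factor defaults to 10 (900 µL buffer + 100 µL
supernatant).

`tpm_and_rank` implements the within-sample length-normalized
expression measure TPM = 10⁶·(count/length_kb)/Σ(count/length_kb) and
ranks genes by median, mean and maximum TPM across samples — the
screening step used to shortlist constitutively high promoter
candidates from expression data. Alignment and counting are out of
scope; the function consumes a prepared count table.

## Data reconciliation

Measured specific rates for substrate, biomass, O₂ and CO₂ (C-mol or
mol basis, consumed negative) should satisfy E·x = 0 with E the 2×4
carbon/degree-of-reduction matrix. With measurement covariance Σ
(diagonal by default, from per-assay relative standard deviations:
substrate 1%, biomass 5%, off-gas 5%), the balance-constrained weighted
least-squares reconciliation is the projection
x̂ = x − Σ·Eᵀ·(E·Σ·Eᵀ)⁻¹·E·x, and h = εᵀ(EΣEᵀ)⁻¹ε with ε = E·x is χ²
distributed with rank(E) = 2 degrees of freedom under consistency. We
test at 95% confidence (critical value 5.991). Cross-covariances are
taken as zero — the assays are physically independent — and the
χ²-calibration of the test under exactly this noise model is itself a
test in the suite (empirical pass rate 95% ± 2.5% over 2000
replicates). Carbon and electron recoveries (produced/consumed × 100)
of raw vectors stay above 90% in ≥ 99% of replicates at these assay
precisions; an undetected 1.5× error on any single rate drives the test
far past its critical value.

The product rate is excluded from the balances for the same reason it
is excluded from the simulator's stoichiometry: activity units carry no
elemental content.

## The synthetic-data generator

The generator exists so every estimator can be exercised against known
ground truth without any external data. It emulates the measurement
layer of a benchtop cultivation: multiplicative Gaussian noise at the
documented assay precisions (DCW 5% with quadruplicate weighings
averaged, HPLC 1%, off-gas 5%, activity 4%), truncation at zero, and
for off-gas a molar-fraction bridge at a fixed 2 L/min air feed. Gas
noise is applied to the inlet–outlet fraction *differences* — the
quantity OUR and CER are computed from and the one whose relative
precision a per-batch recalibrated analyser controls; applying the same
RSD to the absolute fractions instead would inflate rate noise more
than tenfold, contradicting the documented < 5% precision of the
respirometric rates themselves.

What the generator does **not** emulate: sensor drift and
recalibration steps, autocorrelated noise, sampling-volume feedback on
the balances, day-to-day biological variability between replicate
cultivations, or raw sequencing reads (the count-table generator draws
negative-binomial counts directly). Tests passing on synthetic data
therefore demonstrate estimator correctness under the stated noise
model, not robustness to structured measurement pathologies.

For the count-table generator, "dominance" of the designated gene is
defined on the length-normalized (TPM) scale rather than raw library
share, since a raw-count-dominant but long gene can be outranked after
length normalization.

## Scenario pipeline

`run_scenario` ties the stages together from a single YAML file (three
bundled under `inst/extdata/`): build schedule → simulate → sample noisy
measurements → KPI estimation over the feeding window → reconciliation
of the growth-phase mean rates. Determinism is end-to-end under the
config seed. The package is an analysis library, so its command surface
is R functions plus these configs rather than a shell executable;
`report_tables` renders KPI records with the standard row vocabulary
and a fold-change column for pairwise comparisons.

## Numerical and testing choices

Problem sizes used in the test suite: simulations at 0.25–0.5 h output
resolution (a few hundred steps each), 500-replicate noise studies for
estimator recovery and recovery distributions, 2000 replicates for the
χ²-calibration check, 500-replicate bootstrap for the release-fit CI.
These sizes give Monte-Carlo error comfortably below the tolerances
being asserted while keeping the full suite in seconds.

Known limitations, beyond the kinetics divergences noted above: the
quasi-steady feeding assumption breaks if the commanded feed exceeds
μ_max (the simulator then caps growth and substrate accumulates);
reconciliation assumes the balance matrix is exact, so a wrong biomass
elemental composition surfaces as apparent measurement inconsistency;
and the χ² test is a global detector — localizing *which* measurement
is faulty is out of scope.
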