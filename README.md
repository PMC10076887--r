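# fedbatchkit

Design and analysis tools for carbon-limited fed-batch cultivations of
*Komagataella phaffii* (*Pichia pastoris*) on glycerol, with a focus on
**growth-decoupled protein production**: strategies in which biomass is
grown first and the recombinant product is then induced by
*pseudo-starving* — feeding only maintenance-level carbon, which
activates starvation-responsive promoters while constitutive glycolytic
promoters fall silent.

The package is aimed at bioprocess engineers who need to (i) design feed
profiles, (ii) simulate and compare cultivation strategies before
running them, and (iii) extract and validate physiological parameters
from cultivation data.

## What is in the box

| Area | Functions |
|---|---|
| Slow-release substrate kinetics | `fit_release_model`, `released_mass`, `release_rate`, `classify_mechanism`, `predict_culture_rates`, `scale_beads` |
| Feed design | `exponential_feed_rate`, `pseudo_starving_feed_rate`, `build_schedule`, `feed_phase`, `feed_schedule` |
| Fed-batch simulation | `simulate_cultivation`, `simulation_params`, `product_kinetics`, `qp_growth_coupled`, `qp_starvation_induced` |
| Black-box stoichiometry | `compound`, `cmol_properties`, `mass_yield_to_cmol`, `gas_rates_from_yields` |
| Rates, yields, KPIs | `estimate_rates`, `compute_kpis`, `fold_change`, `activity_from_slope`, `tpm_and_rank` |
| Balance reconciliation | `balance_matrix`, `rate_vector`, `reconcile`, `consistency_test`, `recovery` |
| Synthetic data | `noise_model`, `noisy_timecourse`, `release_samples`, `noisy_balanced_rates`, `inject_gross_error`, `synthetic_counts` |
| Scenario pipeline | `run_scenario`, `report_tables` (bundled YAML scenarios in `inst/extdata/`) |

## The models in brief

**Release kinetics.** Silicone-matrix discs release substrate following
the Ritger–Peppas power law *M(t) = k tⁿ* (mg, h). The diffusional
exponent *n* identifies the mechanism (disc geometry: *n* ≤ 0.5 Fickian;
0.5 < *n* < 1 anomalous diffusion + erosion; *n* ≥ 1 case-II). Fitting is
by nonlinear least squares on the original scale.

**Feed design.** From the biomass balance, an exponential profile
*F(t) = (μ_set/Y_X/S + m_S) · X₀V₀ · e^(μ_set t) / S_feed* holds μ
constant; a constant feed *F = q_S,set · X_total / S_feed* delivers a
maintenance-level uptake rate (pseudo-starving, e.g. q_S = 0.005 g g⁻¹
h⁻¹ ⇒ initial μ ≈ 0.003 h⁻¹ at Y_X/S = 0.58).

**Simulator.** Macroscopic balances dV/dt = F, d(XV)/dt = μXV,
d(SV)/dt = F·S_feed − q_S·XV, d(PV)/dt = q_p·XV with Monod growth and
either growth-coupled (q_p = α·μ) or starvation-induced
(q_p = q_p,max · e^(−t_ind/τ) below a repression threshold, re-inducible)
product kinetics. Off-gas (OUR, CER, RQ) attaches to every step from the
carbon balance (CO₂ = 1 − Y per C-mol substrate) and electron balance
(4·O₂ = γ_S − Y·γ_X).

**Reconciliation.** Measured rate vectors (substrate, biomass, O₂, CO₂;
C-mol basis, consumed negative) are projected onto the carbon/electron
balance null space weighted by measurement covariance,
x̂ = x − ΣEᵀ(EΣEᵀ)⁻¹Ex, with the consistency statistic
h = εᵀ(EΣEᵀ)⁻¹ε ~ χ²(rank E) tested at 95% (critical value 5.991 at
2 dof).

## Worked example

Compare a single pseudo-starving induction (PS: grow at μ = 0.15 h⁻¹ to
70 g/L DCW, then feed q_S = 0.005 g g⁻¹ h⁻¹ for 40 h) against a
constitutive producer run at constant μ = 0.025 h⁻¹ to 80 g/L:

```r
library(fedbatchkit)

ps  <- build_schedule("PS", strain = "PDH-PS")
tc1 <- simulate_cultivation(ps, simulation_params(Y_XS = 0.58,
         product = product_kinetics("starvation_induced",
                                    q_p_max = 12.5, q_S_rep = 0.02, tau = 12)))

fb  <- build_schedule("FB-mu", mu_set = 0.025, strain = "GAP-0.025")
tc2 <- simulate_cultivation(fb, simulation_params(Y_XS = 0.54,
         product = product_kinetics("growth_coupled", alpha = 100.45)))

p1 <- phase_table(tc1); p2 <- phase_table(tc2)
report_tables(list(compute_kpis(tc1, c(p1$t_start[2], p1$t_end[3])),
                   compute_kpis(tc2, c(p2$t_start[2], p2$t_end[2]))))
```

```
                               parameter   PDH-PS GAP-0.025 fold_change
1                          Real mu (1/h)   0.0159    0.0250       0.636
2                            q_s (g/g/h)   0.0312    0.0463       0.673
3                            Y_x/s (g/g)   0.5110    0.5400       0.945
4                                     RQ   0.6800    0.7110       0.956
5                            Titer (kAU)  26.9000   22.8000       1.180
6             Lipolytic activity (AU/mL)  10.1000    8.0000       1.260
7                           Y_p/x (AU/g) 175.0000  100.0000       1.740
8                           Y_p/s (AU/g) 101.0000   54.2000       1.870
9  q_p / Specific productivity (AU/g/h)    3.1600    2.5100       1.260
10      Volumetric productivity (AU/L/h) 207.0000   98.7000       2.090
```

The pseudo-starving run reaches a higher titer (26.9 kAU at 10.1 AU/mL
in 2.66 L) with a 1.9-fold higher product-per-substrate yield and
2.1-fold higher volumetric productivity — the operational signature of
growth-decoupled expression. The whole-feeding-window "Real mu" and
"q_s" rows average growth and induction phases; per-phase values come
from `compute_kpis` on the individual phase windows.

Black-box respirometry from a measured yield:

```r
gas_rates_from_yields(q_S = 0.046, Y_XS = 0.54)
#> <gas_rates> qO2 0.6891  qCO2 0.4898 mmol/g/h  RQ 0.711
```

Release-kinetic characterization of three slow-release discs:

```r
t <- c(5, seq(10, 120, 10))
m <- fit_release_model(t, 5.13 * t^0.65)   # HPLC cumulative release, mg
m
#> <release_model> M(t) = 5.13 * t^0.65 mg (3 beads)
#>   r2 = 1.0000, residual SE = 2.443e-14 mg (13 points)
classify_mechanism(m$n)
#> anomalous (diffusion + erosion)
```

Or run a bundled end-to-end scenario (simulation → noisy sampling → KPI
report → balance reconciliation):

```r
run_scenario(system.file("extdata", "scenario_pdh_ps.yaml",
                         package = "fedbatchkit"))
```

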