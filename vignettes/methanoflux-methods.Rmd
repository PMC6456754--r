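---
title: "methanoflux: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methanoflux: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methanoflux)
```

This vignette is the package's own account of the science it implements:
the labeling model and its assumptions, the FBA formulation, the numerical
choices, what the synthetic generators do and do not emulate, and the
decisions taken where the design was genuinely open.

## 1. The steady-state labeling model of the acetyl-CoA node

During balanced growth on a fully ¹³C-labeled C1 substrate, every
intermediate upstream of and including PEP becomes fully labeled, so
steady-state MIDs carry no information about the RuMP/EMP/ED partition.
Information survives only downstream of the pyruvate node, where
carboxylation incorporates CO₂ from a pool that is only partially labeled
(label enters it by substrate oxidation; unlabeled CO₂ diffuses in from the
medium).

The forward model has two parameters:

| parameter | meaning | default | units |
|---|---|---|---|
| `p_pdh` | share of de novo acetyl-CoA made from pyruvate via PDH | strain presets 0.33 (WT), 0.73 (Δldh Δmdh) | fraction |
| `f_co2` | labeled fraction of the intracellular CO₂ pool | 0.24 | fraction |
| `noise_sd` | additive truncated-Gaussian noise per mass channel | 0 (simulations), 0.01 (synthetic datasets) | MID fraction |

Assumptions, stated explicitly:

1. **De novo OAA and malate arise by carboxylation of fully labeled C3**,
   not from the oxidative TCA cycle. Hence
   `OAA = malate = (M+3: 1 − f, M+4: f)`. This is the measured situation on
   methanol (threonine, the OAA proxy, shows M+3 > M+4 and is unchanged in
   TCA-cycle mutants); the estimators inherit this assumption and are wrong
   where a full oxidative TCA cycle supplies malate.
2. **PDH-derived acetyl-CoA is fully labeled (M+2).** Its carbons come from
   pyruvate C2–C3, which are substrate-derived.
3. **MCL-derived acetyl-CoA inherits exactly one CO₂-derived carbon.**
   Malate's C4 (and threonine's) is the carboxylation-derived carbon; the
   malyl-CoA cleavage hands the acetyl moiety one such carbon, so the MCL
   route yields M+1 with probability `1 − f` and M+2 with probability `f`.
   This atom mapping is asserted by the pathway chemistry rather than
   derived from a full atom-transition model.
4. **Citrate is the condensation of OAA and acetyl-CoA**, so its MID is
   their discrete convolution; and **threonine reports the OAA backbone
   unchanged** (4 carbons).

Under these assumptions `AcCoA(M+2) = p + (1 − p) f` and
`AcCoA(M+1) = (1 − p)(1 − f)`, and the estimator chain
(`estimate_accoa_mid()`, `estimate_flux_split()`,
`estimate_co2_fraction()`) inverts the forward model exactly — the test
suite checks the identity on a (p, f) grid to 1e-9.

### Why two of the five published balance equations are diagnostic only

The five equations describing this node are overdetermined: the citrate
deconvolution (two equations), the flux balances
`F_MCL·Mal(M+3) = AcCoA(M+1)` and `F_PDH + F_MCL·Mal(M+4) = AcCoA(M+2)`
(two more), and a fifth, `F_PDH/F_MCL = AcCoA(M+1)/AcCoA(M+2)`. The fifth
contradicts the other four and the route chemistry: a fully labeled PDH
route contributes to M+2, not M+1, so the M+1/M+2 ratio is *not* the
PDH/MCL ratio (at the WT condition it evaluates to ≈ 1.04, far from the
0.33/0.67 split the flux balances give). The package therefore solves the
deconvolution + flux-balance path and reports the fifth equation's implied
ratio only in `diagnostics`, alongside the residual of the redundant
citrate M+6 channel and any clipping events (negative intermediates are
clipped to zero, never silently).

Normalization is `F_PDH + F_MCL = 1`: the quantities are *relative*
contributions; raw unnormalized solutions are retained in the result.

No natural-abundance correction is applied anywhere; data that require it
should be corrected upstream, and the MID table reader is a clean
pass-through for pre-corrected data.

## 2. The FBA formulation

`solve_fba()` maximizes the biomass objective over
`S v = 0` (internal metabolites only; external/boundary species are
excluded from mass balance, the standard exchange convention), box bounds
per reaction, and the scenario's rows:

- **ratio constraints** as equalities `v_num − r·v_den = 0`;
- **order constraints** as `v_a − v_b ≥ 0`;
- **O₂/substrate floor** as `v_O2 − r·v_substrate ≥ 0` on uptake-direction
  magnitudes;
- **measured rates** (substrate uptake, formate secretion) as fixed fluxes
  — both bounds set to the measurement;
- **fixed fluxes / knockouts**: both bounds set to the value; for a
  reversible reaction a fixed 0 therefore zeroes both directions. A fixed
  value outside the reaction's own bounds is infeasible by construction,
  which is what terminates a robustness scan at a capacity limit.
- **maintenance**: NGAM raises the lower bound of the ATP-drain reaction;
  GAM is the ATP coefficient of the biomass equation, rewritten through the
  model's annotation hooks (`atp_metabolite`, `biomass_reaction`). Models
  whose supplement already bakes GAM into biomass simply override it per
  scenario through the same hook.
- **biomass composition**: glycogen and EPS dry-weight fractions are
  converted to molar biomass coefficients via annotated monomer masses
  (0.162 g/mmol hexose unit). Whether EPS belongs in the biomass equation
  or in a separate sink is not fixed by convention, so the packaged fixture
  provides both (the biomass hook is the default; a standalone `EPSt` sink
  exists for the other convention).

Derived outputs: O₂/substrate consumption ratio from the exchange fluxes,
and biomass yield `μ / (uptake × 0.03204)` in g biomass per g methanol
(methanol molar mass fixed at 32.04 g/mol).

### The LP solver

No LP backend is assumed: `lp_solve()` is a dense two-phase tableau
simplex with Bland's anti-cycling rule, adequate for the tens-of-reactions
problems this package targets and fully deterministic. Numerical choices:
pivot/feasibility tolerance 1e-9, phase-1 infeasibility threshold 1e-7,
mass-balance residual asserted `< 1e-6` on every returned optimum. All
variable bounds must be finite (FBA defaults are ±1000), which guarantees
the feasible region is a polytope and the brute-force vertex-enumeration
oracle used in the tests is exhaustive.

**Degeneracy.** FBA optima are routinely degenerate: only the objective
value and explicitly constrained fluxes are contract-stable. For a
canonical flux vector, `minimize_total_flux = TRUE` runs a lexicographic
second LP minimizing total absolute flux at the fixed optimal growth.

### Scans

`robustness_scan()` fixes one reaction's flux on a grid from 0 (default
step 0.1 mmol/(gcdw·h)), re-optimizes, stops at the first infeasible point
and refines the feasibility boundary by bisection to within step/10. By LP
theory the optimal value is a concave piecewise-linear function of the
fixed flux; the tests verify midpoint concavity on random models.
`ratio_sensitivity_scan()` and `atpm_grid()` re-solve per grid point;
growth is non-increasing in each maintenance parameter, which is asserted
against a hand-solved closed form on a toy network.

## 3. Scenarios and the ladder

`scenario_control()` encodes the measured methanol condition: uptake
19.3 mmol/(gcdw·h), formate secretion 1.82 mmol/(gcdw·h), glycogen 42% and
EPS 10% of dry weight, O₂/methanol ≥ 0.5, GAM 54.35 mmol/gcdw and NGAM
8.39 mmol/(gcdw·h). `scenario_ladder_table3()` nests four scenarios:
control; incomplete TCA (fumarase = 0, α-ketoglutarate dehydrogenase ≥
succinyl-CoA synthetase); MCL/PDH flux ratio = 3; ED/EMP flux ratio = 1.
Since each step only adds constraints, optimal growth is non-increasing
down the ladder — a property the tests check both on the fixture and on
random models.

Two deliberate choices here:

- The ladder's default MCL/PDH ratio is the *rounded* published constraint
  3, although the 13C split 0.67/0.33 ≈ 2.03; the discrepancy is a
  normalization/rounding choice in the source material that the package
  records rather than resolves. The pipeline (`run_all()`) passes the raw
  estimator ratio `raw_mcl/raw_pdh` unless a literal ratio is pinned, and
  logs which path was taken.
- "ED flux" and "EMP flux" are identified with the 6-phosphogluconate
  dehydratase (EDD) and fructose-bisphosphate-aldolase-lumped reactions;
  the ids are annotation hooks, so other identifications are configurable.

## 4. The packaged core fixture

`core_model_fixture()` (28 reactions) exists to exercise the engine at
desk scale. It uses lumped ATP/NADH currency metabolites, a lumped
electron-transport reaction, and an **illustrative biomass equation** whose
precursor coefficients were chosen once for plausible carbon totals
(≈ 0.58 g C per g biomass including the glycogen and EPS shares); the real
genome-scale biomass equation lives in the model supplement and is consumed
as data when supplied. Consequences: the fixture's ladder values
demonstrate monotone constraint tightening, not genome-scale predictions,
and nothing in the tests asserts otherwise. ED yields two fewer ATP per
hexose than EMP in the fixture, so ratio scans have the qualitatively
correct direction.

## 5. Synthetic data: what a green test establishes

The generators (`synth_spec()`, `gen_label_data()`, `gen_pool_data()`,
`gen_growth_curves()`) are pure functions of their spec, seed included.

- **Labeling**: the forward model above plus independent truncated-Gaussian
  noise per mass channel (sd 0.01 by default) and renormalization. This
  emulates measurement noise on MID fractions; it does **not** emulate
  natural-abundance effects, derivatization artifacts, or any deviation
  from the four model assumptions — so recovery tests establish estimator
  correctness and noise robustness, not robustness to model
  misspecification.
- **Pools**: lognormal replicates (default CV 20%, n = 3) around condition
  means separated by configurable fold changes. Defaults: KDPG ×60 (the ED
  diagnostic and the largest reported shift), other increased pools
  (G6P, F6P, FBP, citrate, 6PG) ×4, decreased pools (PEP, 2PG+3PG, R5P)
  ×0.3, TCA pools ×1. The ×4 and ×0.3 values are this package's choices of
  a realistic moderate effect where no magnitude is reported; only the
  KDPG magnitude is anchored. Internal-standard and biomass factors are
  drawn per sample so the normalization path is genuinely exercised.
- **Growth**: exponential OD series from a 0.01 starting OD at
  0.205 h⁻¹ with 2% multiplicative noise.

The volcano stage uses Welch's unequal-variance t test on log₁₀ normalized
abundances — a robust default for small-n lognormal pool data; the test
choice is recorded in the output's attributes. Raw p-values are the
default (mirroring how such volcano plots are usually drawn), with opt-in
Benjamini–Hochberg adjustment; the fold-change/significance cutoffs
(2-fold, p < 0.05) are explicit arguments, since the exact cutoffs behind
published category colorings are generally unstated.

## 6. Degenerate inputs and error behavior

- `normalize_mid()` on an all-zero vector, and the estimators when
  `OAA(M+3)` or `Mal(M+3)` ≈ 0 (nothing to deconvolve against) or when both
  raw contributions vanish: explicit "unidentifiable"/degenerate errors,
  not NaNs.
- Negative deconvolution intermediates under noise: clipped to zero with a
  `clipped` flag that propagates into `analyze_dataset()` diagnostics.
- Model validation returns findings (severity + message) rather than
  throwing, so a model can be inspected; `read_model()` refuses models
  with error-level findings.
- Pipeline stages are isolated: a failed stage is reported in the run
  summary, dependent stages are skipped, independent stages still run, and
  the CLI exit code is nonzero iff any stage failed.

## 7. Known limitations

- No EMU/cumomer ¹³C-MFA: the estimators cover exactly the C3–C4/AcCoA
  node identifiable from steady-state MIDs; upstream pathway splits are
  structurally unidentifiable in this labeling design.
- The simplex is dense and unscaled — right for desk-scale and
  genome-scale-supplement models (hundreds of reactions at most), not for
  community-scale LPs.
- Reaction-table round-trips are exact for models following the `_e`
  external-naming convention; annotations travel only in the JSON schema.
- The fixture's quantitative outputs are illustrative by design (lumped
  cofactors, invented biomass); genome-scale conclusions require loading
  the corresponding published model as data.
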