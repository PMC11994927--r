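---
title: "Model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgltsim)
```

sgltsim couples a whole-body physiologically based pharmacokinetic (PBPK)
model of four SGLT2 inhibitors to a mechanistic model of renal-tubule glucose
reabsorption, and layers population simulation, validation statistics,
synthetic-data generation, and a dosage-regimen scenario runner on top. This
vignette documents the model structure, the calibration choices, and the
numerical settings; it makes no empirical claims beyond what the package
itself computes.

## Whole-body PBPK model

Each drug is described by a perfusion-limited whole-body model
(`build_pbpk_model()`, `simulate_pk()`): a gut-lumen depot with first-order
absorption into gut tissue, a portal connection from gut to liver, and
parallel perfusion of the remaining organs from a central blood compartment.
States are drug amounts; doses enter the gut lumen as solver events, so
repeat regimens are exact. Elimination is hepatic intrinsic clearance (scaled
by the unbound fraction) plus drug-specific renal clearance — either a fixed
renal plasma clearance or a GFR fraction. Canagliflozin additionally carries
a saturable P-glycoprotein efflux pathway in gut tissue.

Tissue-to-plasma partition coefficients come from the Rodgers & Rowland
neutral-species equations (`partition_coefficients()`), using the shipped
tissue-composition table (water fractions, neutral lipid and phospholipid
fractions, albumin ratios). Adipose uses a vegetable-oil:water log-partition
derived from logP. Physiology (organ volumes, blood flows, cardiac output,
GFR) is a reference adult scaled allometrically by body weight.

A closed-form check is built in: `onecomp_model()` constructs a degenerate
one-compartment model whose simulation must match the analytic oral
one-compartment solution, which the test suite verifies to 0.1%.

## Renal tubule and urinary glucose excretion

The tubule model (`simulate_uge()`) has three segments: a proximal segment
where both SGLT2 and SGLT1 reabsorb glucose by Michaelis–Menten kinetics, a
downstream transit segment, and the final urine. Drug inhibits reabsorption
through two switchable mechanisms (`use_ki`, `use_occupancy` in the config):

- **Competitive inhibition**: luminal drug raises the apparent Km by
  `(1 + D/Ki)`.
- **Slow-binding occupancy**: a fraction of transporters is occupied, with
  association rate `kon = koff/Kd` and drug-specific dissociation rates; the
  occupied fraction is unavailable for transport.

Luminal drug concentration defaults to the unbound plasma concentration
(`luminal_model: plasma_unbound`); an alternative derives it from the renal
excretion flux divided by tubular flow (`excretion_flux`).

### Calibration

Transporter amounts are calibrated (`calibrate_transporter_amounts()`) to two
physiological targets at reference GFR 105 mL/min:

1. **Maximal reabsorption capacity** Tm = 375 mg/min: the two Vmax values sum
   to Tm exactly.
2. **Renal glucose threshold** at 10 mmol/L plasma glucose, *defined as the
   plasma glucose at which drug-free steady-state urinary spill equals
   2 g/day*. A strict zero-spill threshold is not attainable in a
   Michaelis–Menten model (reabsorption saturates smoothly, so some spill
   always exists); the 2 g/day operational definition matches how thresholds
   are measured clinically and pins down the SGLT2/SGLT1 capacity split in
   closed form. The resulting split is SGLT2-dominant (about 79% of capacity)
   and is invariant to GFR, because both Tm and the spill target scale
   linearly with GFR.

The proximal segment is assigned 95% of fractional reabsorption under normal
conditions, consistent with the dominant proximal role of SGLT2. With this
calibration, drug-free simulation at 5.5 mmol/L produces a essentially
glucose-free urine (< 1 g/day), and complete transporter inhibition excretes
the filtered load (verified to 2% in the tests; 217.9 g/24 h at GFR
105 mL/min and 8 mmol/L).

### Maintenance dosing

The scenario runner simulates one dosing day of ongoing once-daily therapy.
Because drug–transporter dissociation is slow for this class (half-lives far
exceeding the dosing interval), occupancy does not reset between doses;
`simulate_uge(..., occupancy0 = "steady_state")` initializes occupancy at its
long-run periodic level computed from the day-average luminal concentration.
Plasma-side accumulation between doses is comparatively small and is
neglected uniformly across drugs.

## Virtual populations and CKD

`generate_population()` draws subjects with lognormal organ-size variability,
sex-specific anthropometry, and stage-specific GFR (means 105/75/45/15
mL/min for normal/mild/moderate/severe, lognormal with configurable CV).
Renal impairment also scales transporter capacity: moderate CKD retains 85%
of SGLT1 and 40% of SGLT2 capacity, severe CKD 50% and 10%. Per-subject
cardiac output always equals the sum of organ flows.

## Validation statistics

`fold_error()`, `mpe()`, `afe()`, `aafe()`, and `band_fraction()` implement
the standard prediction-accuracy metrics. Band membership is decided on
*unrounded* ratios; two-decimal rounding is a display convention only
(`round_half_up`, half-away-from-zero as in printed tables). The package
ships two paired observed/predicted PK tables (healthy/normal-function and
renal-impairment studies; 56 and 42 values) used by
`validate_against_tables()`.

## Numerical settings

ODEs are solved with `deSolve::lsoda`, relative tolerance 1e-6 and absolute
tolerance 1e-8 (1e-6 μmol for the tubule model), output step 0.1 h. The test
suite checks PBPK mass balance to 0.1% and tubule glucose conservation to
0.5% at these settings.

## Limitations

- Partitioning uses neutral-species Rodgers & Rowland equations only; no
  ionized-species or transporter-mediated tissue uptake terms.
- The threshold calibration is an operational 2 g/day definition, not a fit
  to titration data.
- Plasma PK accumulation at steady state is neglected in the maintenance
  scenario (occupancy carry-over is modeled; concentration carry-over is
  not).
- The scenario grid's absolute UGE values depend on this package's own
  physiology and calibration; only qualitative regimen orderings should be
  compared across platforms.

## A worked example

```{r, eval = FALSE}
pk <- simulate_pk(build_pbpk_model(sglt_drug("dapagliflozin")),
                  dose_regimen(10))
glance(pk)
uge <- simulate_uge(pk, occupancy0 = "steady_state")
glance(uge)
autoplot(uge)
```
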