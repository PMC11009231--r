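---
title: "Projecting forest biomass carbon with age-cohort demography, harvest and wood products"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting forest biomass carbon with age-cohort demography, harvest and wood products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestcarbon)
```

## The problem

Long-horizon projections of a forest estate's biomass carbon sink are
dominated by three things that simple stock–age extrapolations miss:
wood harvest (which removes carbon but also rejuvenates stands), the
true age-accrual of disturbed mixed stands (which is well below one year
per year), and where and with which species new forests are planted.
`forestcarbon` implements both sides of that argument in one package: an
annual age-cohort bookkeeping simulator in which those processes are
explicit, and a statistical growth-curve counterpart in which they are
deliberately absent. Comparing the two on the same synthetic landscape
reproduces the qualitative behaviour of interest — the statistical model
peaks early, the process model peaks one to three decades later — at
desk scale and with complete ground truth.

## The cohort model

The demographic unit is a 1-km² cohort: one species, one age, one carbon
density (Mg C/ha), a management class (timber/non-timber), an origin
(planted/natural) and a mixed-stand flag. Cohorts live inside 0.5° grid
cells which also carry a province label and an available
grassland/shrubland budget for future planting. One simulated year
applies, in order:

1. **Growth.** Each cohort's density increases by the increment of its
   species stock–age curve, modulated by the age factor (below) and a
   scenario growth modifier.
2. **Mortality.** Each cohort independently dies with probability
   `mortality_rate × multiplier` (baseline 0.084 %/yr; multipliers 2–5
   emulate climate-stress scenarios). A dying cohort's carbon is emitted
   to the atmosphere and the stand regenerates in place at age 0 with the
   same species and class.
3. **Harvest** (off in experiment group 3). Only mature timber cohorts
   are eligible: age ≥ `Age2` plus any active rotation extension. Cuts
   proceed oldest-first and are capped per (cell, species, year) by the
   allowable cut — timber units ÷ rotation, with fractional allowance
   carried over but capped below one unit so the long-run cut rate equals
   area/rotation exactly. Harvested cohorts are replanted in place;
   removed carbon becomes wood-product inflow.
4. **Management** (group 2 only). Species replacement converts flagged
   *non-timber* cohorts to their indigenous targets at age 0 (standing
   carbon is routed to the product pool); rotation extension adds five
   years to a species' rotation once its key year has passed. Both honor
   the configured implementation delay.
5. **Age accrual.** Timber and pure non-timber stands age +1 yr exactly.
   Mixed non-timber stands age by a draw from N(I_ave, σ²) truncated at
   zero — the survey-derived accrual that absorbs within-stand mortality,
   regeneration and natural growth.
6. **Forestation** (off in group 4). The provincial plan for the year is
   converted to whole 1-km² planting attempts (fractional areas carry
   over), deployed into cells by descending habitat suitability, each
   cell planted with its most suitable species. An attempt establishes
   with probability `survival_rate` (0.47 baseline, 0.85 improved);
   established units become age-0 cohorts and consume the cell's
   grassland/shrubland budget; shortfalls are logged, never fatal.

A strict annual mass balance — Δstock = growth − mortality − harvest −
replacement, to 1e-9 relative — is checked every year and any violation
aborts the run.

### The age factor

Production capacity depends on cohort age through a logistic factor

$$F_{age}(b) = 1 - a\,\frac{1}{1 + e^{(3/Age1)(b - Age1)}}$$

ranging from $1-a$ for the youngest stands to 1 for old ones, with
midpoint $1 - a/2$ at $b = Age1$. The growth kernel is

$$\Delta C = [C(b+1) - C(b)] \cdot \frac{F_{age}(b)}{F_{age}(Age2)}
\cdot \text{modifier}.$$

Normalizing by $F_{age}(Age2)$ is the central emulation choice: the
stock–age curve already encodes the mean age trajectory of growth, so an
un-normalized factor would double-count age. With the normalization, the
factor expresses *departures* of a cohort's capacity from that of a
mature stand, which is what tracking cohorts (rather than a single mean
stand age per cell) adds. `a` defaults to 0.05 and can be calibrated per
species with `calibrate_age_factor_a()`, a bisection on $a \in [0, 0.95]$
matching the simulator's first-year species sink to the statistical
model's within 0.1 % (falling back to 0.05 with a warning when no root is
bracketed).

### Key years and interventions

A species' *key year* is the first year its annual biomass sink is
non-positive and stays so for `key_year_window` (default 3) consecutive
years — the sink has leveled off, and continued cutting at the old
rotation makes the species a net source. Detection is necessarily causal:
a key year K is only known at K + window − 1, so a delayed extension
activates at max(K + delay, detection + 1). The window trades
responsiveness against robustness to single bad years (mortality spikes,
lumpy cut years); 3 years filters isolated blips without materially
delaying genuine collapses.

### Rotation phase at start

Allowable-cut carryovers are initialized uniformly in [0, 1) per
(cell, species) from a seeded sub-stream. A forest estate entering the
simulation is mid-rotation everywhere, not phase-aligned: zero-initial
carryovers would postpone the first cut of a sparse species by up to a
full rotation and synchronize identical cells into simultaneous cut
years, which are artifacts of the bookkeeping rather than properties of
the system.

## Wood products

Harvested and replaced carbon enters a three-category IPCC Tier-2 pool
(sawn wood, wood-based panels, paper/paperboard; half-lives 35, 25 and 2
years) with the annual first-order recursion

$$C_j(i+1) = e^{-k_j} C_j(i) + \frac{1 - e^{-k_j}}{k_j}\,
\text{Inflow}_j(i), \qquad k_j = \ln 2 / HL_j,$$

implemented with `expm1` so the lossless limit $k \to 0$ is exact. The
recursion has the closed form $C(n) = C_0 e^{-kn} + (I/k)(1-e^{-kn})$
under constant inflow — an independent oracle the tests exercise to
1e-12 — and the steady state $I/k$. Because the pool's historical
spin-up (inflows since 1900) is out of scope, the 2020 initial pool
defaults to the steady state implied by the run's first-decade mean
inflow; this is configurable (`C0`), and pool comparisons across
scenarios difference away most of its influence. Inflow shares follow a
ratio series: `fixed` holds the 2020 shares (61.5 % paper/paperboard,
25.0 % sawn wood, 13.5 % panels); `trending` shifts 0.4 %/yr from paper
to sawn wood until 2060 and holds thereafter, continuing the pre-2020
drift toward longer-lived products.

## The statistical counterpart

`fit_growth_ensemble()` fits carbon stock ~ stand age per stratum with
three theoretical growth equations in their standard forestry forms:

* Richards: $A(1-e^{-kt})^m$
* Korf: $A e^{-k t^{-m}}$
* Hossfeld: $t^c/(b + t^c/A)$

Fitting is Levenberg–Marquardt nonlinear least squares with positivity
bounds, tight tolerances, and log-linearised starting values
($A_0 = 1.2\max y$; rate from a linearising regression; shape started at
1). Validation splits each stratum's plots into ten parts; each part is
held out once while the model trains on the other nine, and held-out R²
selects the best candidate per family (ties: lower validation RMSE, then
lower part index). Predictions average the three winners with weights
proportional to their validation R² (negatives clamped to zero and
dropped). The reading of the validation design as ten-fold (train on
nine parts, validate on the held-out tenth, ten times) is the default; a
`ninefold` switch holds out only the first nine parts for users who
prefer the alternative reading. Inventory stock–age references use
`fit_stock_age()`, which fits both logistic and logarithmic forms and
adopts the higher R².

`statistical_projection()` then ages every stratum +1 yr/yr along its
ensemble curve, with new plantations entering at age 0 scaled by the
survival rate. No harvest, mortality or climate terms appear — a closed,
aging forest under this model saturates, so its sink inevitably peaks
early and declines. That early peak, contrasted with the cohort
simulator's later one, is the package's central comparison.

## Synthetic data and the packaged landscape

All inputs are generated. `gen_species_table()` draws species constants
in realistic ranges (harvest ages 11–101 yr; carbon fractions 0.45–0.55;
the baseline mortality and `a = 0.05` fixed), `gen_nfi_plots()` places
plots exactly on their species' ground-truth curve times multiplicative
lognormal noise and decomposes tree volumes so that the inventory
conversion chain reproduces the plot density exactly, and
`gen_landscape()`, `gen_forestation_plan()`, `gen_suitability_maps()` and
`gen_product_ratio_series()` build the remaining inputs. Each generator
derives its own RNG sub-stream by hashing (name, seed), so adding or
re-running one generator never perturbs another's output. The
volume–biomass step is the continuous biomass-expansion-factor form,
linear in stand volume per hectare — applying it at stand level (summed
tree volume ÷ area) rather than per tree is a documented assumption; it
makes the chain exactly invertible for the generator. Survey quantities
that are not published at species level (age-increment σ, the I_ave
table) carry synthetic defaults and are labelled as such.

The packaged study landscape (`example_inputs()`) is deterministic and
structured rather than random, because the end-to-end properties of
interest are properties of a *composition*: 50 cells each holding a
staggered-rotation pine timber block (rotation 31 yr), a just-mature fir
timber block entering its harvest wave (rotation 45 yr), a dominant
young mixed-conifer non-timber block (ages 5–15, survey accrual
0.6 yr/yr), two flagged short-rotation eucalypt units whose indigenous
replacement is a slow-growing spruce, and one old spruce unit. Species
demography is self-consistent: Richards curves use m = 3 and
k = ln 3/Age1, placing the instantaneous growth peak exactly at Age1 and
the mean-rate peak (the harvest-age definition) at ≈ 1.74·Age1. On this
landscape the forced no-harvest, +1 yr/yr run peaks in the early 2030s
while the full process run peaks in the early 2050s; the fir block's key
year is detected immediately and the pine block's within a few years,
so the rotation-extension pathway is exercised from the start.

What the generator does *not* emulate matters for interpretation: there
is no climate or CO₂ forcing (scenario labels map only to growth and
mortality modifiers), no spatial autocorrelation in suitability or
mortality, no age-dependent mortality, and plot noise is purely
multiplicative-lognormal. Passing tests therefore demonstrate internal
correctness and the demographic mechanisms, not predictive skill on real
inventories.

## Numerical choices

* Nonlinear fits: `minpack.lm::nlsLM`, max 500 iterations, `ftol = ptol
  = 1e-15`, lower bounds 1e-8; noise-free data are recovered to ≤1e-6
  relative, and degenerate (constant) data yield a flagged fit with
  R² ≤ 0 that ensembles exclude.
* Tier-2 retention factor computed as `-expm1(-k)/k` to avoid
  cancellation for long half-lives.
* Harvest ties (equal ages) break by cohort creation index; argmax ties
  in peak detection break by earliest year.
* Peak detection smooths annual sinks with a centered 5-yr moving
  average (configurable) before the argmax, since annual sinks are
  Monte-Carlo lumpy while the quantities of interest are decadal.
* Fractional planting and cutting areas use floor-with-carryover so
  long-run rates are exact; cut carryover is capped below one unit so a
  backlog can never exceed the annual allowable cut by more than one.
* Per-cell sink density converts Mg per cell-year over the cell's
  forested area (units × 1 km²), i.e. 1 Mg/km² = 1 g C m⁻².
* Problem sizes used by the shipped tests: the end-to-end suite runs a
  50-cell, 5-species, 81-year landscape (≈1050–1200 cohorts), seven
  scenario runs in total; the mortality and survival rates are estimated
  at n = 2,000,000 and n = 10,000 Bernoulli trials. These sizes give
  three-binomial-SE resolution on the rates and stable decadal peak
  years while keeping a full run in seconds.

## Design decisions on open points

* **Replacement scope.** Species replacement converts non-timber cohorts
  only, matching the management practice it represents (timber stands
  are managed through the rotation; replacing them would also let the
  replacements re-enter the cutting pool, coupling the two
  interventions).
* **Harvest residue.** 100 % of harvested and replaced biomass carbon
  enters the product pool; no slash fraction. This is the simplest
  defensible default and is isolated in one place (`run_simulation`'s
  inflow line) should a split be wanted.
* **Rotation extension scope.** The extension applies per species, from
  that species' own key year (plus delay), not estate-wide.
* **SSP emulation.** Scenario labels carry only (growth modifier,
  mortality multiplier) pairs. No climate fields exist anywhere in the
  package.
* **Gridded output format.** Per-cell sink maps are written as long CSV
  rasters with row/col indices and lat/lon labels; the grid is abstract
  (row-major, 0-based) and no geodesy is implied.

## Limitations

Soil, litter and dead-wood pools are excluded by construction (the stock
is live biomass only). Mortality is stand-replacing and age-independent.
The product pool does not feed back on anything. The statistical model
shares the simulator's stratification assumption. And all quantitative
results shipped with the package are properties of the synthetic study
conditions — the package's claims about real forests are qualitative
(ordering and timing), not numeric.
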