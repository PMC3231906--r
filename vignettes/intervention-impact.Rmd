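---
title: "Modelling child mortality impact of intervention scale-up"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling child mortality impact of intervention scale-up}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(livesaved)
```

## The model

`livesaved` estimates how scaling up the coverage of maternal and child
health interventions changes cause-specific mortality among children under
five. Children are followed through five age bands — 0 months, 1–5, 6–11,
12–23 and 24–59 months — each with its own all-cause mortality risk and
cause-of-death distribution. Neonatal causes (birth asphyxia, prematurity,
sepsis/pneumonia, congenital anomalies, tetanus, diarrhoea) act only in the
first band; post-neonatal causes (diarrhoea, pneumonia, meningitis, measles,
malaria, pertussis, injury) act in the other four. A residual cause, "all
other causes", absorbs the remainder of each band's distribution so cause
fractions always sum to one; it can never be targeted. AIDS is carried in
the enumeration but inactive, since paediatric AIDS mortality depends on
adult HIV prevalence and belongs to a different modelling layer.

The model is deliberately *static about secular trends*: mortality only
changes because coverage changes. Holding every trajectory flat reproduces
baseline mortality in every projection year, which is both a design
principle and a property test of the implementation.

## Direct effects

The proportional reduction in mortality from cause $j$ in age band $a$ when
intervention $i$ moves from baseline coverage $C_0$ to coverage $C_t$ is

$$R_{i,j,a,t} = \frac{I_{i,j,a}\,(C_{t} - C_{0})}{1 - I_{i,j,a} C_{0}}
  \times AF_{i,j,a},$$

where $I$ is effectiveness among the newly covered and $AF$ the affected
fraction — the share of the cause's deaths whose mechanism the intervention
can touch (0.95 for oral rehydration salts against diarrhoea: 5% of
diarrhoea deaths are of forms ORS cannot prevent). The denominator removes
the impact already embedded in baseline mortality; when $I C_0 = 1$ there
is no residual mortality left and the function refuses to divide. Coverage
declines produce negative reductions, which propagate through composition
but are excluded from attribution (see below).

Several interventions acting on one cause compose on *residual* mortality:

$$R_{j,a,t} = 1 - \prod_i (1 - R_{i,j,a,t}),$$

which is order-free. All-cause impact is the cause-fraction weighted sum
$\sum_j R_{j,a,t} f_{j,a}$.

### Attribution by timing

Credit for deaths averted depends on when an intervention acts:
peri-conceptual, pregnancy, childbirth, vaccines, preventive-after-birth,
curative-after-birth, in that order. The earliest non-empty tier is credited
as if it acted on the whole cause-specific burden; each later tier only on
what remained after all earlier tiers. Within a tier, interventions share
proportionally to their isolated reductions, $R_i / \sum_i R_i$. With $T$
the combined reduction of all tiers and $S_k$ the survival factor
$\prod(1-R_i)$ of tier $k$, tier $k$'s block of the total is
$\big(\prod_{k' < k} S_{k'}\big)(1 - S_k)/T$; blocks telescope to 1, so
shares always sum to one whenever $T > 0$. With a single tier this reduces
exactly to proportional sharing. When the total reduction is zero all
shares are defined as zero; negative isolated reductions are excluded with
a diagnostic, since attribution of mortality *increases* has no meaningful
definition in this calculus.

## Herd effects

Vaccines and bednets can protect the uncovered once population coverage is
high. Herd protection is a phenomenological piecewise-linear curve of
coverage: zero below a lower threshold, maximal above an upper threshold,
linear between. The measles default is (0.90, 0.95, 1.0). The incremental
herd protection of a coverage change is
$H = (HE_t - HE_0)/(1 - HE_0)$, and it acts on the mortality remaining
after the direct effect: $hR = R + H(1-R)$ — exactly residual-mortality
composition of the two components, a property the tests verify. The
herd-adjusted $hR$ replaces $R$ in composition and attribution. Only the
measles curve is anchored in the literature the model follows; other herd
curves are user configuration, defaulting to "no herd effect".

## Intermediate outcomes

Nutrition and environmental interventions act through risk factors rather
than directly on a cause of death.

**Two-status odds decomposition.** A risk factor splits the population
into a risky and a non-risky status (e.g. children without vs with
preventive zinc). Given the odds ratio $OR$, the risky fraction $F_k$ and
the overall prevalence $P$, the status-specific prevalences solve

$$P_k = \frac{OR \cdot P_1}{1 - P_1 + OR \cdot P_1}, \qquad
  F_k P_k + (1-F_k) P_1 = P.$$

Substituting the first relation into the second yields a quadratic in
$P_1$; the implementation uses the closed form and selects the root in
$(0,1)$ (the product of the roots is negative for $OR > 1$, so the
admissible root is unique; for $OR < 1$ both roots are checked). A
residual guard of $10^{-10}$ on both defining relations protects against
numerical drift, and the test suite checks the closed form against an
independent bisection oracle over randomised $(OR, F, P)$ grids. The odds
formulation — rather than relative risks — guarantees status-specific
probabilities never leave $(0,1)$.

Scale-up moves children between statuses while the status-specific
prevalences stay fixed; the projected prevalence is the re-weighted
mixture, and its proportional decline $(P_0 - P_t)/P_0$ is the risk
factor's isolated reduction.

**Four-status complementary feeding.** Food security (above/below the
poverty line) crossed with promotion reach gives four states with three
odds ratios relative to the least risky state (food secure, promoted).
Substituting the three odds relations into the four-term mixture constraint
leaves one strictly increasing equation in the reference prevalence, solved
with `stats::uniroot` at tolerance $10^{-15}$ on the bracket
$(\varepsilon, 1-\varepsilon)$. The same root solves the equivalent quartic
polynomial; the bracketed form avoids quartic branch selection and is
verified by residual substitution and by degeneration to the two-status
closed form when two state fractions are zero. State fractions are built
from the food-secure fraction $q$ and promotion coverage $C$ as
$(qC,\, q(1-C),\, (1-q)C,\, (1-q)(1-C))$.

**Diarrhoea incidence.** The odds ratio of stunting is per-episode, so the
population-average odds ratio is $OR^{\,i}$ with $i$ the mean episodes per
child-year. An incidence decline from $i_0$ to $i_t$ is represented as
moving a fraction $1 - i_t/i_0$ of children from "$i_0$ episodes" to "no
diarrhoea", which plugs straight into the two-status machinery. Incidence
itself is reduced by water and sanitation interventions with the same
coverage calculus used for mortality. Incidence increases are rejected:
the mapping is defined for scale-ups.

**Breastfeeding.** Practice is categorical (exclusive, predominant,
partial, none) per age band, with promotion modelled by the odds of
improved practice without promotion versus with it. The improved-vs-not
dichotomy runs through the two-status solve; categories inside and outside
the improved set are then rescaled proportionally. Which categories count
as "improved" is per-band configuration (exclusive breastfeeding under six
months; any breastfeeding at 6–11 months). Breastfeeding is deliberately
*not* routed through diarrhoea incidence: its mortality relative risks are
combined values that already absorb the incidence pathway, and routing it
twice would double-count.

**Stunting cohort progression.** Five determinants drive stunting:
the carried risk factor (IUGR for neonates, previous-band stunting for
older bands), complementary feeding, diarrhoea episodes and zinc
supplementation. Bands are processed in age order within each projection
year; each determinant's isolated decline is computed in isolation and the
declines are composed on remaining prevalence — the same residual
composition used for mortality, hence order-free. The carry-over and
IUGR-to-stunting odds ratios are required configuration: only the zinc
odds ratio (1.18) is anchored in the published effectiveness reviews, and
inventing defaults for the others would masquerade as evidence.

## From risk factors to mortality

Height-for-age is taken as normally distributed with standard deviation
one on the international standard scale. A stunting prevalence $p$ places
the population curve by shifting the standard normal so that the mass
below the $-2$ SD cut equals $p$ (shift $m = -2 - \Phi^{-1}(p)$); severe
wasting anchors at $-3$ SD instead. Occupancy of the four bands (below
$-3$, $-3$ to $-2$, $-2$ to $-1$, above $-1$) is read off as successive
differences of $\Phi$. Band arithmetic is exact to $10^{-12}$: the two
lowest bands always recover the input prevalence, and mass is conserved.
Prevalences of exactly 0 or 1 are rejected (the shift would be infinite).

Each band carries a cause- and age-specific relative risk, reference band
$RR = 1$. The average relative risk $ARR_t = \sum_s Z_{s,t} RR_s$ converts
occupancy to mortality, and the mortality reduction is
$R = 1 - ARR_t/ARR_0$ — zero when the distribution is unchanged, negative
if the profile worsens. IUGR works the same way with two states instead of
four bands; breastfeeding with its four categories. Supplemental feeding
moves a configured split of treated severely wasted children into the
three better bands (some stay below $-3$ SD: treatment is not always
effective), conserving mass to $10^{-12}$.

These risk-factor routes enter mortality composition as
*pseudo-interventions* (stunting, wasting, IUGR, breastfeeding) in the
preventive tier. Their attributed share of deaths averted is re-split over
the real interventions that moved the risk factor, proportionally to each
determinant's isolated prevalence decline; carried determinants pass their
weight down the chain of bands (and from the IUGR interventions into the
neonatal band). This makes attribution recursive but conservative: the
attributed deaths averted per (cause, band, year) cell sum to the cell
total to $10^{-9}$ wherever any intervention acts.

## The cohort engine

A simplified cohort-component engine stands in for a full demographic
projection. Each annual birth cohort lives its three infant bands in the
year of birth, the 12–23 month band the following year, and the 24–59
month band spread uniformly (one third per year) over the next three.
Within a band slice, cause-specific death risks are the band risk times
cause fraction times slice fraction, scaled by $(1-R)$ for that year; the
survivors carry forward. Running the engine at baseline coverage and at
scenario coverage and differencing gives deaths averted; survivors spill
over, so averting neonatal deaths increases the entrants — and hence the
deaths — of later bands. A consequence worth knowing: per-cell deaths
averted can be *negative* for untargeted causes (children saved from
diarrhoea later die of something else). Totals over all causes and years
remain monotone: scale-up never increases total deaths.

Years before the baseline are warmed up with baseline-year births and
baseline mortality so the ledger is complete — and exactly stationary
under flat coverage — from the first projection year. Mortality risks are
per-child probabilities over the band's duration, not hazard rates.
Synthetic-cohort rates per 1000 births are reported per year: the neonatal
rate is the 0m band risk, the infant rate $1 - \prod(1-q_b)$ over the
first three bands, the under-five rate the product over all five.

## The synthetic-data generator

`demo_scenario()` is the canonical worked-example bundle: ORS
($I=0.93$, $AF=0.95$, coverage 25→50%), zinc for treatment (isolated
reduction 0.25), rotavirus vaccine (0.306, vaccines tier), measles vaccine
($I=0.85$ with the 0.90/0.95/1.0 herd curve, 75→97%), preventive zinc
(stunting OR 1.18, 25→50%), hand washing cutting diarrhoea incidence from
3 to 2 episodes per year at full scale-up, plus complementary feeding,
supplemental feeding, breastfeeding promotion and an IUGR-reducing
pregnancy intervention. Cause-of-death fractions, the non-anchored
relative risks and the carry-over odds ratios are synthetic values chosen
to be typical of high-burden settings (e.g. diarrhoea at 20% of
post-neonatal deaths, severe-stunting diarrhoea RR 4.6 at 1–5 months);
they are demo data, not country estimates.

`random_country_scenario(seed)` draws internally consistent bundles —
neonatal risk in (0.02, 0.04), post-neonatal band risks in (0.005, 0.02),
Dirichlet-style cause fractions with a 15–30% residual, monotone coverage
trajectories, stunting prevalences rising with age in (0.15, 0.45) — with
a locally seeded generator that restores the session RNG state, so the
same seed is byte-identical and generation never perturbs user code. What
these bundles do *not* emulate: secular mortality trends, seasonality,
correlated coverage across interventions, measurement error in baseline
inputs, or any real country's default database. Passing tests on them
demonstrates the calculus and its conservation laws, not country-level
predictive validity.

Problem sizes used in the tests were chosen to keep each property loop
readable and fast: odds-solver grids of 40–60 random parameter triples,
ledgers of 5–10 interventions over 4–6 years, and one full 20-intervention,
15-year synthetic country for the end-to-end run, which completes in well
under ten seconds on a single core.

## Numerical choices and degenerate inputs

* Quadratic root selection in the two-status solve as described above;
  residual guard $10^{-10}$.
* `uniroot` tolerance $10^{-15}$ for the four-status solve; mixture
  residual re-checked after solving.
* Band arithmetic tolerance $10^{-12}$; cause-fraction normalisation
  tolerance $10^{-9}$.
* Saturated baselines ($IC_0 = 1$), fully herd-protected baselines
  ($HE_0 = 1$), zero baseline prevalence and degenerate prevalences 0/1
  raise errors rather than returning infinities.
* Exact no-change guards skip risk-factor routes whose coverage did not
  move, so flat scenarios produce *exactly* zero impact rather than
  solver-noise residues.
* Ties within an attribution tier need no tie-breaking: proportional
  sharing is symmetric.

## Scope and limitations

Maternal mortality, stillbirths, AIDS mortality, costing, uncertainty
intervals and full demographic projection (fertility feedback, migration,
population pyramids) are out of scope. The scenario bundle is a single
JSON document; report tables are tidy CSVs. Effectiveness values, affected
fractions and odds ratios are inputs — the package ships no country
default database, and the worked-example values beyond the published
anchors are synthetic.
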