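---
title: "The birdstrike risk model: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The birdstrike risk model: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(birdstrikeR)
```

## The problem and the model

Birdstrike risk at an airport is heterogeneous across species: a flock of
geese commuting through the approach corridor and a solitary warbler
foraging 8 km away pose incomparably different hazards. Where strike
databases are too sparse to estimate per-species strike probabilities
directly, risk must be scored from what a standard wildlife survey
measures. `birdstrikeR` implements such a scoring model in the ISO 31000
risk-assessment idiom: *likelihood* (how likely is an encounter with an
aircraft) and *severity* (how bad would it be), combined through a banded
risk matrix into an ordinal danger level used to prioritise management.

Likelihood is built from three encounter-geometry traits, each mapped to
a small coefficient set by step functions:

* **Cluster coefficient** $C \in \{0, 0.2, 0.5, 1\}$ from flock size
  ($<3$, $3$–$19$, $20$–$99$, $\geq 100$). Dense flocks manoeuvre poorly
  and raise the chance of multiple impacts.
* **Flight-height coefficient** $F \in \{0.1, 0.5, 1\}$, peaked at the
  30–50 m band around the 40 m critical altitude where departing and
  arriving aircraft concentrate; the coefficient decays symmetrically in
  band value to 0.5 (5–30 m, 50–100 m) and 0.1 ($\leq 5$ m, $>100$ m).
  All band upper boundaries are inclusive: $H = 50$ scores 1,
  $H = 100$ scores 0.5.
* **Activity-range coefficient** $A \in \{0.3, 0.6, 0.9\}$ by the zone
  nearest the flight area in which the species was recorded: A (airport
  grounds) 0.9, B (within 4 km) 0.6, C (4–8 km) 0.3. Most strikes happen
  during take-off, climb, approach and landing, so proximity dominates.

Severity is built from two normalized community-relative quantities:
**comparative number** $CN$ (species total count over the community
maximum) and **comparative weight** $CW$ (species total biomass over the
community maximum), both in $[0, 1]$. Then

$$\mathrm{Likelihood} = (C + F + A) \times 100/3, \qquad
  \mathrm{Severity} = (CN + CW) \times 100/2 .$$

Both scores are banded into five ordinal classes (likelihood thresholds
15/30/50/70, severity thresholds 4/7/14/40) and the class pair is looked
up in a 5×5 matrix of danger levels 1–3. Two post-matrix rules raise a
species one level each (capped at 3): raptors, and species seen crossing
or overflying the runway at least three times.

### A note on the normalization scale

The source formulation multiplies comparative number and weight by 100
*and* multiplies their sum by $100/2$ again in the severity formula,
which would put severity on a 0–10,000 scale — irreconcilable with the
0–100 severity banding table. We store $CN$ and $CW$ as fractions and
apply the $\times 100$ exactly once, inside the severity formula. This
is the unique reading under which every attainable severity lands inside
the banding table's domain.

## The risk matrix

The authoritative cell assignment of the 5×5 matrix is not available in
a machine-readable form, so the package treats the matrix as a required,
validated configuration input and ships a reconstruction as the default:
with band ordinals $\ell, s \in \{1, \dots, 5\}$,

$$\mathrm{level} = \begin{cases} 3 & \ell + s \geq 8 \\ 2 & 5 \leq \ell + s \leq 7 \\ 1 & \ell + s \leq 4. \end{cases}$$

This choice is the simplest grid that (a) sends the two extreme corners
to the extreme levels, (b) is monotone non-decreasing along both axes,
and (c) balances the three levels across the 25 cells (6/13/6). Any
alternative matrix can be supplied via `risk_config(matrix = ...)` or a
YAML/JSON file; configuration validation rejects non-monotone grids, and
JSON reports echo the matrix actually used, so a classification is never
separable from the matrix that produced it.

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `likelihood_bounds` | 15, 30, 50, 70 | score points | published banding table |
| `severity_bounds` | 4, 7, 14, 40 | score points | published banding table |
| `crossing_threshold` | 3 | sightings/year | the crossing rule is worded both as "three times" and "more than three times"; we trigger at ≥ 3 (risk-conservative) and expose the knob |
| `raptor_bump` | `TRUE` | — | raptors are fast and heavy-hitting but solitary and light relative to waterfowl, so the base formulas under-rank them |
| `height_stat` | `"median"` | — | count-weighted median of sighting heights; robust to single outlier sightings (a `"mean"` option exists) |
| `cluster_stat` | `"max"` | — | largest observed group size; risk-conservative (any quantile in (0,1) may be used instead) |
| `weight_basis` | `"total"` | — | "weight of all birds of a single species" read as total biomass = count × mean individual mass; an `"individual"` (per-bird mass) variant is available |
| `season_months` | Mar–May spring, … | — | calendar-quarter scheme for a north-temperate site; fully remappable |

Aggregation choices the source leaves open, decided here: one
*representative* flight height per species (no aggregation rule is
stated; we use the count-weighted median), one characteristic flock size
(we use the maximum observed group size), and an *annual* classification
with *seasonal presence* reporting (factor inputs are pooled over the
survey year; the seasonal table reports which species are present each
season at each level, not season-specific re-classification). No
survey-effort normalization is applied: comparative number is a ratio of
raw totals, so it is invariant to uniform effort scaling but not to
effort that differs systematically between species' habitats.

### Edge cases fixed by design

* **Cluster table gap at $N = 100$**: the printed bands ($N > 100$ vs
  $100 > N \geq 20$) assign nothing to exactly 100; we close the gap
  upward ($N \geq 100 \to 1$), the risk-conservative direction.
* **Non-integer scores**: the printed band ranges are integer
  ("0–14", "15–29"), leaving e.g. 14.5 unassigned. Bands are implemented
  as continuous half-open intervals $[0,15), [15,30), \dots, [70,100]$,
  which agree with the printed table on every integer.
* **Percentage rounding**: reported percentages are rounded half-up to
  one decimal (`round_half_up()`), the convention matching the published
  style (27.1 for 32/118, 55.9 for 66/118). Under this rule 20/118 gives
  16.9, whereas the published figure is 17.0; the package reports the
  correctly rounded 16.9 and documents the 0.1-point discrepancy rather
  than replicating it.
* **Ties**: species tying for the largest total count (or biomass) all
  receive comparative number (weight) 1. The weighted median uses the
  lower-median convention, so it is deterministic.
* **Adjustment stacking**: whether the raptor and runway-crossing bumps
  may stack is unstated; they stack here (a raptor that also crosses the
  runway is raised twice), always capped at level 3, and every applied
  rule is named in the report's `adjustments` column.

## The synthetic community generator

`generate_community()` / `generate_surveys()` emulate the survey design
the model targets: 39 survey units (7 in zone A, 20 in B, 12 in C)
visited monthly for a year — 468 unit-visits — over a community of 118
species. Communities are drawn from six guilds (songbirds, waterfowl,
terrestrial birds, aerial foragers, waders, raptors) with guild-specific
lognormal body masses (~10 g to ~10 kg), modal flight heights, and
flock-size classes; species abundance is lognormal across species
(`meanlog = 2`, `sdlog = 1.2`, giving the few-dominants/many-rare shape
typical of bird communities); each species occupies a zone subset with
its nearest zone dominant in sampling (weight ≥ 0.6) and follows one of
four seasonal patterns (resident 40%, summer visitor 25%, passage
migrant 25%, winter visitor 10% — every pattern includes autumn, giving
the autumn-richest seasonal profile typical of migration corridors).
Expected encounters are ≥ 2 sightings per active month per species, so a
full survey year detects essentially the whole community.

Two deliberate idealizations matter for interpreting tests. First,
flock sizes are drawn in classes whose ranges (1–2, 4–16, 25–80,
130–400) avoid the cluster-band edges, and per-sighting group sizes
vary only ±15% around the species' characteristic flock size — so a
species' true cluster band is well defined and recoverable. Second,
per-sighting flight heights vary lognormally (sd 0.2 on the log scale)
around a species' modal height, with no altitude–behaviour interaction.
Real data have detection error, observer heaping of heights and counts,
effort gaps, and flock sizes that straddle band edges; passing the
recovery tests therefore demonstrates that the *pipeline* is faithful
(aggregation, lookups, classification), not that field estimates of
these quantities are unbiased. The planted extreme species (a maximally
hazardous flocking giant in zone A at 40 m; a rare solitary 15 g bird at
200 m in zone C) verify that the classification's extremes behave
correctly end to end.

Latent truth and recovery checks use these scales: 20 independent seeds,
118 species each, full 12-month campaigns (a few thousand sighting
records per campaign) — small enough to run in seconds, large enough
that every guild, zone set and seasonal pattern is exercised many times.

## Numerical choices

Coefficient-set membership is checked with tolerance $10^{-9}$ (the sets
are exact decimals, but factors may arrive through arithmetic).
Likelihood and severity are kept at full double precision; only reported
percentages are rounded (half-up, one decimal). `score_band()` is
`findInterval()` on the four thresholds — half-open intervals, top band
closed at 100; inputs outside $[0, 100]$ are errors, not clamped.
Degenerate inputs are explicit errors: an all-zero community for the
comparative factors, an empty classification for percentages, an empty
high-danger list for the overlap; an empty *strike* list is a warning
with zero fractions, since that is a legitimate (if uninformative)
cross-check.

Name matching in the strike-record cross-check is deliberately modest:
case-folding, whitespace squashing, and an optional user-supplied
synonym table. Vernacular/scientific synonymy ("pigeons" vs "rock
pigeon") is a data-curation problem the package surfaces rather than
guesses at.

## Limitations

The model is ordinal and community-relative: scores are not strike
probabilities, and a species' level can change when other species'
abundances change the normalization denominators. The default matrix is
a reconstruction, not an authority. Classification is annual; a species
hazardous only during migration pulses is flagged through the seasonal
presence table, not a seasonal re-classification. The simulator makes no
claim to movement ecology, detectability or weather; it exists to make
every pipeline stage testable without field data.
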