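---
title: "Plate-event dietary assessment: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plate-event dietary assessment: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietledger)
```

`dietledger` computes dietary intake from plate-level cafeteria records:
one row per plate of food taken by one consumer at one meal. This
vignette is the package's account of the underlying model, the choices
behind its defaults, and what its tests do and do not demonstrate.

## The data model

Three tables drive everything:

* **Plate events** — consumer ID, dish name, plate type (1 staple,
  2 cooked dish, 3 soup), serving weight (g), price, meal slot, date.
  Each plate is one event; a consumer taking two plates of the same dish
  produces two events. Meal slot is a categorical field, as RFID checkout
  systems record it; for timestamped inputs `classify_meal_slot()`
  offers a window classifier (lunch = 11:00–14:00 by default).
* **Recipe database** — dish name, dish type (`staple`, `cooked`,
  `porridge_soup`), preparation method (stir-fry, steam, boil, roast,
  deep-fry, braise, raw, other), and raw ingredients with weights.
  Condiment-scale ingredients (ginger, garlic, scallion) carry an
  author-supplied `auxiliary` flag; the package deliberately does not
  infer auxiliarity from a weight threshold, because a hidden heuristic
  would make results depend on arbitrary cutoffs.
* **Food composition table** — per ingredient: a food-group category
  from a closed 11-category list and nutrient amounts per 100 g edible
  portion (5 core nutrients required — energy kcal, protein, fat,
  carbohydrate, fiber in g — extensible to 23). The per-edible-portion
  convention is this package's documented choice; sources differ and the
  schema itself cannot distinguish the two.

All dish and ingredient matching is exact after normalization (trim,
case-fold, collapse internal whitespace). Fuzzy matching is out of
scope: silent near-matches are worse than a loud coverage failure.

## Record selection

Analysis-ready records are selected in four fixed stages: the requested
meal slot, a valid plate type, dish resolvable in the recipe database,
and recipe fully covered by the composition table. The stages are
reported as an entering/surviving chain whose counts are non-increasing
and consistent; event order is preserved. Filtering is total — every
record either survives or is dropped at exactly one stage — which is
what makes planted-corruption tests exact.

## The nutrient calculation

A serving of weight $W$ of a dish is split over the counted ingredients
in proportion to raw recipe weights,
$w_i = \frac{r_i}{\sum_j r_j} W$, and per-100 g content is the weighted
sum over ingredients,
$c_x = \sum_i \frac{w_i}{100}\, n_{x,i}$ with $W = 100$ g, where
$n_{x,i}$ is ingredient $i$'s amount of nutrient $x$ per 100 g. Intake
for a serving is $c_x \cdot W / 100$: exactly linear in serving weight,
and aggregation over any partition of records is invariant. Ingredients
are accumulated in sorted-name order so sums are bit-reproducible.

Three deliberate modeling decisions:

* **Raw-weight basis, no retention correction.** Weights are raw recipe
  weights; cooking yield and nutrient retention by preparation method
  are not modeled. Calculated values for cooked dishes therefore carry a
  systematic bias that the MAPD validation quantifies but does not
  remove.
* **Auxiliary ingredients off by default.** Their nutrient contribution
  is ignored unless `include_auxiliary = TRUE`; the flag exists because
  condiments can matter for sodium-like nutrients even when negligible
  for energy.
* **Absent is not zero.** A missing composition cell means "not
  measured". Absence is contagious through weighted sums and
  aggregation, always with a warning, because silently coercing to zero
  would understate intake in exactly the records where data are weakest.

## Reports

Dish-type and preparation-method distributions are tallied over *unique
dishes* (the natural population-level denominator for "what does the
menu-as-consumed look like"); an events-weighted variant is available
via the `weights` argument. The ingredient-category distribution counts
*distinct ingredient kinds* across the union of recipes — an ingredient
in many dishes counts once — with percentages over total distinct kinds.
Percentages are rounded half-up to 1 decimal and reported alongside raw
counts, so rounding is always recoverable; displayed percentages may sum
to 100 ± 0.1 per row. With this rule, counts of 83/391/15 over 489
dishes print as 17.0%, 80.0% and 3.1%. Ordering is by descending count
with alphabetical tie-break, and method distributions default to cooked
dishes only — the preparation question concerns the cooked component of
a Chinese meal.

## Validation by MAPD

Calculated content is compared per nutrient with chemical reference
measurements as $\mathrm{MAPD} = |c - m| / m \times 100$. The cell is
undefined (displayed "—") exactly when $m = 0$: a relative deviation
from zero has no scale, and reporting 0 would claim perfect agreement on
no evidence. A calculated zero against a positive measurement is a 100%
deviation. MAPD is asymmetric in $(c, m)$ by design — the measurement is
the reference. Display rounding is half-up to 2 decimals; full precision
is retained internally. The package ships a benchmark fixture of three
chemically assayed dishes (`make_table1_fixture()`, with CSV twins under
`inst/extdata/`) whose published ingredient lists are reproduced in
`table1_recipes()` with synthetic placeholder weights, since the source
reports none; their calculated values are therefore validated in
replication mode (printed value pairs), not recomputed from recipes.
MAPD here is per nutrient; `dish_mean_mapd()` offers a per-dish mean
over defined cells as a convenience summary only.

## The simulator

`sim_config()` describes a workplace restaurant; the generators are pure
functions of the configuration, including its seed (the caller's RNG
state is untouched). Defaults, chosen once as a realistic desk-scale
study and used as the package's standing test conditions:

* 50 consumers over 30 working days from 2016-01-05, lunch only;
* a 50-dish menu of 8 staple / 40 cooked / 2 porridge-soup dishes
  (16/80/4%, mirroring the roughly 17/80/3% split of a typical Chinese
  lunch menu), drawn from a 60-ingredient pool with category-plausible
  composition values and 23 nutrient columns, 5% of non-core cells left
  absent;
* per-consumer preferences drawn once from a flat Dirichlet over the
  menu; two plates per consumer per lunch; serving weights uniform in
  100–250 g (staple), 150–300 g (cooked), 200–400 g (soup);
* price proportional to weight by plate type.

The corruption machinery plants one violation per corrupted row, cycling
over the four selection stages (wrong meal slot, invalid plate type,
unknown dish, dish with an ingredient deliberately missing from the
composition table), and ledgers every corrupted row. Clean rows pass all
four filters by construction, so the ledger is exact ground truth.
`simulate_personal_scenario()` reproduces the individual-level analysis
setting: 20 working days, one consumer, a rice-and-soup habit planted on
15 days alongside a daily cooked dish, recoverable exactly by
`food_frequency()` and yielding a 20-entry daily intake series.

What the simulator does *not* emulate: culinary co-occurrence structure
(dishes are drawn independently), seasonal menu drift, demographic
covariates, plate waste (serving weight is set by the restaurant, and
consumption equals serving), and realistic nutrient correlations between
ingredients. Passing tests on simulated data demonstrate the
correctness of the bookkeeping — filtering, decomposition arithmetic,
aggregation, report tallies — not the accuracy of nutrient estimates on
any real menu; that accuracy is bounded empirically only by the
three-dish chemical benchmark.

## Numerical and degenerate-input contracts

* Decomposition conserves mass to 1e-9 relative tolerance; a recipe
  whose counted weight is zero is a degenerate-recipe error.
* Zero-measured MAPD cells are `NA`, never 0 or infinity; an empty
  nutrient intersection between calculation and reference is an error,
  not an empty report.
* An empty dish set yields an empty distribution with total 0; a report
  over a non-empty set lists zero-count vocabulary categories.
* Event files with more than 50% invalid rows abort as schema
  mismatches; below that, rejects are itemized per row with the first
  failed check, never dropped silently.

## Test problem sizes

The suite exercises: the full 12-cell benchmark comparison; ~114
generator recipes against an independently coded brute-force
weighted-sum oracle at 1e-9; a 1000-event stream with 30 planted
violations for filter exactness; 2000 preference draws for the
planted-preference recovery check (±0.03); and a 489-dish menu
generation smoke test. These sizes were chosen as the smallest that
exercise every code path with comfortable statistical margins.
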