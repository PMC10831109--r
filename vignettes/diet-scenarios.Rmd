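---
title: "Modelling plant-based diet replacement scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling plant-based diet replacement scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantshift)
library(dplyr)
```

## The model

`plantshift` models what happens to a national average diet when
animal-source foods (ASFs: meats, eggs, dairy, seafood) are partially or
fully replaced by plant-based alternatives (PBAs: processed products that
mimic an ASF) or by whole plant foods (WFs: legumes, grains, nuts,
vegetables, fruits). Each scenario is scored on three axes:

* **nutrition** — per-day nutrient supply against a recommendation table,
* **environment** — greenhouse gas emissions (kg CO2e/day), cropland use
  (m²/day) and consumptive blue freshwater use (L/day),
* **economy** — daily food expenditure.

The accounting is strictly linear. For a consumption-stage diet with
amounts $m_i$ (kg/person/day) over food items $i$, any intensity $x_i$
(nutrient content, footprint or price per kg) aggregates as
$X = \sum_i m_i x_i$. The modelling content lies in how the scenario diets
are constructed and how uncertainty in $x_i$ is propagated; the package
deliberately avoids optimisation (no least-cost or least-impact diets) and
behavioural modelling.

### From supply to consumption

National statistics record food *available* to households. The analysis
works at the *consumption* stage: `apply_waste()` scales each group by
$(1 - w_g)$ with per-group household loss/waste fractions $w_g \in [0, 1)$.
Scenario construction happens after this step, so replacement diets are
defined on what is eaten, not what is bought.

### Scenario construction and functional units

A `scenario_spec()` removes a fraction $r$ of each listed group (1 for
vegan and vegetarian removals, 0.5 for flexitarian) and reallocates the
removed quantity to replacement groups according to a weighted map, under
one of two *functional units*:

* **mass basis** — grams added equal grams removed;
* **energy basis** — the replacement grams are chosen so that the added
  kilocalories equal those removed:
  $g_{\text{added}} = \mathrm{kcal}_{\text{removed}} / \rho_t$ with
  $\rho_t$ the target group's mean energy density (kcal/g).

The default scenario set mirrors the canonical published table shipped in
`inst/extdata/table1_scenarios.csv`: vegan, vegetarian and flexitarian
variants in PBA and WF modes. Three details of that table are encoded as
configuration rather than heuristics:

* eggs route to plant-based meat in PBA scenarios (no plant-based-egg
  category exists at retail);
* conventional snacks swap to plant-based snacks in vegan and flexitarian
  scenarios of both modes, but not in vegetarian ones;
* WF-mode replacement weights are seeded from the vegan-WF deltas of the
  canonical table (vegetables : fruits : legumes : grains : nuts : plant
  fats = 165 : 150 : 150 : 100 : 42 : 6), with upper reference caps
  (legumes 150 g/d, nuts 50 g/d, vegetables 330 g/d, fruits 300 g/d,
  grains 270 g/d).

When a replacement target reaches its cap, the overflow moves to the
next-weighted target (ties broken by group name); if all targets saturate,
construction fails loudly with the unallocated residual. This waterfilling
is order-independent and therefore reproducible. Two invariants hold
whenever no cap binds and are property-tested: exact mass conservation on
the mass basis and kilocalorie conservation (relative error below 1e-6) on
the energy basis. The published WF columns are *not* exactly
mass-conserving (their caps bind and the printed values are rounded), so
only the unambiguous cells — ASF columns of all scenarios and all PBA-mode
replacement columns — are treated as exact anchors.

The canonical table's lower rows are interpreted as kcal/person/day: for
every group untouched by substitution they equal the mass row times the
group's implied energy density (e.g. meats, 190 g × 1.75 kcal/g = 333
kcal), which is how the fixture was validated. Lower-row cells of
*replaced* groups describe the energy-basis scenario whose gram amounts
differ from the mass-basis ones, so they are not used as gram anchors.

### Nutrient adequacy

`adequacy_report()` scores each scenario's supply $s$ against a per-day
threshold $t$ as the normalised deviation

$$\mathrm{score} = s/t - 1,$$

so 0 marks the recommended level. `minimum`-type nutrients pass at score
≥ 0; `limit`-type nutrients (sodium, saturated fat) pass at score ≤ 0.
The relative deviation is the simplest transform consistent with centring
recommendations at zero; it is documented rather than claimed canonical.
The recommendation table carries exactly one row per nutrient: where
sex-specific recommendations differ, the most stringent (largest
minimum-type) value is stored, and this one-row contract is asserted at
load. Dietary energy is reported but never scored. Bioavailability,
protein quality and health outcomes are out of scope.

### Footprints and expenditure

Footprint intensities are cradle-to-consumer (including consumer-stage
cooking); that boundary is a property of the data, recorded in the
database's `boundary_note`, not recomputed. Freshwater is consumptive
blue water only. Contributions are reported per food group with shares of
the total; shares are invariant to unit rescaling and must sum to 1.

Expenditure supports two quantile aggregations. The default
(`group_quantile`) takes the requested percentile of the pooled
within-group item price points and multiplies by the group amount — a
bound on where in a group's price range a consumer shops, not a sampling
confidence interval. The alternative (`item_quantile`) sums item amounts
times item-level price quantiles; it is the form that equals brute-force
item sums exactly and is used in the oracle tests. Whether pooling should
happen before or after weighting by amounts is genuinely open; both forms
are exposed and the pooled-percentile form is the default.

### Uncertainty analysis

Two mechanisms: (1) `quantile_sweep()` recomputes every metric with all
item-level data evaluated at q25, the median and q75, recording the
quantile as provenance — totals are monotone in the quantile because each
triplet is ordered; (2) `conscious_consumer()` reallocates each group's
amount onto the single item optimising an objective (`min_cost`,
`min_ghge`, `max_protein`, ...) at a stated quantile, bounding the effect
of within-group choice. Because the objective is linear, the optimum over
any within-group allocation sits at a vertex, so single-item reallocation
*is* the exact bound; the tests verify it against exhaustive enumeration.
A weighted reallocation can be expressed by editing the returned profile.
Functional-unit sensitivity is summarised by
`functional_unit_comparison()` as the per-scenario ratio of energy-basis
to mass-basis totals.

## The synthetic data generator

No real composition, LCA or price inventory ships with the package.
`generate_database()` emulates the *structure* such inventories share:

* group median footprints ordered ASF > PBA > WF per indicator (e.g.
  meats 11, plant-based meat 2.5, legumes 1.0 kg CO2e/kg). Item draws are
  log-normal multipliers rescaled to median 1, so realised group medians
  equal the targets exactly and the ordering holds strictly;
* PBAs fortified with B12, vitamin D, calcium and iron (plant-based
  meat/dairy/seafood only — retail chocolate is not fortified), and
  carrying 1.5× the sodium of the group they replace;
* right-skewed within-group price dispersion (log-normal, σ = 0.5);
* energy densities within physiological bounds (0.1–9 kcal/g), with
  plant-based meat (1.5 kcal/g) below meat (1.75 kcal/g) so energy-basis
  substitution adds more grams;
* a baseline supply equal to the canonical published group masses, with
  zero PBAs, legumes and soy foods (national intake statistics do not
  record them separately), split randomly but seed-reproducibly across a
  group's items;
* FAO-style waste fractions (5–19% depending on group) and
  recommendation thresholds in the style of Nordic-type references,
  flagged as synthetic placeholders and overridable per nutrient.

Magnitudes were chosen once for realism at Swedish LCA/retail scales. All
randomness is a pure function of the spec's seed; the same spec yields
byte-identical databases, and generated values are snapped to nine
significant digits so CSV round-trips are byte-stable.

**What passing tests do and do not show.** On this synthetic structure
the analysis reproduces the *qualitative* published pattern: every
replacement scenario cuts greenhouse gas emissions (about 40–47% for the
vegan variants at default conditions), ASFs dominate baseline emissions
while providing roughly a third of energy, fortification decides
vitamin-D adequacy between PBA and WF vegan diets, sodium rises only in
PBA scenarios, and WF diets are cheaper while PBA diets cost slightly
more. The *exact* published percentages are properties of the study's
item-level inventory, which the generator does not and cannot reproduce;
the corresponding checks therefore anchor construction cells (which are
exact) and treat inventory-dependent headline values as out of reach of
synthetic data. Real data can be brought in through
`read_food_database()` with a column-mapping config.

## Worked example

```{r example, eval = FALSE}
spec <- synthetic_spec(seed = 1)
db <- generate_database(spec)
bau <- apply_waste(generate_bau_supply(spec, db), db)
scenarios <- build_scenarios(bau, db, basis = "mass")

impact_report(scenarios, db) |> filter(indicator == "ghge")
glance(adequacy_report(scenarios, db))
expenditure_report(scenarios, db)
autoplot(total_impact(scenarios, db))
```

`run_pipeline(pipeline_config(spec))` executes all stages (both
functional units, full quantile sweep) and writes CSV results plus a JSON
manifest with per-file checksums; identical configurations produce
byte-identical output directories. Default problem sizes — 3 items per
food group (51 items), 7 scenarios × 2 functional units × 3 quantiles —
keep a complete run in a few seconds while exercising every code path;
`items_per_group` scales the item dimension when denser databases are
wanted.

## Numerical choices and edge cases

* Quantile triplets must satisfy q25 ≤ median ≤ q75 at load; degenerate
  triplets (all equal) are legal, collapse the sweep, and trigger a
  warning rather than an error.
* Empty diets yield zero totals with `NA` shares (flagged, not silently
  0/0), zero nutrient supplies, and an error for the ASF energy share
  (undefined on zero energy).
* Cap waterfilling uses a 1e-9 convergence tolerance and reports
  infeasibility above 1e-6 unallocated grams/kcal.
* Tie-breaks (equal replacement weights, equal objective values in the
  conscious-consumer reallocation) resolve lexicographically, keeping
  every result order-independent.
* One litre of beverage is treated as one kilogram throughout; per-100 g
  inputs are converted at the reader boundary so all internal intensities
  are per kg and per day.
* The `Other` group (sugar products, salt, soft drinks, coffee, juice)
  passes through every scenario unchanged.

## Known limitations

The generator is not a survey simulator: it does not reproduce intake
distributions, seasonal price movement, or correlations between nutrient
content and footprint within a group. Group-level substitution cannot
express item-targeted policies (e.g. replacing only beef within meats).
Adequacy scoring ignores nutrient bioavailability, which matters for
fortified PBAs. Expenditure excludes preparation energy costs, which
penalises cheap commodities that need long cooking. These bounds are
inherited from the modelling scope, not implementation shortcuts.
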