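---
title: "Methods: hybrid healthy-meal recommendations with explanations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid healthy-meal recommendations with explanations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mealrec)
```

## The problem

Workplace catering menus are small (10–20 meals a day), users have hard
constraints (allergies, vegan/halal/etc.), and the most popular meals are
not the healthiest ones. `mealrec` implements a recommender for this
setting that ranks each day's menu per user by combining three signals
over a safety prefilter, and attaches an explanation to every
recommendation so users can see *why* a meal was suggested.

The pipeline is:

1. **FFQ profiling** — estimate daily nutrient intake from a food
   frequency questionnaire and classify each of twelve nutrients as
   Low / Normal / High against reference ranges.
2. **Contextual prefilter** — drop meals that are at the wrong location,
   unsafe for the user's allergies, in conflict with lifestyle
   constraints, or shown too recently.
3. **Hybrid scoring** — a nutrient-weighted knowledge score (65% of the
   final score), an ingredient-similarity content score (25%), and a
   peer-popularity collaborative score (10%).
4. **Explanation** — three structured payloads (nutritional alignment,
   past choices, popularity) whose every number is recomputable from the
   component scores.

## FFQ intake estimation and status classification

For one questionnaire response, the daily intake of nutrient $n$ is the
standard FFQ aggregation over answered items $i$:

$$I_n \;=\; \sum_i f_i \, m_i \, \frac{p_i}{100}\, c_{i,n},$$

where $f_i$ is consumption frequency (times/day), $m_i$ the portion
multiplier, $p_i$ the standard portion mass (g) from the item bank, and
$c_{i,n}$ the per-100 g composition. The estimate is linear in the
frequencies and invariant to answer order; both properties are tested.

Classification is per nutrient against a range $[\ell_n, u_n]$: Low iff
$I_n < \ell_n$, High iff $I_n > u_n$, Normal otherwise. The bounds
classify as **Normal**: someone at exactly the recommended intake should
not be flagged. The shipped ranges
(`inst/extdata/config/reference_ranges.yaml`) are dietary-reference-value
style placeholders for a generic adult — they are editable configuration
and explicitly **not clinical thresholds**; any deployment should replace
them with values appropriate to its population. Note that saturated fat
has $\ell = 0$, so its Low status is unattainable by construction — which
is consistent with its weight-table row, where Low carries weight 0
anyway.

## The knowledge-based scorer

Within a candidate set, each nutrient column is min–max normalized to
$[0,1]$ (a constant column maps to the neutral 0.5). The raw knowledge
score of a meal is

$$r = \sum_n w(n, s_n)\, x_n,$$

with $x_n$ the normalized amount and $w$ the dietitian-curated weight
table (`default_weight_table()`): e.g. fiber weighs +5 under Low intake
and 0 under High; polyunsaturated fat +3 under Low and −0.5 under High;
total fat −1 under both. Normal status always weighs 0. Raw scores are
min–max rescaled to $[0,1]$ across the candidate set before entering the
hybrid combination.

Two normalization choices were genuinely open and are this package's
own:

* **Normalize over the day's post-filter candidates**, not a global meal
  archive — recommendations compare the options the user can actually
  order today, and a global archive would let off-menu meals distort
  today's scale.
* **Rescale raw scores across candidates** rather than against a
  theoretical maximum — the theoretical maximum depends on the profile
  and would compress scores for users with few flagged nutrients;
  min–max rescaling preserves the ranking, which is what the 65% weight
  acts on.

Both maps are order-preserving, so they never change which meal the
knowledge component prefers.

## Content-based and collaborative scorers

The **taste vector** aggregates history per ingredient: +1 for every
ingredient of an ordered or thumbs-up meal, −2 for each ingredient the
user explicitly named in a thumbs-down (only those). The −2 vs +1
asymmetry makes a single explicit dislike outweigh a single like:
negative feedback is rarer and stronger. The content score is the cosine
between a meal's binary ingredient vector and the taste vector, mapped
to $[0,1]$ via $(c+1)/2$; a cold user scores the neutral 0.5 everywhere.
Ingredients were chosen over nutrients as the content representation
because dislike feedback is collected per ingredient.

The **collaborative score** activates after 14 days of system order
history (two weeks of data collection) and when the user has orders of
their own; before that it is 0 for every meal. Zero — not re-normalized
weights — keeps the printed 65/25/10 semantics intact at all times; a
constant component shift is rank-neutral. Once active, the user's $k=5$
nearest neighbours (cosine similarity over meal-order-count vectors,
alphabetical id tie-break) are found and the score is the fraction of
neighbours who ever ordered the meal. Neighbour count and metric are
this package's choice; five neighbours is small enough for sparse
multi-week histories and large enough that the fraction takes more than
two values.

## The hybrid combination and determinism

$$\text{final} = 0.65\,k + 0.25\,c + 0.10\,f$$

with the weights held in `hybrid_weights()` as configuration (they must
be non-negative and sum to 1). Ranking sorts by final score, breaking
ties by higher knowledge score and then lexicographic meal id, so
identical inputs always give identical rankings on any platform. The
linearity of the final score in each component, with coefficients
exactly equal to the configured weights, is verified by recovering the
coefficients from ranked output in the acceptance suite.

## The contextual prefilter

Filters apply in a fixed order (location, allergen, lifestyle, recency),
and the exclusion log records each meal's *first* triggering reason.
Details that needed a decision:

* **Lifestyle tags** are split into required diet tags (vegan,
  vegetarian, halal, kosher — the meal must carry them) and avoidance
  tags (everything else, e.g. coriander or pig meat — the meal must not
  carry them). The platform's single preference list conflates both;
  the split matches how caterers tag meals.
* **Recency** is a calendar-day window: with the default window of 3, a
  meal put forward on any of the three days before today is held back.
  The default source is shown recommendation lists; orders or both are
  configurable because either reading is defensible.
* **Opaque composite ingredients** ("house sauce" with unknown
  constituents) are treated as unsafe for any user with at least one
  allergy when `strict_composite_mode` is on (the default): unknown
  contents count as unsafe. Lenient mode trusts the meal-level tags.
* **min_candidates fallback** (default 3): if the filters leave too few
  meals, recency exclusions — and only recency exclusions — are restored
  most-stale-first. This prevents empty recommendation screens without
  ever overriding safety.

## Explanations

Each recommendation carries three payloads, in fixed order: nutritional
alignment, past choices, popularity. Sentences are templates in
per-locale YAML with `{pct}` placeholders, so the rendered "65%" and
"10%" are always derived from the configured weights — nothing is
hard-coded, and reconfiguring the weights re-renders the text. The
nutritional payload's detail rows (weight × normalized amount per
flagged nutrient) sum exactly to the meal's raw knowledge score; the
popularity payload carries the neighbour fraction behind the
collaborative score. Tests re-parse rendered payloads and re-derive
every number from the component scores.

## The synthetic world generator

`generate_world()` emulates the deployment's data so every stage is
testable offline: daily menus of 10–20 meals drawn from a stable recipe
pool (dishes recur across days, which is what gives the recency filter
and the collaborative scorer signal), roughly 15% vegan options, a
35-day window, users with ~30% allergy prevalence, and order histories
over which users order on ~80% of days. All randomness derives from one
master seed with per-component sub-streams, so the same configuration is
byte-identical on re-run and adding users never perturbs the menus.

Profile planting is analytic: the item bank carries twelve
single-nutrient "anchor" items (clearly labeled synthetic) alongside ≥50
multi-nutrient items with NUBEL-plausible per-100 g compositions. A
random baseline response is scaled until it sits strictly below every
per-nutrient target, then the anchors top each nutrient up to a target
placed well inside the desired Low/Normal/High band — so
`classify_status(compute_intake(...))` recovers the planted profile
exactly, for 100% of seeded users, by construction. Planted tastes bias
order probabilities toward meals containing preferred ingredients
(weight $1 + 3 \times$ overlap).

What the generator does **not** emulate: real FFQ measurement error and
under-reporting, correlated nutrient compositions within a food,
seasonal menus, participant drop-out, or order behaviour driven by
anything but ingredient preference. Passing tests therefore demonstrate
the engine's arithmetic, determinism, and safety properties — not
predictive quality on real populations.

## Numerical conventions and problem sizes

* Min–max with a degenerate (constant) column → 0.5, everywhere the
  normalization is used.
* Status boundaries classify as Normal; all other comparisons are
  strict.
* All tie-breaks are deterministic and documented: alphabetical food
  group for top contributors, alphabetical user id for neighbours,
  (knowledge, meal id) for rankings.
* Tags are lowercased with whitespace collapsed before exact matching.
* Test and acceptance runs use deliberately small problem sizes — menus
  of 2–6 meals for oracle equivalence (200 random instances), 100 users
  for profile recovery, 41 users for the dietary-shift recovery, 1031
  rows for event-log parsing — chosen so the full pipeline, including
  its brute-force oracles, is verified in seconds.

## Known limitations

* The reference ranges are placeholders (see above).
* Ingredient matching is exact string matching after normalization; no
  synonym handling ("soy" vs "soy sauce" are unrelated tokens).
* The engine has no diversity re-ranking beyond the recency rule; a
  nutritionally optimal menu for a stable profile is repetitive by
  design, a known tension in this setting.
* Nutri-Score letters are consumed as metadata, never computed.
* The flat CSV menu format cannot carry nested sub-ingredient lists;
  use the JSON format when composites are resolved.
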