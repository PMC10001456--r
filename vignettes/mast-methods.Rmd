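---
title: "Menu assessment scoring: model, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Menu assessment scoring: model, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mast)
```

## The problem

Food service outlets contribute a growing share of dietary intake, and
on-site nutrition audits are too slow and expensive for surveillance at
the scale of a whole local government area. This package implements a
desk-based instrument that scores the nutritional quality of a menu from
its item listing alone. It is a *screening* tool for dietary risk, not a
per-item nutrition assessment: the unit of observation is the menu, and
the output is a single integer percentage where 0% is best and 100% is
worst.

## The taxonomy

Menu items are mapped to six food categories — vegetables, fruit, grain
(cereals), meat and alternatives, dairy and alternatives, and beverages
and miscellaneous — each subdivided into *nutrient-poor* (discretionary)
and *nutritious* food groups following the Australian Guide to Healthy
Eating. The default scheme has 15 nutrient-poor and 12 nutritious groups
(27 total). Five categories carry both a nutrient-poor and a nutritious
side; beverages and miscellaneous carries only a nutrient-poor side,
because water is freely available in Australian outlets as a cultural
norm (so its presence carries no signal) and alcohol availability is
regulated and assessed through liquor licensing rather than menus. That
yields 11 assessable slots:

```{r}
tax <- load_taxonomy()
mast_slots(tax)
```

Both exclusions are switches, not hard-coded facts: `include_water =
TRUE` adds a nutritious water group (12 slots), `include_alcohol = TRUE`
adds a nutrient-poor alcoholic-beverages group, for settings where those
assumptions do not hold. The whole scheme lives in one YAML file
(`inst/extdata/default-taxonomy.yaml`) so the tool can be re-aligned to
another country's dietary guidelines by editing configuration only.

One reconstruction should be flagged: the published description of the
scheme gives the group counts (15 + 12 = 27) but the accompanying table
lists only 11 nutritious group names, while its vegetable examples
(salads, steamed vegetables) clearly exceed the two named vegetable
groups. The default taxonomy therefore carries a twelfth nutritious
group, "Vegetables and salads", holding those examples. This affects
naming only — slot structure and scoring are untouched.

## Classification rules

The pilot instrument relied on trained nutritionists coding menus by
hand. This package replaces coder judgement with a deterministic cue
engine plus explicit overrides, keeping the audit trail the manual
process had (every assignment records its matched cues and basis; every
present slot records one evidence item).

Matching is case-insensitive on whole words, tolerant of plural *s*/*es*,
and longest-phrase-first: a cue wholly contained in the span of a longer
match is suppressed, so "garlic bread" never also counts as "bread".
Each group lists `include_cues` (phrases demonstrating membership) and
`exclude_cues` (phrases that veto it — "latte with caramel syrup" is not
a plain latte). Each category additionally lists *neutral* cues: words
like burger, pizza, pasta, coffee that fix the category but say nothing
about preparation. This tier is the mechanism behind the central
risk-assessment principle — *items are assumed nutrient-poor unless the
text demonstrates otherwise*:

```{r}
classify_item("steamed dim sum", tax)[c("slot_id", "basis")]
classify_item("beef burger", tax)[c("slot_id", "basis")]
classify_item("chef's surprise", tax)[c("slot_id", "basis")]
```

A nutritious assignment needs positive evidence (a nutritious include
cue, unvetoed); a nutrient-poor include cue always wins within its
category; neutral-only matches fall to the category's nutrient-poor slot
with basis `risk_default`. An item matching no cue at all is
*unclassified* and excluded — surfaced for human review rather than
guessed into a category, because a wrong category corrupts both the
numerator and the denominator, while an omission only risks
under-counting an engaged category that other items usually engage
anyway.

Cross-category conflicts follow a major-ingredient rule: grain-based
mixed dishes (burger, pizza, sandwich, wrap, sushi, pasta, noodles, ...)
belong to the grain category even when meat or vegetable words also
match — the culturally tempting "anything with meat is a meat dish"
reading is explicitly rejected. Among non-grain candidates the longest
matched cue wins (it is almost always the most specific), with remaining
ties broken by fixed category order for determinism.

Menu-coding conventions mirror desk-audit practice: customisable items
are assessed on their stated default configuration (an optional bacon
topping never reaches the classifier); meal deals are one unit, with any
nutrient-poor cue anywhere in the deal text forcing the nutrient-poor
slot of the deal's category; kids'-menu items count only when listed on
the main menu. Eligibility is an explicit input flag
(`on_main_menu`) — inferring it from section headings is unreliable, so
headings only set the flag's default, and an explicit value always wins.

## Scoring

Penalty points: +1 for each nutrient-poor category available, +1 for
each paired category whose corresponding nutritious side is absent.
Availability is presence/absence — a second ice cream changes nothing.
A category is *engaged* when any of its slots is present. The final
score divides penalties by the number of slots among engaged categories
(2 per paired category, 1 for beverages), times 100, rounded half-up.

The denominator choice is the one genuinely delicate design point. An
initial fixed /11 denominator advantaged narrow menus: an outlet selling
only ice cream collected one availability penalty and five
absent-nutritious penalties for 6/11 = 55%, comfortably mid-range
despite offering nothing nutritious. Under the engaged-category scheme
the same menu scores 2/2 = 100%:

```{r}
slots <- mast_slots(tax)
p <- setNames(slots$slot_id == "dairy:nutrient_poor", slots$slot_id)
a <- assessment_from_pattern(p, tax)
score_assessment(a, tax)
score_assessment(a, tax, mode = "fixed")
```

Symmetrically, categories a menu never touches contribute neither
penalty nor denominator — otherwise the worst-case score of a
four-category menu could never reach 100%, and the published pilot's
9/9 rows would be unreachable. Both modes are kept: `engaged` is the
operative instrument, `fixed` documents the refinement.

Numerical choices: percentages are rounded half-up (none of the 30
published pilot scores distinguishes half-up from half-even; half-up is
chosen as the more transparent convention and applied consistently,
including to batch means). A menu engaging zero categories is an
*error*, never 0% — 0% is the best-case result and must not alias with
"nothing assessable". Batch means are computed over the per-outlet
integer percents and then rounded, matching how the pilot reported its
summary (the alternative — averaging unrounded fractions — differs by
at most one point and is not what the published table prints).

## The synthetic generator

Per-outlet menus from the pilot were never published; only each outlet's
(numerator, denominator, percent) and classification were. The generator
closes that gap in two steps, making every pipeline stage testable
without external data:

* `pattern_for(numerator, denominator, seed)` constructs a slot-presence
  pattern scoring exactly the target. Feasibility under the default
  scheme: denominator = 2k + b (k engaged paired categories, b ∈ {0,1}
  for beverages), b ≤ numerator ≤ denominator. Construction is greedy —
  engage beverages when b = 1 (+1 penalty), then assign paired
  categories +2 (nutrient-poor only), +1 (both slots) or +0 (nutritious
  only); the seed shuffles which category plays which role.
* `generate_menu(pattern, taxonomy, seed)` emits one concrete item per
  present slot, drawn from that slot's cue lexicon restricted to phrases
  that provably classify back to their own slot.

`pilot_fixture()` applies this to all 30 published rows. Because any
pattern consistent with a printed (numerator, denominator) is an equally
valid reconstruction, the recomputed batch statistics are invariant to
the seed — only the cosmetic composition of the fixture menus changes.

What the generator deliberately does not emulate: ambiguous free-text
descriptions, misspellings, items outside the cue vocabulary, and
non-English menus. Passing round-trip tests therefore demonstrates that
the pipeline's logic is exact on lexicon-covered text, not that the
classifier reads arbitrary real menus as a trained nutritionist would;
on real data the unclassified-item list and the override file are the
instrument's safety valves.

## Validation and known limits

The test suite checks, among other properties: equivalence of the scorer
against an independent brute-force enumeration over all 2,048 slot
patterns in both modes; monotonicity of the engaged-mode percent
(adding a nutritious slot never raises it, adding a nutrient-poor slot
never lowers it); invariance to item order and multiplicity;
assess∘generate identity over 200 seeded random patterns; and exact
reproduction of all 30 published pilot triples and their batch summary
(overall mean 71%, range 29–100%). These sizes run in well under a
minute and are fixed properties of the method, not tuned quantities.

One published figure is knowingly not reproduced: the pilot reports a
fast-food/takeaway group mean of 81%, but the 17 printed fast-food
scores average 80.2, which no standard rounding takes to 81. The
package treats this as a transcription discrepancy in the source: the
recomputed value 80 is reported, and a test documents the gap.

Other limits inherited from the instrument itself: menus change
seasonally and the score is a snapshot; cooking methods invisible in
item text (added fat, salt, sugar) are not captured; prices, promotions
and portion sizes are out of scope; and the risk default may
over-estimate risk for outlets whose menus under-describe nutritious
preparation — accepted, because a single demonstrated nutritious item
per category is enough to remove the penalty.
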