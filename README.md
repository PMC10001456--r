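# mast — Menu Assessment Scoring Tool

`mast` implements a desk-based instrument for assessing the nutritional
quality of food service menus, built for public health nutritionists and
dietitians running large-scale audits of neighbourhood food environments
(cafes, restaurants, fast food and takeaway outlets, pubs). It scores a
menu from the text of its item listing alone — no site visit, no nutrient
panel — using a risk-based penalty-point system aligned to the Australian
Guide to Healthy Eating.

## The scoring model

Menu items are classified into six food categories — vegetables, fruit,
grain (cereals), meat and alternatives, dairy and alternatives, and
beverages and miscellaneous — each split into nutrient-poor
("discretionary") and nutritious food groups (15 and 12 groups
respectively, 27 in total). Five categories have both a nutrient-poor and
a nutritious side; beverages and miscellaneous has only a nutrient-poor
side, giving 11 assessable *slots* (category × healthfulness pairs).
Classification follows a risk-assessment principle: an item is assumed
nutrient-poor unless the menu text demonstrates otherwise.

A menu's score is a penalty fraction:

```
        #{ engaged categories with the nutrient-poor slot present }
          + #{ engaged paired categories whose nutritious slot is absent }
score = ─────────────────────────────────────────────────────────────────  × 100
          Σ over engaged categories (2 if paired, 1 if unpaired)
```

where a category is *engaged* when any of its slots is present on the
menu, and the result is rounded half-up to an integer percent. 0% is the
best case (only nutritious groups offered); 100% the worst (no nutritious
groups at all). Restricting both penalties and denominator to engaged
categories stops narrow menus (an ice-cream shop, a fish-and-chips
outlet) from being advantaged over diverse ones: a menu offering only ice
cream scores 2/2 = 100%, not 6/11. The initial fixed-denominator scheme
(`mode = "fixed"`, always /11) is also provided for comparison.

Availability is presence/absence: one item meeting a group definition
engages its slot, and further items change nothing — which is why the
strongest improvement signal to an operator is to *add* a nutritious
option (removes a penalty point outright) rather than to trim
nutrient-poor ones.

## Worked example

```r
library(mast)
tax <- load_taxonomy()   # the default 6-category / 27-group scheme

menu <- mast_menu("cafe-01", "cafe_coffee_shop", items = tibble::tibble(
  name = c("Garlic bread", "Chicken parmigiana", "Garden salad",
           "Flat white", "Cola")))

a <- assess_menu(menu, tax)
score_assessment(a, tax)
#> <mast_score 'cafe-01'> 5/9 = 56% (engaged mode)

writeLines(render_signals(improvement_signals(a, tax), tax))
#> Improvement signals for outlet cafe-01:
#>   Add nutritious options (strongest signal):
#>     - Grain (cereals)
#>     - Meat and alternatives
#>   Reduce nutrient-poor options:
#>     - Grain (cereals) (e.g. item item-001)
#>     - Meat and alternatives (e.g. item item-002)
#>     - Beverages and miscellaneous (e.g. item item-005)
```

Five categories are engaged (garlic bread → grain nutrient-poor, chicken
parmigiana → meat nutrient-poor, garden salad → vegetables nutritious,
flat white → dairy nutritious, cola → beverages), so the denominator is
2+2+2+2+1 = 9. Penalties: three nutrient-poor slots present, plus grain
and meat lacking any nutritious item — 5 points, hence 5/9 = 56%.
Adding, say, a grilled chicken salad and a wholemeal roll would drop the
score to 3/9 = 33%.

Batch use, from a shell:

```sh
Rscript inst/cli/mast.R validate
Rscript inst/cli/mast.R fixtures pilot --out fixtures/
Rscript inst/cli/mast.R score --menus fixtures/ --out results/
Rscript inst/cli/mast.R summarize --scores results/scores.csv
```

The taxonomy is a plain YAML file (`inst/extdata/default-taxonomy.yaml`):
categories, groups, definitions and the cue lexicons the classifier
matches against. Adapting the tool to another country's dietary
guidelines means editing that one file — no code changes.

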