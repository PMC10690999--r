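---
title: "Sales-weighted nutrient profiling of company portfolios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sales-weighted nutrient profiling of company portfolios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npmprofiler)
```

## The problem and the model

Public-health organizations weighing engagement with a food or beverage
manufacturer need a quantitative, auditable answer to one question: *what
share of this company's revenue comes from unhealthy products?* The answer
requires joining two views of the market that are never sold together —
brand-level value sales from market-research panels, and product-level
nutrient composition from label databases — and a defensible rule for
calling a product unhealthy.

`npmprofiler` uses the WHO Regional Office for Europe nutrient profile
model (First Edition, 2015) as its default rule set. The model assigns
every pre-packaged food to one of 20 categories and asks, per category,
whether the product may be marketed to children. Three category modes
exist:

* **never permitted** — chocolate and sugar confectionery; cakes, sweet
  biscuits and pastries; edible ices; energy drinks; juices. Composition is
  irrelevant; every product fails.
* **always permitted** — fresh and frozen fruit, vegetables and legumes;
  fresh and frozen meat, poultry and fish. Every product passes.
* **threshold evaluated** — the remaining categories carry per-100 g/ml
  maxima on some subset of {energy (kcal), total fat, saturated fat, trans
  fat, total sugars, salt}, and some additionally prohibit added sugars
  and/or non-sugar sweeteners (NSS) outright (all beverages, savoury
  snacks).

A product fails — is classified **unhealthy** — if any present nutrient
*strictly exceeds* its maximum or a prohibited sweetener is present;
otherwise it passes and is **healthier**. We read "exceed" literally:
equality with a maximum passes. The thresholds live in
`inst/extdata/who_euro_2015.json`, transcribed from the published WHO Euro
model; because the table is data, a user who disagrees with any transcribed
value — or wants a different NPM entirely — edits a JSON file rather than
code, and `load_threshold_table()` validates the result (complete category
vocabulary, one rule per category, non-negative maxima, criteria present
exactly for threshold-evaluated rules).

Units are harmonized before evaluation: salt from sodium (× 2.5, mg→g) and
energy from kJ (÷ 4.184) when only one of the pair is present. Per-100 ml
beverages are treated identically to per-100 g foods, as the model applies
its thresholds on a per-100 g basis across the board.

## Missing data and the unclassifiable verdict

Label extracts are incomplete, and the handling of gaps was a genuinely
open design choice. We classify a product as **unclassifiable** when its
category's rule names a nutrient that is absent after unit normalization
*and* no other criterion has already failed (a product that is over the
salt maximum is unhealthy regardless of a missing sugar value).
Unclassifiable sales are excluded from every percentage denominator and
reported separately — the same treatment as unmatched brands, and for the
same reason: a denominator mixing verdicts with non-verdicts would be
neither a proportion of classified sales nor of all sales. Trans fat is the
one exception: it is missing from almost all label extracts, so a rule's
trans-fat maximum is evaluated only when a value is present rather than
dragging whole categories into unclassifiability.

## Ingredient screening

The model's added-sugar and NSS prohibitions need a detector, and no
standard one exists for free-text ingredient lists. We chose transparent
lexicon matching over anything statistical: the shipped lexicon
(`inst/extdata/sweetener_lexicon.json`) lists added-sugar synonyms
(sucrose, glucose syrup, honey, ...) and NSS terms including the EU
additive codes E950–E969 and polyols, and matching is case-insensitive
whole-token/phrase matching after punctuation normalization. Two
safeguards keep it honest: multi-word negative-context phrases ("no added
sugar", "sugar snap peas") are blanked out before matching, and token
boundaries prevent substring hits ("honeydew" does not contain the term
"honey"). The lexicon is English-only by design; users profiling
non-English markets supply per-language lexicons. Products with empty
ingredient text are *unscreenable*: they are treated as sweetener-free
rather than unclassifiable — flagging them unclassifiable would eject
entire beverage categories from the denominator on a data-entry artifact —
and their count is reported with every run.

## Linkage and equal-split allocation

Sales are reported per brand ("Yoplait"), composition per product
("Yoplait Original 450 g"). Matching is an **exact join on normalized
(company, country, brand key)**: case folded, trademark glyphs removed,
diacritics transliterated, punctuation collapsed. We deliberately rejected
automatic fuzzy matching — a wrong silent match corrupts a company's
statistic invisibly, while an unmatched brand is at least visible in the
coverage table. Brands with no match are excluded and their sales value
reported (value share, per country and overall).

A matched brand's sales are split equally across its *n_b* matched
variants: *v_i = V_b / n_b*. This is the method's central approximation —
real variant sales are not equal — but variant-level sales data are
effectively unavailable, and the equal split is unbiased absent any
information to the contrary. Allocation conserves sales by construction
and is checked to 1e-6 relative tolerance in the tests.

Out-of-scope records are excluded by rule before matching, each with a
single reason code: baby food and infant formula (the model does not cover
them), pet food/home care and other non-food, alcohol, and brands mapped
to the whole-fresh-meat category (treated as excluded, not unmatched,
since the exclusion is structural rather than a linkage failure).

## Aggregation and reporting

Within any scope (overall, company, category) the unhealthy percentage is
the allocated-sales-weighted share of unhealthy products among
*classifiable matched* sales; healthier and unhealthy percentages sum to
100 by construction. Percentages are computed as `100 * (num/den)` so that
a complete scope yields exactly 100. Human-readable output rounds to whole
percent; machine output (`reports.csv`, `summary.json`) keeps full
precision. The healthier share is also expressed as dollars per $10 spent
(rounded to cents), and engagement verdicts compare each company's
unhealthy percentage against configurable cutoffs using an inclusive
boundary — "at most 25% unhealthy" passes at exactly 25, a reading we fix
in code because prose cutoffs are ambiguous at the boundary.

## The synthetic market and what the tests show

Licensed sales and composition data cannot ship with a package, so the
generator (`generate_market()`) is a first-class module producing both
input tables plus a ground-truth ledger. Its defaults mirror the study
conditions the method was developed under: 20 companies, the 7 countries
AU/BR/CN/IN/ZA/GB/US, 45–85 brands per company (~1300 brands), 5–60
variants per brand (tens of thousands of products), a category mix
weighted toward beverages, confectionery and snacks, 89% of matched value
sales unhealthy and 12.1% of sales value unmatched. Sales magnitudes are
log-uniform over $10^5–$10^9 — arbitrary, since only proportions enter the
results.

Exactness of the planted share is achieved by construction: each matched
brand is planted wholly healthier or wholly unhealthy (never-permitted
categories force unhealthy, always-permitted force healthier; threshold
categories draw a Bernoulli with the target probability, repaired if a
group comes up empty), and then the unhealthy group's sales are rescaled
so the value-weighted share equals the target exactly. Planted unhealthy
products in threshold categories violate one criterion chosen uniformly at
random — including the added-sugar and NSS routes — so every failure path
of the classifier is exercised; planted healthier products sit strictly
below every maximum with clean ingredient text. Unmatched brands are
likewise rescaled to carry exactly the configured fraction of total sales.
An infeasible combination (e.g. a mix of only never-permitted categories
with a target below 1) raises a generation error rather than a silently
missed target.

The test suite verifies: round-trip recovery of the ledger's expected
values (overall, per country, per category) for targets 0, 0.25, 0.5, 0.89
and 1 across five seeds each; agreement of the rules engine with an
independent brute-force criterion-by-criterion re-check on 10,000 random
products; boundary behaviour at/above/below every threshold of every
category; conservation and normalization identities; and byte-identical
output under a fixed seed. Test problem sizes (3–5 companies, a few dozen
brands) keep the default suite in seconds; the generator has been
exercised at full study scale (~300 brands, ~8000 products per 4
companies) with identical round-trip behaviour.

What passing these tests does **not** show: the generator plants
brand-homogeneous verdicts, uncorrelated nutrient panels and clean brand
keys, so it cannot reveal difficulties of real data — variant-level verdict
heterogeneity within a brand, translated or colliding brand names,
systematically missing nutrients, multilingual ingredient text. Those
affect coverage and linkage, which the package surfaces per run, but no
synthetic result here validates the equal-split approximation itself.

## Numerical choices and limitations

* No floating-point tolerance in threshold comparison: config values are
  exact decimals and panels are compared raw after unit normalization.
* Deterministic ordering everywhere (reports sorted by key; joins by row
  index), so identical inputs give byte-identical outputs.
* Single-year analysis; sales year is a passthrough label. No currency
  conversion or deflation.
* Score-based models (Nutri-Score, Health Star Rating, Ofcom) are out of
  scope; the config format expresses per-category threshold/prohibition
  models only.
* One category per brand in the sales table: a real brand spanning
  categories must be split upstream into per-category rows.

## Session info

```{r}
sessionInfo()
```
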