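# npmprofiler

Sales-weighted nutrient profiling of food and beverage company portfolios.

`npmprofiler` quantifies what proportion of a company's value sales derives
from products classified as **unhealthy** under a nutrient profile model
(NPM). It is aimed at public-health organizations, researchers and advocacy
groups that need an objective, transparent basis for deciding whether a food
or beverage manufacturer is high-risk for engagement — and at anyone who
wants to reproduce that kind of portfolio assessment with their own sales
and composition data.

## The method

Two data sources are combined:

1. a **product composition table** — per-100 g/ml nutrient panels (energy,
   fat, saturated fat, sugars, salt, ...) and free-text ingredient lists,
   with a model category pre-assigned to each product;
2. a **brand value-sales table** — annual retail sales *V_b* (USD) per
   brand, with company, country and category.

Each product is classified under the WHO Regional Office for Europe NPM
(First Edition, 2015), which ships with the package as an editable JSON
config. The model covers 20 pre-packaged food categories: five (chocolate
and sugar confectionery; cakes and sweet biscuits; edible ices; energy
drinks; juices) may **never** be marketed to children, two (fresh/frozen
fruit and vegetables; fresh/frozen meat and fish) always may, and the rest
are evaluated against per-100 g/ml maxima plus category-specific
prohibitions on added sugars and non-sugar sweeteners (NSS). A product that
fails any criterion is *unhealthy*; one that passes is *healthier*.
Exceeding means strictly greater: a value exactly at a maximum passes.
Added-sugar and NSS presence is detected from the ingredient list with a
configurable lexicon.

Because sales are reported per brand but composition per product, brand
sales are split equally across the brand's *n_b* matched product variants
(*v_i = V_b / n_b*). The headline statistic is then the sales-weighted
unhealthy proportion

    P_unhealthy = 100 × Σ v_i · 1[product i unhealthy] / Σ v_i ,

computed overall, per company and per category over *matched, classifiable*
sales — brands with no composition match and products missing a required
nutrient are excluded from denominators and reported in a coverage table.
The complementary healthier share is also framed as "healthier dollars per
$10 spent".

Brands outside the model's scope (baby food and infant formula, pet food
and other non-food, alcohol, whole fresh meat) are excluded by rule before
matching. Engagement cutoffs (e.g. at most 49%, 25% or 10% unhealthy) can
be evaluated per company.

## Worked example

No licensed sales or composition data can be redistributed, so the package
includes a synthetic market generator with planted ground truth
(`generate_market()`); by default it emulates a top-20-company study with
89% of matched value sales unhealthy and 12.1% of sales value unmatched.

```r
library(npmprofiler)

cfg <- generator_config(n_companies = 5, brands_per_company = c(10, 30),
                        variants_per_brand = c(2, 12), seed = 2024)
mkt <- generate_market(cfg)
pp  <- profile_portfolio(mkt$products, mkt$sales)
pp
#> Portfolio profile under who_euro_2015 (First Edition (2015))
#>   Matched sales: $4,101,589,794 across 669 products (95 of 114 brands matched)
#>   Unhealthy: 89% of classifiable matched sales; healthier: 11% ($1.10 per $10)
#>   Excluded by rule: 0 brand(s); unmatched: 19 brand(s) (12.1% of sales value)

summary(pp)
#> Company portfolios under who_euro_2015 — overall 89% unhealthy ($1.10 healthier per $10)
#>
#>     company matched_sales_usd unhealthy_pct healthier_pct
#>  Company 02         500097581           100             0
#>  Company 03         657129109           100             0
#>  Company 04        1090162096            98             2
#>  Company 01         308365663            96             4
#>  Company 05        1545835346            73            27
```

The print method reads: of the $4.1bn of brand sales that could be matched
to composition records (the other 12.1% of sales value had no match and is
excluded), 89% was allocated to products failing the WHO Euro model — i.e.
for every $10 spent on these synthetic companies' brands, $1.10 went to
products healthier enough to be marketed to children. The per-company table
shows the same proportions per portfolio; `pp$by_category`, `pp$coverage`
and `pp$engagement` hold the category breakdown, per-country match rates
and threshold verdicts. `plot(pp)` draws the stacked healthier/unhealthy
bars.

File-based workflows use `run_pipeline()` (writes `reports.csv`,
`summary.json` and `run.log`) or the thin CLI at `inst/cli/profiler`
(`profiler simulate|run`). Custom models and lexicons are plain JSON loaded
with `load_threshold_table()` / `load_lexicon()`.

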