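make_report <- function(healthier_pct, matched = 1000) {
  classifiable <- matched
  data.frame(scope = "overall", key = "all",
             matched_sales_usd = matched,
             unhealthy_sales_usd = matched * (100 - healthier_pct) / 100,
             healthier_sales_usd = matched * healthier_pct / 100,
             unclassifiable_sales_usd = 0,
             unhealthy_pct = 100 - healthier_pct,
             healthier_pct = healthier_pct,
             stringsAsFactors = FALSE)
}

test_that("sales-weighted proportions follow the allocations", {
  tab <- who_euro_2015()
  # two products, equal split, one unhealthy -> 50%
  tm <- tiny_market(n_products = 2, sugars = c(1, 40))
  pp <- profile_portfolio(tm$products, tm$sales, tab)
  expect_equal(pp$overall$unhealthy_pct, 50)

  # $90 all-unhealthy brand + $10 all-healthier brand -> 90%
  a <- tiny_market(brand = "Alpha", n_products = 1, sales_usd = 90,
                   sugars = 40)
  b <- tiny_market(brand = "Beta", n_products = 1, sales_usd = 10, sugars = 1)
  pp <- profile_portfolio(rbind(a$products, b$products),
                          rbind(a$sales, b$sales), tab)
  expect_equal(pp$overall$unhealthy_pct, 90)

  # all products in never-permitted categories -> 100% in every scope
  c1 <- tiny_market(brand = "Choc", category = "confectionery",
                    n_products = 3, sales_usd = 70)
  c2 <- tiny_market(brand = "Juicy", category = "juices", n_products = 2,
                    sales_usd = 30)
  pp <- profile_portfolio(rbind(c1$products, c2$products),
                          rbind(c1$sales, c2$sales), tab)
  expect_equal(pp$overall$unhealthy_pct, 100)
  expect_true(all(pp$by_company$unhealthy_pct == 100))
  expect_true(all(pp$by_category$unhealthy_pct == 100))
})

test_that("unclassifiable sales leave the percentage denominator", {
  tab <- who_euro_2015()
  tm <- tiny_market(n_products = 3, sugars = c(1, 40, NA))
  tm$products$total_sugars_g <- c(1, 40, NA)
  pp <- profile_portfolio(tm$products, tm$sales, tab)
  cls <- pp$classifications
  expect_setequal(cls$verdict, c("healthier", "unhealthy", "unclassifiable"))
  # one third of sales unclassifiable; the split is 50/50 on the rest
  expect_equal(pp$overall$unclassifiable_sales_usd, 100 / 3,
               tolerance = 1e-9)
  expect_equal(pp$overall$unhealthy_pct, 50)
  expect_equal(pp$overall$unhealthy_pct + pp$overall$healthier_pct, 100)
})

test_that("per-ten-dollars framing matches the healthier percentage", {
  expect_equal(per_ten_dollars(make_report(11)), 1.10)
  expect_equal(per_ten_dollars(make_report(0)), 0)
  expect_equal(per_ten_dollars(make_report(100)), 10)
  expect_error(per_ten_dollars(make_report(50, matched = 0)),
               class = "npm_value_error")
})

test_that("engagement verdicts use an inclusive boundary", {
  reports <- data.frame(scope = "company",
                        key = c("HighRisk", "Border", "Clean"),
                        unhealthy_pct = c(89, 10, 0),
                        stringsAsFactors = FALSE)
  v <- evaluate_engagement(reports, c(49, 25, 10))
  get <- function(co, thr) v$passes[v$company == co & v$threshold_pct == thr]
  expect_false(get("HighRisk", 49))
  expect_true(get("Border", 10))    # 10 <= 10 passes
  expect_true(all(v$passes[v$company == "Clean"]))
  expect_equal(nrow(v), 9)
  expect_error(evaluate_engagement(reports, c(10, 120)),
               class = "npm_config_error")
})

test_that("coverage summary reports planted and degenerate match rates", {
  mkt <- generate_market(generator_config(n_companies = 3,
                                          brands_per_company = c(2, 5),
                                          variants_per_brand = c(1, 4),
                                          unmatched_fraction = 0.12,
                                          seed = 8))
  mb <- match_brands(mkt$sales, mkt$products)
  cov <- coverage_summary(mb$report)
  expect_equal(cov$matched_pct[cov$country == "overall"], 88,
               tolerance = 1e-9)

  # zero unmatched brands -> 100% matched
  mkt0 <- generate_market(generator_config(n_companies = 2,
                                           brands_per_company = c(2, 4),
                                           variants_per_brand = c(1, 3),
                                           unmatched_fraction = 0,
                                           seed = 8))
  cov0 <- coverage_summary(match_brands(mkt0$sales, mkt0$products)$report)
  expect_true(all(cov0$matched_pct == 100))

  # all brands unmatched -> matched pct 0 and aggregation refuses to run
  mb_none <- match_brands(mkt$sales, mkt$products[0, ])
  expect_equal(coverage_summary(mb_none$report)$matched_pct,
               rep(0, nrow(coverage_summary(mb_none$report))))
  expect_error(profile_portfolio(mkt$products[0, ], mkt$sales),
               class = "npm_value_error")
})

test_that("company and category reports partition the overall sales exactly", {
  mkt <- generate_market(generator_config(n_companies = 4,
                                          brands_per_company = c(2, 6),
                                          variants_per_brand = c(1, 5),
                                          seed = 21))
  pp <- profile_portfolio(mkt$products, mkt$sales)
  for (scope in list(pp$by_company, pp$by_category)) {
    for (col in c("matched_sales_usd", "unhealthy_sales_usd",
                  "healthier_sales_usd", "unclassifiable_sales_usd"))
      expect_equal(sum(scope[[col]]), pp$overall[[col]], tolerance = 1e-9)
  }
  ok <- !is.na(pp$by_company$unhealthy_pct)
  expect_equal(pp$by_company$unhealthy_pct[ok] +
                 pp$by_company$healthier_pct[ok],
               rep(100, sum(ok)), tolerance = 1e-9)
})

test_that("percentages are invariant to rescaling all sales", {
  mkt <- generate_market(generator_config(n_companies = 3,
                                          brands_per_company = c(2, 4),
                                          variants_per_brand = c(1, 4),
                                          seed = 31))
  pp1 <- profile_portfolio(mkt$products, mkt$sales)
  scaled <- mkt$sales
  scaled$value_sales_usd <- scaled$value_sales_usd * 7.3
  pp2 <- profile_portfolio(mkt$products, scaled)
  expect_equal(pp1$overall$unhealthy_pct, pp2$overall$unhealthy_pct,
               tolerance = 1e-9)
  expect_equal(pp1$by_company$unhealthy_pct, pp2$by_company$unhealthy_pct,
               tolerance = 1e-9)
})

test_that("an allocation without a classification is an integrity error", {
  tm <- tiny_market(n_products = 2)
  mb <- match_brands(tm$sales, tm$products)
  alloc <- allocate_sales(tm$sales, mb$matches)
  cls <- classify_products(tm$products, who_euro_2015())
  expect_error(aggregate_portfolio(cls[-1, ], alloc, tm$products, "overall"),
               tm$products$product_id[1], fixed = TRUE,
               class = "npm_integrity_error")
})
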