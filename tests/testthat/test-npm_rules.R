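test_that("packaged WHO Euro table encodes the model's category structure", {
  tab <- who_euro_2015()
  expect_s3_class(tab, "threshold_table")
  expect_length(tab$rules, 20)
  expect_setequal(names(tab$rules), tab$categories)

  expect_equal(tab$rules$confectionery$permission_mode, "never_permitted")
  never <- c("confectionery", "cakes_biscuits", "edible_ices",
             "energy_drinks", "juices")
  for (cc in never)
    expect_equal(tab$rules[[cc]]$permission_mode, "never_permitted")
  expect_equal(tab$rules$fresh_fruit_veg$permission_mode, "always_permitted")
  expect_equal(tab$rules$fresh_meat_fish$permission_mode, "always_permitted")
  # threshold rules carry criteria; never/always rules carry none
  for (r in tab$rules) {
    if (r$permission_mode == "threshold_evaluated")
      expect_true(length(r$maxima) > 0 || r$forbid_added_sugars || r$forbid_nss)
    else
      expect_length(r$maxima, 0)
  }
})

test_that("threshold config validation rejects malformed tables", {
  cfg <- jsonlite::read_json(system.file("extdata", "who_euro_2015.json",
                                         package = "npmprofiler"),
                             simplifyVector = FALSE)
  # a vocabulary category without a rule
  broken <- cfg
  broken$rules <- broken$rules[-1]
  expect_error(load_threshold_table(write_threshold_config(broken)),
               class = "npm_config_error")
  # duplicated category rule
  broken <- cfg
  broken$rules <- c(broken$rules, broken$rules[1])
  expect_error(load_threshold_table(write_threshold_config(broken)),
               "duplicate", class = "npm_config_error")
  # maxima on a never_permitted rule violate the invariant
  broken <- cfg
  broken$rules[[1]]$maxima <- list(total_sugars_g = 5)
  expect_error(load_threshold_table(write_threshold_config(broken)),
               class = "npm_config_error")
  # negative maximum
  broken <- cfg
  idx <- which(vapply(cfg$rules, function(r) r$category_code, character(1)) ==
                 "breakfast_cereals")
  broken$rules[[idx]]$maxima$total_sugars_g <- -1
  expect_error(load_threshold_table(write_threshold_config(broken)),
               class = "npm_config_error")
})

test_that("panel normalization derives salt and energy without touching present values", {
  expect_equal(normalize_panel(data.frame(sodium_mg = 400))$salt_g, 1.0)
  expect_equal(normalize_panel(data.frame(energy_kj = 418.4))$energy_kcal, 100)
  p <- data.frame(sodium_mg = 400, salt_g = 2, energy_kj = 418.4,
                  energy_kcal = 55)
  expect_equal(normalize_panel(p), p)  # identity when both present
  # NA stays NA when nothing is derivable
  expect_true(is.na(normalize_panel(data.frame(salt_g = NA_real_,
                                               total_fat_g = 1))$salt_g))
})

test_that("single-product classification follows the rule modes and boundary convention", {
  tab <- who_euro_2015()
  choc <- list(product_id = "c1", npm_category = "confectionery",
               total_sugars_g = 0, total_fat_g = 0, salt_g = 0)
  res <- classify_product(choc, tab)
  expect_equal(res$verdict, "unhealthy")
  expect_equal(res$failed_criteria, "category_not_permitted")

  zeros <- list(product_id = "z1", npm_category = "breakfast_cereals",
                energy_kcal = 0, total_fat_g = 0, total_sugars_g = 0,
                salt_g = 0)
  expect_equal(classify_product(zeros, tab)$verdict, "healthier")

  # equality with a maximum passes ("exceed" is strict)
  at_max <- list(product_id = "b1", npm_category = "breakfast_cereals",
                 total_fat_g = 0, total_sugars_g = 15, salt_g = 0)
  expect_equal(classify_product(at_max, tab)$verdict, "healthier")
  just_over <- at_max; just_over$total_sugars_g <- 15.0001
  res <- classify_product(just_over, tab)
  expect_equal(res$verdict, "unhealthy")
  expect_equal(res$failed_criteria, "total_sugars_g_exceeds_max")

  # a required nutrient missing (and nothing else failing) is unclassifiable
  missing_sugar <- list(product_id = "m1", npm_category = "breakfast_cereals",
                        total_fat_g = 0, salt_g = 0)
  res <- classify_product(missing_sugar, tab)
  expect_equal(res$verdict, "unclassifiable")
  expect_match(res$reason, "missing_nutrient")
  # ... but a failure elsewhere takes precedence over the missing value
  missing_but_salty <- missing_sugar; missing_but_salty$salt_g <- 99
  expect_equal(classify_product(missing_but_salty, tab)$verdict, "unhealthy")

  expect_error(classify_product(list(product_id = "x",
                                     npm_category = "nonesuch"), tab),
               "nonesuch", class = "npm_classification_error")
})

test_that("sweetener prohibitions are category-specific", {
  tab <- who_euro_2015()
  # soft drinks fail on either flag even with an empty panel
  soda <- list(product_id = "s", npm_category = "other_beverages")
  expect_equal(classify_product(soda, tab, sugar_flag = TRUE)$verdict,
               "unhealthy")
  expect_equal(classify_product(soda, tab, nss_flag = TRUE)$verdict,
               "unhealthy")
  expect_equal(classify_product(soda, tab)$verdict, "healthier")
  # bread has no sweetener prohibition: the flag alone cannot fail it
  loaf <- list(product_id = "b", npm_category = "bread", total_fat_g = 1,
               total_sugars_g = 3, salt_g = 1)
  expect_equal(classify_product(loaf, tab, sugar_flag = TRUE)$verdict,
               "healthier")
  # panel added_sugars_g > 0 sets the flag in the vectorized path
  soda_df <- data.frame(product_id = "s2", npm_category = "other_beverages",
                        added_sugars_g = 5, ingredients_text = "water")
  expect_equal(classify_products(soda_df, tab)$verdict, "unhealthy")
})

test_that("classification is deterministic and forced by category over random panels", {
  tab <- who_euro_2015()
  set.seed(101)
  prods <- random_products(2000)
  flags <- screen_ingredients(prods$ingredients_text)
  a <- classify_products(prods, tab, screen = flags)
  b <- classify_products(prods, tab, screen = flags)
  expect_identical(a, b)

  never <- c("confectionery", "cakes_biscuits", "edible_ices",
             "energy_drinks", "juices")
  always <- c("fresh_fruit_veg", "fresh_meat_fish")
  expect_true(all(a$verdict[prods$npm_category %in% never] == "unhealthy"))
  expect_true(all(a$verdict[prods$npm_category %in% always] == "healthier"))
})

test_that("lowering a maximum never flips a product from unhealthy to healthier", {
  tab <- who_euro_2015()
  set.seed(202)
  prods <- random_products(600, na_rate = 0)
  screen <- screen_ingredients(prods$ingredients_text)
  before <- classify_products(prods, tab, screen = screen)

  for (cc in c("breakfast_cereals", "ready_made", "savoury_snacks")) {
    for (nut in names(tab$rules[[cc]]$maxima)) {
      lowered <- tab
      lowered$rules[[cc]]$maxima[[nut]] <-
        lowered$rules[[cc]]$maxima[[nut]] / 2
      after <- classify_products(prods, lowered, screen = screen)
      flipped <- before$verdict == "unhealthy" & after$verdict == "healthier"
      expect_false(any(flipped),
                   info = sprintf("%s / %s lowered", cc, nut))
    }
  }
})
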