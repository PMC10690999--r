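# Shared fixture builders. All fixtures are constructed in code; callers own
# the RNG state (set.seed before use where draws are involved).

# n products with fully random nutrient panels (occasionally missing values)
# and ingredient text drawn from a mixed pool. Categories default to the
# full WHO Euro vocabulary.
random_products <- function(n, categories = NULL, na_rate = 0.05,
                            company = "ACME", country = "US",
                            brand = NULL) {
  if (is.null(categories)) categories <- who_euro_2015()$categories
  pool <- c("water", "wheat flour", "rolled oats", "salt", "tomatoes",
            "sucrose", "glucose syrup", "honey", "aspartame", "sucralose",
            "steviol glycosides", "milk", "rice", "vegetable oil")
  maybe_na <- function(x) ifelse(stats::runif(n) < na_rate, NA_real_, x)
  data.frame(
    product_id = sprintf("R%05d", seq_len(n)),
    company = company,
    country = country,
    brand = if (is.null(brand)) sprintf("Brand %03d", seq_len(n)) else brand,
    npm_category = sample(categories, n, replace = TRUE),
    energy_kcal = maybe_na(stats::runif(n, 0, 600)),
    energy_kj = NA_real_,
    total_fat_g = maybe_na(stats::runif(n, 0, 40)),
    saturated_fat_g = maybe_na(stats::runif(n, 0, 25)),
    trans_fat_g = maybe_na(stats::runif(n, 0, 3)),
    total_sugars_g = maybe_na(stats::runif(n, 0, 60)),
    fibre_g = stats::runif(n, 0, 10),
    protein_g = stats::runif(n, 0, 30),
    carbohydrate_g = stats::runif(n, 0, 80),
    salt_g = maybe_na(stats::runif(n, 0, 4)),
    ingredients_text = vapply(seq_len(n), function(i)
      paste(sample(pool, sample(2:5, 1)), collapse = ", "), character(1)),
    stringsAsFactors = FALSE)
}

# one matched brand + products pair: brand sales record and its variants
tiny_market <- function(brand = "Brandy", company = "ACME", country = "US",
                        category = "breakfast_cereals", n_products = 2,
                        sales_usd = 100, sugars = rep(1, n_products)) {
  sales <- data.frame(company = company, country = country, brand = brand,
                      sector_tag = "packaged_food", npm_category = category,
                      value_sales_usd = sales_usd, year = 2020L,
                      stringsAsFactors = FALSE)
  products <- data.frame(
    product_id = sprintf("%s-%02d", gsub(" ", "", brand), seq_len(n_products)),
    company = company, country = country, brand = brand,
    npm_category = category,
    energy_kcal = 100, total_fat_g = 1, saturated_fat_g = 0.5,
    total_sugars_g = sugars, salt_g = 0.1,
    ingredients_text = "rolled oats, salt",
    stringsAsFactors = FALSE)
  list(sales = sales, products = products)
}

# Independent brute-force classifier used as an oracle: reads the packaged
# JSON config itself and evaluates every criterion with explicit loops,
# sharing no code with classify_products.
oracle_classify <- function(products, sugar_flag, nss_flag) {
  cfg <- jsonlite::read_json(system.file("extdata", "who_euro_2015.json",
                                         package = "npmprofiler"),
                             simplifyVector = FALSE)
  rules <- cfg$rules
  names(rules) <- vapply(rules, function(r) r$category_code, character(1))
  out <- character(nrow(products))
  for (i in seq_len(nrow(products))) {
    r <- rules[[products$npm_category[i]]]
    if (r$permission_mode == "never_permitted") { out[i] <- "unhealthy"; next }
    if (r$permission_mode == "always_permitted") { out[i] <- "healthier"; next }
    get_val <- function(nm) {
      v <- if (nm %in% names(products)) products[[nm]][i] else NA_real_
      if (nm == "salt_g" && is.na(v) && "sodium_mg" %in% names(products) &&
          !is.na(products$sodium_mg[i]))
        v <- products$sodium_mg[i] * 2.5 / 1000
      if (nm == "energy_kcal" && is.na(v) && "energy_kj" %in% names(products) &&
          !is.na(products$energy_kj[i]))
        v <- products$energy_kj[i] / 4.184
      v
    }
    fail <- FALSE; miss <- FALSE
    for (nm in names(r$maxima)) {
      v <- get_val(nm)
      if (is.na(v)) {
        if (nm != "trans_fat_g") miss <- TRUE
      } else if (v > r$maxima[[nm]]) fail <- TRUE
    }
    if (isTRUE(r$forbid_added_sugars) && sugar_flag[i]) fail <- TRUE
    if (isTRUE(r$forbid_nss) && nss_flag[i]) fail <- TRUE
    out[i] <- if (fail) "unhealthy" else if (miss) "unclassifiable"
              else "healthier"
  }
  out
}

write_threshold_config <- function(cfg, path = tempfile(fileext = ".json")) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  path
}
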