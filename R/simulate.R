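# Synthetic market generator with planted ground truth.
#
# Emulates the two licensed data sources the method consumes — a product
# composition extract and a brand value-sales extract — at the scale of the
# original study: 20 companies across 7 countries, ~1300 brands, tens of
# thousands of product variants, 89% of matched value sales unhealthy and
# 12.1% of sales value unmatched. Only proportions matter downstream, so
# sales magnitudes are drawn log-uniform over $1e5-$1e9 and then the
# unhealthy group's sales are rescaled so the value-weighted unhealthy share
# hits the target exactly.

.default_category_mix <- function() {
  # weighted toward the revenue-dominant categories (beverages,
  # confectionery, snacks), with the rest spread thin
  c(confectionery = 0.16, other_beverages = 0.16, savoury_snacks = 0.12,
    cakes_biscuits = 0.10, juices = 0.06, milk_drinks = 0.05,
    energy_drinks = 0.03, edible_ices = 0.04, breakfast_cereals = 0.05,
    yoghurts_cream = 0.05, cheese = 0.03, ready_made = 0.05,
    butter_fats_oils = 0.02, bread = 0.03, pasta_rice_grains = 0.02,
    processed_meat_fish = 0.01, fresh_fruit_veg = 0.005,
    processed_fruit_veg = 0.005, sauces_dips = 0.01)
}

.study_countries <- c("AU", "BR", "CN", "IN", "ZA", "GB", "US")

# sample one integer from an inclusive range (safe for degenerate ranges)
.sample_range <- function(r) {
  if (r[1] == r[2]) return(r[1])
  sample(seq(r[1], r[2]), 1)
}

#' Configuration for the synthetic market generator
#'
#' Defaults emulate the conditions of a top-20 global manufacturer study:
#' 20 companies in 7 countries, 45-85 brands per company (about 1300 brands),
#' 5-60 product variants per brand (tens of thousands of products), 89% of
#' matched value sales planted unhealthy, and 12.1% of sales value carried by
#' brands with no composition record.
#'
#' @param n_companies Number of companies.
#' @param brands_per_company Integer range \code{c(min, max)}.
#' @param variants_per_brand Integer range \code{c(min, max)}.
#' @param category_mix Named probability vector over category codes; must sum
#'   to 1.
#' @param target_unhealthy_share Fraction of matched value sales that must
#'   classify unhealthy, in [0, 1].
#' @param unmatched_fraction Fraction of total sales value carried by brands
#'   with no composition records, in [0, 1).
#' @param countries Character vector of ISO country codes.
#' @param seed Integer random seed; the same config and seed reproduce the
#'   generated tables exactly.
#' @return A validated list of class \code{generator_config}.
#' @export
generator_config <- function(n_companies = 20,
                             brands_per_company = c(45, 85),
                             variants_per_brand = c(5, 60),
                             category_mix = .default_category_mix(),
                             target_unhealthy_share = 0.89,
                             unmatched_fraction = 0.121,
                             countries = .study_countries,
                             seed = 1L) {
  if (abs(sum(category_mix) - 1) > 1e-8)
    npm_config_error("category_mix probabilities must sum to 1")
  if (any(category_mix < 0))
    npm_config_error("category_mix probabilities must be non-negative")
  if (target_unhealthy_share < 0 || target_unhealthy_share > 1)
    npm_config_error("target_unhealthy_share must lie in [0, 1]")
  if (unmatched_fraction < 0 || unmatched_fraction >= 1)
    npm_config_error("unmatched_fraction must lie in [0, 1)")
  stopifnot(n_companies >= 1, length(brands_per_company) == 2,
            length(variants_per_brand) == 2,
            all(brands_per_company >= 1), all(variants_per_brand >= 1))
  structure(list(n_companies = as.integer(n_companies),
                 brands_per_company = as.integer(brands_per_company),
                 variants_per_brand = as.integer(variants_per_brand),
                 category_mix = category_mix,
                 target_unhealthy_share = target_unhealthy_share,
                 unmatched_fraction = unmatched_fraction,
                 countries = countries,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# A panel guaranteed to pass `rule` (threshold_evaluated): every nutrient in
# the maxima present and strictly below it; remaining fields small.
.passing_panel <- function(rule) {
  panel <- list(energy_kcal = stats::runif(1, 20, 180),
                total_fat_g = stats::runif(1, 0, 3),
                saturated_fat_g = stats::runif(1, 0, 1),
                total_sugars_g = stats::runif(1, 0, 4),
                salt_g = stats::runif(1, 0, 0.08),
                fibre_g = stats::runif(1, 0, 5),
                protein_g = stats::runif(1, 0, 10),
                carbohydrate_g = stats::runif(1, 0, 40))
  for (nut in names(rule$maxima))
    panel[[nut]] <- stats::runif(1, 0, max(rule$maxima[[nut]] * 0.8,
                                           min(rule$maxima[[nut]], 0.01)))
  # keep the hierarchy sane
  panel$saturated_fat_g <- min(panel$saturated_fat_g, panel$total_fat_g)
  panel$energy_kj <- panel$energy_kcal * 4.184
  panel
}

.clean_ingredients <- c("water", "wheat flour", "rolled oats", "milk",
                        "tomatoes", "rice", "vegetable oil", "sea salt",
                        "peas", "lentils", "natural flavouring")
.sugar_ingredients <- c("sucrose", "glucose syrup", "honey",
                        "high fructose corn syrup")
.nss_ingredients <- c("aspartame", "sucralose", "acesulfame k",
                      "steviol glycosides")

# Build one product row for a brand with a planted verdict. Unhealthy
# products in threshold categories violate one criterion chosen uniformly at
# random among the category's criteria, so every failure path is exercised.
.planted_product <- function(pid, brand, rule, verdict) {
  panel <- .passing_panel(rule)
  ingredients <- paste(sample(.clean_ingredients, 3), collapse = ", ")
  if (verdict == "unhealthy" && rule$permission_mode == "threshold_evaluated") {
    criteria <- names(rule$maxima)
    if (rule$forbid_added_sugars) criteria <- c(criteria, ".added_sugar")
    if (rule$forbid_nss) criteria <- c(criteria, ".nss")
    pick <- sample(criteria, 1)
    if (pick == ".added_sugar") {
      ingredients <- paste(ingredients, sample(.sugar_ingredients, 1),
                           sep = ", ")
    } else if (pick == ".nss") {
      ingredients <- paste(ingredients, sample(.nss_ingredients, 1),
                           sep = ", ")
    } else {
      panel[[pick]] <- rule$maxima[[pick]] * stats::runif(1, 1.2, 2) + 0.5
      if (pick == "energy_kcal") panel$energy_kj <- panel$energy_kcal * 4.184
    }
  }
  c(list(product_id = pid, brand = brand, npm_category = rule$category_code,
         ingredients_text = ingredients), panel)
}

#' Generate a synthetic market with planted ground truth
#'
#' Draws companies, brands, categories, product variants and sales values
#' under \code{config}, plants each matched brand's products as uniformly
#' healthier or uniformly unhealthy against \code{table}'s rules, and
#' rescales sales so that (a) the value-weighted unhealthy share of matched
#' sales equals \code{target_unhealthy_share} exactly and (b) unmatched
#' brands carry exactly \code{unmatched_fraction} of total sales value. The
#' returned ledger records the planted truth for verification.
#'
#' Brands in never-permitted categories are necessarily unhealthy and brands
#' in always-permitted categories necessarily healthier; a target share of 0
#' (or 1) is infeasible when the drawn category mix forces the opposite
#' verdict, and generation stops with an error explaining the conflict.
#'
#' @param config A \code{\link{generator_config}}.
#' @param table A \code{threshold_table} the planted products are built
#'   against.
#' @return A list of class \code{synthetic_market}: \code{products} and
#'   \code{sales} data.frames (the two pipeline inputs) and \code{ledger},
#'   a list holding per-brand planted verdicts and sales, the exact expected
#'   unhealthy percentage, expected matched percentage overall and per
#'   country, and expected per-category unhealthy shares.
#' @export
generate_market <- function(config = generator_config(),
                            table = who_euro_2015()) {
  stopifnot(inherits(config, "generator_config"),
            inherits(table, "threshold_table"))
  set.seed(config$seed)
  mix <- config$category_mix
  bad_cat <- setdiff(names(mix), names(table$rules))
  if (length(bad_cat))
    npm_config_error(sprintf("category_mix names unknown to the table: %s",
                             paste(bad_cat, collapse = ", ")))
  p <- config$target_unhealthy_share

  companies <- sprintf("Company %02d", seq_len(config$n_companies))
  brands <- list()
  b <- 0L
  for (co in companies) {
    nb <- .sample_range(config$brands_per_company)
    for (j in seq_len(nb)) {
      b <- b + 1L
      cat_code <- sample(names(mix), 1, prob = mix)
      mode <- table$rules[[cat_code]]$permission_mode
      verdict <- switch(mode,
        never_permitted = "unhealthy",
        always_permitted = "healthier",
        threshold_evaluated = if (stats::runif(1) < p) "unhealthy" else "healthier")
      brands[[b]] <- list(
        brand = sprintf("%s Brand %04d", co, b),
        company = co,
        country = sample(config$countries, 1),
        npm_category = cat_code,
        verdict = verdict,
        matched = TRUE,
        value_sales_usd = 10^stats::runif(1, 5, 9))
    }
  }

  # feasibility of the exact target under the forced verdicts; a share
  # strictly between 0 and 1 needs at least one brand in each group, so an
  # unlucky Bernoulli draw is repaired by flipping one threshold-evaluated
  # brand rather than failing
  verdicts <- vapply(brands, `[[`, character(1), "verdict")
  modes <- vapply(brands, function(x)
    table$rules[[x$npm_category]]$permission_mode, character(1))
  flip_one <- function(to) {
    i <- which(modes == "threshold_evaluated")[1]
    if (is.na(i))
      npm_generation_error(sprintf(paste(
        "target_unhealthy_share = %g needs at least one %s brand, but the",
        "drawn category mix forces every brand's verdict"), p, to))
    brands[[i]]$verdict <<- to
    verdicts[i] <<- to
  }
  if (p > 0 && p < 1) {
    if (!any(verdicts == "unhealthy")) flip_one("unhealthy")
    if (!any(verdicts == "healthier")) flip_one("healthier")
  }
  if (p < 1 && !any(verdicts == "healthier"))
    npm_generation_error(paste(
      "target_unhealthy_share < 1 but every drawn brand is forced unhealthy",
      "(category mix contains no category that can pass the model)"))
  if (p > 0 && !any(verdicts == "unhealthy"))
    npm_generation_error(paste(
      "target_unhealthy_share > 0 but every drawn brand is forced healthier",
      "(category mix contains no category that can fail the model)"))

  sales_v <- vapply(brands, `[[`, numeric(1), "value_sales_usd")
  u_sel <- verdicts == "unhealthy"
  U <- sum(sales_v[u_sel]); H <- sum(sales_v[!u_sel])
  if (p == 1) {
    if (H > 0) npm_generation_error(
      "target_unhealthy_share = 1 conflicts with always-permitted brands in the mix")
  } else if (p == 0) {
    if (U > 0) npm_generation_error(
      "target_unhealthy_share = 0 conflicts with never-permitted brands in the mix")
  } else {
    sales_v[u_sel] <- sales_v[u_sel] * (p * H) / ((1 - p) * U)
  }
  for (i in seq_along(brands)) brands[[i]]$value_sales_usd <- sales_v[i]
  matched_total <- sum(sales_v)

  # unmatched brands: extra sales rows with no composition records, scaled
  # so unmatched / (matched + unmatched) = unmatched_fraction exactly
  u_frac <- config$unmatched_fraction
  if (u_frac > 0) {
    n_unmatched <- max(1L, round(length(brands) * 0.2))
    uv <- 10^stats::runif(n_unmatched, 5, 9)
    uv <- uv * (u_frac * matched_total) / ((1 - u_frac) * sum(uv))
    for (k in seq_len(n_unmatched)) {
      b <- b + 1L
      brands[[b]] <- list(
        brand = sprintf("Unmatched Brand %04d", k),
        company = sample(companies, 1),
        country = sample(config$countries, 1),
        npm_category = sample(names(mix), 1, prob = mix),
        verdict = NA_character_,
        matched = FALSE,
        value_sales_usd = uv[k])
    }
  }

  ledger_brands <- do.call(rbind, lapply(brands, function(x)
    data.frame(brand = x$brand, company = x$company, country = x$country,
               npm_category = x$npm_category, verdict = x$verdict,
               matched = x$matched, value_sales_usd = x$value_sales_usd,
               stringsAsFactors = FALSE)))

  sales <- data.frame(
    company = ledger_brands$company,
    country = ledger_brands$country,
    brand = ledger_brands$brand,
    sector_tag = "packaged_food",
    npm_category = ledger_brands$npm_category,
    value_sales_usd = ledger_brands$value_sales_usd,
    year = 2020L,
    stringsAsFactors = FALSE)

  rows <- list()
  pid <- 0L
  for (x in brands) {
    if (!x$matched) next
    rule <- table$rules[[x$npm_category]]
    nv <- .sample_range(config$variants_per_brand)
    for (v in seq_len(nv)) {
      pid <- pid + 1L
      row <- .planted_product(sprintf("P%06d", pid), x$brand, rule, x$verdict)
      row$company <- x$company
      row$country <- x$country
      rows[[pid]] <- row
    }
  }
  all_cols <- unique(unlist(lapply(rows, names)))
  products <- as.data.frame(
    lapply(stats::setNames(all_cols, all_cols), function(cn)
      unlist(lapply(rows, function(r) r[[cn]] %||% NA))),
    stringsAsFactors = FALSE)

  mt <- ledger_brands[ledger_brands$matched, , drop = FALSE]
  exp_unhealthy_pct <- 100 * (sum(mt$value_sales_usd[mt$verdict == "unhealthy"]) /
    sum(mt$value_sales_usd))
  total_sales <- sum(ledger_brands$value_sales_usd)
  exp_matched_pct <- 100 * (sum(mt$value_sales_usd) / total_sales)
  per_country <- do.call(rbind, lapply(
    split(ledger_brands, ledger_brands$country), function(d)
      data.frame(country = d$country[1],
                 matched_pct = 100 * (sum(d$value_sales_usd[d$matched]) /
                   sum(d$value_sales_usd)),
                 stringsAsFactors = FALSE)))
  rownames(per_country) <- NULL
  per_category <- do.call(rbind, lapply(
    split(mt, mt$npm_category), function(d)
      data.frame(npm_category = d$npm_category[1],
                 unhealthy_pct = 100 *
                   sum(d$value_sales_usd[d$verdict == "unhealthy"]) /
                   sum(d$value_sales_usd),
                 stringsAsFactors = FALSE)))
  rownames(per_category) <- NULL

  structure(list(
    products = products,
    sales = sales,
    ledger = list(config = unclass(config),
                  brands = ledger_brands,
                  expected_unhealthy_pct = exp_unhealthy_pct,
                  expected_matched_pct = exp_matched_pct,
                  expected_matched_pct_by_country = per_country,
                  expected_unhealthy_pct_by_category = per_category)),
    class = "synthetic_market")
}

#' Boundary products for every threshold criterion
#'
#' For every threshold-evaluated category and every nutrient in its maxima,
#' emits three probe products: exactly at the maximum (must pass), a step
#' above (must fail) and a step below (must pass; omitted when the maximum is
#' 0). All other required nutrients are held at 0 and ingredient text is
#' clean, so each probe isolates one criterion.
#'
#' @param table A \code{threshold_table}.
#' @param step Offset used for the above/below probes (default 0.1 units).
#' @return A products data.frame with a \code{probe} column
#'   (\code{at_max}/\code{above_max}/\code{below_max}) and \code{probe_nutrient}.
#' @export
generate_boundary_products <- function(table = who_euro_2015(), step = 0.1) {
  stopifnot(inherits(table, "threshold_table"))
  rows <- list()
  k <- 0L
  for (rule in table$rules) {
    if (rule$permission_mode != "threshold_evaluated") next
    for (nut in names(rule$maxima)) {
      m <- rule$maxima[[nut]]
      probes <- c(at_max = m, above_max = m + step,
                  below_max = if (m - step >= 0) m - step else NA_real_)
      for (pr in names(probes)) {
        if (is.na(probes[[pr]])) next
        k <- k + 1L
        panel <- stats::setNames(as.list(rep(0, length(rule$maxima))),
                                 names(rule$maxima))
        panel[[nut]] <- probes[[pr]]
        rows[[k]] <- c(list(product_id = sprintf("B%04d", k),
                            npm_category = rule$category_code,
                            probe = pr, probe_nutrient = nut,
                            ingredients_text = "water"),
                       panel)
      }
    }
  }
  all_cols <- unique(unlist(lapply(rows, names)))
  as.data.frame(
    lapply(stats::setNames(all_cols, all_cols), function(cn)
      unlist(lapply(rows, function(r) r[[cn]] %||% NA))),
    stringsAsFactors = FALSE)
}
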