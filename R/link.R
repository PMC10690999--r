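# Brand-to-product record linkage and equal-split sales allocation.

#' Normalize a brand label into a join key
#'
#' Deterministic normalization for exact brand joins: trademark glyphs
#' removed, case folded, diacritics transliterated to ASCII, punctuation
#' collapsed to single spaces. "Yoplait®  Original" and
#' "yoplait original" share a key, as do "COCA-COLA" and "Coca Cola".
#'
#' @param label Character vector of brand labels; must be non-empty.
#' @return Character vector of normalized keys.
#' @export
normalize_brand_key <- function(label) {
  label <- as.character(label)
  if (length(label) == 0L || any(is.na(label)) || any(!nzchar(trimws(label))))
    npm_input_error("brand label must be a non-empty string")
  x <- gsub("[®™©]", "", label)
  x <- tolower(trimws(x))
  y <- iconv(x, "UTF-8", "ASCII//TRANSLIT")
  y[is.na(y)] <- x[is.na(y)]
  # glibc transliteration inserts quote marks for accents (cafe' etc.);
  # delete those before collapsing remaining punctuation to spaces
  y <- gsub("['\"`^~]", "", y)
  y <- gsub("[^a-z0-9]+", " ", y)
  y <- trimws(gsub(" +", " ", y))
  if (any(!nzchar(y)))
    npm_input_error("brand label normalizes to an empty key")
  y
}

#' Default exclusion rules for brand sales records
#'
#' Encodes which records fall outside the model's scope: prepared baby foods
#' and infant formula (not covered by the model), non-food sectors such as
#' pet food and home care, alcohol and low-alcohol products, and brands
#' mapped to the whole fresh/frozen meat category for which sales data are
#' unavailable.
#'
#' @return A list with \code{sector} (named map sector_tag -> reason) and
#'   \code{category} (named map npm_category -> reason), plus
#'   \code{known_sectors}, the tags that pass without exclusion.
#' @export
default_exclusion_rules <- function() {
  list(
    sector = c(infant_formula = "baby_food_formula",
               baby_food = "baby_food_formula",
               pet_food = "non_food",
               home_care = "non_food",
               non_food = "non_food",
               alcohol = "alcohol",
               low_alcohol = "alcohol"),
    category = c(fresh_meat_fish = "whole_meat_unavailable"),
    known_sectors = c("packaged_food", "soft_drinks")
  )
}

#' Partition sales records into analysable and excluded
#'
#' Applies the exclusion rules to brand sales records. Each excluded record
#' is tagged with exactly one reason (\code{baby_food_formula},
#' \code{non_food}, \code{alcohol} or \code{whole_meat_unavailable}); sector
#' rules take precedence over category rules. Records with an unrecognized
#' sector tag are kept with a warning.
#'
#' @param sales A data.frame of brand sales records with columns
#'   \code{sector_tag} and \code{npm_category} (others pass through).
#' @param rules Exclusion rules, see \code{\link{default_exclusion_rules}}.
#' @return A list with \code{kept} and \code{excluded}; \code{excluded}
#'   carries an extra \code{exclusion_reason} column. Every input row lands
#'   in exactly one of the two.
#' @export
apply_exclusions <- function(sales, rules = default_exclusion_rules()) {
  stopifnot(is.data.frame(sales))
  n <- nrow(sales)
  sector <- as.character(sales$sector_tag %||% rep("packaged_food", n))
  category <- as.character(sales$npm_category %||% rep(NA_character_, n))

  reason <- rep(NA_character_, n)
  hit <- sector %in% names(rules$sector)
  reason[hit] <- unname(rules$sector[sector[hit]])
  cat_hit <- is.na(reason) & category %in% names(rules$category)
  reason[cat_hit] <- unname(rules$category[category[cat_hit]])

  unknown <- !hit & !sector %in% rules$known_sectors
  if (any(unknown))
    warning(sprintf("unknown sector tag(s) kept in analysis: %s",
                    paste(unique(sector[unknown]), collapse = ", ")),
            call. = FALSE)

  excluded <- sales[!is.na(reason), , drop = FALSE]
  if (nrow(excluded)) excluded$exclusion_reason <- reason[!is.na(reason)]
  else excluded$exclusion_reason <- character(0)
  list(kept = sales[is.na(reason), , drop = FALSE], excluded = excluded)
}

.join_key <- function(company, country, brand_key) {
  paste(tolower(trimws(as.character(company))),
        toupper(trimws(as.character(country))),
        brand_key, sep = "\x1f")
}

#' Match brand sales records to product composition records
#'
#' Exact join on normalized (company, country, brand key). Brands with no
#' composition record are reported as unmatched together with their sales
#' value; they are excluded from all downstream denominators. Percentages in
#' the report are computed over the kept (non-excluded) sales value.
#'
#' @param sales Kept brand sales records (see \code{\link{apply_exclusions}})
#'   with columns \code{company}, \code{country}, \code{brand} (or a
#'   precomputed \code{brand_key}) and \code{value_sales_usd}.
#' @param products Product records with \code{product_id}, \code{company},
#'   \code{country} and \code{brand} (or \code{brand_key}).
#' @return A list of class \code{brand_match}: \code{matches}, a data.frame
#'   pairing \code{product_id} with the matching sales row (\code{sale_id} =
#'   row index into \code{sales}); \code{report}, a \code{match_report} with
#'   totals, unmatched sales value and percentage, and per-country match
#'   rates; \code{unmatched}, the unmatched sales rows.
#' @export
match_brands <- function(sales, products) {
  stopifnot(is.data.frame(sales), is.data.frame(products))
  if (!nrow(sales)) npm_input_error("no sales records to match")
  skey <- if ("brand_key" %in% names(sales)) sales$brand_key
          else normalize_brand_key(sales$brand)
  sales_key <- .join_key(sales$company, sales$country, skey)
  if (nrow(products)) {
    pkey_brand <- if ("brand_key" %in% names(products)) products$brand_key
                  else normalize_brand_key(products$brand)
    prod_key <- .join_key(products$company, products$country, pkey_brand)
    idx <- match(prod_key, sales_key)
    sel <- !is.na(idx)
    matches <- data.frame(
      product_id = as.character(products$product_id[sel]),
      sale_id = idx[sel],
      brand_key = pkey_brand[sel],
      stringsAsFactors = FALSE)
  } else {
    matches <- data.frame(product_id = character(0), sale_id = integer(0),
                          brand_key = character(0), stringsAsFactors = FALSE)
  }

  matched_sale <- seq_len(nrow(sales)) %in% matches$sale_id
  v <- as.numeric(sales$value_sales_usd)
  total <- sum(v)
  unmatched_usd <- sum(v[!matched_sale])

  country <- toupper(trimws(as.character(sales$country)))
  per_country <- do.call(rbind, lapply(split(seq_len(nrow(sales)), country),
    function(ii) {
      tot <- sum(v[ii])
      mat <- sum(v[ii][matched_sale[ii]])
      data.frame(country = country[ii[1]], sales_total_usd = tot,
                 matched_sales_usd = mat,
                 matched_pct = if (tot > 0) 100 * (mat / tot) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  rownames(per_country) <- NULL

  report <- structure(list(
    n_brands_total = nrow(sales),
    n_brands_matched = sum(matched_sale),
    n_brands_unmatched = sum(!matched_sale),
    total_sales_usd = total,
    matched_sales_usd = total - unmatched_usd,
    unmatched_sales_usd = unmatched_usd,
    unmatched_sales_pct = if (total > 0) 100 * (unmatched_usd / total) else NA_real_,
    per_country = per_country
  ), class = "match_report")

  structure(list(matches = matches, report = report,
                 unmatched = sales[!matched_sale, , drop = FALSE]),
            class = "brand_match")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("Brand matching: %d of %d brands matched (%d unmatched, %.1f%% of sales value excluded)\n",
              x$n_brands_matched, x$n_brands_total, x$n_brands_unmatched,
              x$unmatched_sales_pct))
  invisible(x)
}

#' Allocate brand sales equally across matched product variants
#'
#' Implements the equal-split weighting: a brand's annual value sales are
#' divided by the number of matched product variants, so each variant carries
#' \code{value_sales_usd / n} dollars. Sums over a brand's allocations
#' reconstitute the brand's sales value.
#'
#' @param sales Brand sales data.frame (as passed to
#'   \code{\link{match_brands}}).
#' @param matches Either the \code{matches} data.frame from
#'   \code{\link{match_brands}} (with \code{product_id} and \code{sale_id}),
#'   or, for a single brand (one-row \code{sales}), a character vector of
#'   matched product ids.
#' @return A data.frame of allocations: \code{product_id}, \code{sale_id},
#'   \code{brand_key} (when available) and \code{allocated_usd}.
#' @examples
#' allocate_sales(data.frame(value_sales_usd = 100), c("a", "b", "c", "d"))
#' @export
allocate_sales <- function(sales, matches) {
  stopifnot(is.data.frame(sales))
  if (is.character(matches)) {
    if (nrow(sales) != 1L)
      npm_input_error("a product-id vector requires a single sales record")
    if (!length(matches))
      npm_value_error("cannot allocate sales for a brand with no matched products")
    matches <- data.frame(product_id = matches, sale_id = 1L,
                          stringsAsFactors = FALSE)
  }
  if (!nrow(matches))
    npm_value_error("cannot allocate sales: no matched products")
  n_by_sale <- table(matches$sale_id)
  n_b <- as.integer(n_by_sale[as.character(matches$sale_id)])
  v_b <- as.numeric(sales$value_sales_usd)[matches$sale_id]
  out <- data.frame(product_id = as.character(matches$product_id),
                    sale_id = matches$sale_id,
                    allocated_usd = v_b / n_b,
                    stringsAsFactors = FALSE)
  if (!is.null(matches$brand_key)) out$brand_key <- matches$brand_key
  out
}
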