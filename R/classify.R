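# The rules engine: per-100 g/ml threshold evaluation of nutrient panels.

# Panel columns recognised throughout the package. All values per 100 g for
# foods and per 100 ml for beverages (thresholds are applied identically).
.panel_columns <- c("energy_kcal", "energy_kj", "total_fat_g",
                    "saturated_fat_g", "trans_fat_g", "total_sugars_g",
                    "added_sugars_g", "fibre_g", "protein_g",
                    "carbohydrate_g", "salt_g", "sodium_mg")

#' Harmonize nutrient panel units
#'
#' Fills derivable fields without touching values already present:
#' \code{salt_g} from \code{sodium_mg} (salt = sodium x 2.5, mg to g) and
#' \code{energy_kcal} from \code{energy_kj} (1 kcal = 4.184 kJ). Fields that
#' cannot be derived are left missing; downstream classification then yields
#' \code{unclassifiable} if the category's rule needs them.
#'
#' @param panel A data.frame with any subset of the nutrient columns
#'   (\code{energy_kcal}, \code{energy_kj}, \code{total_fat_g},
#'   \code{saturated_fat_g}, \code{trans_fat_g}, \code{total_sugars_g},
#'   \code{added_sugars_g}, \code{fibre_g}, \code{protein_g},
#'   \code{carbohydrate_g}, \code{salt_g}, \code{sodium_mg}), one row per
#'   product. Missing values are \code{NA}.
#' @return The same data.frame with \code{salt_g} and \code{energy_kcal}
#'   populated where derivable.
#' @examples
#' normalize_panel(data.frame(sodium_mg = 400))$salt_g  # 1.0
#' @export
normalize_panel <- function(panel) {
  stopifnot(is.data.frame(panel))
  n <- nrow(panel)
  has <- function(col) col %in% names(panel)
  col <- function(col) if (has(col)) panel[[col]] else rep(NA_real_, n)

  salt <- col("salt_g")
  sodium <- col("sodium_mg")
  fill <- is.na(salt) & !is.na(sodium)
  if (any(fill)) {
    salt[fill] <- sodium[fill] * 2.5 / 1000
    panel$salt_g <- salt
  } else if (!has("salt_g") && has("sodium_mg")) {
    panel$salt_g <- salt
  }

  kcal <- col("energy_kcal")
  kj <- col("energy_kj")
  fill <- is.na(kcal) & !is.na(kj)
  if (any(fill)) {
    kcal[fill] <- kj[fill] / 4.184
    panel$energy_kcal <- kcal
  } else if (!has("energy_kcal") && has("energy_kj")) {
    panel$energy_kcal <- kcal
  }
  panel
}

# Evaluate one product against one rule. panel is a named list of numeric
# scalars (NA = absent, after normalize_panel). Returns list(verdict,
# failed_criteria (character vector), reason).
.classify_one <- function(rule, panel, sugar_flag, nss_flag) {
  mode <- rule$permission_mode
  if (mode == "never_permitted")
    return(list(verdict = "unhealthy",
                failed_criteria = "category_not_permitted", reason = ""))
  if (mode == "always_permitted")
    return(list(verdict = "healthier", failed_criteria = character(0),
                reason = ""))

  failed <- character(0)
  missing <- character(0)
  for (nut in names(rule$maxima)) {
    v <- panel[[nut]]
    if (is.null(v) || is.na(v)) {
      if (!nut %in% .optional_nutrients) missing <- c(missing, nut)
    } else if (v > rule$maxima[[nut]]) {
      # "exceed" read strictly: equality with the maximum passes
      failed <- c(failed, paste0(nut, "_exceeds_max"))
    }
  }
  if (rule$forbid_added_sugars && isTRUE(sugar_flag))
    failed <- c(failed, "added_sugars_present")
  if (rule$forbid_nss && isTRUE(nss_flag))
    failed <- c(failed, "nss_present")

  if (length(failed))
    return(list(verdict = "unhealthy", failed_criteria = failed, reason = ""))
  if (length(missing))
    return(list(verdict = "unclassifiable", failed_criteria = character(0),
                reason = paste0("missing_nutrient:",
                                paste(missing, collapse = "+"))))
  list(verdict = "healthier", failed_criteria = character(0), reason = "")
}

#' Classify one product under a threshold table
#'
#' Applies the product's category rule: never-permitted categories are
#' unhealthy outright, always-permitted categories are healthier outright,
#' and threshold-evaluated categories are unhealthy if any present nutrient
#' strictly exceeds its per-100 g/ml maximum or a forbidden sweetener flag is
#' set. A product whose rule needs a nutrient that is absent after unit
#' normalization — and that fails no other criterion — is unclassifiable and
#' is later excluded from sales denominators.
#'
#' @param product A one-row data.frame (or named list) with
#'   \code{npm_category} and nutrient panel fields.
#' @param table A \code{threshold_table}.
#' @param sugar_flag,nss_flag Logical: does the product contain added sugars
#'   / non-sugar sweeteners? Usually from \code{\link{screen_ingredients}}.
#' @return A list with \code{product_id}, \code{verdict} (one of
#'   \code{"healthier"}, \code{"unhealthy"}, \code{"unclassifiable"}),
#'   \code{failed_criteria} (character vector, empty iff not unhealthy) and
#'   \code{reason} (non-empty iff unclassifiable).
#' @seealso \code{\link{classify_products}} for the vectorized interface.
#' @export
classify_product <- function(product, table, sugar_flag = FALSE,
                             nss_flag = FALSE) {
  stopifnot(inherits(table, "threshold_table"))
  product <- as.data.frame(as.list(product), stringsAsFactors = FALSE)
  cat_code <- as.character(product$npm_category)
  rule <- table$rules[[cat_code]]
  if (is.null(rule))
    npm_classification_error(sprintf("unknown category code: '%s'", cat_code))
  panel <- as.list(normalize_panel(product))
  res <- .classify_one(rule, panel, sugar_flag, nss_flag)
  res$product_id <- as.character(product$product_id %||% NA_character_)
  res[c("product_id", "verdict", "failed_criteria", "reason")]
}

#' Classify a product table under a threshold table
#'
#' Vectorized classification. Unless a precomputed \code{screen} is given,
#' ingredient lists are screened with \code{lexicon} to set the added-sugar
#' and NSS flags; when the panel carries an \code{added_sugars_g} value > 0
#' that also sets the added-sugar flag.
#'
#' @param products A data.frame with \code{product_id}, \code{npm_category},
#'   nutrient panel columns and optionally \code{ingredients_text}.
#' @param table A \code{threshold_table}.
#' @param screen Optional result of \code{\link{screen_ingredients}} aligned
#'   with \code{products}; computed from \code{ingredients_text} when NULL.
#' @param lexicon Sweetener lexicon used when \code{screen} is NULL.
#' @return A data.frame with one row per product: \code{product_id},
#'   \code{verdict}, \code{failed_criteria} (criterion names joined by
#'   \code{";"}, empty iff the product did not fail) and \code{reason}.
#' @examples
#' tab <- who_euro_2015()
#' p <- data.frame(product_id = "p1", npm_category = "breakfast_cereals",
#'                 total_fat_g = 2, total_sugars_g = 22, salt_g = 0.4)
#' classify_products(p, tab)
#' @export
classify_products <- function(products, table, screen = NULL, lexicon = NULL) {
  stopifnot(is.data.frame(products), inherits(table, "threshold_table"))
  n <- nrow(products)
  if (!"npm_category" %in% names(products))
    npm_input_error("products table lacks an 'npm_category' column")
  cats <- as.character(products$npm_category)
  unknown <- setdiff(unique(cats), names(table$rules))
  if (length(unknown))
    npm_classification_error(sprintf("unknown category code: '%s'",
                                     paste(unknown, collapse = "', '")))

  if (is.null(screen)) {
    txt <- if ("ingredients_text" %in% names(products))
      products$ingredients_text else rep("", n)
    screen <- screen_ingredients(txt, lexicon %||% default_lexicon())
  }
  if (nrow(screen) != n)
    npm_input_error("screen result not aligned with products table")
  sugar_flag <- screen$has_added_sugar
  nss_flag <- screen$has_nss
  if ("added_sugars_g" %in% names(products)) {
    asg <- products$added_sugars_g
    sugar_flag <- sugar_flag | (!is.na(asg) & asg > 0)
  }

  panel <- normalize_panel(products)
  pcols <- intersect(.panel_columns, names(panel))
  verdict <- character(n)
  failed <- character(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    p <- lapply(panel[pcols], `[[`, i)
    res <- .classify_one(table$rules[[cats[i]]], p, sugar_flag[i], nss_flag[i])
    verdict[i] <- res$verdict
    failed[i] <- paste(res$failed_criteria, collapse = ";")
    reason[i] <- res$reason
  }
  data.frame(product_id = as.character(products$product_id),
             verdict = verdict, failed_criteria = failed, reason = reason,
             stringsAsFactors = FALSE)
}
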