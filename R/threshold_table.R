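# Threshold-table configuration: the nutrient profile model as data.

# Nutrient names a rule's maxima may refer to; these match the panel columns
# used throughout the package (all per 100 g/ml; energy in kcal, rest in g).
.npm_nutrients <- c("energy_kcal", "total_fat_g", "saturated_fat_g",
                    "trans_fat_g", "total_sugars_g", "salt_g")

# Trans fat is absent from typical label extracts; it is evaluated only when
# a value is present rather than making the product unclassifiable.
.optional_nutrients <- "trans_fat_g"

.permission_modes <- c("always_permitted", "never_permitted",
                       "threshold_evaluated")

#' Load a nutrient profile threshold table from a JSON config
#'
#' A threshold table encodes one rule per product category: whether marketing
#' of the category is never permitted, always permitted, or decided by
#' per-100 g/ml nutrient maxima plus optional prohibitions on added sugars
#' and non-sugar sweeteners (NSS). The package ships the WHO Regional Office
#' for Europe model, First Edition (2015), as
#' \code{system.file("extdata", "who_euro_2015.json", package = "npmprofiler")};
#' see \code{\link{who_euro_2015}}.
#'
#' The config is a JSON object with fields \code{model_name}, \code{version},
#' \code{categories} (the category vocabulary) and \code{rules}, an array of
#' objects \code{{category_code, label, permission_mode, maxima,
#' forbid_added_sugars, forbid_nss}}. Every category in the vocabulary must
#' have exactly one rule; \code{maxima} must be non-empty exactly when
#' \code{permission_mode} is \code{"threshold_evaluated"}, except that a rule
#' may rely solely on sweetener prohibitions (empty maxima with a forbid flag
#' set), as the WHO model does for soft drinks.
#'
#' @param path Path to a JSON threshold-table config.
#' @return An object of class \code{threshold_table}: a list with
#'   \code{rules} (named list of rules), \code{categories},
#'   \code{model_name} and \code{version}.
#' @seealso \code{\link{classify_products}}, \code{\link{who_euro_2015}}
#' @export
load_threshold_table <- function(path) {
  if (!file.exists(path))
    npm_config_error(sprintf("threshold config not found: %s", path))
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(cfg$rules) || length(cfg$rules) == 0L)
    npm_config_error("threshold config has no 'rules' array")

  codes <- vapply(cfg$rules, function(r) as.character(r$category_code %||% ""),
                  character(1))
  if (any(!nzchar(codes)))
    npm_config_error("threshold rule without 'category_code'")
  if (anyDuplicated(codes))
    npm_config_error(sprintf("duplicate category rule(s): %s",
                             paste(unique(codes[duplicated(codes)]),
                                   collapse = ", ")))

  vocab <- unlist(cfg$categories) %||% codes
  missing <- setdiff(vocab, codes)
  if (length(missing))
    npm_config_error(sprintf("category in vocabulary without a rule: %s",
                             paste(missing, collapse = ", ")))
  extra <- setdiff(codes, vocab)
  if (length(extra))
    npm_config_error(sprintf("rule for category not in vocabulary: %s",
                             paste(extra, collapse = ", ")))

  rules <- lapply(cfg$rules, .validate_rule)
  names(rules) <- codes

  structure(
    list(rules = rules,
         categories = as.character(vocab),
         model_name = as.character(cfg$model_name %||% "unnamed"),
         version = as.character(cfg$version %||% "")),
    class = "threshold_table"
  )
}

.validate_rule <- function(r) {
  code <- as.character(r$category_code)
  mode <- as.character(r$permission_mode %||% "")
  if (!mode %in% .permission_modes)
    npm_config_error(sprintf(
      "category '%s': invalid permission_mode '%s' (must be one of %s)",
      code, mode, paste(.permission_modes, collapse = ", ")))

  maxima <- r$maxima %||% list()
  if (length(maxima)) {
    bad <- setdiff(names(maxima), .npm_nutrients)
    if (length(bad))
      npm_config_error(sprintf("category '%s': unknown nutrient(s) in maxima: %s",
                               code, paste(bad, collapse = ", ")))
    vals <- vapply(maxima, function(v) as.numeric(v[[1]]), numeric(1))
    if (anyNA(vals) || any(vals < 0))
      npm_config_error(sprintf("category '%s': maxima must be numeric and >= 0",
                               code))
    maxima <- as.list(vals)
  }
  forbid_sugar <- isTRUE(r$forbid_added_sugars)
  forbid_nss <- isTRUE(r$forbid_nss)

  if (mode != "threshold_evaluated" && length(maxima))
    npm_config_error(sprintf(
      "category '%s': maxima given but permission_mode is '%s'", code, mode))
  if (mode == "threshold_evaluated" && !length(maxima) &&
      !forbid_sugar && !forbid_nss)
    npm_config_error(sprintf(
      "category '%s': threshold_evaluated rule with no criteria", code))

  list(category_code = code,
       label = as.character(r$label %||% code),
       permission_mode = mode,
       maxima = maxima,
       forbid_added_sugars = forbid_sugar,
       forbid_nss = forbid_nss)
}

#' The packaged WHO Euro (2015) nutrient profile model
#'
#' Loads the threshold table shipped with the package: the WHO Regional
#' Office for Europe nutrient profile model, First Edition (2015), covering
#' 20 pre-packaged food categories. Five categories (chocolate and sugar
#' confectionery; cakes and sweet biscuits; edible ices; energy drinks;
#' juices) are never permitted for marketing to children regardless of
#' composition; fresh/frozen fruit and vegetables and fresh/frozen
#' meat and fish are always permitted; the remainder carry per-100 g/ml
#' maxima and, for beverages and savoury snacks, prohibitions on added
#' sugars and non-sugar sweeteners.
#'
#' @return A \code{threshold_table}.
#' @examples
#' tab <- who_euro_2015()
#' tab$rules$confectionery$permission_mode
#' @export
who_euro_2015 <- function() {
  load_threshold_table(system.file("extdata", "who_euro_2015.json",
                                   package = "npmprofiler", mustWork = TRUE))
}

#' @export
print.threshold_table <- function(x, ...) {
  cat(sprintf("Nutrient profile threshold table: %s (%s)\n",
              x$model_name, x$version))
  cat(sprintf("  %d categories: %d never permitted, %d always permitted, %d threshold-evaluated\n",
              length(x$rules),
              sum(vapply(x$rules, function(r) r$permission_mode == "never_permitted", logical(1))),
              sum(vapply(x$rules, function(r) r$permission_mode == "always_permitted", logical(1))),
              sum(vapply(x$rules, function(r) r$permission_mode == "threshold_evaluated", logical(1)))))
  invisible(x)
}
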