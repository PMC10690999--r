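# CSV readers with row-level validation, and machine outputs.

.required_product_cols <- c("product_id", "company", "country", "brand",
                            "npm_category", "ingredients_text")
.required_sales_cols <- c("company", "country", "brand", "sector_tag",
                          "npm_category", "value_sales_usd", "year")

.read_csv <- function(path) {
  if (!file.exists(path)) npm_input_error(sprintf("file not found: %s", path))
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character", encoding = "UTF-8")
}

.check_header <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    npm_input_error(sprintf(
      "%s: missing required column(s): %s (is the header row present?)",
      path, paste(missing, collapse = ", ")))
}

# coerce columns to numeric; returns list(values, bad = row indices whose
# original cell was non-empty but not numeric). "NA" and "" denote missing.
.to_numeric <- function(x) {
  x <- trimws(x)
  v <- suppressWarnings(as.numeric(x))
  list(values = v,
       bad = which(!is.na(x) & nzchar(x) & !x %in% c("NA", "NaN") & is.na(v)))
}

#' Read a product composition CSV
#'
#' Expects a UTF-8, comma-separated file with a header row and columns
#' \code{product_id}, \code{company}, \code{country}, \code{brand},
#' \code{npm_category}, \code{ingredients_text}, plus any subset of the
#' nutrient columns (per 100 g/ml): \code{energy_kcal}, \code{energy_kj},
#' \code{total_fat_g}, \code{saturated_fat_g}, \code{trans_fat_g},
#' \code{total_sugars_g}, \code{added_sugars_g}, \code{fibre_g},
#' \code{protein_g}, \code{carbohydrate_g}, \code{salt_g},
#' \code{sodium_mg}. Rows with non-numeric or negative nutrient values, or a
#' duplicated/blank product id, are rejected (not fatal) and reported in the
#' \code{"rejected"} attribute with their line numbers.
#'
#' @param path Path to the CSV file.
#' @return A validated products data.frame; attribute \code{rejected} is a
#'   data.frame of \code{line} / \code{reason} for rejected rows.
#' @export
read_products <- function(path) {
  df <- .read_csv(path)
  .check_header(df, .required_product_cols, path)
  n <- nrow(df)
  line <- seq_len(n) + 1L  # header is line 1
  reject <- rep(NA_character_, n)

  for (cn in intersect(.panel_columns, names(df))) {
    num <- .to_numeric(df[[cn]])
    if (length(num$bad))
      reject[num$bad] <- ifelse(is.na(reject[num$bad]),
                                sprintf("non_numeric:%s", cn),
                                reject[num$bad])
    neg <- which(!is.na(num$values) & num$values < 0)
    if (length(neg))
      reject[neg] <- ifelse(is.na(reject[neg]),
                            sprintf("negative_value:%s", cn), reject[neg])
    df[[cn]] <- num$values
  }
  blank <- !nzchar(trimws(df$product_id))
  reject[blank & is.na(reject)] <- "blank_product_id"
  dup <- duplicated(df$product_id) & !blank
  reject[dup & is.na(reject)] <- "duplicate_product_id"

  rejected <- data.frame(line = line[!is.na(reject)],
                         reason = reject[!is.na(reject)],
                         stringsAsFactors = FALSE)
  out <- df[is.na(reject), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Read a brand value-sales CSV
#'
#' Expects a UTF-8, comma-separated file with a header row and columns
#' \code{company}, \code{country}, \code{brand}, \code{sector_tag},
#' \code{npm_category}, \code{value_sales_usd}, \code{year}. Rows with
#' non-numeric or negative sales values are rejected and reported in the
#' \code{"rejected"} attribute; duplicated (company, country, brand) rows
#' are an input error.
#'
#' @param path Path to the CSV file.
#' @return A validated sales data.frame with numeric \code{value_sales_usd};
#'   attribute \code{rejected} as in \code{\link{read_products}}.
#' @export
read_sales <- function(path) {
  df <- .read_csv(path)
  .check_header(df, .required_sales_cols, path)
  n <- nrow(df)
  line <- seq_len(n) + 1L
  reject <- rep(NA_character_, n)

  num <- .to_numeric(df$value_sales_usd)
  if (length(num$bad)) reject[num$bad] <- "non_numeric:value_sales_usd"
  neg <- which(!is.na(num$values) & num$values < 0)
  reject[neg] <- "negative_value:value_sales_usd"
  df$value_sales_usd <- num$values

  key <- paste(tolower(trimws(df$company)), toupper(trimws(df$country)),
               tolower(trimws(df$brand)), sep = "\x1f")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup))
    npm_input_error(sprintf(
      "%s: duplicate (company, country, brand) row(s) at line(s) %s",
      path, paste(line[dup], collapse = ", ")))

  rejected <- data.frame(line = line[!is.na(reject)],
                         reason = reject[!is.na(reject)],
                         stringsAsFactors = FALSE)
  out <- df[is.na(reject), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write a synthetic market to CSV + JSON files
#'
#' Emits \code{products.csv}, \code{sales.csv} and \code{ledger.json} into
#' \code{dir}. Output is deterministic: the same market writes byte-identical
#' files.
#'
#' @param market A \code{synthetic_market} from \code{\link{generate_market}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_market <- function(market, dir) {
  stopifnot(inherits(market, "synthetic_market"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(products = file.path(dir, "products.csv"),
             sales = file.path(dir, "sales.csv"),
             ledger = file.path(dir, "ledger.json"))
  utils::write.csv(market$products, paths["products"], row.names = FALSE)
  utils::write.csv(market$sales, paths["sales"], row.names = FALSE)
  jsonlite::write_json(market$ledger, paths["ledger"], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(paths)
}
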