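# Sales-weighted aggregation of classifications into portfolio reports.

#' Aggregate classified, allocated sales into portfolio reports
#'
#' Sums allocated sales by verdict within the requested scope and computes
#' the healthier/unhealthy percentages over classifiable matched sales.
#' Unclassifiable sales are excluded from the percentage denominator and
#' reported separately, mirroring the exclusion of unmatched brands.
#'
#' @param classifications Output of \code{\link{classify_products}} covering
#'   every allocated product.
#' @param allocations Output of \code{\link{allocate_sales}}.
#' @param products Product records supplying \code{company} and
#'   \code{npm_category} per \code{product_id}.
#' @param scope One of \code{"overall"}, \code{"company"},
#'   \code{"category"}.
#' @return A data.frame of class \code{portfolio_report}, one row per scope
#'   key, ordered by key: \code{scope}, \code{key}, \code{matched_sales_usd},
#'   \code{unhealthy_sales_usd}, \code{healthier_sales_usd},
#'   \code{unclassifiable_sales_usd}, \code{unhealthy_pct},
#'   \code{healthier_pct}. Percentages are \code{NA} when a key has no
#'   classifiable sales.
#' @export
aggregate_portfolio <- function(classifications, allocations, products,
                                scope = c("overall", "company", "category")) {
  scope <- match.arg(scope)
  stopifnot(is.data.frame(classifications), is.data.frame(allocations),
            is.data.frame(products))
  if (!nrow(allocations))
    npm_value_error("no allocated sales to aggregate (all brands unmatched?)")

  ci <- match(allocations$product_id, classifications$product_id)
  if (anyNA(ci))
    npm_integrity_error(sprintf(
      "allocation without classification for product_id: %s",
      paste(utils::head(allocations$product_id[is.na(ci)], 5), collapse = ", ")))
  verdict <- classifications$verdict[ci]

  pi <- match(allocations$product_id, products$product_id)
  if (anyNA(pi))
    npm_integrity_error(sprintf(
      "allocation without product record for product_id: %s",
      paste(utils::head(allocations$product_id[is.na(pi)], 5), collapse = ", ")))

  key <- switch(scope,
                overall = rep("all", nrow(allocations)),
                company = as.character(products$company[pi]),
                category = as.character(products$npm_category[pi]))
  usd <- allocations$allocated_usd

  sum_by <- function(sel) {
    if (!any(sel)) return(stats::setNames(numeric(0), character(0)))
    out <- tapply(usd[sel], key[sel], sum)
    out[is.na(out)] <- 0
    out
  }
  keys <- sort(unique(key))
  zero <- stats::setNames(rep(0, length(keys)), keys)
  take <- function(x) { z <- zero; z[names(x)] <- x; unname(z) }

  unhealthy <- take(sum_by(verdict == "unhealthy"))
  healthier <- take(sum_by(verdict == "healthier"))
  unclass <- take(sum_by(verdict == "unclassifiable"))
  classifiable <- unhealthy + healthier

  out <- data.frame(
    scope = scope, key = keys,
    matched_sales_usd = unhealthy + healthier + unclass,
    unhealthy_sales_usd = unhealthy,
    healthier_sales_usd = healthier,
    unclassifiable_sales_usd = unclass,
    unhealthy_pct = ifelse(classifiable > 0, 100 * (unhealthy / classifiable),
                           NA_real_),
    healthier_pct = ifelse(classifiable > 0, 100 * (healthier / classifiable),
                           NA_real_),
    stringsAsFactors = FALSE)
  class(out) <- c("portfolio_report", "data.frame")
  out
}

#' Healthier dollars per $10 spent
#'
#' Re-expresses a report's healthier share as dollars per ten dollars spent,
#' rounded to cents: a portfolio that is 11% healthier returns 1.10.
#'
#' @param report A \code{portfolio_report} row (or data.frame of rows) with
#'   positive \code{matched_sales_usd}.
#' @return Numeric vector of healthier dollars per $10.
#' @export
per_ten_dollars <- function(report) {
  stopifnot(is.data.frame(report))
  if (any(is.na(report$matched_sales_usd)) ||
      any(report$matched_sales_usd <= 0))
    npm_value_error("per_ten_dollars is undefined for zero matched sales")
  round(10 * report$healthier_pct / 100, 2)
}

#' Evaluate engagement thresholds against company reports
#'
#' An organization's engagement policy sets a cutoff on the proportion of a
#' company's sales that may be unhealthy (e.g. 49, 25 or 10 percent). A
#' company passes a cutoff when its unhealthy percentage is at most the
#' cutoff (boundary inclusive).
#'
#' @param reports A company-scope \code{portfolio_report}.
#' @param thresholds Numeric cutoffs in [0, 100].
#' @return A data.frame with one row per (company, threshold):
#'   \code{company}, \code{threshold_pct}, \code{unhealthy_pct},
#'   \code{passes}.
#' @export
evaluate_engagement <- function(reports, thresholds) {
  stopifnot(is.data.frame(reports))
  thresholds <- as.numeric(thresholds)
  if (anyNA(thresholds) || any(thresholds < 0 | thresholds > 100))
    npm_config_error("engagement thresholds must lie in [0, 100]")
  grid <- expand.grid(i = seq_len(nrow(reports)),
                      threshold_pct = sort(thresholds))
  out <- data.frame(
    company = as.character(reports$key)[grid$i],
    threshold_pct = grid$threshold_pct,
    unhealthy_pct = reports$unhealthy_pct[grid$i],
    stringsAsFactors = FALSE)
  out$passes <- !is.na(out$unhealthy_pct) &
    out$unhealthy_pct <= out$threshold_pct
  out[order(out$company, out$threshold_pct), , drop = FALSE]
}

#' Coverage accounting for a pipeline run
#'
#' Combines the match report's per-country sales coverage with the value of
#' matched-but-unclassifiable sales, so every run documents how much of the
#' sales universe its percentages actually describe.
#'
#' @param match_report A \code{match_report} from \code{\link{match_brands}}.
#' @param unclassifiable Either a single total of unclassifiable allocated
#'   sales (USD) or a data.frame with columns \code{country} and
#'   \code{unclassifiable_sales_usd}.
#' @return A data.frame with one row per country plus an \code{"overall"}
#'   row: sales totals, matched value and percentage, unclassifiable value
#'   and its percentage of matched sales.
#' @export
coverage_summary <- function(match_report, unclassifiable = 0) {
  stopifnot(inherits(match_report, "match_report"))
  pc <- match_report$per_country
  if (is.data.frame(unclassifiable)) {
    ui <- match(pc$country, toupper(trimws(unclassifiable$country)))
    u_country <- ifelse(is.na(ui), 0, unclassifiable$unclassifiable_sales_usd[ui])
    u_total <- sum(unclassifiable$unclassifiable_sales_usd)
  } else {
    u_total <- as.numeric(unclassifiable)
    u_country <- rep(NA_real_, nrow(pc))
  }
  overall <- data.frame(
    country = "overall",
    sales_total_usd = match_report$total_sales_usd,
    matched_sales_usd = match_report$matched_sales_usd,
    matched_pct = if (match_report$total_sales_usd > 0)
      100 * (match_report$matched_sales_usd / match_report$total_sales_usd)
      else NA_real_,
    stringsAsFactors = FALSE)
  out <- rbind(pc[order(pc$country), , drop = FALSE], overall)
  out$unclassifiable_sales_usd <- c(u_country[order(pc$country)], u_total)
  out$unclassifiable_pct <- ifelse(
    !is.na(out$unclassifiable_sales_usd) & out$matched_sales_usd > 0,
    100 * (out$unclassifiable_sales_usd / out$matched_sales_usd), NA_real_)
  rownames(out) <- NULL
  out
}
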