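# The end-to-end portfolio profile: exclusions -> match -> screen ->
# classify -> allocate -> aggregate, packaged as one classed result.

#' Profile a company sales portfolio under a nutrient profile model
#'
#' Runs the full method: applies the exclusion rules to the sales records,
#' matches brands to product composition records on normalized
#' (company, country, brand) keys, screens ingredient lists for added sugars
#' and non-sugar sweeteners, classifies every matched product under the
#' threshold table, splits each brand's value sales equally across its
#' matched variants, and aggregates sales-weighted healthier/unhealthy
#' proportions overall, by company and by category. Unmatched brands and
#' unclassifiable products are excluded from all percentage denominators and
#' accounted for in the coverage table.
#'
#' @param products Product records (see \code{\link{read_products}}).
#' @param sales Brand sales records (see \code{\link{read_sales}}).
#' @param table A \code{threshold_table}; the WHO Euro 2015 model by default.
#' @param lexicon A \code{sweetener_lexicon} for ingredient screening.
#' @param thresholds Engagement cutoffs (percent unhealthy) to evaluate.
#' @param exclusion_rules See \code{\link{default_exclusion_rules}}.
#' @return An object of class \code{portfolio_profile}: a list with
#'   \code{overall}, \code{by_company} and \code{by_category}
#'   (\code{portfolio_report} data.frames), \code{coverage},
#'   \code{engagement}, \code{match_report}, \code{unmatched},
#'   \code{excluded}, \code{classifications}, \code{allocations},
#'   \code{screen} (screening diagnostics incl. the unscreenable count) and
#'   \code{model} (threshold-table identity).
#' @examples
#' mkt <- generate_market(generator_config(n_companies = 3,
#'                                         brands_per_company = c(2, 4),
#'                                         variants_per_brand = c(1, 5),
#'                                         seed = 42))
#' pp <- profile_portfolio(mkt$products, mkt$sales)
#' pp
#' @export
profile_portfolio <- function(products, sales, table = who_euro_2015(),
                              lexicon = default_lexicon(),
                              thresholds = c(10, 25, 49),
                              exclusion_rules = default_exclusion_rules()) {
  stopifnot(is.data.frame(products), is.data.frame(sales))
  if (!nrow(sales)) npm_input_error("sales table is empty")

  excl <- apply_exclusions(sales, exclusion_rules)
  if (!nrow(excl$kept))
    npm_input_error("every sales record was excluded by rule")
  mb <- match_brands(excl$kept, products)
  if (!nrow(mb$matches))
    npm_value_error("no brand could be matched to composition records; aggregation cannot run")

  alloc <- allocate_sales(excl$kept, mb$matches)
  keep <- match(alloc$product_id, products$product_id)
  prods <- products[keep, , drop = FALSE]

  txt <- if ("ingredients_text" %in% names(prods)) prods$ingredients_text
         else rep("", nrow(prods))
  screen <- screen_ingredients(txt, lexicon)
  cls <- classify_products(prods, table, screen = screen)

  overall <- aggregate_portfolio(cls, alloc, prods, "overall")
  by_company <- aggregate_portfolio(cls, alloc, prods, "company")
  by_category <- aggregate_portfolio(cls, alloc, prods, "category")

  uc_sel <- cls$verdict[match(alloc$product_id, cls$product_id)] ==
    "unclassifiable"
  uc_country <- toupper(trimws(prods$country[match(alloc$product_id,
                                                   prods$product_id)]))
  uc_by_country <- if (any(uc_sel)) {
    agg <- tapply(alloc$allocated_usd[uc_sel], uc_country[uc_sel], sum)
    data.frame(country = names(agg), unclassifiable_sales_usd = as.numeric(agg),
               stringsAsFactors = FALSE)
  } else {
    data.frame(country = character(0),
               unclassifiable_sales_usd = numeric(0))
  }
  coverage <- coverage_summary(mb$report, uc_by_country)
  engagement <- evaluate_engagement(by_company, thresholds)

  structure(list(
    overall = overall,
    by_company = by_company,
    by_category = by_category,
    coverage = coverage,
    engagement = engagement,
    match_report = mb$report,
    unmatched = mb$unmatched,
    excluded = excl$excluded,
    classifications = cls,
    allocations = alloc,
    screen = list(n_products = nrow(prods),
                  n_unscreenable = sum(!screen$screenable)),
    model = list(model_name = table$model_name, version = table$version)
  ), class = "portfolio_profile")
}

#' @export
print.portfolio_profile <- function(x, ...) {
  ov <- x$overall
  cat(sprintf("Portfolio profile under %s (%s)\n",
              x$model$model_name, x$model$version))
  cat(sprintf("  Matched sales: $%s across %d products (%d of %d brands matched)\n",
              format(round(ov$matched_sales_usd), big.mark = ","),
              x$screen$n_products,
              x$match_report$n_brands_matched, x$match_report$n_brands_total))
  cat(sprintf("  Unhealthy: %.0f%% of classifiable matched sales; healthier: %.0f%% ($%.2f per $10)\n",
              ov$unhealthy_pct, ov$healthier_pct, per_ten_dollars(ov)))
  cat(sprintf("  Excluded by rule: %d brand(s); unmatched: %d brand(s) (%.1f%% of sales value)\n",
              nrow(x$excluded), x$match_report$n_brands_unmatched,
              x$match_report$unmatched_sales_pct))
  if (x$screen$n_unscreenable > 0)
    cat(sprintf("  Products with empty ingredient text (screened as sweetener-free): %d\n",
                x$screen$n_unscreenable))
  invisible(x)
}

#' @export
summary.portfolio_profile <- function(object, ...) {
  co <- object$by_company
  out <- data.frame(company = co$key,
                    matched_sales_usd = co$matched_sales_usd,
                    unhealthy_pct = round(co$unhealthy_pct),
                    healthier_pct = round(co$healthier_pct),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$unhealthy_pct, out$company), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(model = object$model, companies = out,
                 overall_unhealthy_pct = object$overall$unhealthy_pct,
                 healthier_per_ten = per_ten_dollars(object$overall),
                 coverage = object$coverage),
            class = "summary.portfolio_profile")
}

#' @export
print.summary.portfolio_profile <- function(x, ...) {
  cat(sprintf("Company portfolios under %s — overall %.0f%% unhealthy ($%.2f healthier per $10)\n\n",
              x$model$model_name, x$overall_unhealthy_pct,
              x$healthier_per_ten))
  print(x$companies, row.names = FALSE)
  invisible(x)
}

#' @export
plot.portfolio_profile <- function(x, scope = c("company", "category"), ...) {
  scope <- match.arg(scope)
  rep <- if (scope == "company") x$by_company else x$by_category
  rep <- rep[order(rep$unhealthy_pct), , drop = FALSE]
  m <- rbind(healthier = rep$healthier_pct, unhealthy = rep$unhealthy_pct)
  colnames(m) <- rep$key
  op <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(m, horiz = TRUE, las = 1,
                    col = c("#4daf4a", "#e41a1c"),
                    xlab = "% of classifiable matched sales",
                    legend.text = rownames(m),
                    args.legend = list(x = "bottomright", bg = "white"), ...)
  invisible(x)
}

#' Run the full pipeline from files to report artifacts
#'
#' File-level front end to \code{\link{profile_portfolio}}: reads the
#' products and sales CSVs, runs the pipeline, and writes
#' \code{reports.csv} (all scopes), \code{summary.json} (overall report,
#' coverage, engagement verdicts) and \code{run.log} (every rejected row,
#' excluded brand, unmatched brand and unclassifiable product with a reason
#' code) into the output directory. Outputs are deterministic for identical
#' inputs.
#'
#' @param config A list (or path to a JSON file holding one) with entries
#'   \code{products}, \code{sales} (paths), \code{out_dir}, and optionally
#'   \code{threshold_table} (path), \code{lexicon} (path),
#'   \code{thresholds} (numeric vector).
#' @return Invisibly, the \code{portfolio_profile}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  for (field in c("products", "sales", "out_dir"))
    if (is.null(config[[field]]))
      npm_config_error(sprintf("run config lacks '%s'", field))

  table <- if (!is.null(config$threshold_table))
    load_threshold_table(config$threshold_table) else who_euro_2015()
  lexicon <- if (!is.null(config$lexicon))
    load_lexicon(config$lexicon) else default_lexicon()
  thresholds <- config$thresholds %||% c(10, 25, 49)

  products <- read_products(config$products)
  sales <- read_sales(config$sales)
  if (!nrow(sales)) npm_input_error("sales table is empty")

  pp <- profile_portfolio(products, sales, table = table, lexicon = lexicon,
                          thresholds = thresholds)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  reports <- rbind(pp$overall, pp$by_company, pp$by_category)
  utils::write.csv(as.data.frame(reports),
                   file.path(config$out_dir, "reports.csv"),
                   row.names = FALSE)

  jsonlite::write_json(
    list(model = pp$model,
         overall = as.list(pp$overall[1, ]),
         healthier_per_ten_dollars = per_ten_dollars(pp$overall),
         coverage = pp$coverage,
         engagement = pp$engagement,
         n_products_matched = pp$screen$n_products,
         n_unscreenable = pp$screen$n_unscreenable),
    file.path(config$out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)

  log_lines <- c(
    sprintf("model=%s version=%s", pp$model$model_name, pp$model$version),
    vapply(seq_len(nrow(attr(products, "rejected") %||% data.frame())),
           function(i) sprintf("REJECTED_PRODUCT_ROW line=%d reason=%s",
                               attr(products, "rejected")$line[i],
                               attr(products, "rejected")$reason[i]),
           character(1)),
    vapply(seq_len(nrow(attr(sales, "rejected") %||% data.frame())),
           function(i) sprintf("REJECTED_SALES_ROW line=%d reason=%s",
                               attr(sales, "rejected")$line[i],
                               attr(sales, "rejected")$reason[i]),
           character(1)),
    if (nrow(pp$excluded))
      sprintf("EXCLUDED brand=%s reason=%s", pp$excluded$brand,
              pp$excluded$exclusion_reason),
    if (nrow(pp$unmatched))
      sprintf("UNMATCHED brand=%s sales_usd=%.2f", pp$unmatched$brand,
              pp$unmatched$value_sales_usd),
    {
      uc <- pp$classifications[pp$classifications$verdict == "unclassifiable", ]
      if (nrow(uc)) sprintf("UNCLASSIFIABLE product_id=%s reason=%s",
                            uc$product_id, uc$reason)
    })
  writeLines(log_lines[!is.na(log_lines)],
             file.path(config$out_dir, "run.log"))
  invisible(pp)
}
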