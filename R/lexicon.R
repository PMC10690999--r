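# Sweetener lexicons: configurable term lists for ingredient screening.

#' Load a sweetener lexicon from a JSON config
#'
#' The config is a JSON object with arrays \code{added_sugar_terms},
#' \code{nss_terms} and optionally \code{negative_context}. Terms are
#' lowercased and trimmed on load; the two term sets must be disjoint.
#' Negative-context phrases (e.g. "no added sugar", "sugar snap peas") are
#' removed from ingredient text before matching, so they can never trigger a
#' term they contain.
#'
#' @param path Path to a UTF-8 JSON lexicon file.
#' @return An object of class \code{sweetener_lexicon} with components
#'   \code{added_sugar_terms}, \code{nss_terms}, \code{negative_context}.
#' @seealso \code{\link{screen_ingredients}}, \code{\link{default_lexicon}}
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path))
    npm_config_error(sprintf("lexicon config not found: %s", path))
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  norm <- function(x) unique(trimws(tolower(as.character(x %||% character(0)))))
  sugar <- norm(cfg$added_sugar_terms)
  nss <- norm(cfg$nss_terms)
  neg <- norm(cfg$negative_context)
  sugar <- sugar[nzchar(sugar)]
  nss <- nss[nzchar(nss)]
  neg <- neg[nzchar(neg)]
  overlap <- intersect(sugar, nss)
  if (length(overlap))
    npm_config_error(sprintf(
      "term(s) present in both added_sugar_terms and nss_terms: %s",
      paste(overlap, collapse = ", ")))
  structure(list(added_sugar_terms = sugar, nss_terms = nss,
                 negative_context = neg),
            class = "sweetener_lexicon")
}

#' The packaged default sweetener lexicon
#'
#' English-language added-sugar synonyms (sucrose, glucose syrup, honey, ...)
#' and non-sugar sweeteners including EU additive codes E950-E969 and the
#' polyols, plus a negative-context phrase list.
#'
#' @return A \code{sweetener_lexicon}.
#' @export
default_lexicon <- function() {
  load_lexicon(system.file("extdata", "sweetener_lexicon.json",
                           package = "npmprofiler", mustWork = TRUE))
}

#' @export
print.sweetener_lexicon <- function(x, ...) {
  cat(sprintf("Sweetener lexicon: %d added-sugar terms, %d NSS terms, %d negative-context phrases\n",
              length(x$added_sugar_terms), length(x$nss_terms),
              length(x$negative_context)))
  invisible(x)
}
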