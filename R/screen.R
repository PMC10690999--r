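# Lexicon screening of free-text ingredient lists for added sugars and NSS.

.rx_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# lowercase, strip punctuation to spaces, collapse whitespace; parenthetical
# sub-ingredients survive because parentheses just become spaces
.normalize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("[^[:alnum:]]+", " ", x)
  trimws(gsub(" +", " ", x))
}

#' Screen ingredient text for added sugars and non-sugar sweeteners
#'
#' Case-insensitive whole-token/phrase matching of the lexicon's terms
#' against punctuation-normalized ingredient text. Negative-context phrases
#' are blanked out first, so "no added sugar" or "sugar snap peas" never
#' trigger the "sugar" term. Parenthetical sub-ingredient lists are searched
#' like any other text. Empty (or missing) text is unscreenable: both flags
#' are false and \code{screenable} records the fact so coverage diagnostics
#' can report it.
#'
#' @param text Character vector of ingredient lists (one per product).
#' @param lexicon A \code{sweetener_lexicon}; the packaged default by default.
#' @return A data.frame aligned with \code{text}: \code{screenable},
#'   \code{has_added_sugar}, \code{has_nss}, and \code{matched_terms}
#'   (matched lexicon terms joined by \code{";"}).
#' @examples
#' screen_ingredients(c("carbonated water, sucrose, citric acid",
#'                      "water, aspartame, flavouring",
#'                      "rolled oats, salt"))
#' @export
screen_ingredients <- function(text, lexicon = default_lexicon()) {
  stopifnot(inherits(lexicon, "sweetener_lexicon"))
  text <- as.character(text)
  text[is.na(text)] <- ""
  n <- length(text)
  screenable <- nzchar(trimws(text))

  norm <- .normalize_text(text)
  for (phrase in .normalize_text(lexicon$negative_context)) {
    if (nzchar(phrase))
      norm <- gsub(paste0("\\b", .rx_escape(phrase), "\\b"), " ", norm)
  }

  match_set <- function(terms) {
    hits <- vector("list", n)
    if (!length(terms)) {
      hits[] <- list(character(0))
      return(hits)
    }
    terms <- .normalize_text(terms)
    # longer phrases first so multi-word terms are reported over their parts
    terms <- terms[order(-nchar(terms))]
    rx <- paste0("\\b(", paste(.rx_escape(terms), collapse = "|"), ")\\b")
    m <- gregexpr(rx, norm)
    for (i in seq_len(n)) {
      found <- regmatches(norm[i], m[i])[[1]]
      hits[[i]] <- unique(found)
    }
    hits
  }

  sugar_hits <- match_set(lexicon$added_sugar_terms)
  nss_hits <- match_set(lexicon$nss_terms)

  has_sugar <- screenable & lengths(sugar_hits) > 0
  has_nss <- screenable & lengths(nss_hits) > 0
  matched <- mapply(function(a, b, ok) {
    if (!ok) "" else paste(c(a, b), collapse = ";")
  }, sugar_hits, nss_hits, screenable)

  data.frame(screenable = screenable, has_added_sugar = has_sugar,
             has_nss = has_nss, matched_terms = as.character(matched),
             stringsAsFactors = FALSE)
}
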