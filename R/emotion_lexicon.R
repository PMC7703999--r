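# Dictionary-based emotion content: classify tokens into categories by
# literal or stem-prefix matching and report per-report percentages.

EMOTION_CATEGORIES <- c("positive", "negative", "anxiety", "anger", "sadness")

# All entry sets that feed a category: its own plus those of any
# subcategory linked to it through the hierarchy.
category_entries <- function(lexicon, category) {
  if (!category %in% names(lexicon$categories)) {
    stop("unknown lexicon category: ", category, call. = FALSE)
  }
  subs <- names(lexicon$hierarchy)[lexicon$hierarchy == category]
  unique(unlist(lexicon$categories[c(category, subs)], use.names = FALSE))
}

#' Does a token match a lexicon category?
#'
#' A token matches when it equals a literal entry, or starts with the prefix
#' of a stem entry (`prefix*`), of the category or of any subcategory mapped
#' to it through the hierarchy (so e.g. anger words also match `negative`).
#'
#' @param token A lowercase word.
#' @param lexicon An `emotion_lexicon`.
#' @param category Category name.
#' @return `TRUE` or `FALSE` (vectorized over `token`).
#' @export
match_token <- function(token, lexicon, category) {
  entries <- category_entries(lexicon, category)
  is_stem <- endsWith(entries, "*")
  literals <- entries[!is_stem]
  stems <- sub("\\*$", "", entries[is_stem])
  out <- token %in% literals
  if (length(stems) > 0) {
    for (s in stems) out <- out | startsWith(token, s)
  }
  out
}

#' Emotion-category word proportions of a report
#'
#' For each category, the percentage of token occurrences (with
#' multiplicity) matching the category's literal or stem entries, out of
#' the total word count. Because the output is a proportion it is already
#' controlled for report length. A token matching several entries of one
#' category counts once per occurrence for that category; a token may count
#' toward several categories (and subcategory matches count toward
#' `negative` through the hierarchy).
#'
#' @param tokens Character vector of (lexicon-mode) tokens, at least one.
#' @param lexicon An `emotion_lexicon`.
#' @param categories Category names to score (default the five standard
#'   ones present in the lexicon).
#' @return A one-row tibble: `word_count` and one percentage column per
#'   category named `<category>_pct` (`positive` -> `pos_pct`,
#'   `negative` -> `neg_pct`, `anxiety` -> `anx_pct`, `anger` -> `anger_pct`,
#'   `sadness` -> `sad_pct`; other names keep the full category name).
#' @export
emotion_proportions <- function(tokens, lexicon,
                                categories = intersect(EMOTION_CATEGORIES,
                                                       names(lexicon$categories))) {
  tokens <- as.character(tokens)
  if (length(tokens) == 0) stop("empty token sequence", call. = FALSE)
  n <- length(tokens)
  counts <- vapply(categories, function(cat) sum(match_token(tokens, lexicon, cat)),
                   integer(1))
  pct <- 100 * counts / n
  out <- tibble::as_tibble(as.list(stats::setNames(pct, pct_col_name(categories))))
  dplyr::bind_cols(tibble::tibble(word_count = n), out)
}

pct_col_name <- function(categories) {
  std <- c(positive = "pos_pct", negative = "neg_pct", anxiety = "anx_pct",
           anger = "anger_pct", sadness = "sad_pct")
  ifelse(categories %in% names(std), std[categories], paste0(categories, "_pct"))
}
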