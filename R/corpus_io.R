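# Reading, writing and tokenizing dream-report corpora, emotion lexicons,
# word embeddings and psychometric tables.

GROUP_LEVELS <- c("control", "pandemic")

SELF_EVAL_ASPECTS <- c(
  "happy", "sad", "calm", "anxious", "energetic", "tired",
  "peaceful", "aggressive", "altruistic", "selfish", "creative", "confused"
)

#' Read a corpus of dream reports
#'
#' A corpus is a tibble with one row per transcribed report and columns
#' `report_id`, `participant_id`, `group` (`"control"` or `"pandemic"`),
#' `raw_text`, and optionally `date` and `days_since_lockdown`.
#'
#' Two on-disk layouts are supported:
#' * `format = "csv"` — a UTF-8 comma-separated file with a header row and at
#'   least the columns `report_id`, `participant_id`, `group`, `raw_text`.
#' * `format = "dir_of_txt"` — a directory of `.txt` files named
#'   `<participant>_<group>_<n>.txt`, each holding one report's raw text.
#'
#' @param path Path to the CSV file or to the directory of `.txt` files.
#' @param format `"csv"` (default) or `"dir_of_txt"`.
#' @return A tibble of class `dream_corpus`.
#' @export
read_corpus <- function(path, format = c("csv", "dir_of_txt")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("corpus path does not exist: ", path, call. = FALSE)
  }
  if (format == "csv") {
    tbl <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                           locale = readr::locale(encoding = "UTF-8"), progress = FALSE)
    required <- c("report_id", "participant_id", "group", "raw_text")
    missing <- setdiff(required, names(tbl))
    if (length(missing) > 0) {
      stop("corpus CSV is missing required column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if ("days_since_lockdown" %in% names(tbl)) {
      tbl$days_since_lockdown <- as.numeric(tbl$days_since_lockdown)
    }
    if ("date" %in% names(tbl)) {
      tbl$date <- as.Date(tbl$date)
    }
  } else {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    if (length(files) == 0) {
      stop("no .txt files found under ", path, call. = FALSE)
    }
    stems <- sub("\\.txt$", "", basename(files))
    parts <- stringr::str_match(stems, "^(.+)_([^_]+)_([0-9]+)$")
    if (anyNA(parts[, 1])) {
      bad <- stems[is.na(parts[, 1])]
      stop("file name(s) not of the form <participant>_<group>_<n>.txt: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    tbl <- tibble::tibble(
      report_id = stems,
      participant_id = parts[, 2],
      group = parts[, 3],
      raw_text = vapply(files, function(f) {
        paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n")
      }, character(1))
    )
  }
  as_dream_corpus(tbl)
}

#' Validate a tibble as a dream-report corpus
#'
#' Checks report-id uniqueness, group labels and non-empty text, and attaches
#' the `dream_corpus` class.
#'
#' @param tbl A data frame with columns `report_id`, `participant_id`,
#'   `group`, `raw_text`.
#' @return The validated tibble, classed `dream_corpus`.
#' @export
as_dream_corpus <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  if (anyDuplicated(tbl$report_id)) {
    dup <- unique(tbl$report_id[duplicated(tbl$report_id)])
    stop("duplicate report_id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bad_group <- setdiff(unique(tbl$group), GROUP_LEVELS)
  if (length(bad_group) > 0) {
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "),
         "; expected one of ", paste(GROUP_LEVELS, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(trimws(tbl$raw_text)))) {
    stop("raw_text must be non-empty after whitespace stripping", call. = FALSE)
  }
  class(tbl) <- c("dream_corpus", class(tbl))
  tbl
}

#' Write a corpus to CSV
#'
#' @param corpus A `dream_corpus` tibble.
#' @param path Output CSV path (UTF-8).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  readr::write_csv(tibble::as_tibble(unclass(corpus)), path, progress = FALSE)
  invisible(path)
}

#' Read a LIWC-dialect category dictionary
#'
#' The `.dic` dialect: a header block delimited by lines consisting of `%`,
#' mapping numeric category ids to names (`id<TAB>name`); then body lines
#' `word<TAB>id[ id ...]`. A trailing `*` on a word marks a stem pattern that
#' matches any token starting with the prefix before the `*`.
#'
#' When the subcategory names `anxiety`, `anger`, `sadness` are present
#' together with `negative` (or `negemo`), hierarchy links subcategory ->
#' negative are installed, so subcategory words also count as negative.
#'
#' @param path Path to the `.dic` file (UTF-8).
#' @return An `emotion_lexicon` object: a list with `categories` (named list
#'   of character entry vectors, entries possibly ending in `*`) and
#'   `hierarchy` (named character vector, subcategory -> parent).
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon path does not exist: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  pct <- which(trimws(lines) == "%")
  if (length(pct) < 2) {
    stop("lexicon format error: header block must be delimited by two '%' lines",
         call. = FALSE)
  }
  header <- lines[(pct[1] + 1):(pct[2] - 1)]
  body <- if (pct[2] < length(lines)) lines[(pct[2] + 1):length(lines)] else character(0)
  if (length(body) == 0) stop("lexicon has an empty body", call. = FALSE)

  hdr_parts <- stringr::str_split_fixed(trimws(header), "\\s+", 2)
  ids <- hdr_parts[, 1]
  cat_names <- tolower(trimws(hdr_parts[, 2]))
  if (any(!nzchar(cat_names))) {
    stop("lexicon format error: header line without a category name", call. = FALSE)
  }
  categories <- stats::setNames(vector("list", length(cat_names)), cat_names)
  for (i in seq_along(categories)) categories[[i]] <- character(0)

  for (line in body) {
    fields <- strsplit(trimws(line), "\\s+")[[1]]
    word <- tolower(fields[1])
    if (!nzchar(sub("\\*$", "", word))) {
      stop("lexicon format error: empty word entry", call. = FALSE)
    }
    refs <- fields[-1]
    unknown <- setdiff(refs, ids)
    if (length(unknown) > 0) {
      stop("lexicon format error: word '", word,
           "' references undeclared category id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (id in refs) {
      nm <- cat_names[match(id, ids)]
      categories[[nm]] <- c(categories[[nm]], word)
    }
  }
  categories <- lapply(categories, unique)
  new_emotion_lexicon(categories)
}

# Construct an emotion_lexicon, installing the standard subcategory ->
# negative hierarchy when those category names are present.
new_emotion_lexicon <- function(categories, hierarchy = NULL) {
  stopifnot(is.list(categories), !is.null(names(categories)))
  for (nm in names(categories)) {
    entries <- categories[[nm]]
    if (any(!nzchar(sub("\\*$", "", entries)))) {
      stop("lexicon entry with empty stem prefix in category '", nm, "'",
           call. = FALSE)
    }
  }
  if (is.null(hierarchy)) {
    parent <- intersect(c("negative", "negemo"), names(categories))[1]
    subs <- intersect(c("anxiety", "anger", "sadness"), names(categories))
    hierarchy <- if (!is.na(parent) && length(subs) > 0) {
      stats::setNames(rep(parent, length(subs)), subs)
    } else {
      stats::setNames(character(0), character(0))
    }
  }
  structure(list(categories = categories, hierarchy = hierarchy),
            class = "emotion_lexicon")
}

#' @export
print.emotion_lexicon <- function(x, ...) {
  cat("<emotion_lexicon> ", length(x$categories), " categories\n", sep = "")
  for (nm in names(x$categories)) {
    cat("  ", nm, ": ", length(x$categories[[nm]]), " entries", sep = "")
    if (nm %in% names(x$hierarchy)) cat(" -> ", x$hierarchy[[nm]], sep = "")
    cat("\n")
  }
  invisible(x)
}

#' Write an emotion lexicon in the `.dic` dialect
#'
#' @param lexicon An `emotion_lexicon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  cats <- lexicon$categories
  ids <- as.character(seq_along(cats))
  header <- paste0(ids, "\t", names(cats))
  word_ids <- list()
  for (i in seq_along(cats)) {
    for (w in cats[[i]]) word_ids[[w]] <- c(word_ids[[w]], ids[i])
  }
  body <- vapply(names(word_ids), function(w) {
    paste0(w, "\t", paste(word_ids[[w]], collapse = " "))
  }, character(1))
  writeLines(c("%", header, "%", body), path, useBytes = FALSE)
  invisible(path)
}

#' Read word embeddings in word2vec text format
#'
#' First line `<V> <d>`; then `V` lines `word v1 ... vd`. Duplicate words
#' keep their first occurrence with a warning.
#'
#' @param path Path to the embedding file.
#' @return An `embedding_model`: a numeric matrix with one row per word,
#'   words as row names.
#' @export
read_embeddings <- function(path) {
  if (!file.exists(path)) stop("embedding path does not exist: ", path, call. = FALSE)
  con <- file(path, open = "r", encoding = "UTF-8")
  on.exit(close(con))
  hdr <- strsplit(trimws(readLines(con, n = 1)), "\\s+")[[1]]
  if (length(hdr) != 2) stop("embedding format error: header must be '<V> <d>'", call. = FALSE)
  v <- as.integer(hdr[1]); d <- as.integer(hdr[2])
  if (is.na(d) || d <= 0) stop("embedding format error: dimension must be positive", call. = FALSE)
  lines <- readLines(con)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  nfield <- lengths(parts)
  if (any(nfield != d + 1L)) {
    stop("embedding format error: line(s) with wrong component count (expected ",
         d + 1L, " fields): line ", which(nfield != d + 1L)[1] + 1L, call. = FALSE)
  }
  words <- vapply(parts, `[[`, character(1), 1L)
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(d)))
  if (anyNA(vecs)) stop("embedding format error: non-numeric vector component", call. = FALSE)
  if (anyDuplicated(words)) {
    dup <- unique(words[duplicated(words)])
    warning("duplicate embedding word(s), keeping first occurrence: ",
            paste(utils::head(dup, 5), collapse = ", "),
            if (length(dup) > 5) ", ..." else "", call. = FALSE)
    keep <- !duplicated(words)
    words <- words[keep]; vecs <- vecs[keep, , drop = FALSE]
  }
  rownames(vecs) <- words
  as_embedding_model(vecs)
}

#' Validate an embedding matrix
#'
#' @param mat Numeric matrix, words as row names.
#' @return The matrix, classed `embedding_model`.
#' @export
as_embedding_model <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (nrow(mat) < 1) stop("embedding model must contain at least one vector", call. = FALSE)
  if (is.null(rownames(mat))) stop("embedding matrix must have word row names", call. = FALSE)
  if (anyNA(mat)) stop("embedding vectors must not contain NaN/NA components", call. = FALSE)
  class(mat) <- c("embedding_model", class(mat))
  mat
}

#' Write embeddings in word2vec text format
#'
#' @param model An `embedding_model` matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(model, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(model), ncol(model)), con)
  body <- paste(rownames(model),
                apply(model, 1, function(r) paste(sprintf("%.15g", r), collapse = " ")))
  writeLines(body, con)
  invisible(path)
}

#' Default Portuguese stop-word list
#'
#' A standard list of Portuguese function words (articles, prepositions,
#' pronouns, common auxiliaries). Used only by the semantic tokenization
#' mode; graph and lexicon modes keep stop-words. The list is injectable
#' everywhere it is consumed.
#'
#' @return A character vector of lowercase stop-words.
#' @export
stopwords_pt <- function() {
  c("a", "ao", "aos", "aquela", "aquelas", "aquele", "aqueles", "aquilo",
    "as", "até", "com", "como", "da", "das", "de", "dela", "delas",
    "dele", "deles", "depois", "do", "dos", "e", "ela", "elas", "ele",
    "eles", "em", "entre", "era", "eram", "essa", "essas", "esse", "esses",
    "esta", "estas", "este", "estes", "estou", "está", "estão",
    "eu", "foi", "fomos", "for", "foram", "fosse", "fui", "havia", "isso",
    "isto", "já", "lhe", "lhes", "mais", "mas", "me", "mesmo", "meu",
    "meus", "minha", "minhas", "muito", "na", "nas", "nem", "no", "nos",
    "nossa", "nossas", "nosso", "nossos", "num", "numa", "não",
    "nós", "o", "os", "ou", "para", "pela", "pelas", "pelo", "pelos",
    "por", "qual", "quando", "que", "quem", "se", "seja", "sem", "ser",
    "seu", "seus", "somos", "sou", "sua", "suas", "são", "só",
    "também", "te", "tem", "tenho", "ter", "teu", "tinha", "tu",
    "tua", "tuas", "têm", "um", "uma", "você", "vocês",
    "vos", "à", "às", "é", "éramos")
}

#' Tokenize raw report text
#'
#' All modes lowercase the text and split it on non-letter boundaries,
#' keeping only alphabetic tokens (so punctuation, digits and hyphens are
#' token separators; Portuguese diacritics are letters and are preserved).
#' `mode = "semantic"` additionally removes stop-words; `"graph"` and
#' `"lexicon"` keep them.
#'
#' @param raw_text A single string.
#' @param mode `"graph"`, `"lexicon"` or `"semantic"`.
#' @param stopwords Stop-word list used by semantic mode
#'   (default [stopwords_pt()]).
#' @return A character vector of tokens in original order, with attribute
#'   `mode`. Zero surviving tokens yield a zero-length vector (the caller
#'   decides whether that is an error).
#' @export
tokenize <- function(raw_text, mode = c("graph", "lexicon", "semantic"),
                     stopwords = stopwords_pt()) {
  mode <- match.arg(mode)
  stopifnot(is.character(raw_text), length(raw_text) == 1)
  toks <- stringr::str_split_1(stringr::str_to_lower(raw_text), "[^\\p{L}]+")
  toks <- toks[nzchar(toks)]
  if (mode == "semantic") {
    toks <- toks[!(toks %in% stopwords)]
  }
  attr(toks, "mode") <- mode
  toks
}

#' Read a psychometric score table
#'
#' One row per participant; columns `participant_id`, PANSS items `P1`-`P7`
#' (positive), `N1`-`N7` (negative), `G1`-`G16` (general), each in 1..7, and
#' self-evaluation items `SE_happy` ... `SE_confused`, each in 1..10.
#' Self-evaluation columns are optional but must be complete when present.
#'
#' @param path CSV path.
#' @return A validated tibble of psychometric records with added subscale
#'   totals `panss_positive`, `panss_negative`, `panss_general`.
#' @export
read_psychometrics <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(), .default = readr::col_double()
  ), locale = readr::locale(encoding = "UTF-8"), progress = FALSE)
  validate_psychometrics(tbl)
}

panss_item_cols <- function() {
  list(positive = paste0("P", 1:7),
       negative = paste0("N", 1:7),
       general  = paste0("G", 1:16))
}

#' Validate a psychometric table
#'
#' @param tbl Data frame in the layout of [read_psychometrics()].
#' @return The tibble with subscale totals appended.
#' @export
validate_psychometrics <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  items <- panss_item_cols()
  missing <- setdiff(c("participant_id", unlist(items)), names(tbl))
  if (length(missing) > 0) {
    stop("psychometric table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (cols in items) {
    vals <- as.matrix(tbl[cols])
    if (any(vals < 1 | vals > 7, na.rm = TRUE)) {
      stop("PANSS items must lie in 1..7", call. = FALSE)
    }
  }
  se_cols <- paste0("SE_", SELF_EVAL_ASPECTS)
  have_se <- se_cols %in% names(tbl)
  if (any(have_se) && !all(have_se)) {
    stop("self-evaluation columns must be complete when present; missing: ",
         paste(se_cols[!have_se], collapse = ", "), call. = FALSE)
  }
  if (all(have_se)) {
    vals <- as.matrix(tbl[se_cols])
    if (any(vals < 1 | vals > 10, na.rm = TRUE)) {
      stop("self-evaluation items must lie in 1..10", call. = FALSE)
    }
  }
  tbl$panss_positive <- rowSums(tbl[items$positive])
  tbl$panss_negative <- rowSums(tbl[items$negative])
  tbl$panss_general <- rowSums(tbl[items$general])
  tbl
}

#' Write a psychometric table to CSV
#'
#' Subscale total columns are dropped on write (they are derived).
#'
#' @param tbl Psychometric tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_psychometrics <- function(tbl, path) {
  drop <- intersect(c("panss_positive", "panss_negative", "panss_general"), names(tbl))
  readr::write_csv(dplyr::select(tbl, -dplyr::all_of(drop)), path, progress = FALSE)
  invisible(path)
}
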