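# Semantic similarity of a report to probe words: cosine of each report
# word's embedding to the probe's embedding, averaged over words reaching a
# qualifying threshold (default 0.3; maximum similarity is 1).

#' Cosine similarity of two vectors
#'
#' @param u,v Numeric vectors of equal length, both nonzero.
#' @return `dot(u, v) / (||u|| ||v||)`, in `[-1, 1]` up to rounding.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vector dimension mismatch", call. = FALSE)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine undefined for a zero-norm vector", call. = FALSE)
  sum(u * v) / (nu * nv)
}

#' Average similarity of a report to one probe word
#'
#' Every token occurrence present in the embedding vocabulary is scored by
#' its cosine to the probe vector; occurrences with cosine at or above
#' `threshold` qualify and their cosines are averaged. When no occurrence
#' qualifies the similarity is undefined (`NA`), not zero: zero lies outside
#' the attainable range `[threshold, 1]` and would bias group means.
#' Out-of-vocabulary tokens are skipped.
#'
#' @param tokens Character vector of semantic-mode tokens.
#' @param probe A single probe word, present in the model vocabulary.
#' @param model An `embedding_model` matrix.
#' @param threshold Qualifying cosine (default 0.3, inclusive).
#' @return A one-row tibble: `similarity` (`NA` if no token qualifies),
#'   `qualifying_count`, `n_in_vocab`.
#' @export
probe_similarity <- function(tokens, probe, model, threshold = 0.3) {
  if (!probe %in% rownames(model)) {
    stop("probe word not in embedding vocabulary: ", probe, call. = FALSE)
  }
  tokens <- as.character(tokens)
  in_vocab <- tokens[tokens %in% rownames(model)]
  if (length(in_vocab) == 0) {
    return(tibble::tibble(similarity = NA_real_, qualifying_count = 0L, n_in_vocab = 0L))
  }
  pv <- model[probe, ]
  pn <- sqrt(sum(pv^2))
  if (pn == 0) stop("probe vector has zero norm", call. = FALSE)
  tm <- model[in_vocab, , drop = FALSE]
  norms <- sqrt(rowSums(tm^2))
  if (any(norms == 0)) stop("embedding contains a zero-norm vector", call. = FALSE)
  cosines <- as.numeric(tm %*% pv) / (norms * pn)
  qual <- cosines[cosines >= threshold]
  tibble::tibble(
    similarity = if (length(qual) > 0) mean(qual) else NA_real_,
    qualifying_count = length(qual),
    n_in_vocab = length(in_vocab)
  )
}

#' Similarity profile of a report over a probe list
#'
#' Applies [probe_similarity()] per probe and records the report's
#' out-of-vocabulary rate once (fraction of token occurrences absent from
#' the embedding vocabulary).
#'
#' @param tokens Character vector of semantic-mode tokens.
#' @param probes Character vector of probe words, all in the vocabulary.
#' @param model An `embedding_model`.
#' @param threshold Qualifying cosine (default 0.3).
#' @return A one-row tibble with columns `sim_<probe>` (NA when undefined),
#'   `qual_<probe>` (qualifying counts) and `oov_rate`.
#' @export
probe_profile <- function(tokens, probes, model, threshold = 0.3) {
  tokens <- as.character(tokens)
  missing <- setdiff(probes, rownames(model))
  if (length(missing) > 0) {
    stop("probe word(s) not in embedding vocabulary: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  per_probe <- purrr::map(probes, function(p) {
    res <- probe_similarity(tokens, p, model, threshold)
    stats::setNames(list(res$similarity, res$qualifying_count),
                    c(paste0("sim_", p), paste0("qual_", p)))
  })
  oov <- if (length(tokens) == 0) 0 else mean(!(tokens %in% rownames(model)))
  dplyr::bind_cols(tibble::as_tibble(purrr::flatten(per_probe)),
                   tibble::tibble(oov_rate = oov))
}
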