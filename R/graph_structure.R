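# Word graphs: each distinct word of a report is a node, each consecutive
# word pair a directed edge. Connectedness attributes (LCC, LSC) follow the
# speech-graph tradition; multiplicities are kept on edges but never affect
# component sizes.

#' Build a directed word graph from a token sequence
#'
#' Nodes are the distinct tokens; for every consecutive pair an edge
#' `token_i -> token_{i+1}` is added, with repeated transitions accumulated
#' as an edge `weight` (multiplicity). Immediate word repetitions become
#' self-loops; they are stored but never affect component sizes.
#'
#' @param tokens Character vector of tokens (at least one).
#' @return An [igraph::igraph] directed graph with vertex attribute `name`
#'   and edge attribute `weight` (the transition multiplicity).
#' @export
build_word_graph <- function(tokens) {
  tokens <- as.character(tokens)
  if (length(tokens) == 0) stop("cannot build a graph from an empty token sequence", call. = FALSE)
  vocab <- unique(tokens)
  ids <- match(tokens, vocab)
  g <- igraph::make_empty_graph(n = length(vocab), directed = TRUE)
  igraph::V(g)$name <- vocab
  if (length(ids) > 1) {
    pairs <- paste(ids[-length(ids)], ids[-1])
    mult <- table(pairs)
    ends <- do.call(rbind, strsplit(names(mult), " ", fixed = TRUE))
    edge_vec <- as.integer(t(ends))
    g <- igraph::add_edges(g, edge_vec, weight = as.integer(mult))
  }
  g
}

#' Size of the largest connected component
#'
#' Node count of the largest component under direction-blind reachability.
#'
#' @param graph A directed word graph.
#' @return An integer.
#' @export
lcc_size <- function(graph) {
  max(igraph::components(graph, mode = "weak")$csize)
}

#' Size of the largest strongly connected component
#'
#' Node count of the largest set in which every node reaches every other
#' along edge directions (linear-time SCC computation).
#'
#' @param graph A directed word graph.
#' @return An integer.
#' @export
lsc_size <- function(graph) {
  max(igraph::components(graph, mode = "strong")$csize)
}

# Component sizes for one window of the integer-coded token sequence,
# avoiding igraph object construction per window for speed.
window_component_sizes <- function(ids) {
  vocab <- unique(ids)
  local <- match(ids, vocab)
  n <- length(vocab)
  if (length(local) == 1) return(c(lcc = 1, lsc = 1))
  from <- local[-length(local)]
  to <- local[-1]
  g <- igraph::make_graph(rbind(from, to), n = n, directed = TRUE)
  c(lcc = as.numeric(max(igraph::components(g, mode = "weak")$csize)),
    lsc = as.numeric(max(igraph::components(g, mode = "strong")$csize)))
}

#' Windowed word-graph connectedness
#'
#' Slides a fixed-length window along the token sequence with the given
#' step, builds the word graph of each window, and averages the largest
#' connected (LCC) and strongly connected (LSC) component sizes across
#' windows. The fixed window controls for report length: longer reports
#' contribute more windows, not larger graphs.
#'
#' For a sequence of `T` tokens with `T >= window` there are
#' `floor((T - window) / step) + 1` windows. When `T < window` a single
#' graph over the whole sequence is used and `short_text` is `TRUE`, so
#' downstream analyses can filter such reports.
#'
#' @param tokens Character vector of tokens.
#' @param window Window length in tokens (default 30).
#' @param step Window step in tokens (default 1).
#' @return A one-row tibble: `word_count`, `mean_lcc`, `mean_lsc`,
#'   `n_windows`, `short_text`.
#' @export
windowed_connectedness <- function(tokens, window = 30, step = 1) {
  tokens <- as.character(tokens)
  if (length(tokens) == 0) stop("empty token sequence", call. = FALSE)
  stopifnot(window >= 2, step >= 1)
  n <- length(tokens)
  ids <- match(tokens, unique(tokens))
  if (n < window) {
    sizes <- window_component_sizes(ids)
    return(tibble::tibble(word_count = n, mean_lcc = as.numeric(sizes["lcc"]),
                          mean_lsc = as.numeric(sizes["lsc"]),
                          n_windows = 1L, short_text = TRUE))
  }
  starts <- seq.int(1L, n - window + 1L, by = step)
  sizes <- vapply(starts, function(s) window_component_sizes(ids[s:(s + window - 1L)]),
                  c(lcc = 0, lsc = 0))
  tibble::tibble(word_count = n,
                 mean_lcc = mean(sizes["lcc", ]),
                 mean_lsc = mean(sizes["lsc", ]),
                 n_windows = length(starts),
                 short_text = FALSE)
}

#' Export a word graph as a tab-separated edge list
#'
#' Lines are `source<TAB>target<TAB>multiplicity`.
#'
#' @param graph A word graph from [build_word_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  w <- igraph::E(graph)$weight
  if (is.null(w)) w <- rep(1L, nrow(el))
  writeLines(paste(el[, 1], el[, 2], w, sep = "\t"), path)
  invisible(path)
}
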