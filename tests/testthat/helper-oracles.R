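# Independent brute-force oracles used to cross-check the implementation.

# O(n^3) reachability closure by repeated boolean multiplication.
reach_closure <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (all(nxt == reach)) break
    reach <- nxt
  }
  reach
}

# Largest weak / strong component sizes from a directed adjacency matrix.
oracle_component_sizes <- function(adj) {
  n <- nrow(adj)
  weak <- reach_closure(adj | t(adj))
  lcc <- max(vapply(seq_len(n), function(i) sum(weak[i, ] & weak[, i]), integer(1)))
  strong <- reach_closure(adj)
  mutual <- strong & t(strong)
  lsc <- max(rowSums(mutual))
  c(lcc = as.numeric(lcc), lsc = as.numeric(lsc))
}

# Directed adjacency matrix of a word graph built from a token sequence.
tokens_to_adjacency <- function(tokens) {
  vocab <- unique(tokens)
  n <- length(vocab)
  adj <- matrix(FALSE, n, n)
  ids <- match(tokens, vocab)
  if (length(ids) > 1) {
    for (i in seq_len(length(ids) - 1)) adj[ids[i], ids[i + 1]] <- TRUE
  }
  adj
}

# Exact two-sided rank-sum p by full enumeration of group labelings
# (no ties assumed): P(|W - E[W]| >= |w_obs - E[W]|).
oracle_ranksum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2  # Mann-Whitney U for x
  ew <- nx * ny / 2
  labelings <- utils::combn(nx + ny, nx)
  ws <- apply(labelings, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mean(abs(ws - ew) >= abs(w_obs - ew) - 1e-9)
}

# Exact two-sided signed-rank p by enumeration of all sign assignments
# (zero differences must already be removed; no tied |d| assumed).
oracle_signed_rank_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  ev <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.numeric(signs %*% r)
  mean(abs(vs - ev) >= abs(v_obs - ev) - 1e-9)
}

# First canonical correlation by direct numerical maximization of
# cor(X a, Y b) over direction pairs (2-column sets: angle grid + refine).
oracle_cca_first <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  obj <- function(par) {
    a <- c(cos(par[1]), sin(par[1]))
    b <- c(cos(par[2]), sin(par[2]))
    -abs(stats::cor(x %*% a, y %*% b))
  }
  grid <- seq(0, pi, length.out = 60)
  best <- c(0, 0); best_val <- Inf
  for (t1 in grid) for (t2 in grid) {
    v <- obj(c(t1, t2))
    if (v < best_val) { best_val <- v; best <- c(t1, t2) }
  }
  opt <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  -opt$value
}

# Independently coded effect-size and rank-correlation formulas.
oracle_cohens_d <- function(x, y) {
  sp <- sqrt(((length(x) - 1) * stats::sd(x)^2 + (length(y) - 1) * stats::sd(y)^2) /
               (length(x) + length(y) - 2))
  (mean(x) - mean(y)) / sp
}

oracle_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Naive per-word recomputation of a probe similarity profile.
oracle_probe_similarity <- function(tokens, probe, model, threshold = 0.3) {
  sims <- c()
  for (tok in tokens) {
    if (!tok %in% rownames(model)) next
    u <- model[tok, ]; v <- model[probe, ]
    sims <- c(sims, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  }
  qual <- sims[sims >= threshold]
  list(similarity = if (length(qual)) mean(qual) else NA_real_,
       count = length(qual))
}
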