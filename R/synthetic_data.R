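# Synthetic cohorts with planted, known structure: corpora, lexicons,
# embeddings, and psychometric records. Every generator is deterministic
# given its seed, and each report carries bookkeeping of exactly which
# planted tokens it contains, so pipeline features can be checked against
# ground truth.
#
# Synthetic vocabulary is abstract (generated ASCII strings) rather than
# real Portuguese: each category has its own prefix namespace so a token
# can only ever match its own category, which makes emotion-proportion
# recovery an exact bookkeeping identity.

#' Specification of a synthetic dream-report cohort
#'
#' Defaults emulate the study conditions of the motivating design: 31
#' participants per group; the control group contributes one pre-pandemic
#' report each; pandemic participants contribute a shifted
#' negative-binomial number of reports with mean 4.88 and standard
#' deviation about 4.4 (minimum 1); report lengths are log-normal around
#' 150 tokens; anger and sadness word proportions and the
#' contamination/cleanness probe affinities are elevated in the pandemic
#' group, the remaining categories and probes are matched across groups.
#'
#' @param n_per_group Participants per group.
#' @param reports_mean,reports_sd Mean and SD of pandemic reports per
#'   participant (shifted negative binomial, minimum 1).
#' @param control_reports Reports per control participant.
#' @param length_meanlog,length_sdlog Log-normal parameters of tokens per
#'   report.
#' @param emotion_targets Tibble `category`, `control`, `pandemic`: planted
#'   per-token probability of drawing a word of that category, per group.
#' @param probe_affinity Tibble `probe`, `group`, `weight`, `alpha`:
#'   per-token probability of drawing a word from the probe's embedding
#'   cluster, and the exact cosine of that cluster's words to the probe.
#' @param repetition_rate Probability that a token is a copy of a uniformly
#'   chosen earlier token of the same report (raises word recurrence and
#'   hence strongly connected component sizes).
#' @param embedding_dim Embedding dimension.
#' @param cluster_size Words per (probe, alpha) cluster.
#' @param n_filler Filler vocabulary size.
#' @param lexicon_sizes Named entry counts for [make_lexicon()].
#' @param max_days Last observation day (days since lockdown are drawn
#'   uniformly from 0..max_days for pandemic reports).
#' @param seed Integer seed; every draw of the cohort derives from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 31,
                        reports_mean = 4.88,
                        reports_sd = 4.37,
                        control_reports = 1,
                        length_meanlog = log(150),
                        length_sdlog = 0.5,
                        emotion_targets = default_emotion_targets(),
                        probe_affinity = default_probe_affinity(),
                        repetition_rate = 0.05,
                        embedding_dim = 64,
                        cluster_size = 30,
                        n_filler = 300,
                        lexicon_sizes = c(positive = 406, anxiety = 91,
                                          anger = 184, sadness = 101,
                                          negative_extra = 123),
                        max_days = 46,
                        seed = 1) {
  spec <- mget(names(formals()))
  stopifnot(n_per_group >= 2, repetition_rate >= 0, repetition_rate < 1,
            embedding_dim >= 8, cluster_size >= 1)
  if (any(probe_affinity$alpha <= 0.3 | probe_affinity$alpha > 0.95)) {
    stop("probe cluster alpha must lie in (0.3, 0.95]", call. = FALSE)
  }
  probs <- emotion_targets[c("control", "pandemic")]
  if (any(unlist(probs) < 0 | unlist(probs) > 1)) {
    stop("emotion target proportions must lie in [0, 1]", call. = FALSE)
  }
  for (g in c("control", "pandemic")) {
    tot <- sum(emotion_targets[[g]]) +
      sum(probe_affinity$weight[probe_affinity$group == g])
    if (tot > 1) stop("mixture weights for group '", g, "' exceed 1", call. = FALSE)
  }
  structure(spec, class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_emotion_targets <- function() {
  tibble::tribble(
    ~category,        ~control, ~pandemic,
    "positive",       0.030,    0.030,
    "anxiety",        0.020,    0.020,
    "anger",          0.020,    0.040,
    "sadness",        0.020,    0.040,
    "negative_extra", 0.010,    0.010
  )
}

#' @rdname cohort_spec
#' @export
default_probe_affinity <- function() {
  probes <- c("contaminacao", "limpeza", "doenca", "saude", "morte", "vida")
  elevated <- c("contaminacao", "limpeza")
  purrr::map_dfr(probes, function(p) {
    if (p %in% elevated) {
      tibble::tibble(probe = p, group = c("control", "pandemic"),
                     weight = c(0.02, 0.03), alpha = c(0.40, 0.60))
    } else {
      tibble::tibble(probe = p, group = c("control", "pandemic"),
                     weight = 0.02, alpha = 0.45)
    }
  })
}

random_unit_vector <- function(dim) {
  v <- stats::rnorm(dim)
  v / sqrt(sum(v^2))
}

#' Synthetic word embeddings with exact-cosine probe clusters
#'
#' Probe vectors are random unit vectors, re-sampled until every pair has
#' `|cos| < 0.5`. Each cluster word is built as
#' `alpha * v_probe + sqrt(1 - alpha^2) * u` with `u` a random unit vector
#' orthogonal to the probe, so `cos(word, probe) = alpha` exactly by
#' construction (a sharp target for similarity-recovery tests). Filler
#' words are independent random unit vectors.
#'
#' @param clusters Tibble `probe`, `alpha`, `size`: one word cluster per
#'   row, `alpha` in (0, 1).
#' @param filler_words Character vector of extra words embedded as random
#'   unit vectors (may be empty).
#' @param dim Embedding dimension (>= 8).
#' @param seed Optional integer seed.
#' @return An `embedding_model` matrix with attribute `cluster_words`: a
#'   tibble `word`, `probe`, `alpha`.
#' @export
make_embeddings <- function(clusters, filler_words = character(), dim = 64,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(dim >= 8, all(clusters$size >= 1))
  if (any(clusters$alpha <= 0 | clusters$alpha >= 1)) {
    stop("cluster alpha must lie in (0, 1)", call. = FALSE)
  }
  probes <- unique(clusters$probe)
  for (attempt in 1:1000) {
    pv <- t(vapply(probes, function(p) random_unit_vector(dim), numeric(dim)))
    if (length(probes) == 1) break
    cc <- tcrossprod(pv)
    diag(cc) <- 0
    if (max(abs(cc)) < 0.5) break
    if (attempt == 1000) stop("could not draw probe vectors with pairwise |cos| < 0.5")
  }
  rownames(pv) <- probes
  rows <- list()
  cluster_words <- list()
  for (i in seq_len(nrow(clusters))) {
    p <- clusters$probe[i]; alpha <- clusters$alpha[i]; size <- clusters$size[i]
    vp <- pv[p, ]
    words <- paste0("clw", substr(gsub("[^a-z]", "", p), 1, 4),
                    letter_code(round(alpha * 100), 2), letter_code(seq_len(size), 3))
    mat <- t(vapply(seq_len(size), function(j) {
      z <- stats::rnorm(dim)
      u <- z - sum(z * vp) * vp
      u <- u / sqrt(sum(u^2))
      alpha * vp + sqrt(1 - alpha^2) * u
    }, numeric(dim)))
    rownames(mat) <- words
    rows[[i]] <- mat
    cluster_words[[i]] <- tibble::tibble(word = words, probe = p, alpha = alpha)
  }
  fm <- NULL
  if (length(filler_words) > 0) {
    fm <- t(vapply(filler_words, function(w) random_unit_vector(dim), numeric(dim)))
    rownames(fm) <- filler_words
  }
  model <- do.call(rbind, c(list(pv), rows, if (!is.null(fm)) list(fm)))
  model <- as_embedding_model(model)
  attr(model, "cluster_words") <- dplyr::bind_rows(cluster_words)
  model
}

# Letter-coded integer (digits mapped a..j) so synthetic words stay purely
# alphabetic and survive the tokenizer intact.
letter_code <- function(n, width = 5) {
  chartr("0123456789", "abcdefghij", sprintf(paste0("%0", width, "d"), n))
}

synthetic_words <- function(prefix, n) {
  # unique letter-coded core plus random tail, so dropping the tail gives a
  # stem prefix that matches this word's forms and no other word
  tails <- replicate(n, paste(sample(letters, 3, replace = TRUE), collapse = ""))
  paste0(prefix, letter_code(seq_len(n)), tails)
}

#' Synthetic emotion lexicon
#'
#' Generates disjoint word sets per category in separate prefix
#' namespaces; `negative` holds extra words of its own while the anxiety,
#' anger and sadness sets feed it through the category hierarchy (so the
#' default sizes give 91 + 184 + 101 + 123 = 499 negative entries in
#' total). About `stem_fraction` of the entries are emitted as trailing
#' wildcard stems; a stem's prefix is unique to its own word, so stems
#' match exactly their own expansions.
#'
#' @param sizes Named integer vector with entries `positive`, `anxiety`,
#'   `anger`, `sadness`, `negative_extra`.
#' @param stem_fraction Fraction of entries written as stems (default 0.1).
#' @param seed Optional integer seed.
#' @return An `emotion_lexicon` with attribute `words`: a named list of the
#'   full literal word forms per category (the forms reports draw from).
#' @export
make_lexicon <- function(sizes = c(positive = 406, anxiety = 91, anger = 184,
                                   sadness = 101, negative_extra = 123),
                         stem_fraction = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(sizes >= 1))
  prefixes <- c(positive = "pos", anxiety = "anx", anger = "ang",
                sadness = "sad", negative_extra = "neg")
  missing <- setdiff(names(prefixes), names(sizes))
  if (length(missing) > 0) stop("sizes missing: ", paste(missing, collapse = ", "))
  words <- purrr::imap(prefixes, function(pre, cat) synthetic_words(pre, sizes[[cat]]))
  entries <- purrr::map(words, function(w) {
    n_stem <- floor(stem_fraction * length(w))
    if (n_stem > 0) {
      idx <- sample(seq_along(w), n_stem)
      w[idx] <- paste0(substr(w[idx], 1, nchar(w[idx]) - 3), "*")
    }
    w
  })
  categories <- list(
    positive = entries$positive,
    negative = entries$negative_extra,
    anxiety = entries$anxiety,
    anger = entries$anger,
    sadness = entries$sadness
  )
  lex <- new_emotion_lexicon(categories)
  attr(lex, "words") <- list(
    positive = words$positive,
    negative_extra = words$negative_extra,
    anxiety = words$anxiety,
    anger = words$anger,
    sadness = words$sadness
  )
  lex
}

# Shared sampling world for a cohort: lexicon word pools, embedding with
# cluster pools, filler pool.
build_world <- function(spec) {
  lexicon <- make_lexicon(spec$lexicon_sizes, seed = NULL)
  fillers <- synthetic_words("fil", spec$n_filler)
  clusters <- spec$probe_affinity |>
    dplyr::distinct(.data$probe, .data$alpha) |>
    dplyr::mutate(size = spec$cluster_size)
  model <- make_embeddings(clusters, filler_words = character(),
                           dim = spec$embedding_dim, seed = NULL)
  cluster_words <- attr(model, "cluster_words")
  # embed lexicon words and fillers as random unit vectors so the corpus
  # is (near-)fully in-vocabulary
  other <- c(unlist(attr(lexicon, "words"), use.names = FALSE), fillers)
  om <- t(vapply(other, function(w) random_unit_vector(spec$embedding_dim),
                 numeric(spec$embedding_dim)))
  rownames(om) <- other
  model2 <- as_embedding_model(rbind(unclass(model), om))
  attr(model2, "cluster_words") <- cluster_words
  list(lexicon = lexicon, model = model2, fillers = fillers,
       lexicon_words = attr(lexicon, "words"), cluster_words = cluster_words)
}

#' Generate one synthetic dream report
#'
#' Draws a token count from the spec's length distribution, then samples
#' each token from the group's mixture over emotion-category vocabulary,
#' probe-cluster vocabulary and filler words; with probability
#' `repetition_rate` the draw is replaced by a copy of a uniformly chosen
#' earlier token (raising recurrence, hence LSC). Bookkeeping records the
#' exact realized count of each planted component, including copies.
#'
#' @param spec A [cohort_spec()].
#' @param group `"control"` or `"pandemic"`.
#' @param world Internal sampling world; built from the spec when `NULL`
#'   (pass one explicitly to share vocabulary across reports).
#' @param report_id,participant_id Identifiers for the emitted report row.
#' @return A list: `report` (one-row corpus tibble), `truth` (one-row
#'   tibble of planted per-category counts and proportions), `tokens`.
#' @export
make_report <- function(spec, group, world = NULL,
                        report_id = "r1", participant_id = "p1") {
  stopifnot(group %in% GROUP_LEVELS)
  if (is.null(world)) world <- build_world(spec)
  n <- 0L
  for (attempt in 1:100) {
    n <- round(stats::rlnorm(1, spec$length_meanlog, spec$length_sdlog))
    if (n >= 2) break
    if (attempt == 100) stop("degenerate report length after 100 attempts", call. = FALSE)
  }
  et <- spec$emotion_targets
  pa <- spec$probe_affinity[spec$probe_affinity$group == group, ]
  comp_names <- c(et$category, paste0("probe:", pa$probe), "filler")
  comp_prob <- c(et[[group]], pa$weight, 1 - sum(et[[group]]) - sum(pa$weight))
  pools <- c(
    stats::setNames(world$lexicon_words[et$category], et$category),
    stats::setNames(
      purrr::map(pa$probe, function(p) {
        cw <- world$cluster_words
        cw$word[cw$probe == p & abs(cw$alpha - pa$alpha[pa$probe == p]) < 1e-12]
      }),
      paste0("probe:", pa$probe)
    ),
    list(filler = world$fillers)
  )
  tokens <- character(n)
  comps <- character(n)
  draws <- sample(length(comp_names), n, replace = TRUE, prob = comp_prob)
  reps <- stats::runif(n) < spec$repetition_rate
  reps[1] <- FALSE
  for (i in seq_len(n)) {
    if (reps[i]) {
      j <- sample.int(i - 1L, 1L)
      tokens[i] <- tokens[j]
      comps[i] <- comps[j]
    } else {
      comp <- comp_names[draws[i]]
      pool <- pools[[comp]]
      tokens[i] <- pool[sample.int(length(pool), 1L)]
      comps[i] <- comp
    }
  }
  counts <- table(factor(comps, levels = comp_names))
  truth <- tibble::tibble(report_id = report_id, participant_id = participant_id,
                          group = group, n_tokens = n)
  for (cat in et$category) {
    truth[[paste0(cat, "_count")]] <- as.integer(counts[[cat]])
    truth[[paste0(cat, "_pct")]] <- 100 * counts[[cat]] / n
  }
  for (p in pa$probe) {
    truth[[paste0("probe_", p, "_count")]] <- as.integer(counts[[paste0("probe:", p)]])
    truth[[paste0("alpha_", p)]] <- pa$alpha[pa$probe == p]
  }
  report <- tibble::tibble(report_id = report_id, participant_id = participant_id,
                           group = group,
                           raw_text = paste(tokens, collapse = " "))
  list(report = report, truth = truth, tokens = tokens)
}

#' Generate a synthetic cohort
#'
#' Builds the shared vocabulary world (lexicon, embeddings, fillers), then
#' one set of reports per participant per group, with per-report planted
#' bookkeeping aggregated into a per-participant truth table.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `dream_cohort`: `corpus` (a `dream_corpus`),
#'   `lexicon`, `embeddings`, `truth_reports`, `truth_participants`,
#'   `spec`.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  world <- build_world(spec)
  reports <- list(); truths <- list()
  for (group in GROUP_LEVELS) {
    n_reports <- if (group == "control") {
      rep(spec$control_reports, spec$n_per_group)
    } else {
      mu <- spec$reports_mean - 1
      size <- if (spec$reports_sd^2 > spec$reports_mean) {
        mu^2 / (spec$reports_sd^2 - spec$reports_mean)
      } else 1e6
      stats::rnbinom(spec$n_per_group, size = size, mu = mu) + 1L
    }
    for (i in seq_len(spec$n_per_group)) {
      pid <- sprintf("%s%02d", substr(group, 1, 4), i)
      for (r in seq_len(n_reports[i])) {
        rid <- sprintf("%s_rep%02d", pid, r)
        out <- make_report(spec, group, world, report_id = rid, participant_id = pid)
        if (group == "pandemic") {
          out$report$days_since_lockdown <- sample(0:spec$max_days, 1)
        } else {
          out$report$days_since_lockdown <- NA_integer_
        }
        reports[[rid]] <- out$report
        truths[[rid]] <- out$truth
      }
    }
  }
  corpus <- as_dream_corpus(dplyr::bind_rows(reports))
  truth_reports <- dplyr::bind_rows(truths)
  pct_cols <- grep("_pct$", names(truth_reports), value = TRUE)
  alpha_cols <- grep("^alpha_", names(truth_reports), value = TRUE)
  truth_participants <- truth_reports |>
    dplyr::group_by(.data$participant_id, .data$group) |>
    dplyr::summarise(n_reports = dplyr::n(),
                     dplyr::across(dplyr::all_of(c(pct_cols, alpha_cols)), mean),
                     .groups = "drop")
  structure(list(corpus = corpus, lexicon = world$lexicon,
                 embeddings = world$model, truth_reports = truth_reports,
                 truth_participants = truth_participants, spec = spec),
            class = "dream_cohort")
}

#' @export
print.dream_cohort <- function(x, ...) {
  cat("<dream_cohort> ", nrow(x$corpus), " reports, ",
      dplyr::n_distinct(x$corpus$participant_id), " participants, seed ",
      x$spec$seed, "\n", sep = "")
  invisible(x)
}

#' Specification of a planted linear link from text features to a
#' psychometric response
#'
#' @param response Which subscale the link drives (default
#'   `"panss_negative"`).
#' @param coefficients Named numeric vector over feature columns.
#' @param intercept Intercept.
#' @param noise_sd Gaussian noise SD (> 0, or exactly 0 for the noiseless
#'   limit).
#' @param range Valid response range before item distribution (defaults to
#'   the subscale's bounds).
#' @return A list of class `linear_link_spec`.
#' @export
linear_link_spec <- function(response = "panss_negative",
                             coefficients = c(anger_pct = 1.5, sad_pct = 0.5,
                                              sim_contaminacao = 10,
                                              sim_limpeza = 20),
                             intercept = 7,
                             noise_sd = 2,
                             range = NULL) {
  stopifnot(noise_sd >= 0)
  if (is.null(range)) {
    range <- switch(response,
                    panss_positive = c(7, 49), panss_negative = c(7, 49),
                    panss_general = c(16, 112), c(-Inf, Inf))
  }
  structure(list(response = response, coefficients = coefficients,
                 intercept = intercept, noise_sd = noise_sd, range = range),
            class = "linear_link_spec")
}

#' Noise level giving a target population R-squared for a linear link
#'
#' With signal variance `v` (the variance of the linear predictor over the
#' supplied features), returns `sqrt(v (1 - R2) / R2)` so that the planted
#' link has population R-squared `target_r2`.
#'
#' @param features Feature tibble containing the link's variables.
#' @param coefficients Named coefficient vector.
#' @param target_r2 Desired R-squared in (0, 1).
#' @return The noise standard deviation.
#' @export
calibrate_noise_sd <- function(features, coefficients, target_r2) {
  stopifnot(target_r2 > 0, target_r2 < 1)
  lp <- linear_predictor(features, coefficients, 0)
  v <- stats::var(lp)
  sqrt(v * (1 - target_r2) / target_r2)
}

#' Population R-squared whose fitted R-squared centers on a target
#'
#' The in-sample R-squared of an ordinary least-squares fit is biased
#' upward: with `p` predictors and `n` rows,
#' `E[R2_hat] ~ 1 - (1 - rho2) (n - p - 1) / (n - 1)`. This inverts that
#' relation, giving the population `rho2` to plant so that the expected
#' fitted R-squared equals `r2_fitted`. Useful when emulating a reported
#' (hence fitted) R-squared at a small sample size.
#'
#' @param r2_fitted Target expected fitted R-squared.
#' @param n Number of rows of the eventual fit.
#' @param p Number of predictors.
#' @return The population R-squared to pass to [calibrate_noise_sd()].
#' @export
target_population_r2 <- function(r2_fitted, n, p) {
  stopifnot(n > p + 1)
  rho2 <- 1 - (1 - r2_fitted) * (n - 1) / (n - p - 1)
  if (rho2 <= 0) stop("target fitted R-squared is below the null expectation",
                      call. = FALSE)
  rho2
}

linear_predictor <- function(features, coefficients, intercept) {
  missing <- setdiff(names(coefficients), names(features))
  if (length(missing) > 0) {
    stop("features missing link variable(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(features[names(coefficients)])
  as.numeric(x %*% coefficients) + intercept
}

# Spread an integer subscale total across items within bounds.
distribute_items <- function(total, n_items, lo, hi) {
  total <- min(max(round(total), n_items * lo), n_items * hi)
  base <- total %/% n_items
  items <- rep(base, n_items)
  rem <- total - base * n_items
  if (rem > 0) items[seq_len(rem)] <- items[seq_len(rem)] + 1
  # push any out-of-bound mass around (can only occur at the bounds)
  items <- pmin(pmax(items, lo), hi)
  items
}

#' Generate psychometric records from a planted linear link
#'
#' The link's response subscale is `intercept + sum(coef * feature) +
#' Gaussian noise`, clipped to the subscale's valid range, and distributed
#' over its items (rounded, bounds respected). The remaining PANSS items
#' are drawn at healthy-range low values, and the twelve self-evaluation
#' items are drawn with positive aspects rated higher than negative ones.
#' A warning is raised when clipping affects more than 20% of records (the
#' link is mis-scaled for the feature ranges).
#'
#' @param features Per-participant feature tibble with `participant_id` and
#'   the link's variables (complete rows required).
#' @param link A [linear_link_spec()].
#' @param seed Optional integer seed.
#' @param noise `"sampled"` (default): i.i.d. Gaussian draws.
#'   `"variance_matched"`: the Gaussian noise vector is centered and
#'   rescaled so its sample standard deviation equals `noise_sd` exactly —
#'   a sharper planting used when the noise level was calibrated to a
#'   target R-squared, removing the chi-square spread of the realized
#'   noise variance while leaving the noise-signal correlation intact.
#' @return A psychometric tibble in the layout of [read_psychometrics()],
#'   with subscale totals, plus `response_true` (the pre-rounding planted
#'   response).
#' @export
make_psychometrics <- function(features, link, seed = NULL,
                               noise = c("sampled", "variance_matched")) {
  noise <- match.arg(noise)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(link, "linear_link_spec"))
  keep <- stats::complete.cases(features[names(link$coefficients)])
  if (!all(keep)) {
    stop("features incomplete for the link's variables; drop undefined rows first",
         call. = FALSE)
  }
  n <- nrow(features)
  lp <- linear_predictor(features, link$coefficients, link$intercept)
  eps <- stats::rnorm(n, 0, link$noise_sd)
  if (noise == "variance_matched" && link$noise_sd > 0 && n > 2) {
    eps <- (eps - mean(eps)) / stats::sd(eps) * link$noise_sd
  }
  resp <- lp + eps
  clipped <- resp < link$range[1] | resp > link$range[2]
  if (mean(clipped) > 0.2) {
    warning("clipping affected ", round(100 * mean(clipped)),
            "% of records; the link looks mis-scaled", call. = FALSE)
  }
  resp_clipped <- pmin(pmax(resp, link$range[1]), link$range[2])
  items <- panss_item_cols()
  out <- tibble::tibble(participant_id = features$participant_id)
  subscale_of <- c(panss_positive = "positive", panss_negative = "negative",
                   panss_general = "general")
  for (sub in names(subscale_of)) {
    cols <- items[[subscale_of[[sub]]]]
    if (sub == link$response) {
      mat <- t(vapply(resp_clipped, distribute_items, numeric(length(cols)),
                      n_items = length(cols), lo = 1, hi = 7))
    } else {
      mat <- matrix(sample(1:3, n * length(cols), replace = TRUE,
                           prob = c(0.7, 0.2, 0.1)),
                    nrow = n)
    }
    colnames(mat) <- cols
    out <- dplyr::bind_cols(out, tibble::as_tibble(mat))
  }
  positive_aspects <- c("happy", "calm", "energetic", "peaceful", "altruistic", "creative")
  for (aspect in SELF_EVAL_ASPECTS) {
    hi <- aspect %in% positive_aspects
    out[[paste0("SE_", aspect)]] <-
      pmin(pmax(round(stats::rnorm(n, mean = if (hi) 7 else 4, sd = 1.5)), 1), 10)
  }
  out <- validate_psychometrics(out)
  out$response_true <- resp_clipped
  out
}
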