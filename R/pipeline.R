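# End-to-end orchestration: feature extraction per report, per-participant
# averaging, the comparison/correlation/association battery, and output
# emission.

#' Analysis configuration
#'
#' Bundles the tunable parameters of a full run. Defaults: a 30-token
#' window with step 1 for the structural analysis, a 0.3 qualifying cosine
#' for probe similarity, family-wise alpha 0.05 with Bonferroni families of
#' size 3 (structural), 5 (emotion proportions) and 6 (probe
#' similarities).
#'
#' @param probes Probe word list (must be in the embedding vocabulary).
#' @param window,step Sliding-window length and step for connectedness.
#' @param similarity_threshold Qualifying cosine for probe similarity.
#' @param alpha Family-wise error rate before Bonferroni division.
#' @param stopwords Stop-word list for semantic tokenization.
#' @param paired Use the paired signed-rank instead of the unpaired
#'   rank-sum for group comparisons (off by default; the unpaired test is
#'   the primary design, participants present in both groups are treated
#'   as independent rows).
#' @param regression_only Restrict the association stage to the
#'   confirmatory regression (for small subgroups where a canonical
#'   correlation over several variables would overfit).
#' @param seed Integer seed recorded in run metadata.
#' @param out_dir Output directory for [run_full_analysis()] (`NULL` to
#'   skip writing).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(probes = c("contaminacao", "limpeza", "doenca",
                                       "saude", "morte", "vida"),
                            window = 30, step = 1,
                            similarity_threshold = 0.3,
                            alpha = 0.05,
                            stopwords = stopwords_pt(),
                            paired = FALSE,
                            regression_only = FALSE,
                            seed = 1,
                            out_dir = NULL) {
  stopifnot(window >= 2, step >= 1,
            similarity_threshold > 0, similarity_threshold < 1,
            alpha > 0, alpha < 1, length(probes) >= 1)
  structure(as.list(environment()), class = "analysis_config")
}

analysis_families <- function(config) {
  list(structural = c("wc", "mean_lcc", "mean_lsc"),
       emotional = c("pos_pct", "neg_pct", "anx_pct", "anger_pct", "sad_pct"),
       semantic = paste0("sim_", config$probes))
}

#' Extract text features for every report and average per participant
#'
#' Per report: total word count and windowed mean LCC/LSC (graph-mode
#' tokens), the five emotion-category percentages (lexicon-mode tokens),
#' and the probe similarity profile (semantic-mode tokens, stop-words
#' removed). Reports whose text yields no tokens are skipped with a
#' message. Participant rows are the per-column means of their reports
#' (undefined similarities excluded per column).
#'
#' @param corpus A `dream_corpus`.
#' @param lexicon An `emotion_lexicon`.
#' @param model An `embedding_model`.
#' @param config An [analysis_config()].
#' @return A list: `per_report` and `per_participant` feature tibbles.
#' @export
compute_features <- function(corpus, lexicon, model, config = analysis_config()) {
  if (nrow(corpus) == 0) stop("empty corpus", call. = FALSE)
  rows <- purrr::map(seq_len(nrow(corpus)), function(i) {
    rep <- corpus[i, ]
    toks <- tokenize(rep$raw_text, "graph")
    if (length(toks) == 0) return(NULL)
    gm <- windowed_connectedness(toks, config$window, config$step)
    ep <- emotion_proportions(toks, lexicon)
    sem <- tokenize(rep$raw_text, "semantic", stopwords = config$stopwords)
    pp <- probe_profile(sem, config$probes, model, config$similarity_threshold)
    pp <- dplyr::select(pp, dplyr::starts_with("sim_"), "oov_rate")
    dplyr::bind_cols(
      tibble::tibble(report_id = rep$report_id,
                     participant_id = rep$participant_id,
                     group = rep$group,
                     days_since_lockdown = if ("days_since_lockdown" %in% names(rep))
                       as.numeric(rep$days_since_lockdown) else NA_real_),
      tibble::tibble(wc = gm$word_count, mean_lcc = gm$mean_lcc,
                     mean_lsc = gm$mean_lsc, n_windows = gm$n_windows,
                     short_text = gm$short_text),
      dplyr::select(ep, -"word_count"),
      pp
    )
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0) message("skipped ", skipped, " report(s) with no tokens")
  per_report <- dplyr::bind_rows(rows)
  if (nrow(per_report) == 0) stop("no analyzable reports", call. = FALSE)
  keep <- c("wc", "mean_lcc", "mean_lsc", "pos_pct", "neg_pct", "anx_pct",
            "anger_pct", "sad_pct", paste0("sim_", config$probes), "oov_rate")
  per_participant <- average_per_participant(
    dplyr::select(per_report, "participant_id", "group", dplyr::all_of(keep)))
  list(per_report = per_report, per_participant = per_participant)
}

#' Compare the pandemic and control groups feature by feature
#'
#' Runs the two-sided Wilcoxon rank-sum test per feature, grouped into
#' three analysis families (structural, emotion proportions, probe
#' similarities) each with its own Bonferroni threshold, and Cohen's d
#' oriented control minus pandemic. Features passing their family
#' threshold form the significant set used by the downstream stages; as a
#' length-bias check, the significant non-structural features are then
#' Spearman-correlated with word count within the pandemic group (family
#' size = number of such features).
#'
#' @param per_participant Per-participant feature tibble.
#' @param config An [analysis_config()].
#' @return A list of class `dream_comparison`: `comparison` (tibble:
#'   `family`, `feature`, `statistic`, `p_value`, `method`, `cohens_d`,
#'   `threshold`, `significant`), `wc_correlations` (Spearman vs word
#'   count), `significant_features`.
#' @export
compare_groups <- function(per_participant, config = analysis_config()) {
  groups <- split(per_participant, per_participant$group)
  if (!all(GROUP_LEVELS %in% names(groups))) stop("both groups must be present", call. = FALSE)
  if (any(vapply(groups, nrow, integer(1)) < 2)) {
    stop("each group needs at least two participants", call. = FALSE)
  }
  fams <- analysis_families(config)
  comparison <- purrr::imap_dfr(fams, function(features, fam) {
    thr <- bonferroni_threshold(config$alpha, length(features))
    purrr::map_dfr(features, function(f) {
      x <- groups$control[[f]]; y <- groups$pandemic[[f]]
      tr <- if (config$paired) {
        both <- intersect(groups$control$participant_id, groups$pandemic$participant_id)
        xi <- x[match(both, groups$control$participant_id)]
        yi <- y[match(both, groups$pandemic$participant_id)]
        signed_rank_test(xi, yi)
      } else {
        ranksum_test(x, y)
      }
      d <- tryCatch(cohens_d(x, y), error = function(e) NA_real_)
      dplyr::mutate(tr, family = fam, feature = f, cohens_d = d,
                    threshold = thr, significant = .data$p_value < thr,
                    .before = 1)
    })
  })
  sig <- comparison$feature[comparison$significant]
  sig_nonstructural <- setdiff(sig, fams$structural)
  pandemic <- groups$pandemic
  wc_correlations <- if (length(sig_nonstructural) > 0) {
    thr <- bonferroni_threshold(config$alpha, length(sig_nonstructural))
    purrr::map_dfr(sig_nonstructural, function(f) {
      sc <- spearman_corr(pandemic$wc, pandemic[[f]])
      dplyr::mutate(sc, feature = f, threshold = thr,
                    significant = !is.na(.data$p_value) & .data$p_value < thr,
                    .before = 1)
    })
  } else {
    tibble::tibble()
  }
  structure(list(comparison = comparison, wc_correlations = wc_correlations,
                 significant_features = sig),
            class = "dream_comparison")
}

#' @export
print.dream_comparison <- function(x, ...) {
  cat("<dream_comparison>\n")
  print(dplyr::select(x$comparison, "family", "feature", "p_value",
                      "cohens_d", "threshold", "significant"), n = Inf)
  invisible(x)
}

#' Correlate pandemic-dream features with time since lockdown
#'
#' Spearman correlation of each selected feature against
#' `days_since_lockdown`, computed over individual pandemic reports, with
#' a Bonferroni threshold at the family size (= number of selected
#' features).
#'
#' @param per_report Per-report feature tibble (pandemic rows must carry
#'   `days_since_lockdown`).
#' @param features Character vector of feature columns to correlate
#'   (typically the significant set plus word count).
#' @param config An [analysis_config()].
#' @return A tibble: `feature`, `rho`, `p_value`, `threshold`,
#'   `significant`, `n`.
#' @export
longitudinal_correlations <- function(per_report, features,
                                      config = analysis_config()) {
  pand <- dplyr::filter(per_report, .data$group == "pandemic",
                        !is.na(.data$days_since_lockdown))
  if (nrow(pand) < 3) stop("need at least three dated pandemic reports", call. = FALSE)
  features <- features[features %in% names(pand)]
  if (length(features) == 0) return(tibble::tibble())
  thr <- bonferroni_threshold(config$alpha, length(features))
  purrr::map_dfr(features, function(f) {
    ok <- !is.na(pand[[f]])
    if (sum(ok) < 3 || stats::sd(pand[[f]][ok]) == 0) {
      return(tibble::tibble(feature = f, rho = NA_real_, p_value = NA_real_,
                            threshold = thr, significant = FALSE, n = sum(ok)))
    }
    sc <- spearman_corr(pand$days_since_lockdown[ok], pand[[f]][ok])
    tibble::tibble(feature = f, rho = sc$rho, p_value = sc$p_value,
                   threshold = thr,
                   significant = !is.na(sc$p_value) & sc$p_value < thr,
                   n = sc$n)
  })
}

#' Associate pandemic-dream features with psychometric scores
#'
#' Four linked analyses on the pandemic participants:
#' 1. canonical correlation of the feature set against the three PANSS
#'    subscale totals;
#' 2. confirmatory multiple regression of the subscale carrying the
#'    largest first-pair canonical coefficient on the feature set;
#' 3. item-level canonical correlation of the feature with the largest
#'    canonical coefficient against the seven negative-subscale items;
#' 4. the self-evaluation block: the six positive aspects compared with
#'    their paired negative aspects (signed-rank, Bonferroni m = 6), then
#'    canonical correlations of the features against the positive and the
#'    negative aspect sets.
#'
#' @param per_participant Per-participant feature tibble (pandemic rows
#'   used).
#' @param psychometrics Psychometric tibble from [read_psychometrics()] or
#'   [make_psychometrics()].
#' @param features Feature columns to use (typically the significant
#'   non-structural set from [compare_groups()]).
#' @param config An [analysis_config()].
#' @return A list of class `dream_association`: `cca_subscales`,
#'   `regression` (with `response` name), `cca_items`, `self_eval`
#'   (comparison tibble), `cca_self_positive`, `cca_self_negative`, `n`.
#'   Under `config$regression_only`, only `regression` (of
#'   `panss_negative`) is computed.
#' @export
associate_psychometrics <- function(per_participant, psychometrics, features,
                                    config = analysis_config()) {
  pand <- dplyr::filter(per_participant, .data$group == "pandemic")
  joined <- dplyr::inner_join(pand, psychometrics, by = "participant_id")
  features <- features[features %in% names(pand)]
  if (length(features) == 0) stop("no usable feature columns", call. = FALSE)
  complete <- stats::complete.cases(joined[features])
  joined <- joined[complete, , drop = FALSE]
  if (nrow(joined) < 8) stop("need at least 8 complete joined rows", call. = FALSE)
  x <- joined[features]

  if (config$regression_only) {
    reg <- ols_regression(x, joined$panss_negative)
    return(structure(list(regression = reg, response = "panss_negative",
                          n = nrow(joined)),
                     class = "dream_association"))
  }

  subscales <- c("panss_positive", "panss_negative", "panss_general")
  cca_sub <- canonical_correlation(x, joined[subscales])
  top_sub <- subscales[which.max(abs(cca_sub$y_coefficients[, 1]))]
  reg <- ols_regression(x, joined[[top_sub]])
  top_feat <- features[which.max(abs(cca_sub$x_coefficients[, 1]))]
  item_cols <- paste0("N", 1:7)
  cca_items <- if (all(item_cols %in% names(joined))) {
    item_tbl <- joined[item_cols]
    item_tbl <- item_tbl[vapply(item_tbl, function(v) stats::sd(v) > 0, logical(1))]
    if (ncol(item_tbl) >= 1) {
      tryCatch(canonical_correlation(joined[top_feat], item_tbl),
               error = function(e) NULL)
    } else NULL
  } else NULL

  pairs <- tibble::tribble(
    ~positive, ~negative,
    "happy", "sad", "calm", "anxious", "energetic", "tired",
    "peaceful", "aggressive", "altruistic", "selfish", "creative", "confused"
  )
  se_cols <- paste0("SE_", SELF_EVAL_ASPECTS)
  self_eval <- NULL; cca_pos <- NULL; cca_neg <- NULL
  if (all(se_cols %in% names(joined))) {
    thr <- bonferroni_threshold(config$alpha, nrow(pairs))
    self_eval <- purrr::pmap_dfr(pairs, function(positive, negative) {
      tr <- signed_rank_test(joined[[paste0("SE_", positive)]],
                             joined[[paste0("SE_", negative)]])
      dplyr::mutate(tr, positive = positive, negative = negative,
                    threshold = thr, significant = .data$p_value < thr,
                    .before = 1)
    })
    pos_tbl <- joined[paste0("SE_", pairs$positive)]
    neg_tbl <- joined[paste0("SE_", pairs$negative)]
    safe_cca <- function(y) {
      y <- y[vapply(y, function(v) stats::sd(v) > 0, logical(1))]
      tryCatch(canonical_correlation(x, y), error = function(e) NULL)
    }
    cca_pos <- safe_cca(pos_tbl)
    cca_neg <- safe_cca(neg_tbl)
  }

  structure(list(cca_subscales = cca_sub, regression = reg, response = top_sub,
                 top_feature = top_feat, cca_items = cca_items,
                 self_eval = self_eval, cca_self_positive = cca_pos,
                 cca_self_negative = cca_neg, n = nrow(joined)),
            class = "dream_association")
}

#' @export
print.dream_association <- function(x, ...) {
  cat("<dream_association> n =", x$n, "\n")
  if (!is.null(x$cca_subscales)) {
    cat(" first canonical correlation (features vs PANSS subscales): ",
        signif(x$cca_subscales$correlations[1], 4),
        " (p = ", signif(x$cca_subscales$p_value, 4), ")\n", sep = "")
  }
  cat(" confirmatory regression of ", x$response, ": R^2 = ",
      signif(x$regression$r_squared, 4), " (p = ",
      signif(x$regression$p_value, 4), ")\n", sep = "")
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Executes feature extraction, group comparison, longitudinal correlation
#' and (when psychometrics are supplied) the psychometric association
#' stage, optionally writing all tables plus run metadata under
#' `config$out_dir`. Given the same inputs, config and seed the emitted
#' tables are byte-identical across runs.
#'
#' @param corpus A `dream_corpus` (or path to a corpus CSV).
#' @param lexicon An `emotion_lexicon` (or path to a `.dic` file).
#' @param model An `embedding_model` (or path to word2vec-text embeddings).
#' @param psychometrics Optional psychometric tibble (or CSV path).
#' @param config An [analysis_config()].
#' @return A list of class `dream_results`: `features`, `comparison`,
#'   `longitudinal`, `association` (`NULL` without psychometrics),
#'   `config`, `metadata`.
#' @export
run_full_analysis <- function(corpus, lexicon, model, psychometrics = NULL,
                              config = analysis_config()) {
  if (is.character(corpus)) corpus <- read_corpus(corpus)
  if (is.character(lexicon)) lexicon <- read_lexicon(lexicon)
  if (is.character(model)) model <- read_embeddings(model)
  if (is.character(psychometrics)) psychometrics <- read_psychometrics(psychometrics)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  run <- function() {
    set.seed(config$seed)
    feats <- compute_features(corpus, lexicon, model, config)
    comp <- compare_groups(feats$per_participant, config)
    longi_features <- comp$significant_features
    longi <- if (length(longi_features) > 0 &&
                 any(!is.na(feats$per_report$days_since_lockdown))) {
      longitudinal_correlations(feats$per_report, longi_features, config)
    } else {
      tibble::tibble()
    }
    assoc <- NULL
    if (!is.null(psychometrics)) {
      fam <- analysis_families(config)
      assoc_features <- setdiff(comp$significant_features, fam$structural)
      if (length(assoc_features) > 0) {
        assoc <- associate_psychometrics(feats$per_participant, psychometrics,
                                         assoc_features, config)
      }
    }
    cfg_for_hash <- config[setdiff(names(config), "out_dir")]
    metadata <- list(
      config_hash = rlang::hash(cfg_for_hash),
      seed = config$seed,
      n_reports = nrow(feats$per_report),
      n_participants = nrow(feats$per_participant),
      package_version = as.character(utils::packageVersion("dreamtext")),
      timestamp = NULL
    )
    structure(list(features = feats, comparison = comp, longitudinal = longi,
                   association = assoc, config = config, metadata = metadata),
              class = "dream_results")
  }
  results <- tryCatch(run(), error = function(e) {
    if (!is.null(out_dir)) {
      writeLines(c("FAILED", conditionMessage(e)), file.path(out_dir, "FAILED"))
    }
    stop(e)
  })
  if (!is.null(out_dir)) write_results(results, out_dir)
  results
}

#' Write a results bundle to disk
#'
#' Emits CSV tables (per-report and per-participant features, comparison,
#' word-count and longitudinal correlations, self-evaluation comparisons),
#' a JSON association report and JSON run metadata.
#'
#' @param results A `dream_results` bundle.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(results, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(tbl, name) {
    if (!is.null(tbl) && nrow(tbl) > 0) {
      readr::write_csv(tbl, file.path(out_dir, name), progress = FALSE)
    }
  }
  w(results$features$per_report, "features_per_report.csv")
  w(results$features$per_participant, "features_per_participant.csv")
  w(results$comparison$comparison, "comparison.csv")
  w(results$comparison$wc_correlations, "wc_correlations.csv")
  w(results$longitudinal, "longitudinal.csv")
  assoc <- results$association
  if (!is.null(assoc)) {
    w(assoc$self_eval, "self_evaluation.csv")
    cca_json <- function(cc) {
      if (is.null(cc)) return(NULL)
      list(correlations = cc$correlations,
           x_coefficients = as.data.frame(cc$x_coefficients),
           y_coefficients = as.data.frame(cc$y_coefficients),
           statistic = cc$statistic, df = cc$df, p_value = cc$p_value, n = cc$n)
    }
    report <- list(
      regression = if (!is.null(assoc$regression)) list(
        response = assoc$response,
        coefficients = as.list(assoc$regression$coefficients),
        intercept = assoc$regression$intercept,
        r_squared = assoc$regression$r_squared,
        p_value = assoc$regression$p_value,
        n = assoc$regression$n
      ),
      cca_subscales = cca_json(assoc$cca_subscales),
      top_feature = assoc$top_feature,
      cca_items = cca_json(assoc$cca_items),
      cca_self_positive = cca_json(assoc$cca_self_positive),
      cca_self_negative = cca_json(assoc$cca_self_negative)
    )
    jsonlite::write_json(report, file.path(out_dir, "association.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  jsonlite::write_json(results$metadata, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}
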