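test_that("synthetic embeddings plant exact cluster cosines", {
  clusters <- tibble::tibble(probe = c("alvo", "outro"), alpha = c(0.7, 0.4),
                             size = c(10, 5))
  m <- make_embeddings(clusters, filler_words = paste0("f", letters[1:10]),
                       dim = 64, seed = 5)
  cw <- attr(m, "cluster_words")
  expect_equal(nrow(cw), 15)
  for (i in seq_len(nrow(cw))) {
    expect_equal(cosine_similarity(m[cw$word[i], ], m[cw$probe[i], ]),
                 cw$alpha[i], tolerance = 1e-9)
  }
  # probe vectors kept nearly unrelated by construction
  expect_lt(abs(cosine_similarity(m["alvo", ], m["outro", ])), 0.5)
  expect_error(make_embeddings(tibble::tibble(probe = "p", alpha = 1.2, size = 1)),
               "alpha")
})

test_that("filler vectors concentrate near orthogonality in high dimension", {
  m <- make_embeddings(tibble::tibble(probe = "alvo", alpha = 0.5, size = 1),
                       filler_words = paste0("f", seq_len(1000)),
                       dim = 100, seed = 6)
  pv <- m["alvo", ]
  fillers <- rownames(m)[startsWith(rownames(m), "f")]
  cosines <- as.numeric(m[fillers, ] %*% pv)
  expect_lt(mean(abs(cosines)), 0.15)
})

test_that("synthetic lexicons honor requested sizes and round-trip", {
  lex <- make_lexicon(seed = 8)
  expect_length(lex$categories$positive, 406)
  expect_length(lex$categories$anxiety, 91)
  expect_length(lex$categories$anger, 184)
  expect_length(lex$categories$sadness, 101)
  # negative = its own 123 extras + 376 subcategory entries via hierarchy
  expect_length(lex$categories$negative, 123)
  expect_length(dreamtext:::category_entries(lex, "negative"), 499)

  path <- withr::local_tempfile(fileext = ".dic")
  write_lexicon(lex, path)
  back <- read_lexicon(path)
  for (nm in names(lex$categories)) {
    expect_setequal(back$categories[[nm]], lex$categories[[nm]])
  }

  # stem entries match their own full word forms
  words <- attr(lex, "words")
  for (cat in c("anger", "sadness")) {
    stems <- lex$categories[[cat]][endsWith(lex$categories[[cat]], "*")]
    expect_gt(length(stems), 0)
    for (s in utils::head(stems, 5)) {
      prefix <- sub("\\*$", "", s)
      expect_true(any(startsWith(words[[cat]], prefix)))
    }
    # every full form still matches its category
    expect_true(all(match_token(words[[cat]], lex, cat)))
  }
})

test_that("generated reports respect planted structure and repetition control", {
  spec <- small_cohort_spec(seed = 15)
  set.seed(15)
  world <- dreamtext:::build_world(spec)

  set.seed(16)
  out <- make_report(spec, "pandemic", world)
  expect_equal(out$truth$n_tokens, length(out$tokens))
  expect_equal(out$report$raw_text, paste(out$tokens, collapse = " "))

  # zero repetition with (near-)distinct draws keeps LSC at 1 (no recurrence
  # means no directed cycles except via repeated vocabulary draws)
  spec0 <- cohort_spec(n_per_group = 2, repetition_rate = 0,
                       length_meanlog = log(40), length_sdlog = 0.01,
                       n_filler = 5000, cluster_size = 15, seed = 1)
  set.seed(17)
  world0 <- dreamtext:::build_world(spec0)
  set.seed(18)
  lscs <- replicate(10, {
    rep0 <- make_report(spec0, "control", world0)
    if (anyDuplicated(rep0$tokens)) NA else lsc_size(build_word_graph(rep0$tokens))
  })
  expect_true(all(lscs == 1, na.rm = TRUE))

  # higher repetition rate raises windowed LSC (monotonicity over seeds)
  mean_lsc_at <- function(rate, seed) {
    spec_r <- cohort_spec(n_per_group = 2, repetition_rate = rate,
                          length_meanlog = log(150), length_sdlog = 0.01,
                          n_filler = 300, cluster_size = 15, seed = 1)
    set.seed(seed)
    world_r <- dreamtext:::build_world(spec_r)
    out_r <- make_report(spec_r, "control", world_r)
    windowed_connectedness(out_r$tokens)$mean_lsc
  }
  wins <- vapply(1:20, function(s) {
    mean_lsc_at(0.5, 3000 + s) > mean_lsc_at(0.05, 3000 + s)
  }, logical(1))
  expect_true(all(wins))
})

test_that("cohorts are reproducible bit-for-bit and match the report-count regime", {
  spec <- small_cohort_spec(seed = 99)
  c1 <- make_cohort(spec)
  c2 <- make_cohort(spec)
  expect_identical(c1$corpus, c2$corpus)
  expect_identical(c1$truth_reports, c2$truth_reports)
  expect_identical(unclass(c1$embeddings), unclass(c2$embeddings))

  # every participant has at least one report; both groups present
  counts <- table(c1$corpus$participant_id)
  expect_true(all(counts >= 1))
  expect_setequal(unique(c1$corpus$group), c("control", "pandemic"))

  # pandemic report counts: shifted negative binomial with mean ~4.88
  spec_big <- cohort_spec(n_per_group = 100, seed = 5,
                          length_meanlog = log(20), length_sdlog = 0.1)
  set.seed(5)
  mu <- spec_big$reports_mean - 1
  size <- mu^2 / (spec_big$reports_sd^2 - spec_big$reports_mean)
  draws <- stats::rnbinom(10000, size = size, mu = mu) + 1
  expect_lt(abs(mean(draws) - 4.88), 0.15)
  cb <- make_cohort(cohort_spec(n_per_group = 100, seed = 5,
                                length_meanlog = log(20), length_sdlog = 0.1))
  per_part <- table(cb$corpus$participant_id[cb$corpus$group == "pandemic"])
  expect_lt(abs(mean(per_part) - 4.88), 0.5)
})

test_that("identical group parameters yield few false-positive flags", {
  # type-I behavior of the rank-sum on matched planted proportions
  null_affinity <- default_probe_affinity()
  null_affinity$weight <- 0.02
  null_affinity$alpha <- 0.45
  et <- default_emotion_targets()
  et$pandemic <- et$control
  hits <- vapply(1:25, function(s) {
    spec <- cohort_spec(n_per_group = 10, reports_mean = 2, reports_sd = 1,
                        emotion_targets = et, probe_affinity = null_affinity,
                        length_meanlog = log(80), length_sdlog = 0.2,
                        cluster_size = 10, n_filler = 120, seed = 4000 + s)
    coh <- make_cohort(spec)
    ep <- purrr::map_dfr(seq_len(nrow(coh$corpus)), function(i) {
      toks <- tokenize(coh$corpus$raw_text[i], "lexicon")
      dplyr::mutate(emotion_proportions(toks, coh$lexicon),
                    participant_id = coh$corpus$participant_id[i],
                    group = coh$corpus$group[i])
    })
    per_part <- average_per_participant(
      dplyr::select(ep, "participant_id", "group", "anger_pct"))
    x <- per_part$anger_pct[per_part$group == "control"]
    y <- per_part$anger_pct[per_part$group == "pandemic"]
    ranksum_test(x, y)$p_value < 0.01
  }, logical(1))
  expect_gte(mean(!hits), 0.9)
})

test_that("planted group differences are detected with high power", {
  # anger 8% vs 4% at 30 per group on planted proportions
  et <- default_emotion_targets()
  et$control[et$category == "anger"] <- 0.04
  et$pandemic[et$category == "anger"] <- 0.08
  hits <- vapply(1:50, function(s) {
    spec <- cohort_spec(n_per_group = 30, reports_mean = 3, reports_sd = 2,
                        emotion_targets = et,
                        length_meanlog = log(150), length_sdlog = 0.3,
                        seed = 5000 + s)
    set.seed(spec$seed)
    # planted per-report proportions via the bookkeeping truth, no text pass
    world <- dreamtext:::build_world(spec)
    truth <- purrr::map_dfr(1:spec$n_per_group, function(i) {
      dplyr::bind_rows(
        dplyr::mutate(make_report(spec, "control", world)$truth,
                      participant_id = paste0("c", i)),
        purrr::map_dfr(1:3, function(r)
          dplyr::mutate(make_report(spec, "pandemic", world)$truth,
                        participant_id = paste0("p", i)))
      )
    })
    per_part <- average_per_participant(
      dplyr::select(truth, "participant_id", "group", "anger_pct"))
    x <- per_part$anger_pct[per_part$group == "control"]
    y <- per_part$anger_pct[per_part$group == "pandemic"]
    ranksum_test(x, y)$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("psychometric generation respects the planted linear link", {
  set.seed(61)
  feats <- tibble::tibble(
    participant_id = sprintf("p%02d", 1:31),
    anger_pct = rnorm(31, 4, 1), sad_pct = rnorm(31, 4, 1),
    sim_contaminacao = rnorm(31, 0.55, 0.05),
    sim_limpeza = rnorm(31, 0.55, 0.05)
  )
  # noiseless limit: regression recovers coefficients and R^2 = 1
  link0 <- linear_link_spec(noise_sd = 0)
  psy0 <- make_psychometrics(feats, link0, seed = 62)
  fit0 <- suppressWarnings(  # lm flags the intentionally perfect fit
    ols_regression(feats[names(link0$coefficients)], psy0$response_true))
  expect_equal(unname(fit0$coefficients), unname(link0$coefficients), tolerance = 1e-6)
  expect_equal(fit0$r_squared, 1, tolerance = 1e-9)
  # item distribution reconstructs the rounded subscale total
  expect_equal(psy0$panss_negative, round(psy0$response_true))

  # subscale invariants
  expect_true(all(psy0$panss_negative >= 7 & psy0$panss_negative <= 49))
  expect_true(all(as.matrix(psy0[paste0("N", 1:7)]) >= 1 &
                    as.matrix(psy0[paste0("N", 1:7)]) <= 7))

  # mis-scaled link warns about clipping
  bad <- linear_link_spec(coefficients = c(anger_pct = 100), intercept = 0,
                          noise_sd = 1)
  expect_warning(make_psychometrics(feats, bad, seed = 63), "clipping")
})

test_that("calibrated noise reproduces the target R^2 regime at n = 31", {
  link_coef <- c(anger_pct = 1.5, sad_pct = 0.5,
                 sim_contaminacao = 10, sim_limpeza = 20)
  # plant the population R^2 whose fitted value centers on 0.4 at n = 31,
  # with variance-matched noise for a sharp calibration
  rho2 <- target_population_r2(0.4, n = 31, p = length(link_coef))
  r2s <- vapply(1:50, function(s) {
    set.seed(7000 + s)
    feats <- tibble::tibble(
      participant_id = sprintf("p%02d", 1:31),
      anger_pct = rnorm(31, 4, 1), sad_pct = rnorm(31, 4, 1),
      sim_contaminacao = rnorm(31, 0.55, 0.05),
      sim_limpeza = rnorm(31, 0.55, 0.05)
    )
    sd_cal <- calibrate_noise_sd(feats, link_coef, rho2)
    link <- linear_link_spec(coefficients = link_coef, noise_sd = sd_cal)
    psy <- make_psychometrics(feats, link, noise = "variance_matched")
    ols_regression(feats[names(link_coef)], psy$panss_negative)$r_squared
  }, numeric(1))
  expect_lt(abs(mean(r2s) - 0.4), 0.05)
  expect_gte(mean(r2s >= 0.25 & r2s <= 0.55), 0.8)

  # null link: non-significant regressions in >= 90% of seeds
  ps <- vapply(1:50, function(s) {
    set.seed(8000 + s)
    feats <- tibble::tibble(
      participant_id = sprintf("p%02d", 1:31),
      anger_pct = rnorm(31, 4, 1), sad_pct = rnorm(31, 4, 1),
      sim_contaminacao = rnorm(31, 0.55, 0.05),
      sim_limpeza = rnorm(31, 0.55, 0.05)
    )
    link <- linear_link_spec(coefficients = c(anger_pct = 0, sad_pct = 0,
                                              sim_contaminacao = 0,
                                              sim_limpeza = 0),
                             intercept = 25, noise_sd = 4)
    psy <- make_psychometrics(feats, link)
    ols_regression(feats[names(link$coefficients)], psy$panss_negative)$p_value
  }, numeric(1))
  expect_gte(mean(ps >= 0.05), 0.9)
})
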