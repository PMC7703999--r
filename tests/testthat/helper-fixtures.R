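# Small fixtures built in code.

tiny_lexicon <- function() {
  dreamtext:::new_emotion_lexicon(list(
    positive = c("feliz", "amor", "alegr*"),
    negative = c("ruim"),
    anxiety = c("nervoso", "preocup*"),
    anger = c("mat*", "odiar", "raiva"),
    sadness = c("triste", "chor*")
  ))
}

tiny_lexicon_dic <- function(path) {
  writeLines(c(
    "%",
    "1\tposemo", "2\tnegative", "3\tanxiety", "4\tanger", "5\tsadness",
    "%",
    "feliz\t1", "amor\t1", "alegr*\t1",
    "ruim\t2",
    "nervoso\t3", "preocup*\t3",
    "mat*\t4", "odiar\t4 2", "raiva\t4",
    "triste\t5", "chor*\t5"
  ), path, useBytes = TRUE)
  path
}

# Deterministic tiny embedding: explicit vectors so cosines are hand-checkable.
tiny_embeddings <- function() {
  m <- rbind(
    probe = c(1, 0, 0, 0),
    same  = c(2, 0, 0, 0),     # cos = 1 with probe
    ortho = c(0, 1, 0, 0),     # cos = 0
    anti  = c(-1, 0, 0, 0),    # cos = -1
    mid4  = c(0.4, sqrt(1 - 0.16), 0, 0),  # cos = 0.4
    mid6  = c(0.6, sqrt(1 - 0.36), 0, 0),  # cos = 0.6
    low2  = c(0.2, sqrt(1 - 0.04), 0, 0)   # cos = 0.2
  )
  as_embedding_model(m)
}

tiny_corpus_csv <- function(path, rows = NULL) {
  if (is.null(rows)) {
    rows <- data.frame(
      report_id = c("r1", "r2"),
      participant_id = c("p1", "p2"),
      group = c("control", "pandemic"),
      raw_text = c("Sonhei com o mar.", "Tive um sonho estranho, muito estranho!")
    )
  }
  utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  path
}

# Small cohort spec for fast end-to-end tests: fewer participants than the
# paper-scale default, with a stronger planted emotion contrast so the
# rank-sum retains power at this reduced n.
small_cohort_spec <- function(seed = 7, n_per_group = 10) {
  et <- default_emotion_targets()
  et$pandemic[et$category %in% c("anger", "sadness")] <- 0.06
  cohort_spec(n_per_group = n_per_group, reports_mean = 3, reports_sd = 2,
              length_meanlog = log(150), length_sdlog = 0.3,
              emotion_targets = et,
              cluster_size = 15, n_filler = 150, seed = seed)
}
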