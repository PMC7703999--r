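---
title: "Computational analysis of dream reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computational analysis of dream reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dreamtext)
```

dreamtext quantifies transcribed dream reports along three axes — structural
connectedness of word graphs, dictionary-based emotion word proportions, and
embedding-based semantic similarity to probe words — and links those features
to psychometric scores. This vignette documents the model behind each stage,
the tunable parameters and their defaults, the synthetic-data generator used
for ground-truth testing, and the numerical and design choices that were
genuinely open.

## Word graphs and connectedness

A report's word graph treats each distinct word token as a node and each
consecutive token pair as a directed edge, so the graph traces the temporal
trajectory of speech through its vocabulary. Repeated transitions accumulate
an edge multiplicity, and immediate repetitions become self-loops; neither
affects connectivity, but the multigraph representation keeps the
information for density-style metrics. Two attributes summarize
connectedness:

* **LCC** — node count of the largest connected component, ignoring edge
  direction;
* **LSC** — node count of the largest strongly connected component, i.e.
  the largest vocabulary subset in which every word is reachable from every
  other along the spoken order. LSC grows with word recurrence: a discourse
  that returns to earlier words closes directed cycles.

Longer reports trivially have larger graphs, so connectedness is computed
on a sliding window: `window = 30` tokens, `step = 1`, giving
`floor((T - window)/step) + 1` windows for a `T`-token report, and the
per-window LCC/LSC are averaged. A 60-token report therefore contributes
exactly 31 windows. The window normalizes report length: verbose reports
contribute more windows, not bigger graphs.

Reports shorter than the window get a single full-text graph and a
`short_text` flag rather than being dropped or padded — no data is lost and
downstream analyses can filter explicitly. Component sizes are computed by
igraph's linear-time algorithms; the test suite cross-checks them against a
cubic-time boolean-closure reachability oracle on hundreds of random
graphs.

```{r graph-example}
windowed_connectedness(tokenize("sonhei que sonhei e acordei e sonhei de novo", "graph"))
```

## Emotion word proportions

An `emotion_lexicon` maps categories to entries that are either literal
words or trailing-wildcard stems (`preocup*` matches `preocupado`,
`preocupada`, ...). The standard five categories are positive, negative,
anxiety, anger and sadness, with the three last linked to `negative`
through a category hierarchy, following the usual structure of LIWC-style
dictionaries: an anger word is also a negative word. A report's emotion
profile is, per category, the percentage of token occurrences matching the
category — a length-controlled measure by construction. A token matching
several entries of one category counts once per occurrence; a token may
count toward several categories.

Tokenization decisions (fixed across the package): text is lowercased and
split on every non-letter character, so hyphenated clitics (`deu-me`) split
and digits vanish; Portuguese diacritics are letters and are never folded,
because lexicon entries carry them. Stop-words are *kept* for the graph and
lexicon analyses — function-word transitions are part of discourse
structure, and dictionary proportions are defined against the full word
count — and removed only for the semantic analysis, where function words
carry no useful embedding signal. The stop-word list is injectable;
`stopwords_pt()` ships a standard Portuguese default.

## Semantic similarity to probe words

Each semantic-mode token that exists in the embedding vocabulary is scored
by the cosine between its vector and the probe word's vector. The report's
similarity to the probe is the mean cosine over tokens that reach the
qualifying threshold 0.3 (inclusive; maximum similarity is 1). Averaging
only qualifying words keeps the statistic insensitive to report length and
focused on genuinely related vocabulary.

When no token qualifies the similarity is *undefined* (`NA`), not zero:
zero lies outside the attainable range `[0.3, 1]`, and coding it as zero
would drag group means toward an impossible value. Undefined cells are
skipped in per-participant averaging and dropped listwise in the
multivariate analyses. Out-of-vocabulary tokens are skipped and tallied in
an `oov_rate` column; no subword composition is attempted. Token
*occurrences* (not distinct types) enter the average, reading the statistic
as "the average similarity of the running words"; the choice is documented
here because the alternative (types) is equally defensible.

Default probes are the Portuguese forms contaminação/limpeza/doença/saúde/
morte/vida-style single tokens; any probe list present in the embedding
vocabulary can be configured.

## The statistics layer

One data point per participant: all of a participant's reports are averaged
column-wise before any group statistic (undefined similarity cells excluded
per column).

**Group comparison.** Two-sided Wilcoxon rank-sum per feature. The exact
rank-sum distribution is enumerated when the combined sample is ≤ 20
without ties — the regime of toy examples and tests — and the
tie-corrected, continuity-corrected normal approximation is used otherwise,
which is the regime of realistic cohorts (31 + 31). Features are grouped
into three Bonferroni families with thresholds `alpha / m` displayed at
four decimals: structural (WC, LCC, LSC; m = 3 → 0.0167), emotion
proportions (m = 5 → 0.0100), probe similarities (m = 6 → 0.0083). Cohen's
d uses the pooled-SD convention, oriented control − pandemic so features
elevated under the pandemic carry negative signs. Participants present in
both groups are treated as independent rows by default (`paired = FALSE`),
matching the primary unpaired design; a paired mode exists.

**Follow-up correlations.** Features passing their family threshold form
the "significant set". As a length-bias check the non-structural members
are Spearman-correlated with word count (family m = their number, e.g.
4 → 0.0125); the longitudinal stage correlates the significant set with
days since lockdown over individual dated reports (e.g. m = 5 → 0.0100).
Spearman is implemented as Pearson on mid-ranks with the t approximation on
n − 2 degrees of freedom, which handles ties transparently.

**Canonical correlation.** Columns are standardized; directions come from
the SVD of the whitened cross-covariance
`Sxx^{-1/2} Sxy Syy^{-1/2}`, whose singular values are the canonical
correlations. Significance uses Bartlett's chi-square approximation of
Wilks' lambda over all pairs (a standard default; the choice matters little
at these dimensions and is recorded here because the method was an open
choice). Canonical directions are defined only up to a joint sign flip, so
they are canonicalized with the dominant y-coefficient positive — printed
signs elsewhere may differ by a global flip without contradiction.
Whitening refuses near-singular within-set covariance (eigenvalue below
1e-10 of the largest) and names the offending side, suggesting a dropped
column rather than silently regularizing.

**Association battery.** Canonical correlation of the significant feature
set against the three PANSS subscale totals; confirmatory OLS regression of
the subscale with the largest first-pair canonical coefficient on the
features (reported as coefficients, R², overall-F p); item-level canonical
correlation of the dominant feature against the seven negative-subscale
items; and the self-evaluation block — six positive aspects tested against
their paired negative aspects with the signed-rank test (m = 6 → 0.0083),
then canonical correlations of features against each aspect set. The
paired positive-versus-negative test is not named in the source protocol;
the signed-rank is this package's documented assumption, being the
standard nonparametric paired choice. For small medicated subgroups a
`regression_only` mode skips the multivariate stages, which would overfit.

**Rater agreement.** A one-feature Gaussian Naive Bayes classifier
predicts a binary human judgment from an emotion proportion and reports
percent accuracy. The evaluation protocol is configurable
(leave-one-out by default, resubstitution as the alternative) because the
original evaluation protocol is underdetermined; neither protocol is
claimed to reproduce any particular published accuracy. Class variances
receive a smoothing term of 1e-9 times the overall score variance so
perfectly separated classes stay well-defined.

## The synthetic cohort generator

`make_cohort()` builds a corpus, lexicon, embedding and truth tables with
planted structure, so every pipeline stage has a ground-truth recovery
test. Defaults encode the emulated study conditions:

* 31 participants per group; controls contribute 1 report each, pandemic
  participants a shifted negative-binomial count with mean 4.88 and SD
  ≈ 4.4 (minimum 1; size parameter from moment matching);
* report lengths log-normal around 150 tokens (`sdlog` 0.5);
* planted per-token emotion probabilities: anger and sadness 2% (control)
  vs 4% (pandemic); positive 3%, anxiety 2%, extra negative 1% in both;
* probe affinities: contamination and cleanness clusters at weight
  2%/cosine 0.40 (control) vs 3%/0.60 (pandemic); the four remaining
  probes matched at 2%/0.45;
* token repetition rate 5%; observation days uniform over 0–46.

The synthetic vocabulary is abstract ASCII (category-prefixed namespaces),
not real Portuguese: every token can match only its own category, which
turns emotion-proportion recovery into an exact bookkeeping identity, and
the proprietary dictionary need not be shipped. About 10% of lexicon
entries are emitted as stems whose prefixes are unique to their own word.

Probe clusters are exact by construction: a cluster word is
`alpha * v_probe + sqrt(1 - alpha^2) * u` with `u` random orthogonal to the
probe, so its cosine to the probe is exactly `alpha`. Because the
similarity statistic averages qualifying cosines (and is insensitive to
how many there are), a group difference in mean similarity is planted by
giving the groups clusters at different `alpha`, not merely different
weights. The embedding dimension defaults to 64: unrelated random vectors
then clear the 0.3 threshold for ~0.8% of tokens, which mirrors the real
phenomenon of incidental qualifiers and supplies natural between-participant
variance in the similarity features; at much higher dimension the planted
similarities become exactly constant within groups and degenerate the
association analyses. Sharp recovery checks therefore use reports drawn
entirely from a cluster, where the planted cosine is recovered to within
Monte-Carlo tolerance regardless of dimension.

Psychometric records derive from a planted linear link: the chosen subscale
is `intercept + sum(coef * feature) + noise`, clipped to its valid range
and distributed over items within bounds; remaining PANSS items draw
healthy-range low values, and self-evaluation items plant positive aspects
above negative ones. Two calibration helpers matter when emulating a
reported fitted R² at small n:

* `target_population_r2(r2, n, p)` inverts the upward bias of in-sample R²
  (`E[R2_hat] ≈ 1 − (1 − rho²)(n − p − 1)/(n − 1)`), giving the population
  value to plant so the *fitted* R² centers on the target — at n = 31 with
  4 predictors, a fitted 0.40 corresponds to a population ≈ 0.31;
* `make_psychometrics(..., noise = "variance_matched")` rescales the
  Gaussian noise vector to its nominal standard deviation, removing the
  chi-square spread of the realized noise variance while leaving the
  noise–signal correlation (the phenomenon under study) untouched. The
  default remains fully sampled Gaussian noise.

Even with both, the sampling SD of fitted R² at n = 31, p = 4 is ≈ 0.11,
so a ±0.15 recovery band captures roughly 80% of seeds — that spread is a
property of small-sample regression, not of the generator.

What the generator does *not* emulate: linguistic structure (syntax, topic
coherence, Zipfian frequencies), inter-report dependence within a
participant beyond shared sampling parameters, real dictionary coverage
gaps, and embedding anisotropy. Passing recovery tests therefore
demonstrates algorithmic correctness and statistical calibration of the
pipeline, not performance on real transcripts.

## Numerical choices and degenerate inputs

* Rank-sum/signed-rank exactness cutoffs: combined n ≤ 20 / effective
  n ≤ 15, both requiring tie-free values; identical samples short-circuit
  to p = 1 rather than erroring.
* Spearman with a constant margin returns a degenerate marker instead of a
  correlation; |rho| = 1 maps to p = 0 via the t limit.
* Texts with no alphabetic tokens yield an empty token sequence; the
  feature extractor skips such reports with a logged count.
* Duplicate embedding rows keep the first occurrence with a warning;
  zero-norm vectors are rejected wherever a cosine would be formed.
* OLS drops incomplete rows with a message and refuses rank-deficient
  designs, naming collinear columns.
* Report lengths of zero are redrawn (at most 100 attempts); planted
  responses clip to the subscale's range, warning when clipping touches
  more than 20% of records.

## Problem sizes used by the test suite

The packaged tests run the full pipeline on reduced cohorts (10 per group,
~3 reports per pandemic participant, ~150-token reports, with a
proportionally stronger planted emotion contrast so the rank-sum retains
power at that n), and the acceptance script runs the paper-scale
31-per-group cohort once. Oracle cross-checks use hundreds of small random
instances. These sizes are the package's chosen balance between coverage
and a test suite that stays fast enough to run habitually.

## Known limitations

Semantic similarity depends on the supplied embedding; no subword fallback
means heavy OOV inflates `oov_rate` and thins the qualifying sets.
The unpaired design treats the few doubly-observed participants as
independent. Bonferroni families are config-driven; alternative family
partitions change thresholds. The rater-agreement classifier is
intentionally minimal (one feature, Gaussian classes) — it is an
agreement check, not a text classifier.
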