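# Statistical layer: per-participant averaging, rank-based comparisons,
# effect sizes, correlations, Bonferroni families, canonical correlation,
# multiple regression, and the Gaussian Naive Bayes rater-agreement check.

#' Average per-report features to one row per participant
#'
#' Each participant contributes a single data point to the group analyses:
#' the arithmetic mean of each feature over their reports. Undefined
#' (`NA`) similarity cells are excluded from their column's mean; a
#' participant whose reports are all undefined for a column keeps `NA`.
#'
#' @param per_report_features Tibble with `participant_id`, `group` and
#'   numeric feature columns (one row per report).
#' @return A tibble with one row per `(participant_id, group)` and the
#'   per-column means, plus `n_reports`.
#' @export
average_per_participant <- function(per_report_features) {
  if (nrow(per_report_features) == 0) stop("empty feature table", call. = FALSE)
  num_cols <- names(per_report_features)[vapply(per_report_features, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, c("days_since_lockdown"))
  per_report_features |>
    dplyr::group_by(.data$participant_id, .data$group) |>
    dplyr::summarise(
      n_reports = dplyr::n(),
      dplyr::across(dplyr::all_of(num_cols),
                    ~ if (all(is.na(.x))) NA_real_ else mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided. The exact rank-sum distribution is enumerated when the
#' combined sample size is at most 20 and there are no ties; otherwise the
#' normal approximation with tie-corrected variance and continuity
#' correction is used. `NA` values are dropped per sample.
#'
#' @param x,y Numeric samples (each at least one value after `NA` removal).
#' @param exact_max Combined-size cutoff for the exact test (default 20).
#' @return A one-row tibble: `statistic` (Mann-Whitney U for `x`),
#'   `p_value`, `method` (`"ranksum_exact"` or `"ranksum_normal"`).
#' @export
ranksum_test <- function(x, y, exact_max = 20) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1) stop("both samples need at least one value", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  if (length(unique(c(x, y))) == 1) {
    return(tibble::tibble(statistic = length(x) * length(y) / 2, p_value = 1,
                          method = "ranksum_degenerate"))
  }
  use_exact <- (length(x) + length(y) <= exact_max) && !ties
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = TRUE, alternative = "two.sided"))
  tibble::tibble(statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 method = if (use_exact) "ranksum_exact" else "ranksum_normal")
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided; zero differences are dropped. Exact when the effective sample
#' size (nonzero differences) is at most 15 and the differences are untied
#' in absolute value; otherwise the normal approximation with continuity
#' correction.
#'
#' @param a,b Paired numeric samples of equal length.
#' @param exact_max Effective-size cutoff for the exact test (default 15).
#' @return A one-row tibble: `statistic` (V, sum of positive ranks),
#'   `p_value`, `method`.
#' @export
signed_rank_test <- function(a, b, exact_max = 15) {
  if (length(a) != length(b)) stop("paired samples must have equal length", call. = FALSE)
  keep <- !(is.na(a) | is.na(b))
  d <- a[keep] - b[keep]
  d <- d[d != 0]
  if (length(d) == 0) {
    return(tibble::tibble(statistic = 0, p_value = 1, method = "signed_rank_degenerate"))
  }
  use_exact <- length(d) <= exact_max && !anyDuplicated(abs(d))
  ht <- suppressWarnings(stats::wilcox.test(d, exact = use_exact, correct = TRUE,
                                            alternative = "two.sided"))
  tibble::tibble(statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 method = if (use_exact) "signed_rank_exact" else "signed_rank_normal")
}

#' Cohen's d with pooled standard deviation
#'
#' `(mean(x) - mean(y)) / s_pooled`, with
#' `s_pooled^2 = ((n_x - 1) s_x^2 + (n_y - 1) s_y^2) / (n_x + n_y - 2)`.
#' With `x` the control sample and `y` the pandemic sample, features
#' elevated in the pandemic group yield negative d.
#'
#' @param x Control sample (>= 2 values).
#' @param y Pandemic sample (>= 2 values).
#' @return A single number.
#' @export
cohens_d <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("both samples need at least two values", call. = FALSE)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 == 0) stop("pooled standard deviation is zero", call. = FALSE)
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks); p-value
#' from the t approximation with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric samples of equal length (>= 3 complete pairs).
#' @return A one-row tibble: `rho`, `statistic` (t), `p_value`, `method`,
#'   `n`.
#' @export
spearman_corr <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least three complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(rho = NA_real_, statistic = NA_real_, p_value = NA_real_,
                          method = "spearman_degenerate", n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    tstat <- sign(rho) * Inf
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(rho = rho, statistic = tstat, p_value = p,
                 method = "spearman_t", n = n)
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / m`, rounded to four decimals for display (the three analysis
#' families of the default pipeline render as 0.0167, 0.0100 and 0.0083 at
#' `alpha = 0.05`).
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param m Number of comparisons in the family (>= 1).
#' @param digits Display rounding (default 4); use `NULL` for the exact
#'   value.
#' @return The threshold.
#' @export
bonferroni_threshold <- function(alpha, m, digits = 4) {
  stopifnot(alpha > 0, alpha < 1)
  if (!is.numeric(m) || m < 1) stop("m must be a positive integer", call. = FALSE)
  thr <- alpha / m
  if (!is.null(digits)) thr <- round(thr, digits)
  thr
}

#' Multiple linear regression with intercept
#'
#' Ordinary least squares of `y` on the columns of `x`; rows containing
#' undefined cells are dropped (with a message when any are). Errors on a
#' rank-deficient design, naming the collinear columns.
#'
#' @param x Data frame of numeric predictors.
#' @param y Numeric response.
#' @return An object of class `dream_ols`: list with `coefficients` (named,
#'   without intercept), `intercept`, `r_squared`, `statistic` (overall F),
#'   `p_value`, `n`, `n_dropped` and the underlying `fit`.
#' @export
ols_regression <- function(x, y) {
  x <- tibble::as_tibble(x)
  stopifnot(nrow(x) == length(y))
  keep <- stats::complete.cases(x) & !is.na(y)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) message("dropping ", n_dropped, " incomplete row(s)")
  x <- x[keep, , drop = FALSE]; y <- y[keep]
  if (nrow(x) < ncol(x) + 2) stop("need at least p + 2 complete rows", call. = FALSE)
  dat <- dplyr::bind_cols(x, tibble::tibble(.response = y))
  fit <- stats::lm(.response ~ ., data = dat)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  cf <- stats::coef(fit)
  structure(list(
    coefficients = cf[-1],
    intercept = unname(cf[1]),
    r_squared = sm$r.squared,
    statistic = unname(fstat[1]),
    p_value = unname(p),
    n = nrow(x),
    n_dropped = n_dropped,
    fit = fit
  ), class = "dream_ols")
}

#' @export
print.dream_ols <- function(x, ...) {
  cat("<dream_ols> n =", x$n, " R^2 =", signif(x$r_squared, 4),
      " F p =", signif(x$p_value, 4), "\n")
  cat("  intercept:", signif(x$intercept, 4), "\n")
  for (nm in names(x$coefficients)) {
    cat("  ", nm, ":", signif(x$coefficients[[nm]], 4), "\n")
  }
  invisible(x)
}

#' Canonical correlation analysis
#'
#' Finds paired linear combinations of two variable sets with maximal
#' correlation. Columns are standardized to zero mean and unit variance;
#' canonical directions come from the singular value decomposition of the
#' whitened cross-covariance `Sxx^{-1/2} Sxy Syy^{-1/2}`; the canonical
#' correlations are the singular values (clipped to `[0, 1]`). Significance
#' of the full correlation structure is assessed with Bartlett's chi-square
#' approximation of Wilks' lambda. Directions are defined only up to a
#' joint sign flip per pair; they are canonicalized so the y-coefficient of
#' largest magnitude is positive.
#'
#' @param x,y Data frames of numeric variables on the same rows (incomplete
#'   rows dropped listwise).
#' @return An object of class `dream_cca`: list with `correlations`
#'   (non-increasing, in `[0, 1]`), `x_coefficients`, `y_coefficients`
#'   (standardized scale; matrices, one column per canonical pair),
#'   `x_coefficients_raw`, `y_coefficients_raw` (back-transformed to the
#'   raw variable scale), `statistic` (Bartlett chi-square), `df`,
#'   `p_value`, `n`.
#' @export
canonical_correlation <- function(x, y) {
  x <- tibble::as_tibble(x); y <- tibble::as_tibble(y)
  stopifnot(nrow(x) == nrow(y))
  keep <- stats::complete.cases(x) & stats::complete.cases(y)
  x <- x[keep, , drop = FALSE]; y <- y[keep, , drop = FALSE]
  n <- nrow(x); p <- ncol(x); q <- ncol(y)
  if (n < max(p, q) + 2) stop("need at least max(dim X, dim Y) + 2 complete rows", call. = FALSE)
  sx <- vapply(x, stats::sd, numeric(1)); sy <- vapply(y, stats::sd, numeric(1))
  if (any(sx == 0) || any(sy == 0)) {
    bad <- c(names(x)[sx == 0], names(y)[sy == 0])
    stop("constant column(s): ", paste(bad, collapse = ", "),
         "; consider dropping them", call. = FALSE)
  }
  xs <- scale(as.matrix(x)); ys <- scale(as.matrix(y))
  sxx <- stats::cov(xs); syy <- stats::cov(ys); sxy <- stats::cov(xs, ys)
  inv_sqrt <- function(s, side) {
    e <- eigen(s, symmetric = TRUE)
    if (min(e$values) < 1e-10 * max(e$values)) {
      stop("singular within-set covariance in ", side,
           "; consider dropping a collinear column", call. = FALSE)
    }
    e$vectors %*% diag(1 / sqrt(e$values), nrow = length(e$values)) %*% t(e$vectors)
  }
  kx <- inv_sqrt(sxx, "X"); ky <- inv_sqrt(syy, "Y")
  sv <- svd(kx %*% sxy %*% ky)
  k <- min(p, q)
  rho <- pmin(pmax(sv$d[seq_len(k)], 0), 1)
  a <- kx %*% sv$u[, seq_len(k), drop = FALSE]   # standardized x coefficients
  b <- ky %*% sv$v[, seq_len(k), drop = FALSE]   # standardized y coefficients
  for (j in seq_len(k)) {
    lead <- which.max(abs(b[, j]))
    if (b[lead, j] < 0) {
      a[, j] <- -a[, j]; b[, j] <- -b[, j]
    }
  }
  rownames(a) <- names(x); rownames(b) <- names(y)
  # Bartlett's chi-square approximation of Wilks' lambda over all pairs
  lambda <- prod(1 - rho^2)
  chi2 <- -(n - 1 - (p + q + 1) / 2) * log(max(lambda, .Machine$double.xmin))
  df <- p * q
  structure(list(
    correlations = rho,
    x_coefficients = a,
    y_coefficients = b,
    x_coefficients_raw = a / sx,
    y_coefficients_raw = b / sy,
    statistic = chi2,
    df = df,
    p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
    n = n
  ), class = "dream_cca")
}

#' @export
print.dream_cca <- function(x, ...) {
  cat("<dream_cca> n =", x$n,
      " correlations:", paste(signif(x$correlations, 4), collapse = ", "),
      "\n  Bartlett chi^2 =", signif(x$statistic, 4),
      "df =", x$df, "p =", signif(x$p_value, 4), "\n")
  invisible(x)
}

#' Gaussian Naive Bayes agreement between a score and binary labels
#'
#' Fits a one-feature Gaussian Naive Bayes classifier (class-conditional
#' normal likelihoods with class-frequency priors) predicting the binary
#' label from the score, and reports classification accuracy as a
#' percentage under the chosen protocol: `"loo"` (leave-one-out, default)
#' or `"resubstitution"`. Class variances receive a small smoothing term
#' (1e-9 times the overall score variance) so perfectly separated classes
#' remain well-defined.
#'
#' @param scores Numeric vector (e.g. an emotion proportion per text).
#' @param labels Binary labels (two distinct values, >= 2 examples each).
#' @param protocol `"loo"` or `"resubstitution"`.
#' @return Accuracy as a percentage in `[0, 100]`.
#' @export
nb_agreement <- function(scores, labels, protocol = c("loo", "resubstitution")) {
  protocol <- match.arg(protocol)
  keep <- !(is.na(scores) | is.na(labels))
  scores <- scores[keep]; labels <- as.character(labels[keep])
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("labels must contain exactly two classes", call. = FALSE)
  if (min(table(labels)) < 2) stop("need at least two examples per class", call. = FALSE)
  eps <- 1e-9 * max(stats::var(scores), .Machine$double.eps)
  predict_one <- function(train_s, train_l, s) {
    ll <- vapply(classes, function(cl) {
      sc <- train_s[train_l == cl]
      mu <- mean(sc)
      v <- if (length(sc) > 1) stats::var(sc) else 0
      v <- v + eps
      log(length(sc) / length(train_s)) + stats::dnorm(s, mu, sqrt(v), log = TRUE)
    }, numeric(1))
    classes[which.max(ll)]
  }
  pred <- if (protocol == "resubstitution") {
    vapply(scores, function(s) predict_one(scores, labels, s), character(1))
  } else {
    vapply(seq_along(scores), function(i) {
      predict_one(scores[-i], labels[-i], scores[i])
    }, character(1))
  }
  100 * mean(pred == labels)
}
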