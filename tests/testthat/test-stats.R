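test_that("per-participant averaging collapses reports with NA-skipping", {
  tbl <- tibble::tibble(
    participant_id = c("p1", "p2", "p2", "p3", "p3"),
    group = c("control", "pandemic", "pandemic", "pandemic", "pandemic"),
    wc = c(50, 100, 200, 80, 120),
    sim_x = c(0.4, 0.5, NA, NA, NA)
  )
  out <- average_per_participant(tbl)
  expect_equal(nrow(out), 3)
  p2 <- out[out$participant_id == "p2", ]
  expect_equal(p2$wc, 150)
  expect_equal(p2$sim_x, 0.5)        # undefined cell skipped
  p3 <- out[out$participant_id == "p3", ]
  expect_true(is.na(p3$sim_x))       # all-undefined stays undefined
  p1 <- out[out$participant_id == "p1", ]
  expect_equal(p1$wc, 50)            # single report: identity
  expect_error(average_per_participant(tbl[0, ]), "empty")
})

test_that("rank-sum test: exact enumeration cases and degenerate input", {
  r <- ranksum_test(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(r$method, "ranksum_exact")

  same <- ranksum_test(c(1, 2, 3), c(3, 1, 2))
  expect_equal(same$p_value, 1)

  deg <- ranksum_test(c(2, 2), c(2, 2, 2))
  expect_equal(deg$p_value, 1)
  expect_equal(deg$method, "ranksum_degenerate")

  big <- ranksum_test(rnorm(30), rnorm(30))
  expect_equal(big$method, "ranksum_normal")
  expect_true(big$p_value >= 0 && big$p_value <= 1)
})

test_that("exact rank-sum p equals full labeling enumeration on random instances", {
  set.seed(202)
  for (i in 1:200) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    vals <- sample(1:1000, nx + ny)  # untied
    x <- vals[seq_len(nx)]; y <- vals[-seq_len(nx)]
    mine <- ranksum_test(x, y)
    expect_equal(mine$method, "ranksum_exact")
    expect_equal(mine$p_value, oracle_ranksum_p(x, y), tolerance = 1e-10)
  }
})

test_that("signed-rank test: exact tail cases and sign-flip enumeration", {
  a <- 1:6; b <- a - (1:6)   # all differences positive, n = 6
  r <- signed_rank_test(a, b)
  expect_equal(r$p_value, 2 / 2^6, tolerance = 1e-12)
  expect_equal(r$method, "signed_rank_exact")

  expect_equal(signed_rank_test(1:5, 1:5)$p_value, 1)
  expect_error(signed_rank_test(1:3, 1:4), "equal length")

  set.seed(303)
  for (i in 1:200) {
    n <- sample(4:9, 1)
    d <- sample(setdiff(-1000:1000, 0), n)
    while (anyDuplicated(abs(d))) d <- sample(setdiff(-1000:1000, 0), n)
    mine <- signed_rank_test(d, rep(0, n))
    expect_equal(mine$method, "signed_rank_exact")
    expect_equal(mine$p_value, oracle_signed_rank_p(d), tolerance = 1e-10)
  }
})

test_that("Cohen's d follows the pooled-SD formula and its symmetries", {
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), -2)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "zero")

  set.seed(404)
  for (i in 1:50) {
    x <- rnorm(sample(3:20, 1)); y <- rnorm(sample(3:20, 1), mean = 0.5)
    d <- cohens_d(x, y)
    expect_equal(d, oracle_cohens_d(x, y), tolerance = 1e-12)
    expect_equal(d, -cohens_d(y, x), tolerance = 1e-12)
    # invariance under common location/scale shift
    expect_equal(cohens_d(3 * x + 7, 3 * y + 7), d, tolerance = 1e-10)
  }
})

test_that("Spearman correlation uses mid-ranks and the t approximation", {
  expect_equal(spearman_corr(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_corr(1:10, -(1:10))$rho, -1)

  set.seed(505)
  for (i in 1:50) {
    n <- sample(5:25, 1)
    x <- sample(1:8, n, replace = TRUE)   # ties on purpose
    y <- sample(1:8, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    mine <- spearman_corr(x, y)
    expect_equal(mine$rho, oracle_spearman_rho(x, y), tolerance = 1e-12)
    # invariant under strictly monotone transforms
    expect_equal(spearman_corr(exp(x), y^3 + y)$rho, mine$rho, tolerance = 1e-12)
    # t approximation p agrees with cor.test
    if (abs(mine$rho) < 1) {
      ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
      expect_equal(mine$p_value, ct$p.value, tolerance = 1e-9)
    }
  }
  deg <- spearman_corr(rep(1, 5), 1:5)
  expect_equal(deg$method, "spearman_degenerate")
})

test_that("Bonferroni thresholds divide alpha by the family size", {
  expect_equal(bonferroni_threshold(0.05, 3), 0.0167)
  expect_equal(bonferroni_threshold(0.05, 5), 0.0100)
  expect_equal(bonferroni_threshold(0.05, 6), 0.0083)
  expect_equal(bonferroni_threshold(0.05, 4), 0.0125)
  expect_equal(bonferroni_threshold(0.05, 3, digits = NULL), 0.05 / 3)
  expect_error(bonferroni_threshold(0.05, 0), "positive")
})

test_that("OLS regression recovers exact and planted structure", {
  x <- tibble::tibble(x1 = seq(0, 5, length.out = 20))
  fit <- suppressWarnings(  # lm flags the intentionally perfect fit
    ols_regression(x, 2 * x$x1 + 1))
  expect_equal(unname(fit$coefficients["x1"]), 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # independent noise: R^2 near zero over seeds
  set.seed(606)
  r2 <- replicate(50, {
    xx <- tibble::tibble(a = rnorm(200), b = rnorm(200))
    ols_regression(xx, rnorm(200))$r_squared
  })
  expect_lt(mean(r2), 0.05)

  # planted coefficients recovered within their confidence intervals
  set.seed(607)
  xx <- tibble::tibble(a = rnorm(100), b = rnorm(100))
  yy <- 1.5 * xx$a - 2 * xx$b + 3 + rnorm(100, sd = 0.5)
  fit2 <- ols_regression(xx, yy)
  ci <- stats::confint(fit2$fit)
  expect_true(ci["a", 1] < 1.5 && 1.5 < ci["a", 2])
  expect_true(ci["b", 1] < -2 && -2 < ci["b", 2])

  # rank deficiency errors with the collinear column named
  xx$c <- xx$a + xx$b
  expect_error(ols_regression(xx, yy), "collinear.*c")
})

test_that("canonical correlation handles exact-dependence cases", {
  set.seed(707)
  z <- rnorm(40)
  cc <- canonical_correlation(tibble::tibble(x = z), tibble::tibble(y = z))
  expect_equal(cc$correlations[1], 1, tolerance = 1e-8)

  x <- tibble::tibble(a = rnorm(40), b = rnorm(40))
  yy <- tibble::tibble(y = 2 * x$a - x$b)
  cc2 <- canonical_correlation(x, yy)
  expect_equal(cc2$correlations[1], 1, tolerance = 1e-8)

  expect_error(canonical_correlation(tibble::tibble(a = rep(1, 20)),
                                     tibble::tibble(y = rnorm(20))),
               "constant|singular")
})

test_that("first canonical correlation matches direct maximization and cancor", {
  set.seed(808)
  for (i in 1:25) {
    n <- 200
    x <- tibble::tibble(a = rnorm(n), b = rnorm(n))
    y <- tibble::tibble(c = rnorm(n), d = rnorm(n))
    cc <- canonical_correlation(x, y)
    expect_equal(cc$correlations[1], oracle_cca_first(x, y), tolerance = 1e-6)
    base <- stats::cancor(scale(as.matrix(x)), scale(as.matrix(y)))
    expect_equal(cc$correlations, base$cor, tolerance = 1e-8)
  }
})

test_that("canonical correlation invariants hold", {
  set.seed(909)
  for (i in 1:10) {
    n <- 60
    x <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    y <- tibble::tibble(d = rnorm(n), e = rnorm(n))
    cc <- canonical_correlation(x, y)
    expect_true(all(diff(cc$correlations) <= 1e-12))
    expect_true(all(cc$correlations >= 0 & cc$correlations <= 1))
    expect_true(cc$p_value >= 0 && cc$p_value <= 1)
    # first correlation dominates any single-column Pearson r
    singles <- abs(stats::cor(as.matrix(x), as.matrix(y)))
    expect_gte(cc$correlations[1] + 1e-10, max(singles))
    # sign canonicalization: dominant y-coefficient positive
    for (j in seq_along(cc$correlations)) {
      expect_gte(cc$y_coefficients[which.max(abs(cc$y_coefficients[, j])), j], 0)
    }
  }
})

test_that("tidy and glance summarize fitted objects", {
  set.seed(31)
  x <- tibble::tibble(a = rnorm(30), b = rnorm(30))
  fit <- ols_regression(x, x$a + rnorm(30, sd = 0.1))
  td <- broom::tidy(fit)
  expect_setequal(td$term, c("(Intercept)", "a", "b"))
  gl <- broom::glance(fit)
  expect_equal(gl$r_squared, fit$r_squared)

  cc <- canonical_correlation(x, tibble::tibble(y = x$b + rnorm(30)))
  tdc <- broom::tidy(cc)
  expect_true(all(c("pair", "set", "variable", "coefficient") %in% names(tdc)))
  expect_equal(broom::glance(cc)$first_correlation, cc$correlations[1])
})

test_that("Gaussian Naive Bayes agreement behaves across separability regimes", {
  # perfect separation -> 100%
  expect_equal(nb_agreement(c(rep(0, 10), rep(10, 10)),
                            rep(c("no", "yes"), each = 10)), 100)
  # label-independent scores -> near 50% under leave-one-out
  set.seed(13)
  acc <- replicate(20, {
    s <- rnorm(200)
    l <- rep(c(0, 1), each = 100)
    nb_agreement(s, l)
  })
  expect_lt(abs(mean(acc) - 50), 5)
  expect_error(nb_agreement(1:5, rep(1, 5)), "two classes")

  # matches a hand-rolled class-conditional Gaussian oracle (resubstitution)
  set.seed(14)
  for (i in 1:20) {
    s <- c(rnorm(15, 0), rnorm(15, 1.5))
    l <- rep(c("a", "b"), each = 15)
    mine <- nb_agreement(s, l, protocol = "resubstitution")
    eps <- 1e-9 * var(s)
    post <- function(v) {
      la <- log(0.5) + dnorm(v, mean(s[1:15]), sqrt(var(s[1:15]) + eps), log = TRUE)
      lb <- log(0.5) + dnorm(v, mean(s[16:30]), sqrt(var(s[16:30]) + eps), log = TRUE)
      ifelse(la >= lb, "a", "b")
    }
    expect_equal(mine, 100 * mean(post(s) == l))
  }
})
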