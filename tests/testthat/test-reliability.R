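test_that("Cronbach's alpha matches the closed form on constructed fixtures", {
  # two items with unit variances and covariance 1/2: alpha = 2(1 - 2/3) = 2/3
  m <- two_item_fixture()
  expect_equal(stats::var(m[, 1]), 1, tolerance = 1e-12)
  expect_equal(stats::var(m[, 2]), 1, tolerance = 1e-12)
  expect_equal(stats::cov(m[, 1], m[, 2]), 0.5, tolerance = 1e-12)
  expect_equal(cronbach_alpha(m), 2 / 3, tolerance = 1e-9)

  # identical columns with nonzero variance: perfect consistency
  x <- c(1, 3, 2, 5, 4)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1, tolerance = 1e-12)

  # a 3-item fixture evaluated directly from the defining formula
  set.seed(42)
  m3 <- matrix(rnorm(60), 20, 3) + rnorm(20)
  expect_equal(cronbach_alpha(m3),
               3 / 2 * (1 - sum(apply(m3, 2, var)) / var(rowSums(m3))),
               tolerance = 1e-12)
})

test_that("alpha of independent items is near zero in expectation", {
  set.seed(7)
  alphas <- replicate(100,
    suppressWarnings(cronbach_alpha(matrix(rnorm(1000), 500, 2))))
  expect_lt(abs(mean(alphas)), 0.05)
})

test_that("alpha equals the standardized form when item variances are equal", {
  m <- two_item_fixture()
  rbar <- stats::cor(m[, 1], m[, 2])
  expect_equal(cronbach_alpha(m), 2 * rbar / (1 + rbar), tolerance = 1e-9)
  expect_equal(cronbach_alpha(m, standardized = TRUE), cronbach_alpha(m),
               tolerance = 1e-9)
})

test_that("alpha is invariant to item shifts and row permutation; negatives warn", {
  set.seed(11)
  m <- matrix(rnorm(80), 20, 4) + rnorm(20)
  shifted <- m; shifted[, 2] <- shifted[, 2] + 100
  expect_equal(cronbach_alpha(shifted), cronbach_alpha(m), tolerance = 1e-12)
  expect_equal(cronbach_alpha(m[sample(20), ]), cronbach_alpha(m), tolerance = 1e-12)
  neg <- cbind(c(1, 2, 3, 4), c(4, 3, 2, 1) * 2)
  expect_warning(a <- cronbach_alpha(neg), "negative")
  expect_lt(a, 0)
})

test_that("alpha-if-deleted equals direct recomputation on every submatrix", {
  g <- generate_cohort(sim_params(n = 80, seed = 13))
  m <- item_matrix(compute_icfi(g$cohort$feeding))
  aid <- alpha_if_deleted(m)
  expect_equal(nrow(aid), ncol(m))
  expect_equal(aid$item, colnames(m))
  for (j in seq_len(ncol(m)))
    expect_equal(aid$alpha_if_deleted[j],
                 cronbach_alpha(m[, -j, drop = FALSE]), tolerance = 1e-12)
  # deleting a duplicate of another column never lowers alpha arbitrarily:
  # compare against the brute-force recomputation on a 3-item fixture
  x <- c(1, 3, 2, 5, 4); y <- c(2, 1, 4, 3, 5)
  m3 <- cbind(a = x, b = x, c = y)
  aid3 <- alpha_if_deleted(m3)
  expect_equal(aid3$alpha_if_deleted[1], cronbach_alpha(cbind(x, y)), tolerance = 1e-12)
})

test_that("item-total correlations behave as Pearson r with/without correction", {
  # single dominant-variance item among constants: uncorrected r = 1
  m <- cbind(big = c(-10, 0, 10, 20), c1 = rep(1, 4), c2 = rep(2, 4))
  expect_warning(itc <- item_total_correlation(m), "zero variance")
  expect_equal(itc$r[1], 1, tolerance = 1e-12)
  expect_true(all(is.na(itc$r[2:3])))

  # corrected r of an item independent of the others is near zero
  set.seed(5)
  reps <- replicate(100, {
    q <- rnorm(300)
    m <- cbind(q + rnorm(300), q + rnorm(300), indep = rnorm(300))
    item_total_correlation(m, corrected = TRUE)$r[3]
  })
  expect_lt(abs(mean(reps)), 0.03)

  # uncorrected >= corrected on positively correlated items
  set.seed(6)
  for (i in 1:20) {
    q <- rnorm(100)
    m <- sapply(1:4, function(j) q + rnorm(100))
    u <- item_total_correlation(m, corrected = FALSE)$r
    c_ <- item_total_correlation(m, corrected = TRUE)$r
    expect_true(all(u >= c_))
  }
})

test_that("Feldt interval contains the estimate, shrinks with n, collapses at 1", {
  a <- 0.7
  widths <- sapply(c(30, 100, 300, 1000), function(n) {
    ci <- alpha_confidence_interval(a, n, 9)
    expect_lt(ci[["lower"]], a)
    expect_gt(ci[["upper"]], a)
    ci[["upper"]] - ci[["lower"]]
  })
  expect_true(all(diff(widths) < 0))
  ci1 <- alpha_confidence_interval(1, 100, 9)
  expect_equal(unname(ci1), c(1, 1))
  expect_error(alpha_confidence_interval(0.7, 5, 9), "degrees of freedom")
})

test_that("the reliability report recovers the generator's implied alpha", {
  p <- sim_params(n = 2000, seed = 17)
  g <- generate_cohort(p)
  rep_ <- reliability_report(score_cohort(g$cohort), by_band = TRUE)
  target <- implied_alpha(p, n_sim = 20000)
  expect_lt(abs(rep_$overall$alpha - target), 0.05)
  expect_true(rep_$overall$alpha_ci[["lower"]] <= rep_$overall$alpha)
  expect_true(rep_$overall$alpha_ci[["upper"]] >= rep_$overall$alpha)
  expect_equal(nrow(rep_$overall$per_item), 9)
  expect_equal(rep_$overall$per_item$item, icfikit:::icfi_item_order())
  # pooling equals by_band = FALSE
  rep2 <- reliability_report(score_cohort(g$cohort), by_band = FALSE)
  expect_equal(rep2$overall$alpha, rep_$overall$alpha)
  # a stratum too small to estimate is flagged, others survive
  few <- score_cohort(g$cohort)$scores
  few <- few[few$band != "band_6_8" | seq_len(nrow(few)) <= 2, ]
  rep3 <- reliability_report(few, by_band = TRUE)
  expect_false(is.null(rep3$band_6_8$error))
  expect_null(rep3$band_12_17$error)
})
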