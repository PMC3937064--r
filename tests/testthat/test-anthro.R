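test_that("the LMS transform has the median, L = 1 and L -> 0 behaviours", {
  # x = M maps to zero for any L, S
  for (L in c(-1, 0, 0.5, 1, 2))
    expect_equal(lms_zscore(8.5, L, 8.5, 0.11), 0)
  # L = 1 reduces to (x - M)/(S M)
  expect_equal(lms_zscore(9, 1, 8, 0.1), (9 - 8) / (0.1 * 8), tolerance = 1e-12)
  # continuity at L = 0
  expect_lt(abs(lms_zscore(9, 1e-6, 8, 0.1) - log(9 / 8) / 0.1), 1e-4)
  expect_error(lms_zscore(-1, 0.3, 8, 0.1), "x > 0")
})

test_that("lms_zscore is strictly increasing in the measurement", {
  x <- seq(3, 15, by = 0.1)
  for (L in c(-0.5, 0, 0.3, 1))
    expect_true(all(diff(lms_zscore(x, L, 8, 0.12)) > 0))
})

test_that("the inverse LMS transform round-trips to 1e-9", {
  set.seed(3)
  for (i in 1:50) {
    L <- runif(1, -1, 2); M <- runif(1, 3, 90); S <- runif(1, 0.02, 0.2)
    z <- runif(1, -4, 4)
    if (L != 0 && 1 + L * S * z <= 0) next
    x <- lms_inverse(z, L, M, S)
    expect_equal(lms_zscore(x, L, M, S), z, tolerance = 1e-9)
  }
})

test_that("LMS interpolation is linear between grid rows and errors off-span", {
  ref <- toy_lms_reference()
  # exact grid hit returns the row
  row <- ref$table[ref$table$sex == "male" & ref$table$measure == "wfa" &
                     ref$table$index == 10, ]
  p <- interpolate_lms(ref, "male", "wfa", 10)
  expect_equal(unname(p), unname(c(row$L, row$M, row$S)))
  # midpoint is the arithmetic mean of the neighbours
  r9 <- ref$table[ref$table$sex == "male" & ref$table$measure == "wfa" &
                    ref$table$index == 9, ]
  p2 <- interpolate_lms(ref, "male", "wfa", 9.5)
  expect_equal(p2[["M"]], (r9$M + row$M) / 2)
  # interpolated M lies between the neighbours on random grids
  set.seed(9)
  for (i in 1:20) {
    idx <- sort(runif(6, 0, 24))
    rg <- data.frame(sex = "male", measure = "wfa", index = idx,
                     L = 0.3, M = sort(runif(6, 3, 15)), S = 0.1)
    rr <- lms_reference(rg)
    at <- runif(1, min(idx), max(idx))
    lo <- max(which(idx <= at)); hi <- min(which(idx >= at))
    m <- interpolate_lms(rr, "male", "wfa", at)[["M"]]
    expect_gte(m, min(rg$M[lo], rg$M[hi]) - 1e-12)
    expect_lte(m, max(rg$M[lo], rg$M[hi]) + 1e-12)
  }
  expect_error(interpolate_lms(ref, "male", "wfa", 30), "span")
})

test_that("compute_zscores flags strictly below -2 and honours coverage", {
  ref <- toy_lms_reference()
  # a child sitting at the reference medians scores (0, 0, 0), no flags
  age <- 12
  m_w <- interpolate_lms(ref, "male", "wfa", age)[["M"]]
  m_l <- interpolate_lms(ref, "male", "lfa", age)[["M"]]
  an <- data.frame(child_id = "z0", sex = "male", age_months = age,
                   weight_kg = m_w, length_cm = m_l)
  # use the wfl median at that length so all three are defined medians
  p_wfl <- interpolate_lms(ref, "male", "wfl", m_l)
  an$weight_kg <- p_wfl[["M"]]  # wlz = 0; waz then nonzero unless consistent
  z <- compute_zscores(an, ref)
  expect_equal(z$wlz, 0, tolerance = 1e-12)
  an$weight_kg <- m_w
  z <- compute_zscores(an, ref)
  expect_equal(z$waz, 0, tolerance = 1e-12)
  expect_equal(z$laz, 0, tolerance = 1e-12)
  expect_false(any(z$underweight, z$stunted))

  # measurement constructed to sit at z = -2.5 is flagged
  p_l <- interpolate_lms(ref, "female", "lfa", 8)
  an2 <- data.frame(child_id = "z1", sex = "female", age_months = 8,
                    weight_kg = 7, length_cm = lms_inverse(-2.5, p_l[["L"]], p_l[["M"]], p_l[["S"]]))
  z2 <- compute_zscores(an2, ref)
  expect_equal(z2$laz, -2.5, tolerance = 1e-9)
  expect_true(z2$stunted)

  # z exactly -2.0 is not flagged (strict inequality); use L = 1 so the
  # boundary value is computed without power functions
  ref1 <- lms_reference(data.frame(sex = "male", measure = "wfa",
                                   index = c(0, 24), L = 1, M = 10, S = 0.1))
  an3 <- data.frame(child_id = "z2", sex = "male", age_months = 12,
                    weight_kg = 10 * (1 - 0.1 * 2), length_cm = 70)
  z3 <- compute_zscores(an3, ref1)
  expect_gte(z3$waz, -2)
  expect_false(z3$underweight)
  expect_true(is.na(z3$laz))  # no lfa table: out of coverage, flagged not dropped
  expect_true("z2" %in% attr(z3, "out_of_coverage"))

  # out-of-span ages yield NA rather than an error
  an4 <- data.frame(child_id = "z3", sex = "male", age_months = 40,
                    weight_kg = 12, length_cm = 80)
  z4 <- compute_zscores(an4, toy_lms_reference())
  expect_true(is.na(z4$waz))
})

test_that("prevalence summary counts strictly-below-minus-2 children", {
  z <- data.frame(child_id = as.character(1:10),
                  waz = rep(0, 10),
                  laz = c(rep(-2.5, 3), rep(0, 7)),
                  wlz = c(-2, rep(0, 9)),
                  underweight = FALSE,
                  stunted = c(rep(TRUE, 3), rep(FALSE, 7)),
                  wasted = FALSE)
  class(z) <- c("icfi_zscores", "data.frame")
  pv <- prevalence_summary(z)
  expect_equal(pv$prevalence_pct[pv$index == "stunting (LAZ)"], 30)
  expect_equal(pv$prevalence_pct[pv$index == "underweight (WAZ)"], 0)
  expect_equal(pv$prevalence_pct[pv$index == "wasting (WLZ)"], 0)  # -2 not below
  expect_equal(pv$mean_z[pv$index == "stunting (LAZ)"], mean(z$laz))
})
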