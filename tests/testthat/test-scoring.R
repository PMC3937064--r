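test_that("age bands are half-open and partition [6, 18)", {
  expect_equal(as.character(age_band(c(6, 8.99, 9, 11.99, 12, 17.9))),
               c("band_6_8", "band_6_8", "band_9_11", "band_9_11",
                 "band_12_17", "band_12_17"))
  expect_error(age_band(5.9), "6")
  expect_error(age_band(18), "18")
})

test_that("component scorers reproduce the published scoring system", {
  # breastfeeding: 2/0 in the younger bands, constant 1 in the oldest
  expect_equal(score_breastfeeding(TRUE, "band_6_8"), 2L)
  expect_equal(score_breastfeeding(FALSE, "band_9_11"), 0L)
  expect_equal(score_breastfeeding(TRUE, "band_12_17"), 1L)
  expect_equal(score_breastfeeding(FALSE, "band_12_17"), 1L)

  # bottle feeding: yes 0 / no 1, band-invariant
  expect_equal(score_bottle(TRUE), 0L)
  expect_equal(score_bottle(FALSE), 1L)

  # dietary diversity cutoffs per band
  expect_equal(score_dietary_diversity(1, "band_6_8"), 1L)
  expect_equal(score_dietary_diversity(2, "band_6_8"), 2L)
  expect_equal(score_dietary_diversity(2, "band_9_11"), 1L)
  expect_equal(score_dietary_diversity(3, "band_9_11"), 2L)
  expect_equal(score_dietary_diversity(1, "band_12_17"), 0L)
  expect_equal(score_dietary_diversity(3, "band_12_17"), 1L)
  expect_equal(score_dietary_diversity(4, "band_12_17"), 2L)

  # meal frequency, including the 0-3 range in the oldest band
  expect_equal(score_meal_frequency(0, "band_6_8"), 0L)
  expect_equal(score_meal_frequency(2, "band_9_11"), 1L)
  expect_equal(score_meal_frequency(3, "band_9_11"), 2L)
  expect_equal(score_meal_frequency(3, "band_12_17"), 2L)
  expect_equal(score_meal_frequency(4, "band_12_17"), 3L)
  expect_equal(score_meal_frequency(7, "band_6_8"), 2L)  # saturation

  # per-group 7-day rule: 0 / 1-3 / 4+
  expect_equal(seven_day_group_score(c(0, 1, 2, 3, 4, 5, 7)),
               c(0L, 1L, 1L, 1L, 2L, 2L, 2L))
  expect_error(seven_day_group_score(8), "0, 7")

  # band rescoring of the 0-14 sum
  expect_equal(score_seven_day(2, "band_6_8"), 1L)
  expect_equal(score_seven_day(3, "band_6_8"), 2L)
  expect_equal(score_seven_day(4, "band_9_11"), 1L)
  expect_equal(score_seven_day(5, "band_9_11"), 2L)
  expect_equal(score_seven_day(3, "band_12_17"), 0L)
  expect_equal(score_seven_day(6, "band_12_17"), 1L)
  expect_equal(score_seven_day(7, "band_12_17"), 2L)
})

test_that("dietary diversity count and 7-day sum behave as set cardinality / sums", {
  expect_equal(dietary_diversity_count(character(0)), 0L)
  expect_equal(dietary_diversity_count(c("grains", "milk")), 2L)
  expect_equal(dietary_diversity_count(food_groups_24h()), 8L)
  expect_error(dietary_diversity_count("pizza"), "unknown")

  d0 <- stats::setNames(rep(0, 7), food_groups_7d())
  expect_equal(seven_day_sum(d0), 0L)
  d_all <- stats::setNames(rep(5, 7), food_groups_7d())
  expect_equal(seven_day_sum(d_all), 14L)
  d_mix <- d0; d_mix[["grains_tubers"]] <- 7; d_mix[["milk"]] <- 2
  expect_equal(seven_day_sum(d_mix), 3L)  # 2 + 1, hand-summed
  expect_error(seven_day_sum(d0[-1]), "missing group")
})

test_that("compute_icfi totals match independent hand computation", {
  # maximal 7-month-old reaches the index ceiling of 13
  expect_equal(compute_icfi(maximal_row("m", 7))$total, 13L)
  # all-minimal responses hit the floor
  expect_equal(compute_icfi(minimal_row("m", 7))$total, 0L)
  # a mixed 13-month-old: 1+0+1+1+1+1+1+0+0 = 6
  rec <- feeding_row("x", 13, currently_breastfed = FALSE, bottle_fed_24h = TRUE,
                     fg24_count = 2, solid_feeds_24h = 2,
                     d7 = stats::setNames(c(4, 1, 1, 1, 1, 1, 0), food_groups_7d()),
                     wash_before_cooking = TRUE, wash_before_feeding = TRUE,
                     helped_to_eat = FALSE, refusal_response = "nothing")
  sc <- compute_icfi(rec)
  expect_equal(sc$d7_sum, 7L)  # 2 + five 1s
  expect_equal(sc$seven_day_ff, 2L)
  rec2 <- feeding_row("y", 13, currently_breastfed = FALSE, bottle_fed_24h = TRUE,
                      fg24_count = 2, solid_feeds_24h = 2,
                      d7 = stats::setNames(c(4, 1, 0, 0, 0, 0, 0), food_groups_7d()),
                      wash_before_cooking = TRUE, wash_before_feeding = TRUE,
                      helped_to_eat = FALSE, refusal_response = "nothing")
  sc2 <- compute_icfi(rec2)
  expect_equal(sc2$d7_sum, 3L)
  expect_equal(sc2$total, 1L + 0L + 1L + 1L + 0L + 1L + 1L + 0L + 0L)
})

test_that("exhaustive enumeration: bounds, additivity against component scorers", {
  # bounded response grid per the component domains; 7-day pattern encoded
  # as (groups on 2 days, groups on 5 days)
  d7_pat <- expand.grid(n2 = 0:7, n5 = 0:7)
  d7_pat <- d7_pat[d7_pat$n2 + d7_pat$n5 <= 7, ]
  grid <- expand.grid(bf = c(TRUE, FALSE), bot = c(TRUE, FALSE),
                      dd = 0:8, feeds = 0:5, pat = seq_len(nrow(d7_pat)),
                      bin = 0:15)
  ages <- c(band_6_8 = 7, band_9_11 = 10, band_12_17 = 14)
  for (b in names(ages)) {
    n <- nrow(grid)
    fd <- feeding_row("e", ages[[b]])[rep(1, n), ]
    fd$child_id <- paste0("e", seq_len(n))
    fd$currently_breastfed <- grid$bf
    fd$bottle_fed_24h <- grid$bot
    for (k in seq_along(food_groups_24h()))
      fd[[paste0("fg24_", food_groups_24h()[k])]] <- as.integer(k <= grid$dd)
    fd$solid_feeds_24h <- grid$feeds
    for (k in seq_along(food_groups_7d())) {
      n2 <- d7_pat$n2[grid$pat]; n5 <- d7_pat$n5[grid$pat]
      fd[[paste0("d7_", food_groups_7d()[k])]] <-
        ifelse(k <= n2, 2L, ifelse(k <= n2 + n5, 5L, 0L))
    }
    fd$wash_before_cooking <- bitwAnd(grid$bin, 1L) > 0
    fd$wash_before_feeding <- bitwAnd(grid$bin, 2L) > 0
    fd$helped_to_eat <- bitwAnd(grid$bin, 4L) > 0
    fd$refusal_response <- ifelse(bitwAnd(grid$bin, 8L) > 0, "other", "nothing")

    sc <- compute_icfi(fd)
    expect_true(all(sc$total >= 0 & sc$total <= 13))
    expect_equal(max(sc$total), 13L)
    expect_equal(min(sc$total), if (b == "band_12_17") 1L else 0L)

    # additivity: total equals the sum of independently invoked scorers;
    # per-group 7-day scores: 2 days -> 1, 5 days -> 2
    d7sum <- d7_pat$n2[grid$pat] * 1L + d7_pat$n5[grid$pat] * 2L
    indep <- score_breastfeeding(grid$bf, b) + score_bottle(grid$bot) +
      score_dietary_diversity(grid$dd, b) + score_meal_frequency(grid$feeds, b) +
      score_seven_day(d7sum, b) +
      as.integer(fd$wash_before_cooking) + as.integer(fd$wash_before_feeding) +
      as.integer(fd$helped_to_eat) + as.integer(fd$refusal_response == "other")
    expect_equal(sc$total, indep)
  }
})

test_that("every scorer is monotone in its raw response", {
  for (b in c("band_6_8", "band_9_11", "band_12_17")) {
    expect_true(all(diff(score_dietary_diversity(0:8, b)) >= 0))
    expect_true(all(diff(score_meal_frequency(0:10, b)) >= 0))
    expect_true(all(diff(score_seven_day(0:14, b)) >= 0))
    expect_gte(score_breastfeeding(TRUE, b), score_breastfeeding(FALSE, b))
  }
  expect_true(all(diff(seven_day_group_score(0:7)) >= 0))
  expect_gt(score_bottle(FALSE), score_bottle(TRUE))
})

test_that("fixed tertiles partition the 14 totals into three ordered categories", {
  lab <- classify_tertile(0:13)
  expect_equal(levels(lab), c("low", "medium", "high"))
  expect_equal(as.character(lab[c(1, 8, 9, 11, 12, 14)]),
               c("low", "low", "medium", "medium", "high", "high"))
  expect_equal(as.integer(table(lab)), c(8L, 3L, 3L))
  expect_error(classify_tertile(14), "0, 13")
})

test_that("empirical tertiles use linear-interpolation percentiles with ties to lower", {
  cp <- derive_empirical_tertiles(1:9)
  expect_gt(cp$low_max, 3); expect_lt(cp$low_max, 4)
  expect_gt(cp$medium_max, 6); expect_lt(cp$medium_max, 7)
  # permutation invariance
  cp2 <- derive_empirical_tertiles(sample(1:9))
  expect_equal(cp2$low_max, cp$low_max)
  expect_equal(cp2$medium_max, cp$medium_max)
  # degenerate: constant totals collapse to all-low with a warning
  expect_warning(cpd <- derive_empirical_tertiles(rep(5, 10)), "degenerate")
  expect_equal(as.character(classify_tertile(rep(5, 3), cpd)),
               rep("low", 3))
  expect_error(derive_empirical_tertiles(c(1, 2)), "at least 3")
  # a total exactly at a cutpoint goes to the lower category: with the
  # 7-point sample below the percentiles land exactly on 6 and 10
  cp3 <- derive_empirical_tertiles(c(2, 4, 6, 8, 10, 12, 13))
  expect_equal(cp3$low_max, 6)
  expect_equal(cp3$medium_max, 10)
  expect_equal(as.character(classify_tertile(c(6, 10, 12), cp3)),
               c("low", "medium", "high"))
})

test_that("score_cohort summary matches independent recomputation", {
  g <- generate_cohort(sim_params(n = 60, seed = 21))
  res <- score_cohort(g$cohort)
  sc <- res$scores
  expect_equal(nrow(sc), nrow(g$cohort$feeding))
  for (b in unique(sc$band)) {
    x <- sc$total[sc$band == b]
    row <- res$summary[res$summary$stratum == b, ]
    expect_equal(row$mean, mean(x))
    expect_equal(row$sd, stats::sd(x))
    half <- stats::qt(0.975, length(x) - 1) * stats::sd(x) / sqrt(length(x))
    expect_equal(row$ci_lower, mean(x) - half)
    expect_equal(row$ci_upper, mean(x) + half)
  }
  # single record: mean defined, CI flagged undefined
  one <- g$cohort
  one$feeding <- one$feeding[1, ]
  res1 <- score_cohort(one)
  ov <- res1$summary[res1$summary$stratum == "overall", ]
  expect_equal(ov$mean, res1$scores$total[1])
  expect_true(is.na(ov$ci_lower))
  # identical records: SD 0
  dup <- g$cohort
  dup$feeding <- dup$feeding[rep(1, 5), ]
  dup$feeding$child_id <- paste0("d", 1:5)
  expect_equal(score_cohort(dup)$summary$sd[
    score_cohort(dup)$summary$stratum == "overall"], 0)
})

test_that("a custom scoring table loads from YAML and is validated", {
  tab <- default_scoring_table()
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    seven_day_group_cuts = c(1, 4),
    band_6_8 = list(breastfeeding = list(yes = 2, no = 0),
                    dietary_diversity = c(1, 2), meal_frequency = c(1, 2),
                    seven_day = c(1, 3)),
    band_9_11 = list(breastfeeding = list(yes = 2, no = 0),
                     dietary_diversity = c(1, 3), meal_frequency = c(1, 3),
                     seven_day = c(2, 5)),
    band_12_17 = list(breastfeeding = list(yes = 1, no = 1),
                      dietary_diversity = c(2, 4), meal_frequency = c(2, 3, 4),
                      seven_day = c(4, 7))), path)
  tab2 <- read_scoring_table(path)
  expect_equal(tab2$band_12_17$meal_frequency, tab$band_12_17$meal_frequency)
  # a table whose maxima do not sum to 13 is refused unless overridden
  bad <- yaml::read_yaml(path)
  bad$band_6_8$seven_day <- c(1, 3, 5)
  path2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(bad, path2)
  expect_error(read_scoring_table(path2), "expected 13")
  expect_s3_class(read_scoring_table(path2, allow_custom_total = TRUE),
                  "icfi_scoring_table")
})
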