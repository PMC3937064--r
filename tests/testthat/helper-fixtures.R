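# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# one feeding row in the cohort column layout
feeding_row <- function(child_id = "c1", age_months = 7,
                        currently_breastfed = TRUE, bottle_fed_24h = FALSE,
                        fg24_count = 2, solid_feeds_24h = 2,
                        d7 = c(grains_tubers = 7, milk = 2, vita_fruit_veg = 0,
                               other_fruit_veg = 0, animal_source = 0,
                               legumes = 0, fats = 0),
                        wash_before_cooking = TRUE, wash_before_feeding = TRUE,
                        helped_to_eat = TRUE, refusal_response = "other") {
  row <- data.frame(child_id = child_id, age_months = age_months,
                    currently_breastfed = currently_breastfed,
                    bottle_fed_24h = bottle_fed_24h,
                    solid_feeds_24h = solid_feeds_24h,
                    wash_before_cooking = wash_before_cooking,
                    wash_before_feeding = wash_before_feeding,
                    helped_to_eat = helped_to_eat,
                    refusal_response = refusal_response,
                    stringsAsFactors = FALSE)
  groups <- food_groups_24h()
  for (i in seq_along(groups))
    row[[paste0("fg24_", groups[i])]] <- as.integer(i <= fg24_count)
  for (g in food_groups_7d())
    row[[paste0("d7_", g)]] <- as.integer(d7[[g]])
  row[, icfikit:::cohort_feeding_cols()]
}

# minimal/maximal responses for a given age
minimal_row <- function(child_id, age) {
  feeding_row(child_id, age, currently_breastfed = FALSE, bottle_fed_24h = TRUE,
              fg24_count = 0, solid_feeds_24h = 0,
              d7 = stats::setNames(rep(0, 7), food_groups_7d()),
              wash_before_cooking = FALSE, wash_before_feeding = FALSE,
              helped_to_eat = FALSE, refusal_response = "nothing")
}

maximal_row <- function(child_id, age) {
  feeding_row(child_id, age, currently_breastfed = TRUE, bottle_fed_24h = FALSE,
              fg24_count = 8, solid_feeds_24h = 7,
              d7 = stats::setNames(rep(7, 7), food_groups_7d()),
              wash_before_cooking = TRUE, wash_before_feeding = TRUE,
              helped_to_eat = TRUE, refusal_response = "other")
}

# a small LMS reference on a coarse grid, consistent across measures is not
# needed for unit tests of the transform itself
toy_lms_reference <- function() {
  grid <- expand.grid(sex = c("male", "female"),
                      measure = c("wfa", "lfa", "wfl"),
                      stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    idx <- if (grid$measure[i] == "wfl") seq(45, 110, by = 5) else 0:24
    M0 <- switch(grid$measure[i], wfa = 3 + 0.5 * idx,
                 lfa = 50 + 1.5 * idx, wfl = 2 + 0.1 * idx)
    data.frame(sex = grid$sex[i], measure = grid$measure[i], index = idx,
               L = 0.5, M = M0 * ifelse(grid$sex[i] == "female", 0.96, 1),
               S = 0.1, stringsAsFactors = FALSE)
  }))
  lms_reference(rows, name = "toy")
}

# two-column item fixture with unit sample variances and covariance 1/2
# (constructed from orthogonal unit-variance contrasts), so Cronbach's
# alpha has the closed-form value 2/3
two_item_fixture <- function() {
  a <- c(1, 0, -1)
  c_ <- c(1, -2, 1) / sqrt(3)
  b <- 0.5 * a + sqrt(0.75) * c_
  cbind(x1 = a, x2 = b)
}
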