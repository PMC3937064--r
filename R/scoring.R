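#' @title CS-ICFI component scoring
#' @description Age-band assignment and the nine component scorers of the
#'   cross-sectional infant and child feeding index, plus aggregation to the
#'   0-13 total and tertile classification.
#' @name icfi-scoring
NULL

#' Canonical 24-hour food groups (eight) and 7-day food groups (seven)
#'
#' The 24-h dietary diversity recall distinguishes grains and roots/tubers;
#' the 7-day food-group frequency combines them into one group, giving seven
#' groups.
#'
#' @return Character vector of canonical group labels.
#' @export
food_groups_24h <- function() {
  c("grains", "tubers", "milk", "vita_fruit_veg", "other_fruit_veg",
    "animal_source", "legumes", "fats")
}

#' @rdname food_groups_24h
#' @export
food_groups_7d <- function() {
  c("grains_tubers", "milk", "vita_fruit_veg", "other_fruit_veg",
    "animal_source", "legumes", "fats")
}

# Fixed item order of the nine-column item matrix used by the reliability
# module (matches the component listing of the index's item analysis).
icfi_item_order <- function() {
  c("meal_frequency", "dietary_diversity", "seven_day_ff",
    "refusal_response", "helped_to_eat", "bottle",
    "wash_cooking", "wash_feeding", "breastfeeding")
}

#' Assign the CS-ICFI age band
#'
#' Ages are partitioned into half-open bands [6,9), [9,12) and [12,18)
#' months, so a child of exactly 9.0 months falls in the 9-11-month band.
#'
#' @param age_months Numeric vector of ages in months, each in [6, 18).
#' @return Factor with levels `band_6_8`, `band_9_11`, `band_12_17`.
#' @export
#' @examples
#' age_band(c(6, 8.9, 9, 11.99, 12, 17.9))
age_band <- function(age_months) {
  if (any(is.na(age_months)) || any(age_months < 6 | age_months >= 18))
    stop("age_months must be in [6, 18)")
  cut(age_months, breaks = c(6, 9, 12, 18), right = FALSE,
      labels = c("band_6_8", "band_9_11", "band_12_17"))
}

band_levels <- function() c("band_6_8", "band_9_11", "band_12_17")

as_band <- function(band) {
  if (is.factor(band)) band <- as.character(band)
  if (!all(band %in% band_levels())) stop("unknown age band: ",
                                          paste(setdiff(band, band_levels()), collapse = ", "))
  band
}

#' Score current breastfeeding
#'
#' In the 6-8 and 9-11-month bands continued breastfeeding scores 2 and its
#' absence 0; in the 12-17-month band both responses score 1 (the component
#' is constant there, reflecting the weaker feeding recommendation at that
#' age for this population).
#'
#' @param currently_breastfed Logical vector.
#' @param band Age band (character or factor, recycled against the first
#'   argument).
#' @param table Scoring table, see [default_scoring_table()].
#' @return Integer vector of scores.
#' @export
score_breastfeeding <- function(currently_breastfed, band,
                                table = default_scoring_table()) {
  band <- as_band(band)
  n <- max(length(currently_breastfed), length(band))
  currently_breastfed <- rep_len(currently_breastfed, n)
  band <- rep_len(band, n)
  vapply(seq_len(n), function(i) {
    bf <- table[[band[i]]]$breastfeeding
    unname(bf[if (isTRUE(currently_breastfed[i])) "yes" else "no"])
  }, integer(1))
}

#' Score bottle feeding (24-hour recall)
#'
#' Bottle use in the previous 24 hours scores 0, its absence 1, identically
#' in every age band.
#'
#' @param bottle_fed_24h Logical vector.
#' @return Integer vector of 0/1 scores.
#' @export
score_bottle <- function(bottle_fed_24h) {
  as.integer(!bottle_fed_24h)
}

#' 24-hour dietary diversity count
#'
#' Number of distinct food groups (of the eight in [food_groups_24h()])
#' received in the previous 24 hours.
#'
#' @param food_groups_24h A character vector of group labels (single child),
#'   or a logical/0-1 matrix or data frame with one column per group (one
#'   row per child).
#' @return Integer count(s) in [0, 8].
#' @export
dietary_diversity_count <- function(food_groups_24h) {
  if (is.character(food_groups_24h)) {
    bad <- setdiff(food_groups_24h, food_groups_24h())
    if (length(bad)) stop("unknown 24-h food group: ", paste(bad, collapse = ", "))
    return(length(unique(food_groups_24h)))
  }
  m <- as.matrix(as.data.frame(food_groups_24h))
  as.integer(rowSums(m > 0))
}

#' Score 24-hour dietary diversity
#'
#' Applies the age-band-specific cutoffs to a food-group count: in the
#' 6-8-month band one group scores 1 and two or more score 2; in the
#' 9-11-month band one or two groups score 1 and three or more score 2; in
#' the 12-17-month band two or three groups score 1 and four or more score 2.
#'
#' @param count Integer vector of food-group counts in [0, 8].
#' @inheritParams score_breastfeeding
#' @return Integer vector of 0/1/2 scores.
#' @export
score_dietary_diversity <- function(count, band, table = default_scoring_table()) {
  if (any(count < 0 | count > 8)) stop("dietary diversity count must be in [0, 8]")
  band <- as_band(band)
  n <- max(length(count), length(band))
  count <- rep_len(count, n); band <- rep_len(band, n)
  vapply(seq_len(n), function(i)
    score_from_cuts(count[i], table[[band[i]]]$dietary_diversity), integer(1))
}

#' Score 24-hour solid/semi-solid meal frequency
#'
#' Feeds above the band's highest listed threshold saturate at the top score
#' (2 in the 6-8 and 9-11-month bands, 3 in the 12-17-month band).
#'
#' @param solid_feeds_24h Non-negative integer vector of feeds.
#' @inheritParams score_breastfeeding
#' @return Integer vector of scores.
#' @export
score_meal_frequency <- function(solid_feeds_24h, band,
                                 table = default_scoring_table()) {
  if (any(solid_feeds_24h < 0)) stop("solid_feeds_24h must be non-negative")
  band <- as_band(band)
  n <- max(length(solid_feeds_24h), length(band))
  solid_feeds_24h <- rep_len(solid_feeds_24h, n); band <- rep_len(band, n)
  vapply(seq_len(n), function(i)
    score_from_cuts(solid_feeds_24h[i], table[[band[i]]]$meal_frequency), integer(1))
}

#' Per-food-group 7-day frequency score
#'
#' A food group given on no day in the previous week scores 0, on one to
#' three days 1, and on four or more days 2 — the same rule for every group
#' and band.
#'
#' @param days Integer vector of day counts in [0, 7].
#' @param table Scoring table.
#' @return Integer vector of 0/1/2 scores.
#' @export
seven_day_group_score <- function(days, table = default_scoring_table()) {
  if (any(days < 0 | days > 7)) stop("7-day day count must be in [0, 7]")
  score_from_cuts(days, table$seven_day_group_cuts)
}

#' Summed 7-day food-group frequency
#'
#' Sums the per-group 0/1/2 scores over the seven combined food groups,
#' giving a total in [0, 14].
#'
#' @param seven_day_days A named numeric vector / list mapping every group in
#'   [food_groups_7d()] to a day count (single child), or a matrix/data frame
#'   with one column per group.
#' @param table Scoring table.
#' @return Integer sum(s) in [0, 14].
#' @export
seven_day_sum <- function(seven_day_days, table = default_scoring_table()) {
  groups <- food_groups_7d()
  if (is.matrix(seven_day_days) || is.data.frame(seven_day_days)) {
    m <- as.matrix(as.data.frame(seven_day_days))
    if (!all(groups %in% colnames(m)))
      stop("seven_day_days missing group(s): ",
           paste(setdiff(groups, colnames(m)), collapse = ", "))
    m <- m[, groups, drop = FALSE]
    sc <- sapply(groups, function(g) seven_day_group_score(m[, g], table = table))
    if (is.null(dim(sc))) sc <- matrix(sc, nrow = nrow(m))
    return(as.integer(rowSums(sc)))
  }
  v <- unlist(seven_day_days)
  if (!all(groups %in% names(v)))
    stop("seven_day_days missing group(s): ",
         paste(setdiff(groups, names(v)), collapse = ", "))
  sum(seven_day_group_score(v[groups], table = table))
}

#' Score the summed 7-day food-group frequency
#'
#' Rescores the 0-14 sum to 0/1/2 with age-band-specific cutoffs: 6-8
#' months, 1-2 scores 1 and 3+ scores 2; 9-11 months, 2-4 scores 1 and 5+
#' scores 2; 12-17 months, 4-6 scores 1 and 7+ scores 2.
#'
#' @param sum Integer vector in [0, 14].
#' @inheritParams score_breastfeeding
#' @return Integer vector of 0/1/2 scores.
#' @export
score_seven_day <- function(sum, band, table = default_scoring_table()) {
  if (any(sum < 0 | sum > 14)) stop("7-day frequency sum must be in [0, 14]")
  band <- as_band(band)
  n <- max(length(sum), length(band))
  sum <- rep_len(sum, n); band <- rep_len(band, n)
  vapply(seq_len(n), function(i)
    score_from_cuts(sum[i], table[[band[i]]]$seven_day), integer(1))
}

#' Score the hygiene and psychosocial binary items
#'
#' Hand washing before cooking, hand washing before feeding and helping the
#' child to eat each score 1 for yes / 0 for no; the caregiver's response to
#' food refusal scores 0 if the child is left alone ("nothing") and 1 for
#' any active response ("other").
#'
#' @param wash_before_cooking,wash_before_feeding,helped_to_eat Logical
#'   vectors.
#' @param refusal_response Character vector with values `"nothing"` or
#'   `"other"`.
#' @return A data frame with integer columns `wash_cooking`, `wash_feeding`,
#'   `helped_to_eat`, `refusal_response`.
#' @export
score_binary_items <- function(wash_before_cooking, wash_before_feeding,
                               helped_to_eat, refusal_response) {
  rr <- tolower(as.character(refusal_response))
  if (!all(rr %in% c("nothing", "other")))
    stop("refusal_response must be 'nothing' or 'other'")
  data.frame(
    wash_cooking = as.integer(wash_before_cooking),
    wash_feeding = as.integer(wash_before_feeding),
    helped_to_eat = as.integer(helped_to_eat),
    refusal_response = as.integer(rr == "other")
  )
}

#' Compute the CS-ICFI for feeding records
#'
#' Applies all nine component scorers to one or more feeding records and
#' sums them into the 0-13 index total. Accepts either a single record as a
#' list (with `seven_day_days` a named vector and `food_groups_24h` a
#' character vector of group labels) or a feeding data frame in the cohort
#' column layout (see [read_cohort()]).
#'
#' @param record A single-record list or a feeding data frame.
#' @param table Scoring table.
#' @return A data frame of class `icfi_scores` with one row per child:
#'   `child_id`, `band`, the nine component scores (columns named as in the
#'   item matrix: `breastfeeding`, `bottle`, `dietary_diversity`,
#'   `meal_frequency`, `seven_day_ff`, `wash_cooking`, `wash_feeding`,
#'   `helped_to_eat`, `refusal_response`) and `total`.
#' @export
#' @examples
#' rec <- list(child_id = "c1", age_months = 7, currently_breastfed = TRUE,
#'             bottle_fed_24h = FALSE,
#'             food_groups_24h = c("grains", "milk"),
#'             solid_feeds_24h = 2,
#'             seven_day_days = c(grains_tubers = 7, milk = 2,
#'               vita_fruit_veg = 0, other_fruit_veg = 0, animal_source = 0,
#'               legumes = 0, fats = 0),
#'             wash_before_cooking = TRUE, wash_before_feeding = TRUE,
#'             helped_to_eat = TRUE, refusal_response = "other")
#' compute_icfi(rec)$total
compute_icfi <- function(record, table = default_scoring_table()) {
  df <- if (is.data.frame(record)) record else feeding_record_to_row(record)
  band <- as.character(age_band(df$age_months))
  dd_cols <- paste0("fg24_", food_groups_24h())
  d7_cols <- paste0("d7_", food_groups_7d())
  dd_count <- as.integer(rowSums(df[, dd_cols, drop = FALSE] > 0))
  d7 <- df[, d7_cols, drop = FALSE]
  colnames(d7) <- food_groups_7d()
  d7_sum <- seven_day_sum(d7, table = table)
  bin <- score_binary_items(df$wash_before_cooking, df$wash_before_feeding,
                            df$helped_to_eat, df$refusal_response)
  out <- data.frame(
    child_id = df$child_id,
    band = band,
    breastfeeding = score_breastfeeding(df$currently_breastfed, band, table),
    bottle = score_bottle(df$bottle_fed_24h),
    dietary_diversity = score_dietary_diversity(dd_count, band, table),
    meal_frequency = score_meal_frequency(df$solid_feeds_24h, band, table),
    seven_day_ff = score_seven_day(d7_sum, band, table),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, bin)
  out$dd_count <- dd_count
  out$d7_sum <- d7_sum
  out$total <- out$breastfeeding + out$bottle + out$dietary_diversity +
    out$meal_frequency + out$seven_day_ff + out$wash_cooking +
    out$wash_feeding + out$helped_to_eat + out$refusal_response
  class(out) <- c("icfi_scores", "data.frame")
  out
}

# single-record list -> one-row data frame in cohort column layout
feeding_record_to_row <- function(rec) {
  row <- data.frame(child_id = as.character(rec$child_id),
                    age_months = rec$age_months,
                    currently_breastfed = rec$currently_breastfed,
                    bottle_fed_24h = rec$bottle_fed_24h,
                    solid_feeds_24h = rec$solid_feeds_24h,
                    wash_before_cooking = rec$wash_before_cooking,
                    wash_before_feeding = rec$wash_before_feeding,
                    helped_to_eat = rec$helped_to_eat,
                    refusal_response = rec$refusal_response,
                    stringsAsFactors = FALSE)
  for (g in food_groups_24h())
    row[[paste0("fg24_", g)]] <- as.integer(g %in% rec$food_groups_24h)
  d7 <- unlist(rec$seven_day_days)
  for (g in food_groups_7d())
    row[[paste0("d7_", g)]] <- as.integer(d7[[g]])
  row
}

#' Tertile cutpoints for the CS-ICFI
#'
#' The study's fixed categorization assigns totals 0-7 to the low, 8-10 to
#' the medium and 11-13 to the high tertile. `tertile_cutpoints()` builds a
#' cutpoint object; [derive_empirical_tertiles()] estimates cutpoints from
#' observed totals instead.
#'
#' @param low_max Largest total classified low.
#' @param medium_max Largest total classified medium.
#' @param basis `"fixed"` for the canonical 7/10 cutpoints, `"empirical"`
#'   for data-derived ones.
#' @return A list of class `icfi_cutpoints`.
#' @export
tertile_cutpoints <- function(low_max = 7, medium_max = 10, basis = "fixed") {
  if (!low_max < medium_max) stop("low_max must be below medium_max")
  structure(list(low_max = low_max, medium_max = medium_max, basis = basis),
            class = "icfi_cutpoints")
}

#' Classify CS-ICFI totals into tertiles
#'
#' With the fixed cutpoints, totals of 0-7 are low, 8-10 medium and 11-13
#' high. With empirical cutpoints, a total equal to a cutpoint is assigned
#' to the lower category.
#'
#' @param total Integer vector of index totals in [0, 13].
#' @param cutpoints An `icfi_cutpoints` object.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
classify_tertile <- function(total, cutpoints = tertile_cutpoints()) {
  if (any(total < 0 | total > 13)) stop("CS-ICFI total must be in [0, 13]")
  factor(ifelse(total <= cutpoints$low_max, "low",
                ifelse(total <= cutpoints$medium_max, "medium", "high")),
         levels = c("low", "medium", "high"))
}

#' Derive empirical tertile cutpoints from observed totals
#'
#' Cutpoints are the 33 1/3 and 66 2/3 percentiles of the observed totals,
#' computed with the linear-interpolation quantile definition
#' (`stats::quantile`, type 7). Classification with the resulting cutpoints
#' assigns a total lying exactly on a cutpoint to the lower category. With
#' `by_band = TRUE` one cutpoint pair is estimated per age band, reflecting
#' the age-specific index distribution.
#'
#' @param totals Integer vector of index totals.
#' @param by_band If `TRUE`, `band` must be given and cutpoints are
#'   estimated per band.
#' @param band Optional band vector parallel to `totals`.
#' @return An `icfi_cutpoints` object, or a named list of them (one per
#'   band) when `by_band = TRUE`.
#' @export
derive_empirical_tertiles <- function(totals, by_band = FALSE, band = NULL) {
  one <- function(x) {
    if (length(x) < 3) stop("need at least 3 observations to derive tertiles")
    q <- stats::quantile(x, probs = c(1, 2) / 3, names = FALSE, type = 7)
    if (q[1] == q[2]) {
      warning("degenerate tertile cutpoints: observed totals nearly constant")
      # keep an orderable pair; everything at/below q[1] is low
      q[2] <- q[1] + .Machine$double.eps * max(1, abs(q[1]))
    }
    tertile_cutpoints(low_max = q[1], medium_max = q[2], basis = "empirical")
  }
  if (!by_band) return(one(totals))
  if (is.null(band)) stop("by_band = TRUE requires a band vector")
  band <- as_band(band)
  lapply(split(totals, factor(band, levels = band_levels())), one)
}

#' Score a cohort and summarize the index by age band
#'
#' Computes component scores, totals and tertile labels for every accepted
#' feeding record of a cohort, and a band-wise summary of the total (n,
#' mean, SD, 95% t-based confidence interval).
#'
#' @param cohort An `icfi_cohort` (see [read_cohort()]).
#' @param tertiles `"fixed"` for the canonical 0-7/8-10/11-13 cutpoints or
#'   `"empirical"` for band-specific data-derived cutpoints.
#' @param table Scoring table.
#' @param conf_level Confidence level for the band-wise mean CI.
#' @return A list of class `icfi_cohort_scores` with elements `scores` (the
#'   per-child `icfi_scores` data frame plus a `tertile` column), `summary`
#'   (per-band and overall rows: n, mean, sd, ci_lower, ci_upper) and
#'   `cutpoints`.
#' @export
score_cohort <- function(cohort, tertiles = c("fixed", "empirical"),
                         table = default_scoring_table(), conf_level = 0.95) {
  tertiles <- match.arg(tertiles)
  stopifnot(inherits(cohort, "icfi_cohort"))
  if (nrow(cohort$feeding) == 0) stop("cohort has no accepted feeding records")
  sc <- compute_icfi(cohort$feeding, table = table)
  if (tertiles == "fixed") {
    cp <- tertile_cutpoints()
    sc$tertile <- classify_tertile(sc$total, cp)
  } else {
    cp <- derive_empirical_tertiles(sc$total, by_band = TRUE, band = sc$band)
    sc$tertile <- factor(NA_character_, levels = c("low", "medium", "high"))
    for (b in band_levels()) {
      i <- sc$band == b
      if (any(i)) sc$tertile[i] <- classify_tertile(sc$total[i], cp[[b]])
    }
  }
  summ_one <- function(x, label) {
    n <- length(x); m <- mean(x); s <- stats::sd(x)
    half <- if (n > 1) stats::qt(1 - (1 - conf_level) / 2, n - 1) * s / sqrt(n) else NA_real_
    data.frame(stratum = label, n = n, mean = m, sd = s,
               ci_lower = m - half, ci_upper = m + half,
               stringsAsFactors = FALSE)
  }
  summ <- do.call(rbind, c(
    lapply(band_levels(), function(b) {
      x <- sc$total[sc$band == b]
      if (length(x)) summ_one(x, b) else NULL
    }),
    list(summ_one(sc$total, "overall"))
  ))
  rownames(summ) <- NULL
  structure(list(scores = sc, summary = summ, cutpoints = cp),
            class = "icfi_cohort_scores")
}

#' @export
print.icfi_cohort_scores <- function(x, ...) {
  cat("CS-ICFI cohort scores:", nrow(x$scores), "children\n")
  cat("Tertile basis:",
      if (inherits(x$cutpoints, "icfi_cutpoints")) x$cutpoints$basis else "empirical (per band)", "\n")
  print(x$summary, row.names = FALSE, digits = 4)
  tt <- table(x$scores$tertile)
  cat("Tertiles: low", tt[["low"]], "| medium", tt[["medium"]],
      "| high", tt[["high"]], "\n")
  invisible(x)
}
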