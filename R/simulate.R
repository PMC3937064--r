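#' @title Synthetic cohort generator
#' @description Generates survey cohorts with the statistical structure the
#'   index analysis assumes — a single latent feeding-quality factor
#'   inducing inter-item correlation (so Cronbach's alpha has a known
#'   implied value), age-dependent breastfeeding, an urban shift of the
#'   latent factor, and specified standardized effects of the index on LAZ
#'   and WAZ — so every pipeline stage is testable against known ground
#'   truth without external data.
#' @name icfi-simulate
NULL

#' Simulation parameters for the synthetic cohort generator
#'
#' Returns the full parameterization of [generate_cohort()], with defaults
#' calibrated to the study conditions this generator emulates: cohort size
#' 184; 72.8% urban; 57.6% male; breastfeeding prevalence declining across
#' the three age bands; single-factor item loadings tuned so the implied
#' Cronbach's alpha of the nine scored items is about 0.70; standardized
#' index effects of 0.183 on LAZ and 0.168 on WAZ and a null WLZ effect;
#' income (+0.199) and pre-lacteal feeding (-0.162) effects on LAZ; and
#' mean z-scores of -0.86 (LAZ), -0.72 (WAZ), -0.19 (WLZ). Any component
#' can be overridden through `...`.
#'
#' @param n Cohort size.
#' @param seed Integer seed; all randomness flows from it through one
#'   generator stream in a documented draw order.
#' @param ... Overrides for any default parameter (unknown names are an
#'   error).
#' @return A list of class `icfi_sim_params`.
#' @export
sim_params <- function(n = 184, seed = 1, ...) {
  p <- list(
    n = n, seed = seed,
    # demographics / covariates
    age_weights = stats::setNames(rep(1, 12), as.character(6:17)),
    p_urban = 0.728, p_male = 0.576,
    income_meanlog = log(1000), income_sdlog = 0.6,
    p_pre_lacteal = 0.15, p_diarrhea = 0.20,
    age_cf_mean = 5.5, age_cf_sd = 1.5, p_married = 0.845,
    # latent feeding-quality factor
    urban_shift = 0.40,
    age_trend = 0.7,
    breastfeeding_curve = c(band_6_8 = 0.95, band_9_11 = 0.85, band_12_17 = 0.70),
    latent_loading = c(meal_frequency = 1.1, dietary_diversity = 1.6,
                       seven_day_ff = 1.4, refusal_response = 1.2,
                       helped_to_eat = 1.2, bottle = 0.3,
                       wash_cooking = 1.3, wash_feeding = 1.3,
                       breastfeeding = -0.2),
    item_marginals = list(
      bottle = 0.25,
      fg24 = c(grains = 0.85, tubers = 0.45, milk = 0.55, vita_fruit_veg = 0.35,
               other_fruit_veg = 0.30, animal_source = 0.30, legumes = 0.40,
               fats = 0.30),
      mean_feeds = 3.0,
      d7 = c(grains_tubers = 0.80, milk = 0.55, vita_fruit_veg = 0.28,
             other_fruit_veg = 0.22, animal_source = 0.22, legumes = 0.32,
             fats = 0.27),
      wash_cooking = 0.62, wash_feeding = 0.58, helped_to_eat = 0.72,
      refusal_other = 0.68),
    # outcome model (standardized effects on z-scored predictors)
    effect_laz = 0.183, effect_waz = 0.168, effect_wlz = 0,
    covariate_effects = c(income = 0.199, pre_lacteal = -0.162,
                          age_at_cf = -0.062, married = 0.054,
                          diarrhea = -0.15),
    interaction_terms = NULL,
    noise_sd = 0.94,
    laz_mean = -0.86, waz_mean = -0.72, wlz_mean = -0.19,
    round_measurements = FALSE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown simulation parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  validate_sim_params(structure(p, class = "icfi_sim_params"))
}

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "icfi_sim_params"))
  probs <- c(p$p_urban, p$p_male, p$p_pre_lacteal, p$p_diarrhea, p$p_married,
             p$breastfeeding_curve, p$item_marginals$bottle, p$item_marginals$fg24,
             p$item_marginals$d7, p$item_marginals$wash_cooking,
             p$item_marginals$wash_feeding, p$item_marginals$helped_to_eat,
             p$item_marginals$refusal_other)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0, 1]")
  if (p$n < 1) stop("n must be at least 1")
  if (p$noise_sd <= 0) stop("noise_sd must be positive")
  if (p$item_marginals$mean_feeds <= 0) stop("mean_feeds must be positive")
  if (!all(icfi_item_order() %in% names(p$latent_loading)))
    stop("latent_loading must name all nine items")
  if (any(p$age_weights < 0) || sum(p$age_weights) == 0)
    stop("age_weights must be non-negative and not all zero")
  p
}

# Per-child success probabilities for a binary item: logit link tilted by
# loading * latent factor, with the intercept solved so that the average
# probability over the realized factor values equals the target marginal —
# tilting therefore changes the dependence structure, not the base rates.
tilt_calibrated <- function(p_target, loading, q) {
  if (p_target <= 0 || p_target >= 1 || loading == 0)
    return(rep(p_target, length(q)))
  a <- stats::uniroot(function(a) mean(stats::plogis(a + loading * q)) - p_target,
                      c(-25, 25), tol = 1e-10)$root
  stats::plogis(a + loading * q)
}

# Draw the feeding items for n children with latent factor q, in the fixed,
# documented order: breastfeeding, bottle, the eight 24-h food groups, the
# solid-feed count, the seven 7-day day counts, then the four binaries.
draw_feeding_items <- function(p, age, band, q) {
  n <- length(q)
  lam <- p$latent_loading
  mg <- p$item_marginals
  # breastfeeding marginal is age-band-specific; calibrate within band
  p_bf <- numeric(n)
  for (b in unique(band)) {
    i <- band == b
    p_bf[i] <- tilt_calibrated(unname(p$breastfeeding_curve[b]),
                               lam[["breastfeeding"]], q[i])
  }
  fd <- data.frame(
    age_months = age,
    currently_breastfed = stats::rbinom(n, 1, p_bf) == 1,
    bottle_fed_24h = stats::rbinom(n, 1,
      tilt_calibrated(mg$bottle, -lam[["bottle"]], q)) == 1,
    stringsAsFactors = FALSE
  )
  for (g in food_groups_24h())
    fd[[paste0("fg24_", g)]] <- stats::rbinom(n, 1,
      tilt_calibrated(mg$fg24[[g]], lam[["dietary_diversity"]], q))
  # Poisson mean on the log scale; intercept solved in closed form so the
  # cohort-average rate stays at mean_feeds
  fd$solid_feeds_24h <- stats::rpois(n,
    mg$mean_feeds * exp(lam[["meal_frequency"]] * q) /
      mean(exp(lam[["meal_frequency"]] * q)))
  for (g in food_groups_7d())
    fd[[paste0("d7_", g)]] <- stats::rbinom(n, 7,
      tilt_calibrated(mg$d7[[g]], lam[["seven_day_ff"]], q))
  fd$wash_before_cooking <- stats::rbinom(n, 1,
    tilt_calibrated(mg$wash_cooking, lam[["wash_cooking"]], q)) == 1
  fd$wash_before_feeding <- stats::rbinom(n, 1,
    tilt_calibrated(mg$wash_feeding, lam[["wash_feeding"]], q)) == 1
  fd$helped_to_eat <- stats::rbinom(n, 1,
    tilt_calibrated(mg$helped_to_eat, lam[["helped_to_eat"]], q)) == 1
  fd$refusal_response <- ifelse(stats::rbinom(n, 1,
    tilt_calibrated(mg$refusal_other, lam[["refusal_response"]], q)) == 1,
    "other", "nothing")
  fd
}

scale_or_zero <- function(x) {
  x <- as.numeric(x)
  if (stats::sd(x) == 0) return(rep(0, length(x)))
  as.numeric(scale(x))
}

#' Generate a synthetic survey cohort
#'
#' Draws, for each child and in a fixed documented order: age (months,
#' uniform within month), sex, residence, the household covariates, a
#' latent feeding-quality factor q ~ Normal(urban_shift x urban, 1), every
#' feeding item from its marginal tilted on the logit scale by its loading
#' times q (counts via a latent-shifted Poisson, 7-day day counts via
#' latent-shifted Binomial(7)), and finally the nutritional outcomes:
#' LAZ = mean + effect_laz x standardized index + covariate effects +
#' optional interactions + Normal(0, noise_sd) noise, analogously WAZ
#' (adjusted for diarrheal morbidity) and WLZ (null index effect by
#' default). Anthropometric measurements are emitted by inverting the LMS
#' fixture reference, so [compute_zscores()] recovers the intended WAZ and
#' LAZ; WLZ is implied by the resulting weight and length rather than
#' separately enforceable (two measurements cannot pin three indices), and
#' the drawn WLZ target is recorded in the truth record.
#'
#' Regeneration with the same parameters and seed is reproducible: all
#' randomness flows from `params$seed` through one generator stream.
#'
#' @param params An `icfi_sim_params` from [sim_params()].
#' @param reference Optional `lms_reference` used to emit measurements
#'   (defaults to [generate_lms_fixture()]).
#' @return A list of class `icfi_generated_cohort`: `cohort` (an
#'   `icfi_cohort`), `latent` (the per-child factor values), `truth` (the
#'   parameter record plus the drawn z-score targets and true index
#'   totals), and `reference` (the LMS reference used).
#' @export
generate_cohort <- function(params = sim_params(), reference = NULL) {
  params <- validate_sim_params(params)
  if (is.null(reference)) reference <- generate_lms_fixture()
  n <- params$n
  set.seed(params$seed)

  # 1. demographics and covariates
  month <- sample(as.integer(names(params$age_weights)), n, replace = TRUE,
                  prob = params$age_weights)
  age <- month + stats::runif(n)
  sex <- ifelse(stats::rbinom(n, 1, params$p_male) == 1, "male", "female")
  urban <- stats::rbinom(n, 1, params$p_urban)
  income <- stats::rlnorm(n, params$income_meanlog, params$income_sdlog)
  pre_lacteal <- stats::rbinom(n, 1, params$p_pre_lacteal) == 1
  diarrhea <- stats::rbinom(n, 1, params$p_diarrhea) == 1
  age_cf <- pmin(pmax(stats::rnorm(n, params$age_cf_mean, params$age_cf_sd), 0), age)
  married <- stats::rbinom(n, 1, params$p_married) == 1

  # 2. latent feeding-quality factor: unit-variance noise around an urban
  # shift and a standardized age trend (feeding quality rises with age)
  q <- stats::rnorm(n, params$urban_shift * urban +
                      params$age_trend * (age - 12) / sqrt(12), 1)

  # 3. feeding items
  band <- as.character(age_band(age))
  feeding <- draw_feeding_items(params, age, band, q)
  feeding <- cbind(data.frame(child_id = sprintf("c%05d", seq_len(n)),
                              stringsAsFactors = FALSE), feeding)

  # 4. the child's true index and the outcome draws
  scores <- compute_icfi(feeding)
  index_z <- scale_or_zero(scores$total)
  ce <- params$covariate_effects
  lin_laz <- params$laz_mean + params$effect_laz * index_z +
    ce[["income"]] * scale_or_zero(log(income)) +
    ce[["pre_lacteal"]] * scale_or_zero(pre_lacteal) +
    ce[["age_at_cf"]] * scale_or_zero(age_cf) +
    ce[["married"]] * scale_or_zero(married)
  if (!is.null(params$interaction_terms)) {
    mods <- list(residence = urban, income = log(income), diarrhea = diarrhea,
                 pre_lacteal = pre_lacteal, married = married)
    for (nm in names(params$interaction_terms)) {
      if (!nm %in% names(mods)) stop("unknown interaction moderator: ", nm)
      lin_laz <- lin_laz +
        params$interaction_terms[[nm]] * index_z * scale_or_zero(mods[[nm]])
    }
  }
  laz <- lin_laz + stats::rnorm(n, 0, params$noise_sd)
  waz <- params$waz_mean + params$effect_waz * index_z +
    ce[["diarrhea"]] * scale_or_zero(diarrhea) +
    stats::rnorm(n, 0, params$noise_sd)
  wlz_target <- params$wlz_mean + params$effect_wlz * index_z +
    stats::rnorm(n, 0, params$noise_sd)

  # 5. anthropometry by inverting the LMS reference at each child's age
  weight <- length_cm <- numeric(n)
  for (i in seq_len(n)) {
    pw <- interpolate_lms(reference, sex[i], "wfa", age[i])
    pl <- interpolate_lms(reference, sex[i], "lfa", age[i])
    weight[i] <- lms_inverse(waz[i], pw[["L"]], pw[["M"]], pw[["S"]])
    length_cm[i] <- lms_inverse(laz[i], pl[["L"]], pl[["M"]], pl[["S"]])
  }
  if (params$round_measurements) {
    weight <- round(weight, 1)
    length_cm <- round(length_cm, 1)
  }

  anthro <- data.frame(child_id = feeding$child_id, sex = sex, age_months = age,
                       weight_kg = weight, length_cm = length_cm,
                       stringsAsFactors = FALSE)
  covariates <- data.frame(child_id = feeding$child_id,
                           residence = ifelse(urban == 1, "urban", "rural"),
                           monthly_income = income,
                           pre_lacteal_feeding = pre_lacteal,
                           diarrhea_2wk = diarrhea,
                           age_at_cf_months = age_cf,
                           marital_status_married = married,
                           stringsAsFactors = FALSE)
  cohort <- icfi_cohort(feeding, anthro, covariates)
  structure(list(cohort = cohort, latent = q,
                 truth = list(params = params, laz = laz, waz = waz,
                              wlz_target = wlz_target, total = scores$total,
                              index_z = index_z),
                 reference = reference),
            class = "icfi_generated_cohort")
}

#' @export
print.icfi_generated_cohort <- function(x, ...) {
  cat("Synthetic ICFI cohort (seed ", x$truth$params$seed, ")\n", sep = "")
  print(x$cohort)
  invisible(x)
}

#' Implied Cronbach's alpha of a simulation parameterization
#'
#' The alpha a parameter set implies for the nine scored items under its
#' single-factor covariance structure. Because the scoring nonlinearity
#' (thresholding, band cutoffs) has no convenient closed form on the scored
#' scale, the implied value is computed by large-sample simulation of the
#' item-generation step with a dedicated internal seed, independent of
#' `params$seed`; the caller's random state is left untouched.
#'
#' @param params An `icfi_sim_params`.
#' @param n_sim Number of simulated children used to evaluate the implied
#'   covariance structure.
#' @return The implied alpha (scalar).
#' @export
implied_alpha <- function(params = sim_params(), n_sim = 40000) {
  params <- validate_sim_params(params)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(20140218)
  month <- sample(as.integer(names(params$age_weights)), n_sim, replace = TRUE,
                  prob = params$age_weights)
  age <- month + stats::runif(n_sim)
  urban <- stats::rbinom(n_sim, 1, params$p_urban)
  q <- stats::rnorm(n_sim, params$urban_shift * urban +
                      params$age_trend * (age - 12) / sqrt(12), 1)
  band <- as.character(age_band(age))
  feeding <- draw_feeding_items(params, age, band, q)
  feeding$child_id <- sprintf("s%06d", seq_len(n_sim))
  cronbach_alpha(item_matrix(compute_icfi(feeding)))
}

#' Generate a synthetic LMS growth-reference fixture
#'
#' Builds a smooth, internally consistent synthetic growth reference for
#' tests and simulation: monotone median weight and length curves over age,
#' a weight-for-length median derived from the same curves (so a child at
#' the weight-for-age and length-for-age medians is also at the
#' weight-for-length median), constant L, small S, and a small
#' multiplicative sex effect. This is a synthetic stand-in with plausible
#' magnitudes, not any official growth standard; real LMS tables can be
#' supplied through [read_lms_reference()] in the same layout.
#'
#' @param age_range Age span in months covered by the age-indexed tables.
#' @param age_step Grid spacing in months.
#' @param length_range Length span in cm covered by the weight-for-length
#'   table.
#' @param sex_effects Multiplicative female/male median ratios for weight
#'   and length.
#' @param seed Optional seed; when given, the S column gets a small smooth
#'   lognormal jitter so tests can exercise interpolation on varied grids.
#' @return An `lms_reference`.
#' @export
generate_lms_fixture <- function(age_range = c(0, 24), age_step = 0.5,
                                 length_range = c(45, 110),
                                 sex_effects = c(weight = 0.95, length = 0.98),
                                 seed = NULL) {
  m_weight <- function(age) 3.3 + 0.5 * age - 0.004 * age^2
  m_length <- function(age) 50 + 1.6 * age - 0.010 * age^2
  ages <- seq(age_range[1], age_range[2], by = age_step)
  lens <- seq(length_range[1], length_range[2], by = 1)
  # invert the length curve on an extended span so the wfl median is the
  # weight median at the age attaining each length
  age_fine <- seq(-4, 60, by = 0.05)
  rows <- list()
  for (sx in c("male", "female")) {
    wmul <- if (sx == "female") sex_effects[["weight"]] else 1
    lmul <- if (sx == "female") sex_effects[["length"]] else 1
    age_at_len <- stats::approx(lmul * m_length(age_fine), age_fine,
                                xout = lens, rule = 2)$y
    rows[[paste0(sx, "_wfa")]] <- data.frame(
      sex = sx, measure = "wfa", index = ages, L = 0.30,
      M = wmul * m_weight(ages), S = 0.12)
    rows[[paste0(sx, "_lfa")]] <- data.frame(
      sex = sx, measure = "lfa", index = ages, L = 1.00,
      M = lmul * m_length(ages), S = 0.035)
    rows[[paste0(sx, "_wfl")]] <- data.frame(
      sex = sx, measure = "wfl", index = lens, L = 0.30,
      M = wmul * m_weight(age_at_len), S = 0.11)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    df$S <- df$S * exp(stats::rnorm(nrow(df), 0, 0.03))
  }
  lms_reference(df, name = "synthetic LMS fixture")
}
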