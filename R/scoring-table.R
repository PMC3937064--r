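#' Default CS-ICFI scoring table
#'
#' Returns the scoring system used to build the cross-sectional infant and
#' child feeding index (CS-ICFI) for children aged 6-17 months: nine
#' components (current breastfeeding, bottle feeding, 24-h dietary diversity,
#' 24-h solid/semi-solid meal frequency, summed 7-day food-group frequency,
#' two hand-washing items, help with eating, and caregiver response to food
#' refusal), each scored with age-band-specific cutoffs so that every band
#' has a maximum total of 13.
#'
#' Count-type components are encoded as ascending threshold vectors
#' (`cuts`): the score equals the number of thresholds the observed count
#' reaches, so counts above the highest threshold saturate at the top score.
#' Breastfeeding is encoded as explicit yes/no scores per band (in the
#' 12-17-month band both map to 1, so the component is constant there and
#' the achievable band minimum is 1 rather than 0).
#'
#' @return A list of class `icfi_scoring_table` with one entry per age band
#'   (`band_6_8`, `band_9_11`, `band_12_17`), each holding `breastfeeding`
#'   (named vector `yes`/`no`), and `cuts` for `dietary_diversity`,
#'   `meal_frequency` and `seven_day`; plus `seven_day_group_cuts`, the
#'   band-invariant per-food-group 7-day thresholds.
#' @seealso [read_scoring_table()], [compute_icfi()]
#' @export
#' @examples
#' tab <- default_scoring_table()
#' tab$band_12_17$meal_frequency  # thresholds 2, 3, 4 -> scores 1, 2, 3
default_scoring_table <- function() {
  tab <- list(
    band_6_8 = list(
      breastfeeding     = c(yes = 2L, no = 0L),
      dietary_diversity = c(1L, 2L),
      meal_frequency    = c(1L, 2L),
      seven_day         = c(1L, 3L)
    ),
    band_9_11 = list(
      breastfeeding     = c(yes = 2L, no = 0L),
      dietary_diversity = c(1L, 3L),
      meal_frequency    = c(1L, 3L),
      seven_day         = c(2L, 5L)
    ),
    band_12_17 = list(
      breastfeeding     = c(yes = 1L, no = 1L),
      dietary_diversity = c(2L, 4L),
      meal_frequency    = c(2L, 3L, 4L),
      seven_day         = c(4L, 7L)
    ),
    seven_day_group_cuts = c(1L, 4L)
  )
  class(tab) <- "icfi_scoring_table"
  validate_scoring_table(tab)
  tab
}

#' Read a CS-ICFI scoring table from a YAML or JSON file
#'
#' The file mirrors the structure of [default_scoring_table()]: one block per
#' age band with `breastfeeding: {yes: s, no: s}` and integer threshold lists
#' `dietary_diversity`, `meal_frequency`, `seven_day`, plus a top-level
#' `seven_day_group_cuts`. The table is validated on load; unless
#' `allow_custom_total = TRUE`, each band's component maxima must sum to 13.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param allow_custom_total If `TRUE`, accept scoring systems whose band
#'   maxima differ from the canonical 13.
#' @return An `icfi_scoring_table`.
#' @export
read_scoring_table <- function(path, allow_custom_total = FALSE) {
  if (!file.exists(path)) stop("scoring table file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  tab <- list(seven_day_group_cuts = as.integer(raw$seven_day_group_cuts))
  for (b in c("band_6_8", "band_9_11", "band_12_17")) {
    blk <- raw[[b]]
    if (is.null(blk)) stop("scoring table missing band block: ", b)
    tab[[b]] <- list(
      breastfeeding = c(yes = as.integer(blk$breastfeeding$yes),
                        no  = as.integer(blk$breastfeeding$no)),
      dietary_diversity = as.integer(blk$dietary_diversity),
      meal_frequency    = as.integer(blk$meal_frequency),
      seven_day         = as.integer(blk$seven_day)
    )
  }
  class(tab) <- "icfi_scoring_table"
  validate_scoring_table(tab, allow_custom_total = allow_custom_total)
  tab
}

#' Validate a CS-ICFI scoring table
#'
#' Checks structural integrity: thresholds strictly increasing and positive,
#' breastfeeding scores non-negative, and (by default) that each band's
#' maximum attainable total is 13 (breastfeeding max + 1 for bottle + top
#' dietary-diversity, meal-frequency and 7-day scores + 4 binary items).
#'
#' @param tab An `icfi_scoring_table`.
#' @param allow_custom_total Skip the total-of-13 check.
#' @return `tab`, invisibly, if valid; otherwise an error.
#' @export
validate_scoring_table <- function(tab, allow_custom_total = FALSE) {
  stopifnot(inherits(tab, "icfi_scoring_table"))
  ck_cuts <- function(x, what) {
    if (length(x) < 1L || any(x < 1L) || is.unsorted(x, strictly = TRUE))
      stop("scoring table: ", what, " thresholds must be strictly increasing positive integers")
  }
  ck_cuts(tab$seven_day_group_cuts, "seven_day_group_cuts")
  for (b in c("band_6_8", "band_9_11", "band_12_17")) {
    blk <- tab[[b]]
    bf <- blk$breastfeeding
    if (!all(c("yes", "no") %in% names(bf)) || any(bf < 0L))
      stop("scoring table: ", b, " breastfeeding must have non-negative 'yes' and 'no' scores")
    for (comp in c("dietary_diversity", "meal_frequency", "seven_day"))
      ck_cuts(blk[[comp]], paste(b, comp))
    band_max <- max(bf) + 1L + length(blk$dietary_diversity) +
      length(blk$meal_frequency) + length(blk$seven_day) + 4L
    if (!allow_custom_total && band_max != 13L)
      stop("scoring table: ", b, " component maxima sum to ", band_max,
           ", expected 13 (use allow_custom_total to override)")
  }
  invisible(tab)
}

# score = number of ascending thresholds reached; saturates at the top score
score_from_cuts <- function(x, cuts) {
  vapply(x, function(xi) sum(xi >= cuts), integer(1))
}
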