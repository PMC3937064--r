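#' @title Survey cohort representation and CSV I/O
#' @description Typed representation, validation and round-trip CSV I/O for
#'   infant-feeding survey records, anthropometry and household covariates.
#' @name icfi-cohort
NULL

cohort_feeding_cols <- function() {
  c("child_id", "age_months", "currently_breastfed", "bottle_fed_24h",
    paste0("fg24_", food_groups_24h()), "solid_feeds_24h",
    paste0("d7_", food_groups_7d()),
    "wash_before_cooking", "wash_before_feeding", "helped_to_eat",
    "refusal_response")
}

cohort_anthro_cols <- function() c("child_id", "sex", "age_months", "weight_kg", "length_cm")

cohort_covariate_cols <- function() {
  c("child_id", "residence", "monthly_income", "pre_lacteal_feeding",
    "diarrhea_2wk", "age_at_cf_months", "marital_status_married")
}

#' Construct a validated survey cohort
#'
#' A cohort bundles three per-child tables joined on `child_id`: feeding
#' records (the raw index inputs), anthropometry and covariates. The join is
#' left on the feeding table; anthropometry and covariates are optional per
#' child. Rows failing validation are moved to a rejects table with the row
#' number and reason rather than silently dropped.
#'
#' @param feeding Data frame with the columns of the feeding layout
#'   (`child_id`, `age_months`, `currently_breastfed`, `bottle_fed_24h`,
#'   eight `fg24_*` 0/1 columns, `solid_feeds_24h`, seven `d7_*` day-count
#'   columns, the two hand-washing items, `helped_to_eat`,
#'   `refusal_response`).
#' @param anthro Optional data frame: `child_id`, `sex` (`"male"`/`"female"`),
#'   `age_months`, `weight_kg`, `length_cm`.
#' @param covariates Optional data frame: `child_id`, `residence`
#'   (`"urban"`/`"rural"`), `monthly_income`, `pre_lacteal_feeding`,
#'   `diarrhea_2wk`, `age_at_cf_months`, `marital_status_married`.
#' @param validate If `TRUE` (default), run row-level validation and route
#'   failures to the rejects table.
#' @return A list of class `icfi_cohort` with elements `feeding`, `anthro`,
#'   `covariates`, `rejects` (data frame: table, row, child_id, reason) and
#'   `warnings` (anthropometric sanity-bound flags that do not reject).
#' @export
icfi_cohort <- function(feeding, anthro = NULL, covariates = NULL, validate = TRUE) {
  empty_rejects <- data.frame(table = character(), row = integer(),
                              child_id = character(), reason = character(),
                              stringsAsFactors = FALSE)
  if (is.null(anthro)) anthro <- empty_df(cohort_anthro_cols())
  if (is.null(covariates)) covariates <- empty_df(cohort_covariate_cols())
  obj <- list(feeding = feeding, anthro = anthro, covariates = covariates,
              rejects = empty_rejects, warnings = character())
  class(obj) <- "icfi_cohort"
  if (validate) obj <- validate_cohort(obj)
  obj
}

empty_df <- function(cols) {
  df <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  df
}

#' Validate a cohort row by row
#'
#' Checks every feeding record against the domain invariants (age in
#' [6, 18); all 7-day day counts in [0, 7]; boolean items 0/1 or
#' TRUE/FALSE; refusal response `nothing`/`other`; no missing cells) and
#' moves failing rows, with reasons, to the rejects table. Anthropometric
#' sanity bounds (weight in (1, 30) kg, length in (40, 120) cm) are flagged
#' as warnings, not rejections. Duplicate `child_id`s within a table are
#' rejected after the first occurrence.
#'
#' @param cohort An `icfi_cohort`.
#' @return The cohort with `feeding` reduced to accepted rows and `rejects`
#'   and `warnings` populated. Validation is total: every input row is
#'   either accepted or present in `rejects`.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "icfi_cohort"))
  fd <- cohort$feeding
  missing_cols <- setdiff(cohort_feeding_cols(), names(fd))
  if (length(missing_cols))
    stop("feeding table missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))

  reasons <- rep(NA_character_, nrow(fd))
  note <- function(i, why) reasons[i] <<- ifelse(is.na(reasons[i]), why, reasons[i])

  num_cols <- c("age_months", "solid_feeds_24h",
                paste0("fg24_", food_groups_24h()), paste0("d7_", food_groups_7d()))
  bool_cols <- c("currently_breastfed", "bottle_fed_24h",
                 "wash_before_cooking", "wash_before_feeding", "helped_to_eat")
  for (cl in c(num_cols, bool_cols, "refusal_response", "child_id"))
    note(which(is.na(fd[[cl]])), paste0("missing value in ", cl))

  ok <- is.na(reasons)  # only apply range checks where the cell parsed
  note(which(ok & (fd$age_months < 6 | fd$age_months >= 18)), "age out of band")
  note(which(ok & fd$solid_feeds_24h < 0), "negative solid feed count")
  for (g in food_groups_7d()) {
    cl <- paste0("d7_", g)
    note(which(ok & (fd[[cl]] < 0 | fd[[cl]] > 7)), "day count > 7 or negative")
  }
  for (g in food_groups_24h()) {
    cl <- paste0("fg24_", g)
    note(which(ok & !fd[[cl]] %in% c(0, 1)), paste0("non-binary value in ", cl))
  }
  for (cl in bool_cols)
    note(which(ok & !(fd[[cl]] %in% c(0, 1, TRUE, FALSE))),
         paste0("non-binary value in ", cl))
  note(which(ok & !tolower(as.character(fd$refusal_response)) %in% c("nothing", "other")),
       "refusal_response not nothing/other")
  note(which(ok & duplicated(fd$child_id)), "duplicate child_id")

  rej <- which(!is.na(reasons))
  if (length(rej)) {
    cohort$rejects <- rbind(cohort$rejects, data.frame(
      table = "feeding", row = rej,
      child_id = as.character(fd$child_id[rej]),
      reason = reasons[rej], stringsAsFactors = FALSE))
    fd <- fd[-rej, , drop = FALSE]
  }
  for (cl in bool_cols) fd[[cl]] <- as.logical(fd[[cl]])
  fd$refusal_response <- tolower(as.character(fd$refusal_response))
  cohort$feeding <- fd

  an <- cohort$anthro
  if (nrow(an)) {
    a_reason <- rep(NA_character_, nrow(an))
    anote <- function(i, why) a_reason[i] <<- ifelse(is.na(a_reason[i]), why, a_reason[i])
    for (cl in cohort_anthro_cols()) anote(which(is.na(an[[cl]])), paste0("missing value in ", cl))
    aok <- is.na(a_reason)
    anote(which(aok & !tolower(as.character(an$sex)) %in% c("male", "female")),
          "sex not male/female")
    anote(which(aok & (an$weight_kg <= 0 | an$length_cm <= 0)), "non-positive measurement")
    anote(which(aok & duplicated(an$child_id)), "duplicate child_id")
    arej <- which(!is.na(a_reason))
    # sanity bounds warn but do not reject
    warn_i <- which(is.na(a_reason) &
                      (an$weight_kg <= 1 | an$weight_kg >= 30 |
                         an$length_cm <= 40 | an$length_cm >= 120))
    if (length(warn_i))
      cohort$warnings <- c(cohort$warnings, sprintf(
        "anthro row %d (child %s): measurement outside sanity bounds (weight %.1f kg, length %.1f cm)",
        warn_i, an$child_id[warn_i], an$weight_kg[warn_i], an$length_cm[warn_i]))
    if (length(arej)) {
      cohort$rejects <- rbind(cohort$rejects, data.frame(
        table = "anthro", row = arej, child_id = as.character(an$child_id[arej]),
        reason = a_reason[arej], stringsAsFactors = FALSE))
      an <- an[-arej, , drop = FALSE]
    }
    an$sex <- tolower(as.character(an$sex))
    cohort$anthro <- an
  }

  cv <- cohort$covariates
  if (nrow(cv)) {
    c_reason <- rep(NA_character_, nrow(cv))
    cnote <- function(i, why) c_reason[i] <<- ifelse(is.na(c_reason[i]), why, c_reason[i])
    for (cl in cohort_covariate_cols()) cnote(which(is.na(cv[[cl]])), paste0("missing value in ", cl))
    cok <- is.na(c_reason)
    cnote(which(cok & !tolower(as.character(cv$residence)) %in% c("urban", "rural")),
          "residence not urban/rural")
    cnote(which(cok & cv$monthly_income < 0), "negative income")
    cnote(which(cok & duplicated(cv$child_id)), "duplicate child_id")
    crej <- which(!is.na(c_reason))
    if (length(crej)) {
      cohort$rejects <- rbind(cohort$rejects, data.frame(
        table = "covariates", row = crej, child_id = as.character(cv$child_id[crej]),
        reason = c_reason[crej], stringsAsFactors = FALSE))
      cv <- cv[-crej, , drop = FALSE]
    }
    cv$residence <- tolower(as.character(cv$residence))
    for (cl in c("pre_lacteal_feeding", "diarrhea_2wk", "marital_status_married"))
      cv[[cl]] <- as.logical(cv[[cl]])
    cohort$covariates <- cv
  }
  cohort
}

#' Read a survey cohort from CSV
#'
#' Reads a single UTF-8 comma-separated file with one header row holding the
#' feeding, anthropometry and covariate columns (booleans encoded 0/1, the
#' eight 24-h food groups as `fg24_*` 0/1 columns, the seven 7-day counts as
#' `d7_*` integer columns). Foreign column names can be mapped onto the
#' canonical ones through `schema_config`, a named list/vector
#' `canonical = "foreign"` or the path of a YAML/JSON file holding one.
#' Rows failing validation land in the cohort's rejects table with row
#' number and reason; unparseable cells reject the row rather than the
#' file.
#'
#' @param path CSV file path.
#' @param schema_config Optional column-name mapping (named list, named
#'   character vector, or YAML/JSON path).
#' @return An `icfi_cohort`.
#' @export
read_cohort <- function(path, schema_config = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  if (!is.null(schema_config)) {
    map <- schema_config
    if (is.character(map) && length(map) == 1 && file.exists(map)) {
      map <- if (grepl("\\.json$", map, ignore.case = TRUE))
        jsonlite::read_json(map, simplifyVector = TRUE) else yaml::read_yaml(map)
    }
    map <- unlist(map)
    for (canon in names(map)) {
      if (!map[[canon]] %in% names(df))
        stop("schema_config maps '", canon, "' to absent column '", map[[canon]], "'")
      names(df)[names(df) == map[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(cohort_feeding_cols(), names(df))
  if (length(missing_cols))
    stop("cohort file missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))

  to_num <- function(x) {
    x[x %in% c("TRUE", "true")] <- "1"   # accept logical encodings too
    x[x %in% c("FALSE", "false")] <- "0"
    suppressWarnings(as.numeric(x))
  }
  num_cols <- c("age_months", "solid_feeds_24h", "weight_kg", "length_cm",
                "monthly_income", "age_at_cf_months",
                paste0("fg24_", food_groups_24h()), paste0("d7_", food_groups_7d()),
                "currently_breastfed", "bottle_fed_24h", "wash_before_cooking",
                "wash_before_feeding", "helped_to_eat", "pre_lacteal_feeding",
                "diarrhea_2wk", "marital_status_married")
  for (cl in intersect(num_cols, names(df))) {
    df[[cl]][df[[cl]] == ""] <- NA
    df[[cl]] <- to_num(df[[cl]])
  }
  for (cl in intersect(c("child_id", "refusal_response", "sex", "residence"), names(df)))
    df[[cl]][df[[cl]] == ""] <- NA

  feeding <- df[, cohort_feeding_cols(), drop = FALSE]
  # children with no anthropometry / covariates at all are simply absent from
  # those tables, not rejected for missingness
  drop_all_na <- function(tabl) {
    body <- tabl[, setdiff(names(tabl), c("child_id", "age_months")), drop = FALSE]
    tabl[rowSums(!is.na(body)) > 0, , drop = FALSE]
  }
  anthro <- if (all(cohort_anthro_cols() %in% names(df)))
    drop_all_na(df[, cohort_anthro_cols(), drop = FALSE]) else NULL
  covariates <- if (all(cohort_covariate_cols() %in% names(df)))
    drop_all_na(df[, cohort_covariate_cols(), drop = FALSE]) else NULL
  icfi_cohort(feeding, anthro, covariates)
}

#' Write a survey cohort to CSV
#'
#' Serializes a validated cohort back to the single-file CSV layout read by
#' [read_cohort()] (booleans as 0/1), so that write followed by read is the
#' identity on accepted records.
#'
#' @param cohort An `icfi_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "icfi_cohort"))
  fd <- cohort$feeding
  out <- fd
  bool_cols <- c("currently_breastfed", "bottle_fed_24h", "wash_before_cooking",
                 "wash_before_feeding", "helped_to_eat")
  for (cl in bool_cols) out[[cl]] <- as.integer(out[[cl]])
  join <- function(base, extra, cols) {
    idx <- if (nrow(extra)) match(base$child_id, extra$child_id) else rep(NA_integer_, nrow(base))
    for (cl in setdiff(cols, c("child_id", "age_months")))
      base[[cl]] <- extra[[cl]][idx]
    base
  }
  out <- join(out, cohort$anthro, cohort_anthro_cols())
  cv <- cohort$covariates
  for (cl in c("pre_lacteal_feeding", "diarrhea_2wk", "marital_status_married"))
    if (cl %in% names(cv)) cv[[cl]] <- as.integer(cv[[cl]])
  out <- join(out, cv, cohort_covariate_cols())
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
print.icfi_cohort <- function(x, ...) {
  cat("ICFI survey cohort\n")
  cat("  feeding records:", nrow(x$feeding), "accepted\n")
  cat("  anthropometry:  ", nrow(x$anthro), "records\n")
  cat("  covariates:     ", nrow(x$covariates), "records\n")
  cat("  rejects:        ", nrow(x$rejects), "rows\n")
  if (length(x$warnings)) cat("  warnings:       ", length(x$warnings), "\n")
  invisible(x)
}
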