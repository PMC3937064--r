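#' @title LMS anthropometric z-scores
#' @description Weight-for-age, length-for-age and weight-for-length
#'   z-scores through the LMS (lambda-mu-sigma) transformation against a
#'   pluggable growth reference, with strict below-minus-2-SD malnutrition
#'   flags and prevalence summaries. Official growth-reference tables are
#'   not bundled; any reference in the documented CSV layout (e.g. the WHO
#'   LMS tables) can be supplied.
#' @name icfi-anthro
NULL

lms_measures <- function() c("wfa", "lfa", "wfl")

#' Construct an LMS growth reference
#'
#' An LMS reference is a grid of (L, M, S) parameters indexed by sex and an
#' index variable — age in months for weight-for-age (`wfa`) and
#' length-for-age (`lfa`), length in cm for weight-for-length (`wfl`).
#'
#' @param df Data frame with columns `sex` (`"male"`/`"female"`), `measure`
#'   (`"wfa"`, `"lfa"`, `"wfl"`), `index`, `L`, `M`, `S`.
#' @param name Reference name recorded as metadata.
#' @return A list of class `lms_reference` (validated: M and S positive,
#'   index strictly increasing within each sex-by-measure block).
#' @export
lms_reference <- function(df, name = "unnamed reference") {
  need <- c("sex", "measure", "index", "L", "M", "S")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("LMS reference missing column(s): ", paste(missing, collapse = ", "))
  df$sex <- tolower(as.character(df$sex))
  df$measure <- tolower(as.character(df$measure))
  if (!all(df$sex %in% c("male", "female"))) stop("LMS reference sex must be male/female")
  if (!all(df$measure %in% lms_measures()))
    stop("LMS reference measure must be one of: ", paste(lms_measures(), collapse = ", "))
  if (any(df$M <= 0) || any(df$S <= 0)) stop("LMS reference requires M > 0 and S > 0")
  for (sx in unique(df$sex)) for (ms in unique(df$measure)) {
    idx <- df$index[df$sex == sx & df$measure == ms]
    if (length(idx) && is.unsorted(idx, strictly = TRUE))
      stop("LMS reference index must be strictly increasing within ", sx, "/", ms)
  }
  structure(list(table = df[order(df$sex, df$measure, df$index), ], name = name),
            class = "lms_reference")
}

#' Read an LMS reference from CSV
#'
#' Expects the documented layout: columns `sex`, `measure`, `index`, `L`,
#' `M`, `S` — one row per grid point.
#'
#' @param path CSV path.
#' @param name Optional reference name (defaults to the file name).
#' @return An `lms_reference`.
#' @export
read_lms_reference <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("LMS reference file not found: ", path)
  lms_reference(utils::read.csv(path, stringsAsFactors = FALSE), name = name)
}

#' @export
print.lms_reference <- function(x, ...) {
  cat("LMS growth reference:", x$name, "\n")
  tb <- x$table
  for (ms in unique(tb$measure)) {
    sub <- tb[tb$measure == ms, ]
    cat(sprintf("  %s: index span [%g, %g], %d rows\n",
                ms, min(sub$index), max(sub$index), nrow(sub)))
  }
  invisible(x)
}

#' LMS z-score transformation
#'
#' Converts a measurement x to a z-score given the reference parameters:
#' \deqn{z = \frac{(x/M)^L - 1}{L\,S}} for L != 0 and
#' \eqn{z = \ln(x/M)/S} in the L = 0 limit. Strictly increasing in x; the
#' reference median (x = M) maps to 0.
#'
#' @param x Positive measurement(s).
#' @param L,M,S LMS parameters (M > 0, S > 0); vectors are recycled.
#' @return Numeric z-score(s) in SD units.
#' @export
lms_zscore <- function(x, L, M, S) {
  if (any(x <= 0) || any(M <= 0) || any(S <= 0))
    stop("lms_zscore requires x > 0, M > 0, S > 0")
  ifelse(L == 0, log(x / M) / S, ((x / M)^L - 1) / (L * S))
}

#' Inverse LMS transformation
#'
#' Reconstructs the measurement attaining a target z-score:
#' \eqn{x = M (1 + L S z)^{1/L}} for L != 0 and \eqn{x = M e^{S z}} when
#' L = 0. Exact inverse of [lms_zscore()] wherever \eqn{1 + LSz > 0}.
#'
#' @param z Target z-score(s).
#' @inheritParams lms_zscore
#' @return The measurement(s).
#' @export
lms_inverse <- function(z, L, M, S) {
  base <- 1 + L * S * z
  if (any(base[L != 0] <= 0))
    stop("target z outside the representable range for these LMS parameters")
  ifelse(L == 0, M * exp(S * z), M * base^(1 / L))
}

#' Interpolate LMS parameters from the reference grid
#'
#' Linear interpolation of L, M and S between the bracketing grid rows for
#' the requested sex, measure and index value; exact grid hits return the
#' row itself. Requests outside the grid span are an error naming the span.
#'
#' @param ref An `lms_reference`.
#' @param sex `"male"` or `"female"`.
#' @param measure `"wfa"`, `"lfa"` or `"wfl"`.
#' @param index_value Age in months (wfa, lfa) or length in cm (wfl).
#' @return Named numeric vector `c(L, M, S)`.
#' @export
interpolate_lms <- function(ref, sex, measure, index_value) {
  stopifnot(inherits(ref, "lms_reference"))
  sub <- ref$table[ref$table$sex == tolower(sex) & ref$table$measure == tolower(measure), ]
  if (nrow(sub) == 0) stop("reference has no rows for ", sex, "/", measure)
  if (index_value < min(sub$index) || index_value > max(sub$index))
    stop(sprintf("index %g outside reference span [%g, %g] for %s/%s",
                 index_value, min(sub$index), max(sub$index), sex, measure))
  c(L = stats::approx(sub$index, sub$L, xout = index_value)$y,
    M = stats::approx(sub$index, sub$M, xout = index_value)$y,
    S = stats::approx(sub$index, sub$S, xout = index_value)$y)
}

#' Compute WAZ, LAZ and WLZ for anthropometric records
#'
#' Weight-for-age from (weight, age), length-for-age from (length, age) and
#' weight-for-length from (weight, length), each through the LMS reference.
#' Malnutrition flags use the strict rule z < -2: `underweight` on WAZ,
#' `stunted` on LAZ, `wasted` on WLZ; a z of exactly -2.0 is not flagged.
#' Records outside the reference's coverage get `NA` for the affected index
#' and are listed in the `out_of_coverage` attribute rather than dropped.
#'
#' @param anthro Data frame with columns `child_id`, `sex`, `age_months`,
#'   `weight_kg`, `length_cm` (e.g. the `$anthro` table of an
#'   `icfi_cohort`).
#' @param ref An `lms_reference`.
#' @return Data frame of class `icfi_zscores`: `child_id`, `waz`, `laz`,
#'   `wlz`, `underweight`, `stunted`, `wasted`.
#' @export
compute_zscores <- function(anthro, ref) {
  stopifnot(inherits(ref, "lms_reference"))
  if (nrow(ref$table) == 0) stop("empty LMS reference")
  n <- nrow(anthro)
  if (n == 0) stop("no anthropometric records")
  z_one <- function(sex, measure, idx, x) {
    tryCatch({
      p <- interpolate_lms(ref, sex, measure, idx)
      lms_zscore(x, p[["L"]], p[["M"]], p[["S"]])
    }, error = function(e) NA_real_)
  }
  waz <- laz <- wlz <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    waz[i] <- z_one(anthro$sex[i], "wfa", anthro$age_months[i], anthro$weight_kg[i])
    laz[i] <- z_one(anthro$sex[i], "lfa", anthro$age_months[i], anthro$length_cm[i])
    wlz[i] <- z_one(anthro$sex[i], "wfl", anthro$length_cm[i], anthro$weight_kg[i])
  }
  out <- data.frame(child_id = as.character(anthro$child_id),
                    waz = waz, laz = laz, wlz = wlz,
                    underweight = !is.na(waz) & waz < -2,
                    stunted = !is.na(laz) & laz < -2,
                    wasted = !is.na(wlz) & wlz < -2,
                    stringsAsFactors = FALSE)
  ooc <- out$child_id[is.na(waz) | is.na(laz) | is.na(wlz)]
  attr(out, "out_of_coverage") <- ooc
  class(out) <- c("icfi_zscores", "data.frame")
  out
}

#' Prevalence of stunting, underweight and wasting
#'
#' Percentages of children with z < -2 on LAZ (stunting), WAZ
#' (underweight) and WLZ (wasting), each over the children with a defined
#' z for that index, plus mean z per index. Denominators are reported.
#'
#' @param results An `icfi_zscores` data frame.
#' @return Data frame with one row per index: `index`, `n`, `mean_z`,
#'   `n_below`, `prevalence_pct`.
#' @export
prevalence_summary <- function(results) {
  if (nrow(results) == 0) stop("no z-score results to summarize")
  one <- function(z, label) {
    ok <- !is.na(z)
    data.frame(index = label, n = sum(ok),
               mean_z = if (any(ok)) mean(z[ok]) else NA_real_,
               n_below = sum(z[ok] < -2),
               prevalence_pct = if (any(ok)) 100 * mean(z[ok] < -2) else NA_real_,
               stringsAsFactors = FALSE)
  }
  rbind(one(results$laz, "stunting (LAZ)"),
        one(results$waz, "underweight (WAZ)"),
        one(results$wlz, "wasting (WLZ)"))
}
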