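#' @title Internal-consistency analysis of the index items
#' @description Cronbach's alpha on the nine scored index components, Feldt
#'   F-based confidence intervals, alpha-if-item-deleted and item-total
#'   correlations.
#' @name icfi-reliability
NULL

#' Build the children-by-items score matrix
#'
#' Extracts the nine component-score columns from a per-child scores data
#' frame (as produced by [compute_icfi()] or [score_cohort()]) in the fixed
#' item order: meal frequency, dietary diversity, 7-day food frequency,
#' refusal response, helped to eat, bottle, wash before cooking, wash before
#' feeding, breastfeeding.
#'
#' @param scores An `icfi_scores` data frame (or the `$scores` element of an
#'   `icfi_cohort_scores`).
#' @return Numeric matrix, children in rows, the nine items in columns.
#' @export
item_matrix <- function(scores) {
  if (inherits(scores, "icfi_cohort_scores")) scores <- scores$scores
  items <- icfi_item_order()
  missing <- setdiff(items, names(scores))
  if (length(missing)) stop("scores lack item column(s): ", paste(missing, collapse = ", "))
  m <- as.matrix(scores[, items])
  if (anyNA(m)) stop("item matrix must have no missing cells (complete cases only)")
  storage.mode(m) <- "double"
  m
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' \deqn{\alpha = \frac{k}{k-1}\Big(1 - \frac{\sum_i s_i^2}{s_T^2}\Big)}
#' where \eqn{s_i^2} are the sample variances (n-1 denominator) of the k
#' items and \eqn{s_T^2} the variance of the row sums. Computed on the raw
#' (covariance) scale by default, appropriate when items have unequal score
#' ranges; `standardized = TRUE` rescales each item to unit variance first
#' (items with zero variance are then dropped with a warning). Negative
#' values are possible and reported as computed, with a warning.
#'
#' @param m Numeric matrix or data frame, children in rows, items in columns.
#' @param standardized Use the standardized (correlation-based) form.
#' @return The alpha coefficient (scalar).
#' @export
#' @examples
#' set.seed(1)
#' q <- rnorm(200)
#' m <- sapply(1:4, function(i) q + rnorm(200))
#' cronbach_alpha(m)
cronbach_alpha <- function(m, standardized = FALSE) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("item matrix must have no missing cells")
  n <- nrow(m); k <- ncol(m)
  if (n < 3) stop("need at least 3 rows for Cronbach's alpha")
  if (k < 2) stop("need at least 2 items for Cronbach's alpha")
  if (standardized) {
    v <- apply(m, 2, stats::var)
    if (any(v == 0)) {
      warning("dropping ", sum(v == 0), " zero-variance item(s) for standardized alpha")
      m <- m[, v > 0, drop = FALSE]
      k <- ncol(m)
      if (k < 2) stop("fewer than 2 items with variance for standardized alpha")
    }
    m <- scale(m)
  }
  total_var <- stats::var(rowSums(m))
  if (total_var <= 0) stop("total-score variance is zero; alpha undefined")
  a <- k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
  if (a < 0) warning("negative Cronbach's alpha (", format(a, digits = 3),
                     "): items are negatively related on average")
  a
}

#' Alpha if item deleted
#'
#' Recomputes Cronbach's alpha with each item removed in turn; an item whose
#' deletion raises alpha depresses the scale's internal consistency.
#'
#' @inheritParams cronbach_alpha
#' @return Data frame with columns `item` (column name or index, in column
#'   order) and `alpha_if_deleted`.
#' @export
alpha_if_deleted <- function(m, standardized = FALSE) {
  m <- as.matrix(m)
  if (ncol(m) < 3) stop("need at least 3 items for alpha-if-deleted")
  nm <- colnames(m)
  if (is.null(nm)) nm <- as.character(seq_len(ncol(m)))
  vals <- vapply(seq_len(ncol(m)), function(j)
    cronbach_alpha(m[, -j, drop = FALSE], standardized = standardized), numeric(1))
  data.frame(item = nm, alpha_if_deleted = vals, stringsAsFactors = FALSE)
}

#' Item-total correlations
#'
#' Pearson correlation of each item with the total score. By default the
#' item is included in its own total (uncorrected); `corrected = TRUE`
#' excludes it. Items with zero variance get `NA` with a warning rather
#' than a silent 0.
#'
#' @inheritParams cronbach_alpha
#' @param corrected Exclude each item from its own total.
#' @return Data frame with columns `item` and `r`.
#' @export
item_total_correlation <- function(m, corrected = FALSE) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  nm <- colnames(m)
  if (is.null(nm)) nm <- as.character(seq_len(ncol(m)))
  tot <- rowSums(m)
  r <- vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    y <- if (corrected) tot - x else tot
    if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  if (anyNA(r))
    warning("item-total correlation undefined (zero variance) for: ",
            paste(nm[is.na(r)], collapse = ", "))
  data.frame(item = nm, r = r, stringsAsFactors = FALSE)
}

#' Feldt confidence interval for Cronbach's alpha
#'
#' Closed-form interval based on the F distribution: with n subjects and k
#' items, \eqn{(1-\alpha)/(1-\hat\alpha) \sim F} with (n-1) and (n-1)(k-1)
#' degrees of freedom, giving bounds
#' \eqn{1 - (1-\hat\alpha) F_{1-p/2}} and \eqn{1 - (1-\hat\alpha) F_{p/2}}.
#'
#' @param alpha Point estimate of Cronbach's alpha.
#' @param n Number of subjects.
#' @param k Number of items.
#' @param level Confidence level in (0, 1).
#' @return Named numeric vector `c(lower, upper)` containing `alpha`.
#' @export
alpha_confidence_interval <- function(alpha, n, k, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (n <= k || n < 3 || k < 2) stop("invalid degrees of freedom: need n > k, n >= 3, k >= 2")
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  p <- 1 - level
  lower <- 1 - (1 - alpha) * stats::qf(1 - p / 2, df1, df2)
  upper <- 1 - (1 - alpha) * stats::qf(p / 2, df1, df2)
  c(lower = lower, upper = upper)
}

#' Reliability report for scored cohorts
#'
#' Assembles, overall and optionally per age band, Cronbach's alpha with its
#' Feldt confidence interval, each item's item-total correlation and
#' alpha-if-item-deleted — the standard item-analysis block for a summary
#' index. Strata too small for estimation are flagged and skipped; the
#' remaining strata are still reported.
#'
#' @param scores An `icfi_scores` data frame or `icfi_cohort_scores`.
#' @param by_band Also report each age band separately.
#' @param level Confidence level for the alpha interval.
#' @param corrected Use corrected (item-excluded) item-total correlations.
#' @param standardized Use standardized alpha.
#' @return A list of class `icfi_reliability`: one entry per stratum
#'   (`overall` and, if requested, each band), each holding `alpha`,
#'   `alpha_ci`, `per_item` (item, r, alpha_if_deleted), `n`, `k`; skipped
#'   strata hold an `error` message instead.
#' @export
reliability_report <- function(scores, by_band = FALSE, level = 0.95,
                               corrected = FALSE, standardized = FALSE) {
  if (inherits(scores, "icfi_cohort_scores")) scores <- scores$scores
  one <- function(sub, label) {
    res <- try({
      m <- item_matrix(sub)
      a <- cronbach_alpha(m, standardized = standardized)
      ci <- alpha_confidence_interval(a, n = nrow(m), k = ncol(m), level = level)
      itc <- suppressWarnings(item_total_correlation(m, corrected = corrected))
      aid <- alpha_if_deleted(m, standardized = standardized)
      per <- merge(itc, aid, by = "item", sort = FALSE)
      per <- per[match(icfi_item_order(), per$item), ]
      rownames(per) <- NULL
      list(stratum = label, alpha = a, alpha_ci = ci, level = level,
           per_item = per, n = nrow(m), k = ncol(m))
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      res <- list(stratum = label, error = conditionMessage(attr(res, "condition")),
                  n = nrow(sub))
    res
  }
  out <- list(overall = one(scores, "overall"))
  if (by_band)
    for (b in band_levels())
      out[[b]] <- one(scores[scores$band == b, , drop = FALSE], b)
  class(out) <- "icfi_reliability"
  out
}

#' @export
print.icfi_reliability <- function(x, ...) {
  cat("CS-ICFI internal consistency\n")
  for (st in x) {
    if (!is.null(st$error)) {
      cat(sprintf("  %-10s  skipped: %s\n", st$stratum, st$error))
      next
    }
    cat(sprintf("  %-10s  n = %d  alpha = %.3f  (%d%% CI %.3f-%.3f)\n",
                st$stratum, st$n, st$alpha, round(100 * st$level),
                st$alpha_ci[["lower"]], st$alpha_ci[["upper"]]))
  }
  invisible(x)
}
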