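#' @title Association analysis between the index and nutritional status
#' @description The statistical battery accompanying the feeding index:
#'   tertile-wise one-way ANOVA, two-group t-tests, Levene's
#'   variance-homogeneity check, chi-square contingency tests, multivariable
#'   linear regression with standardized coefficients, and interaction
#'   screening. Complete-case analysis throughout; the per-model n is
#'   reported. No multiple-testing correction is applied (two-sided 0.05
#'   convention), which callers should keep in mind when screening many
#'   moderators.
#' @name icfi-association
NULL

group_stats <- function(values_by_group) {
  data.frame(
    group = names(values_by_group),
    n = vapply(values_by_group, length, integer(1)),
    mean = vapply(values_by_group, mean, numeric(1)),
    sd = vapply(values_by_group, stats::sd, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' One-way analysis of variance across groups
#'
#' Classical fixed-effects F test (between over within mean squares) of
#' equality of group means, e.g. of mean LAZ across the three index
#' tertiles.
#'
#' @param values_by_group Named list mapping group label to a numeric
#'   vector; at least two groups of at least two values each.
#' @return A list of class `icfi_group_comparison`: `test`, per-`groups`
#'   n/mean/sd, `statistic` (F), `df`, `p_value`.
#' @export
oneway_anova <- function(values_by_group) {
  if (length(values_by_group) < 2) stop("need at least 2 groups")
  if (any(vapply(values_by_group, length, integer(1)) < 2))
    stop("each group needs at least 2 observations")
  y <- unlist(values_by_group, use.names = FALSE)
  g <- factor(rep(names(values_by_group), vapply(values_by_group, length, integer(1))))
  if (stats::var(y) == 0) stop("total variance is zero; ANOVA undefined")
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1]]
  structure(list(test = "one-way ANOVA", groups = group_stats(values_by_group),
                 statistic = tab[["F value"]][1],
                 df = c(tab[["Df"]][1], tab[["Df"]][2]),
                 p_value = tab[["Pr(>F)"]][1]),
            class = "icfi_group_comparison")
}

#' Two-group t-test
#'
#' Independent-samples t-test of a mean difference (e.g. urban vs rural
#' mean index). Pooled-variance (classical) by default; Welch with
#' `equal_variance = FALSE`.
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @param equal_variance Pool the variances (classical two-sample t).
#' @return An `icfi_group_comparison` with the t statistic, df and
#'   two-sided p.
#' @export
two_group_ttest <- function(a, b, equal_variance = TRUE) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs at least 2 observations")
  if (stats::var(c(a, b)) == 0) stop("all observations identical; t-test undefined")
  ht <- stats::t.test(a, b, var.equal = equal_variance)
  structure(list(test = if (equal_variance) "pooled t-test" else "Welch t-test",
                 groups = group_stats(list(a = a, b = b)),
                 statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value),
            class = "icfi_group_comparison")
}

#' Levene's test of variance homogeneity
#'
#' Levene's test with deviations taken about the group means (the classical
#' form), screening the equal-variance assumption behind the ANOVA and
#' pooled t-test.
#'
#' @inheritParams oneway_anova
#' @return An `icfi_group_comparison` with the Levene F statistic and p.
#' @export
variance_homogeneity <- function(values_by_group) {
  if (length(values_by_group) < 2) stop("need at least 2 groups")
  if (any(vapply(values_by_group, length, integer(1)) < 2))
    stop("each group needs at least 2 observations")
  y <- unlist(values_by_group, use.names = FALSE)
  g <- factor(rep(names(values_by_group), vapply(values_by_group, length, integer(1))))
  lt <- car::leveneTest(y, g, center = mean)
  structure(list(test = "Levene (center = mean)",
                 groups = group_stats(values_by_group),
                 statistic = lt[["F value"]][1],
                 df = c(lt[["Df"]][1], lt[["Df"]][2]),
                 p_value = lt[["Pr(>F)"]][1]),
            class = "icfi_group_comparison")
}

#' @export
print.icfi_group_comparison <- function(x, ...) {
  cat(x$test, "\n")
  print(x$groups, row.names = FALSE, digits = 4)
  cat(sprintf("statistic = %.4f, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Pearson chi-square contingency test
#'
#' Pearson chi-square without continuity correction on an r-by-c table of
#' counts (df = (r-1)(c-1)), e.g. index tertile by maternal
#' characteristic. The proportion of cells with expected count below 5 is
#' reported as a small-sample caveat; for 2-by-2 tables with such cells,
#' Fisher's exact p is attached as well.
#'
#' @param table Matrix of non-negative integer counts, at least 2x2, with
#'   no zero row or column margin.
#' @return A list of class `icfi_contingency`: observed counts, `statistic`,
#'   `df`, `p_value`, `prop_expected_lt5`, and `fisher_p` where computed.
#' @export
contingency_test <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) stop("need at least a 2x2 table")
  if (any(table < 0) || any(table != round(table))) stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column margin; chi-square undefined")
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  prop_lt5 <- mean(ht$expected < 5)
  fisher_p <- NULL
  if (prop_lt5 > 0 && nrow(table) == 2 && ncol(table) == 2)
    fisher_p <- stats::fisher.test(table)$p.value
  structure(list(observed = table, statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value,
                 prop_expected_lt5 = prop_lt5, fisher_p = fisher_p),
            class = "icfi_contingency")
}

#' @export
print.icfi_contingency <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X2 = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (x$prop_expected_lt5 > 0)
    cat(sprintf("caveat: %.0f%% of cells have expected count < 5\n",
                100 * x$prop_expected_lt5))
  if (!is.null(x$fisher_p)) cat(sprintf("Fisher exact p = %.4g\n", x$fisher_p))
  invisible(x)
}

#' Multivariable linear regression with standardized coefficients
#'
#' Ordinary least squares after z-scoring the outcome and every predictor,
#' so the reported coefficients are standardized betas (in simple
#' regression the beta equals the Pearson correlation). Two-sided p-values
#' come from t statistics on n - p - 1 degrees of freedom. Complete-case:
#' rows with any missing value are dropped and the model n reported.
#' Unstandardized coefficients are available with `standardize = FALSE`.
#'
#' @param outcome Numeric outcome vector.
#' @param predictors Data frame (or named list) of numeric predictor
#'   columns; logicals are coerced to 0/1.
#' @param standardize Report standardized betas (default).
#' @return A list of class `icfi_regression`: `coefficients` (data frame
#'   predictor/beta/se/t/p_value), `n`, `outcome_name`, `standardized`,
#'   `r_squared`.
#' @export
standardized_ols <- function(outcome, predictors, standardize = TRUE) {
  pred <- as.data.frame(predictors)
  if (ncol(pred) == 0) stop("no predictors supplied")
  for (j in seq_along(pred)) pred[[j]] <- as.numeric(pred[[j]])
  dat <- cbind(data.frame(.y = as.numeric(outcome)), pred)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  if (n <= ncol(pred) + 1) stop("too few complete cases for the model")
  const <- vapply(names(pred), function(nm) stats::var(dat[[nm]]) == 0, logical(1))
  if (any(const)) stop("constant predictor column(s): ",
                       paste(names(pred)[const], collapse = ", "))
  if (standardize) {
    if (stats::var(dat$.y) == 0) stop("outcome has zero variance")
    dat <- as.data.frame(scale(dat))
  }
  X <- as.matrix(dat[, names(pred), drop = FALSE])
  if (qr(cbind(1, X))$rank < ncol(X) + 1) {
    # name the offending columns for the caller
    qrX <- qr(cbind(1, X))
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- setdiff(seq_len(ncol(X) + 1), keep) - 1L
    stop("rank-deficient design; collinear column(s): ",
         paste(names(pred)[dropped[dropped > 0]], collapse = ", "))
  }
  fit <- stats::lm(.y ~ ., data = dat)
  sm <- summary(fit)$coefficients
  sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  structure(list(
    coefficients = data.frame(predictor = rownames(sm),
                              beta = sm[, "Estimate"], se = sm[, "Std. Error"],
                              t = sm[, "t value"], p_value = sm[, "Pr(>|t|)"],
                              stringsAsFactors = FALSE, row.names = NULL),
    n = n, standardized = standardize,
    r_squared = summary(fit)$r.squared),
    class = "icfi_regression")
}

#' @export
print.icfi_regression <- function(x, ...) {
  cat(sprintf("%s linear regression (n = %d, R2 = %.3f)\n",
              if (x$standardized) "Standardized" else "Unstandardized",
              x$n, x$r_squared))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Screen moderators for interaction with the index
#'
#' For each candidate moderator fits outcome ~ index + moderator +
#' index:moderator on z-scored index and moderator (the product term is the
#' product of the two z-scores) and reports the product-term coefficient
#' and its two-sided p — the usual check that the index-outcome association
#' is not conditioned on child, maternal or household characteristics.
#' Constant moderators are flagged as degenerate and skipped with a
#' warning.
#'
#' @param outcome Numeric outcome vector.
#' @param index Numeric index vector (e.g. CS-ICFI totals).
#' @param moderators Data frame / named list of candidate moderators;
#'   logicals coerced to 0/1.
#' @return Data frame: `moderator`, `interaction_beta`, `p_value`, `n`
#'   (`NA` beta for skipped degenerate moderators).
#' @export
interaction_screen <- function(outcome, index, moderators) {
  mods <- as.data.frame(moderators)
  if (ncol(mods) == 0) stop("no moderators supplied")
  rows <- lapply(names(mods), function(nm) {
    m <- as.numeric(mods[[nm]])
    keep <- stats::complete.cases(outcome, index, m)
    y <- outcome[keep]; xi <- index[keep]; xm <- m[keep]
    if (length(y) < 5 || stats::var(xm) == 0 || stats::var(xi) == 0) {
      warning("moderator '", nm, "' degenerate (constant or too few cases); skipped")
      return(data.frame(moderator = nm, interaction_beta = NA_real_,
                        p_value = NA_real_, n = length(y), stringsAsFactors = FALSE))
    }
    zi <- as.numeric(scale(xi)); zm <- as.numeric(scale(xm))
    fit <- standardized_ols(y, data.frame(index = zi, moderator = zm,
                                          interaction = zi * zm))
    k <- fit$coefficients[fit$coefficients$predictor == "interaction", ]
    data.frame(moderator = nm, interaction_beta = k$beta, p_value = k$p_value,
               n = fit$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
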