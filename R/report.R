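#' @title End-to-end analysis run
#' @description Orchestrates the full pipeline — scoring, reliability,
#'   anthropometry, association — over one cohort and writes per-stage
#'   outputs plus a combined human-readable report.
#' @name icfi-report
NULL

#' Run the full CS-ICFI analysis pipeline
#'
#' Executes score -> reliability -> anthropometry -> association on a
#' cohort, writing per-stage outputs (`scores.csv`, `reliability.json`,
#' `zscores.csv`, `association.json`) and a combined plain-text report
#' (`report.txt`) plus a machine-readable `report.json` into the output
#' directory. The report carries index summaries by band and residence, the
#' tertile distribution, the item-analysis block, the tertile-wise ANOVA of
#' each z-score, the multivariable regression for LAZ and WAZ, and an
#' interaction screen; every record exclusion is logged with reason and
#' count, and record conservation (accepted + rejected = read) is asserted.
#' A stage failure aborts with the failing stage named; outputs of earlier
#' stages are retained.
#'
#' @param config A list: `input` (cohort CSV path or an `icfi_cohort`),
#'   `reference` (LMS CSV path or an `lms_reference`; mandatory for the
#'   anthropometry stage), `output_dir`; optional `scoring_table` (path or
#'   `icfi_scoring_table`), `tertiles` (`"fixed"`/`"empirical"`),
#'   `conf_level`, `covariates` (predictor names for the regression among
#'   `monthly_income`, `pre_lacteal_feeding`, `age_at_cf_months`,
#'   `marital_status_married`, `diarrhea_2wk`), `interactions` (moderator
#'   names among `residence`, `monthly_income`), `schema_config`.
#' @return Invisibly, a list of class `icfi_run` with the per-stage results
#'   and output paths.
#' @export
run_full_analysis <- function(config) {
  need <- c("input", "reference", "output_dir")
  missing <- setdiff(need, names(config))
  if (length(missing)) stop("config missing field(s): ", paste(missing, collapse = ", "))
  cfg <- utils::modifyList(list(
    scoring_table = NULL, tertiles = "fixed", conf_level = 0.95,
    covariates = c("monthly_income", "pre_lacteal_feeding",
                   "age_at_cf_months", "marital_status_married"),
    interactions = c("residence", "monthly_income"),
    schema_config = NULL), config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "configuration"
  fail <- function(e) stop("pipeline failed at stage '", stage, "': ",
                           conditionMessage(e), call. = FALSE)
  tab <- if (is.null(cfg$scoring_table)) default_scoring_table()
         else if (inherits(cfg$scoring_table, "icfi_scoring_table")) cfg$scoring_table
         else read_scoring_table(cfg$scoring_table)
  ref <- if (inherits(cfg$reference, "lms_reference")) cfg$reference
         else read_lms_reference(cfg$reference)
  cohort <- if (inherits(cfg$input, "icfi_cohort")) cfg$input
            else tryCatch(read_cohort(cfg$input, cfg$schema_config), error = fail)
  n_read <- nrow(cohort$feeding) + sum(cohort$rejects$table == "feeding")

  stage <- "score"
  scored <- tryCatch(score_cohort(cohort, tertiles = cfg$tertiles, table = tab,
                                  conf_level = cfg$conf_level), error = fail)
  scores_path <- file.path(cfg$output_dir, "scores.csv")
  utils::write.csv(scored$scores, scores_path, row.names = FALSE)

  stage <- "reliability"
  rel <- tryCatch(reliability_report(scored, by_band = TRUE,
                                     level = cfg$conf_level), error = fail)
  rel_path <- file.path(cfg$output_dir, "reliability.json")
  jsonlite::write_json(unclass(rel), rel_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)

  stage <- "anthropometry"
  zs <- tryCatch(compute_zscores(cohort$anthro, ref), error = fail)
  z_path <- file.path(cfg$output_dir, "zscores.csv")
  utils::write.csv(zs, z_path, row.names = FALSE)
  prev <- prevalence_summary(zs)

  stage <- "association"
  assoc <- tryCatch(run_association_block(scored, zs, cohort$covariates,
                                          covariates = cfg$covariates,
                                          interactions = cfg$interactions),
                    error = fail)
  assoc_path <- file.path(cfg$output_dir, "association.json")
  jsonlite::write_json(assoc_to_json(assoc), assoc_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)

  stage <- "report"
  run <- structure(list(cohort = cohort, scored = scored, reliability = rel,
                        zscores = zs, prevalence = prev, association = assoc,
                        n_read = n_read,
                        paths = c(scores = scores_path, reliability = rel_path,
                                  zscores = z_path, association = assoc_path)),
                   class = "icfi_run")
  txt <- render_report(run)
  report_path <- file.path(cfg$output_dir, "report.txt")
  writeLines(txt, report_path)
  jsonlite::write_json(
    list(n_read = n_read, n_accepted = nrow(cohort$feeding),
         n_rejected = sum(cohort$rejects$table == "feeding"),
         summary = scored$summary,
         tertiles = as.list(table(scored$scores$tertile)),
         prevalence = prev),
    file.path(cfg$output_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  run$paths <- c(run$paths, report = report_path)
  invisible(run)
}

# tertile ANOVA + Levene per z-score, urban/rural t-test, regressions and
# interaction screen; tables joined on child_id, complete-case per model
run_association_block <- function(scored, zs, cov,
                                  covariates = c("monthly_income",
                                                 "pre_lacteal_feeding",
                                                 "age_at_cf_months",
                                                 "marital_status_married"),
                                  interactions = c("residence", "monthly_income")) {
  dat <- merge(scored$scores[, c("child_id", "total", "tertile")], zs,
               by = "child_id")
  dat <- merge(dat, cov, by = "child_id", all.x = TRUE)
  out <- list()

  by_tert <- function(z) {
    keep <- !is.na(dat[[z]])
    split(dat[[z]][keep], dat$tertile[keep], drop = FALSE)
  }
  for (z in c("wlz", "waz", "laz")) {
    groups <- Filter(function(g) length(g) >= 2, by_tert(z))
    out$anova[[z]] <- if (length(groups) >= 2) oneway_anova(groups) else NULL
    out$levene[[z]] <- if (length(groups) >= 2) variance_homogeneity(groups) else NULL
  }

  if ("residence" %in% names(dat)) {
    u <- dat$total[dat$residence == "urban" & !is.na(dat$residence)]
    r <- dat$total[dat$residence == "rural" & !is.na(dat$residence)]
    if (length(u) >= 2 && length(r) >= 2)
      out$urban_rural <- two_group_ttest(u, r)
    tt <- table(dat$residence, dat$tertile)
    if (all(dim(tt) >= 2) && all(rowSums(tt) > 0) && all(colSums(tt) > 0))
      out$tertile_by_residence <- contingency_test(as.matrix(tt))
  }

  preds <- intersect(covariates, names(dat))
  for (z in c("laz", "waz")) {
    pd <- dat[, c("total", preds), drop = FALSE]
    names(pd)[1] <- "cs_icfi"
    out$regression[[z]] <- tryCatch(standardized_ols(dat[[z]], pd),
                                    error = function(e) NULL)
  }

  mods <- list()
  if ("residence" %in% interactions && "residence" %in% names(dat))
    mods$residence <- as.integer(dat$residence == "urban")
  if ("monthly_income" %in% interactions && "monthly_income" %in% names(dat))
    mods$monthly_income <- dat$monthly_income
  if (length(mods))
    out$interactions <- suppressWarnings(
      interaction_screen(dat$laz, dat$total, as.data.frame(mods)))
  out
}

assoc_to_json <- function(assoc) {
  strip <- function(x) if (is.null(x)) NULL else unclass(x)
  list(
    anova = lapply(assoc$anova, strip),
    levene = lapply(assoc$levene, strip),
    urban_rural = strip(assoc$urban_rural),
    tertile_by_residence = strip(assoc$tertile_by_residence),
    regression = lapply(assoc$regression, strip),
    interactions = assoc$interactions
  )
}

render_report <- function(run) {
  o <- character()
  p <- function(...) o <<- c(o, sprintf(...))
  p("CS-ICFI analysis report")
  p("=======================")
  p("")
  n_acc <- nrow(run$cohort$feeding)
  n_rej <- sum(run$cohort$rejects$table == "feeding")
  p("Records read: %d | accepted: %d | rejected: %d (conservation: %s)",
    run$n_read, n_acc, n_rej, ifelse(run$n_read == n_acc + n_rej, "ok", "VIOLATED"))
  if (n_rej > 0)
    for (rsn in unique(run$cohort$rejects$reason[run$cohort$rejects$table == "feeding"]))
      p("  excluded (%s): %d", rsn,
        sum(run$cohort$rejects$reason == rsn & run$cohort$rejects$table == "feeding"))
  p("")
  p("Index summary (total, by age band)")
  s <- run$scored$summary
  for (i in seq_len(nrow(s)))
    p("  %-10s n=%4d  mean %.2f  sd %.2f  95%% CI [%.2f, %.2f]",
      s$stratum[i], s$n[i], s$mean[i], s$sd[i], s$ci_lower[i], s$ci_upper[i])
  tt <- table(run$scored$scores$tertile)
  p("Tertiles: low %d | medium %d | high %d (sum %d)",
    tt[["low"]], tt[["medium"]], tt[["high"]], sum(tt))
  p("")
  p("Internal consistency")
  for (st in run$reliability) {
    if (!is.null(st$error)) { p("  %-10s skipped: %s", st$stratum, st$error); next }
    p("  %-10s n=%4d  alpha %.3f (CI %.3f-%.3f)", st$stratum, st$n, st$alpha,
      st$alpha_ci[["lower"]], st$alpha_ci[["upper"]])
  }
  p("")
  p("Nutritional status")
  pv <- run$prevalence
  for (i in seq_len(nrow(pv)))
    p("  %-18s n=%4d  mean z %.2f  below -2: %d (%.1f%%)",
      pv$index[i], pv$n[i], pv$mean_z[i], pv$n_below[i], pv$prevalence_pct[i])
  p("")
  p("Association")
  for (z in names(run$association$anova)) {
    a <- run$association$anova[[z]]
    if (!is.null(a)) p("  ANOVA %s across tertiles: F = %.3f, p = %.4f",
                       toupper(z), a$statistic, a$p_value)
  }
  if (!is.null(run$association$urban_rural)) {
    ur <- run$association$urban_rural
    p("  Urban vs rural mean index: %.2f vs %.2f (t = %.3f, p = %.4f)",
      ur$groups$mean[1], ur$groups$mean[2], ur$statistic, ur$p_value)
  }
  for (z in names(run$association$regression)) {
    rg <- run$association$regression[[z]]
    if (is.null(rg)) next
    p("  Regression for %s (n = %d):", toupper(z), rg$n)
    cf <- rg$coefficients
    for (i in seq_len(nrow(cf)))
      p("    %-24s beta %7.3f  p %.4f", cf$predictor[i], cf$beta[i], cf$p_value[i])
  }
  if (!is.null(run$association$interactions)) {
    p("  Interaction screen (LAZ):")
    ia <- run$association$interactions
    for (i in seq_len(nrow(ia)))
      p("    index x %-16s beta %7.3f  p %.4f", ia$moderator[i],
        ia$interaction_beta[i], ia$p_value[i])
  }
  o
}

#' @export
print.icfi_run <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
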