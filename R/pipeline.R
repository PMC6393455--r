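# Config-driven end-to-end analysis: harmonize -> estimate -> scatter
# table -> heterogeneity/pleiotropy -> leave-one-out -> single-SNP ->
# threshold sweep / continuous outcome -> optional reverse direction.

#' Assemble an analysis configuration
#'
#' @param exposure,outcome [sumstats] sets or paths to canonical-dialect
#'   TSV files.  `outcome` may be omitted when `outcome_cohort` is given.
#' @param outcome_cohort Optional `synthetic_cohort` with an ordinal
#'   outcome; enables the threshold sweep and the continuous-outcome
#'   variant (per-SNP association scans are then computed internally).
#' @param thresholds Dichotomization thresholds to analyse: category
#'   labels and/or `"continuous"` (ordinal categories coded 0-3 and
#'   analysed with per-SNP least squares).  Ignored without
#'   `outcome_cohort`.
#' @param reverse Optional list with `exposure` and `outcome` sets (or
#'   paths) for the reverse causal direction.
#' @param methods,ivw_variant,n_boot,egger_distribution Estimator
#'   options, see [mr_estimate_all()].
#' @param seed Master seed; all randomness (the weighted-median
#'   bootstrap) flows from it.
#' @param palindrome_policy,eaf_window Passed to [harmonize()].
#' @param out_dir Optional directory for TSV/JSON outputs.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(exposure, outcome = NULL, outcome_cohort = NULL,
                            thresholds = "nearly_every_day", reverse = NULL,
                            methods = c("ivw", "weighted_median", "egger"),
                            ivw_variant = "fixed", n_boot = 5000,
                            egger_distribution = "normal", seed = 1,
                            palindrome_policy = "infer_by_eaf",
                            eaf_window = 0.08, out_dir = NULL) {
  if (is.null(outcome) && is.null(outcome_cohort)) {
    stop("either outcome summary statistics or an outcome cohort is required",
         call. = FALSE)
  }
  if (!is.null(outcome_cohort)) {
    valid <- c(fatigue_levels(), "continuous")
    bad <- setdiff(thresholds, valid)
    if (length(bad) > 0) {
      stop("unknown threshold(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(
    exposure = exposure, outcome = outcome, outcome_cohort = outcome_cohort,
    thresholds = thresholds, reverse = reverse, methods = methods,
    ivw_variant = ivw_variant, n_boot = n_boot,
    egger_distribution = egger_distribution, seed = seed,
    palindrome_policy = palindrome_policy, eaf_window = eaf_window,
    out_dir = out_dir
  ), class = "analysis_config")
}

resolve_sumstats <- function(x, label) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("config path does not exist: ", x, call. = FALSE)
    return(read_sumstats(x, study_label = label))
  }
  stopifnot(is.data.frame(x))
  x
}

#' Run the full MR analysis described by a configuration
#'
#' Executes every stage the configuration asks for: harmonization of
#' exposure and outcome statistics, the requested MR estimators per
#' dichotomization threshold (plus the continuous-outcome variant if
#' requested), Cochran's Q and the Egger intercept, leave-one-out and
#' single-SNP tables, the per-SNP scatter table (effect pairs with SEs
#' and per-method slopes/intercepts, the data behind a two-sample MR
#' scatter plot), and the reverse-direction analysis when configured.
#' All odds ratios are per 1-SD decrease in the exposure.  The run is
#' deterministic given the configuration's seed; when `out_dir` is set
#' the tables are also written as TSV and the report as JSON.
#'
#' @param config An [analysis_config()], or a path to a YAML file with
#'   the same fields.
#' @return A list of class `mr_run_report`: `estimates` (method x
#'   threshold), `heterogeneity`, `egger_intercept`, `leave_one_out`,
#'   `single_snp`, `scatter`, `harmonization`, `reverse` (or NULL),
#'   `provenance`.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    }
    config <- do.call(analysis_config, yaml::read_yaml(config))
  }
  stopifnot(inherits(config, "analysis_config"))

  exposure <- resolve_sumstats(config$exposure, "exposure")

  # One outcome summary-statistics set per analysed threshold.
  outcome_sets <- list()
  if (!is.null(config$outcome_cohort)) {
    for (thr in config$thresholds) {
      outcome_sets[[thr]] <- if (thr == "continuous") {
        gwas_continuous(config$outcome_cohort,
                        trait = as.integer(config$outcome_cohort$outcome_ordinal) - 1L)
      } else {
        gwas_logistic(config$outcome_cohort, dichotomize_at = thr)
      }
    }
  } else {
    outcome_sets[["primary"]] <-
      resolve_sumstats(config$outcome, "outcome")
  }

  primary_label <- names(outcome_sets)[1]
  estimates <- NULL
  harmonized <- list()
  for (thr in names(outcome_sets)) {
    h <- harmonize(exposure, outcome_sets[[thr]],
                   palindrome_policy = config$palindrome_policy,
                   eaf_window = config$eaf_window)
    harmonized[[thr]] <- h
    est <- mr_estimate_all(h, methods = config$methods,
                           ivw_variant = config$ivw_variant,
                           n_boot = config$n_boot, seed = config$seed,
                           egger_distribution = config$egger_distribution)
    estimates <- rbind(estimates, cbind(threshold = thr, est))
  }
  rownames(estimates) <- NULL

  h0 <- harmonized[[primary_label]]
  het <- cochran_q(h0)
  egger <- mr_egger(h0, distribution = config$egger_distribution)
  loo <- mr_leave_one_out(h0, method = "ivw",
                          ivw_variant = config$ivw_variant)
  single <- mr_single_snp(h0)

  ivw_fit <- mr_ivw(h0, variant = config$ivw_variant)
  scatter <- list(
    points = h0[, c("rsid", "beta_exposure", "se_exposure",
                    "beta_outcome", "se_outcome")],
    lines = data.frame(
      method = c(ivw_fit$method, "egger_slope"),
      slope = c(ivw_fit$beta, egger$slope$beta),
      intercept = c(0, egger$intercept)
    )
  )

  reverse <- NULL
  if (!is.null(config$reverse)) {
    rev_exp <- resolve_sumstats(config$reverse$exposure, "reverse exposure")
    rev_out <- resolve_sumstats(config$reverse$outcome, "reverse outcome")
    hr <- harmonize(rev_exp, rev_out,
                    palindrome_policy = config$palindrome_policy,
                    eaf_window = config$eaf_window)
    reverse <- list(
      harmonized = hr,
      estimates = mr_estimate_all(hr, methods = config$methods,
                                  ivw_variant = config$ivw_variant,
                                  n_boot = config$n_boot, seed = config$seed,
                                  egger_distribution = config$egger_distribution))
  }

  report <- structure(list(
    estimates = estimates,
    heterogeneity = het,
    egger_intercept = list(intercept = egger$intercept,
                           se = egger$intercept_se,
                           pvalue = egger$intercept_pvalue),
    leave_one_out = loo,
    single_snp = single,
    scatter = scatter,
    harmonization = attr(h0, "report"),
    harmonized = harmonized,
    reverse = reverse,
    provenance = list(
      package_version = as.character(utils::packageVersion("vitdmr")),
      seed = config$seed,
      methods = config$methods,
      ivw_variant = config$ivw_variant,
      thresholds = names(outcome_sets),
      n_instruments = nrow(h0)
    )
  ), class = "mr_run_report")

  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

write_run_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(report$estimates, "estimates.tsv")
  wt(report$leave_one_out, "loo.tsv")
  wt(report$single_snp, "single_snp.tsv")
  wt(report$scatter$points, "scatter.tsv")
  jsonlite::write_json(
    list(heterogeneity = unclass(report$heterogeneity),
         egger_intercept = report$egger_intercept,
         harmonization = unclass(report$harmonization),
         provenance = report$provenance),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.mr_run_report <- function(x, ...) {
  cat("Two-sample MR run\n\nEstimates (OR per 1-SD exposure decrease):\n")
  est <- x$estimates
  est$or_95ci <- sprintf("%.2f (%.2f-%.2f)", est$or, est$or_ci_low,
                         est$or_ci_high)
  print.data.frame(est[, c("threshold", "method", "or_95ci", "pvalue",
                           "n_snps")], digits = 3)
  cat("\n")
  print(x$heterogeneity)
  cat(sprintf("Egger intercept %.4g (SE %.4g, p = %.3g)\n",
              x$egger_intercept$intercept, x$egger_intercept$se,
              x$egger_intercept$pvalue))
  invisible(x)
}
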