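# Leave-one-out and single-SNP sensitivity analyses, bidirectional MR
# orchestration, and polygenic-score confounder checks.

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the causal effect omitting each instrument in turn, with
#' identical estimator settings across rows, to expose individually
#' influential SNPs (e.g. through horizontal pleiotropy).
#'
#' @param h Harmonized instrument set with >= 3 rows.
#' @param method `"ivw"` (default), `"weighted_median"` or `"egger"`.
#' @param ivw_variant,n_boot,seed,egger_distribution Estimator options,
#'   held fixed across omissions.
#' @return A data frame with one row per omitted SNP: `omitted_rsid`
#'   plus the `mr_estimate` columns.
#' @export
mr_leave_one_out <- function(h, method = c("ivw", "weighted_median", "egger"),
                             ivw_variant = "fixed", n_boot = 1000, seed = 1,
                             egger_distribution = "normal") {
  method <- match.arg(method)
  check_harmonized(h, 3L, "mr_leave_one_out")
  min_remaining <- if (method == "ivw") 2L else 3L
  if (nrow(h) - 1L < min_remaining) {
    stop("method '", method, "' needs at least ", min_remaining,
         " instruments after omission", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(h)), function(i) {
    sub <- h[-i, , drop = FALSE]
    est <- switch(method,
      ivw = mr_ivw(sub, variant = ivw_variant),
      weighted_median = mr_weighted_median(sub, n_boot = n_boot, seed = seed),
      egger = mr_egger(sub, distribution = egger_distribution)$slope)
    cbind(omitted_rsid = h$rsid[i], est)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Single-SNP (per-instrument) Wald ratios
#'
#' The forest of per-SNP causal estimates: each instrument's Wald ratio
#' with its confidence interval, in input order.  The IVW estimate is
#' the inverse-variance-weighted mean of these rows.
#'
#' @param h Harmonized instrument set with >= 1 row.
#' @return A data frame with one row per SNP: `rsid` plus `mr_estimate`
#'   columns.
#' @export
mr_single_snp <- function(h) {
  check_harmonized(h, 1L, "mr_single_snp")
  rows <- lapply(seq_len(nrow(h)), function(i) {
    cbind(rsid = h$rsid[i], wald_ratio(h[i, , drop = FALSE]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bidirectional two-sample MR
#'
#' Runs harmonization and the requested estimators in both causal
#' directions with independent instrument sets: the forward direction
#' instruments the exposure, the reverse direction instruments the
#' (former) outcome trait with its own genome-wide-significant SNPs.
#' Overlapping instrument sets between directions are flagged with a
#' warning (shared SNPs blur the interpretation of the two directions)
#' but tolerated.
#'
#' @param forward List with elements `exposure` and `outcome`
#'   ([sumstats] sets) for the forward direction.
#' @param reverse Same structure for the reverse direction.
#' @param methods,ivw_variant,n_boot,seed Passed to [mr_estimate_all()],
#'   identical in both directions.
#' @param palindrome_policy,eaf_window Passed to [harmonize()].
#' @return A list with elements `forward` and `reverse`, each containing
#'   `harmonized` and `estimates`.
#' @export
mr_bidirectional <- function(forward, reverse,
                             methods = c("ivw", "weighted_median", "egger"),
                             ivw_variant = "fixed", n_boot = 5000, seed = 1,
                             palindrome_policy = "infer_by_eaf",
                             eaf_window = 0.08) {
  stopifnot(is.list(forward), is.list(reverse),
            !is.null(forward$exposure), !is.null(forward$outcome),
            !is.null(reverse$exposure), !is.null(reverse$outcome))
  overlap <- intersect(forward$exposure$rsid, reverse$exposure$rsid)
  if (length(overlap) > 0) {
    warning("instrument sets overlap between directions: ",
            paste(overlap, collapse = ", "), call. = FALSE)
  }
  run_one <- function(pair) {
    h <- harmonize(pair$exposure, pair$outcome,
                   palindrome_policy = palindrome_policy,
                   eaf_window = eaf_window)
    list(harmonized = h,
         estimates = mr_estimate_all(h, methods = methods,
                                     ivw_variant = ivw_variant,
                                     n_boot = n_boot, seed = seed))
  }
  list(forward = run_one(forward), reverse = run_one(reverse))
}

#' Weighted polygenic score from allele dosages
#'
#' `score_i = sum_j weight_j * dosage_ij`.  With exposure-GWAS betas as
#' weights the score sits on the standardized log-exposure scale.  A
#' missing dosage makes the person's score missing unless
#' `impute_missing = TRUE`, in which case it is replaced by the SNP's
#' mean dosage.
#'
#' @param genotypes Person x SNP dosage matrix (values in \[0, 2\];
#'   columns named by rsid) or data frame.
#' @param weights Named numeric vector of per-SNP weights, or data frame
#'   with `rsid` and `beta` columns; names must be a subset of the
#'   genotype columns.
#' @param impute_missing Mean-impute missing dosages?
#' @return A data frame with `person_id` and `score`.
#' @export
build_prs <- function(genotypes, weights, impute_missing = FALSE) {
  g <- as.matrix(genotypes)
  if (is.data.frame(weights)) {
    weights <- stats::setNames(weights$beta, weights$rsid)
  }
  if (is.null(names(weights)) || is.null(colnames(g))) {
    stop("weights and genotype columns must both be named by rsid",
         call. = FALSE)
  }
  missing_snps <- setdiff(names(weights), colnames(g))
  if (length(missing_snps) > 0) {
    stop("weight rsid(s) absent from genotypes: ",
         paste(missing_snps, collapse = ", "), call. = FALSE)
  }
  g <- g[, names(weights), drop = FALSE]
  if (any(g < 0 | g > 2, na.rm = TRUE)) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  if (impute_missing && anyNA(g)) {
    for (j in seq_len(ncol(g))) {
      gj <- g[, j]
      gj[is.na(gj)] <- mean(gj, na.rm = TRUE)
      g[, j] <- gj
    }
  }
  score <- as.vector(g %*% weights)
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(g)))
  data.frame(person_id = ids, score = score, stringsAsFactors = FALSE)
}

#' Test a covariate for association with the polygenic score
#'
#' Ordinary least squares of the PRS on one covariate (dummy-coded when
#' categorical), reporting the overall model F-test p-value; for
#' categorical covariates the per-level score means and SDs are returned
#' as well (the tabular equivalent of a stratified boxplot).  A small
#' p-value indicates the genetic instrument is associated with the
#' putative confounder, threatening the MR exchangeability assumption.
#'
#' @param prs Output of [build_prs()] (or any data frame with `score`).
#' @param covariate Vector (factor/character = categorical, numeric =
#'   continuous) of the same length as the PRS.
#' @return A list of class `confounder_check`: `covariate_type`,
#'   `model_pvalue`, `f_statistic`, `df`, and `group_means` (categorical
#'   only).
#' @export
confounder_check <- function(prs, covariate) {
  score <- prs$score
  stopifnot(!is.null(score))
  if (length(covariate) != length(score)) {
    stop("covariate length must equal the number of scores", call. = FALSE)
  }
  keep <- !is.na(score) & !is.na(covariate)
  score <- score[keep]; covariate <- covariate[keep]
  categorical <- is.factor(covariate) || is.character(covariate) ||
    is.logical(covariate)
  if (categorical) {
    covariate <- factor(covariate)
    covariate <- droplevels(covariate)
    if (nlevels(covariate) < 2) {
      stop("categorical covariate needs at least 2 levels", call. = FALSE)
    }
  }
  fit <- stats::lm(score ~ covariate)
  fstat <- summary(fit)$fstatistic
  pvalue <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  group_means <- NULL
  if (categorical) {
    group_means <- do.call(rbind, lapply(levels(covariate), function(l) {
      s <- score[covariate == l]
      data.frame(level = l, n = length(s), mean = mean(s), sd = stats::sd(s),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(
    covariate_type = if (categorical) "categorical" else "continuous",
    model_pvalue = unname(pvalue),
    f_statistic = unname(fstat[1]),
    df = unname(fstat[2:3]),
    group_means = group_means
  ), class = "confounder_check")
}

#' @export
print.confounder_check <- function(x, ...) {
  cat(sprintf("PRS ~ %s covariate: F = %.3f on %d/%d df, p = %.3g\n",
              x$covariate_type, x$f_statistic, x$df[1], x$df[2],
              x$model_pvalue))
  if (!is.null(x$group_means)) print.data.frame(x$group_means)
  invisible(x)
}
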