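# Two-sample MR estimators on a harmonized instrument set.
#
# All estimates are on the log-odds scale per 1-SD decrease in the
# exposure (the harmonized orientation); `or` columns exponentiate.
# P-values are two-sided throughout.

new_mr_estimate <- function(method, beta, se, n_snps, pvalue = NULL,
                            level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci_low <- beta - z * se
  ci_high <- beta + z * se
  if (is.null(pvalue)) pvalue <- 2 * stats::pnorm(-abs(beta / se))
  structure(data.frame(
    method = method, beta = beta, se = se,
    ci_low = ci_low, ci_high = ci_high, pvalue = pvalue,
    n_snps = as.integer(n_snps),
    or = exp(beta), or_ci_low = exp(ci_low), or_ci_high = exp(ci_high),
    stringsAsFactors = FALSE
  ), class = c("mr_estimate", "data.frame"))
}

check_harmonized <- function(h, min_snps = 1L, caller = "estimator") {
  stopifnot(is.data.frame(h))
  needed <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  missing_cols <- setdiff(needed, names(h))
  if (length(missing_cols) > 0) {
    stop(caller, ": harmonized set lacks column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(h) < min_snps) {
    extra <- if (min_snps == 2L) " (use wald_ratio for a single instrument)" else ""
    stop(caller, " requires at least ", min_snps, " instrument(s)", extra,
         call. = FALSE)
  }
  if (any(h$se_outcome <= 0) || any(h$se_exposure <= 0)) {
    stop(caller, ": standard errors must be > 0", call. = FALSE)
  }
  invisible(h)
}

#' Wald ratio for a single instrument
#'
#' The per-SNP causal estimate: the SNP-outcome effect divided by the
#' SNP-exposure effect, with the first-order delta-method standard error
#' `se_outcome / |beta_exposure|` (exposure-side uncertainty enters only
#' at second order and is ignored, the usual two-sample MR convention).
#'
#' @param snp One row of a harmonized instrument set.
#' @return An `mr_estimate` row with method `"wald_ratio"`.
#' @export
wald_ratio <- function(snp) {
  check_harmonized(snp, 1L, "wald_ratio")
  if (nrow(snp) != 1) stop("wald_ratio takes a single instrument", call. = FALSE)
  if (snp$beta_exposure == 0) {
    stop("wald_ratio undefined: beta_exposure is zero", call. = FALSE)
  }
  beta <- snp$beta_outcome / snp$beta_exposure
  se <- snp$se_outcome / abs(snp$beta_exposure)
  new_mr_estimate("wald_ratio", beta, se, 1L)
}

mr_weights <- function(h) h$beta_exposure^2 / h$se_outcome^2

#' Inverse-variance-weighted MR estimate
#'
#' The IVW estimate is the inverse-variance-weighted mean of the per-SNP
#' Wald ratios, with weights `beta_exposure^2 / se_outcome^2`.  It is
#' algebraically the slope of the weighted through-origin regression of
#' `beta_outcome` on `beta_exposure` with weights `1/se_outcome^2`.
#' The fixed-effect variant uses `se = (sum w)^(-1/2)`; the
#' multiplicative-random-effects variant scales that SE by the residual
#' standard deviation of the through-origin regression, floored at 1, so
#' it never reports less uncertainty than the fixed-effect model.
#'
#' @param h Harmonized instrument set with >= 2 rows.
#' @param variant `"fixed"` (default) or `"multiplicative_random"`.
#' @return An `mr_estimate` row.
#' @export
mr_ivw <- function(h, variant = c("fixed", "multiplicative_random")) {
  variant <- match.arg(variant)
  check_harmonized(h, 2L, "mr_ivw")
  w <- mr_weights(h)
  r <- h$beta_outcome / h$beta_exposure
  beta <- sum(w * r) / sum(w)
  se <- 1 / sqrt(sum(w))
  if (variant == "multiplicative_random") {
    sigma2 <- sum(w * (r - beta)^2) / (nrow(h) - 1)
    se <- se * max(1, sqrt(sigma2))
  }
  new_mr_estimate(if (variant == "fixed") "ivw_fixed" else "ivw_mre",
                  beta, se, nrow(h))
}

#' MR-Egger regression
#'
#' Weighted linear regression of `beta_outcome` on `beta_exposure` with
#' an intercept, weights `1/se_outcome^2`, on the decreasing-allele
#' orientation (all `beta_exposure > 0`).  The slope is a pleiotropy-
#' robust causal estimate under the InSIDE assumption; the intercept
#' estimates the average directional pleiotropic effect and is zero when
#' no unbalanced horizontal pleiotropy is present.  Coefficient SEs use
#' the weighted-least-squares residual standard deviation floored at 1
#' (never tighter than the purely sampling-based SE); inference uses the
#' normal reference distribution by default, with Student t on k-2
#' degrees of freedom as an option.
#'
#' @param h Harmonized instrument set with >= 3 rows.
#' @param distribution `"normal"` (default) or `"t"`.
#' @return A list of class `mr_egger_result`: `slope` (an `mr_estimate`
#'   with method `"egger_slope"`), `intercept`, `intercept_se`,
#'   `intercept_pvalue`, `residual_sd`, `distribution`.
#' @export
mr_egger <- function(h, distribution = c("normal", "t")) {
  distribution <- match.arg(distribution)
  check_harmonized(h, 3L, "mr_egger")
  if (any(h$beta_exposure <= 0)) {
    stop("mr_egger requires the decreasing-allele orientation ",
         "(all beta_exposure > 0); run harmonize() first", call. = FALSE)
  }
  w <- 1 / h$se_outcome^2
  fit <- stats::lm(beta_outcome ~ beta_exposure, data = h, weights = w)
  coefs <- summary(fit)$coefficients
  sigma <- summary(fit)$sigma
  infl <- 1 / min(1, sigma)  # floor the residual sd at 1
  b <- coefs["beta_exposure", "Estimate"]
  se_b <- coefs["beta_exposure", "Std. Error"] * infl
  a <- coefs["(Intercept)", "Estimate"]
  se_a <- coefs["(Intercept)", "Std. Error"] * infl
  k <- nrow(h)
  pfun <- if (distribution == "normal") {
    function(est, se) 2 * stats::pnorm(-abs(est / se))
  } else {
    function(est, se) 2 * stats::pt(-abs(est / se), df = k - 2)
  }
  slope <- new_mr_estimate("egger_slope", b, se_b, k, pvalue = pfun(b, se_b))
  structure(list(
    slope = slope,
    intercept = a,
    intercept_se = se_a,
    intercept_pvalue = pfun(a, se_a),
    residual_sd = sigma,
    distribution = distribution
  ), class = "mr_egger_result")
}

#' @export
print.mr_egger_result <- function(x, ...) {
  cat("MR-Egger regression\n")
  print.data.frame(x$slope)
  cat(sprintf("  intercept %.4g (SE %.4g, p = %.3g, %s reference)\n",
              x$intercept, x$intercept_se, x$intercept_pvalue,
              x$distribution))
  invisible(x)
}

# Bowden-style weighted median of ratio estimates.
weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  wn <- weights[ord] / sum(weights)
  p <- cumsum(wn) - wn / 2
  if (p[1] >= 0.5) return(r[1])
  if (p[length(p)] <= 0.5) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median MR estimate
#'
#' The 50% point of the weighted empirical distribution of the per-SNP
#' Wald ratios (weights `beta_exposure^2 / se_outcome^2`, cumulative
#' midpoint interpolation).  Consistent when instruments carrying at
#' least half the weight are valid.  The SE comes from a parametric
#' bootstrap: exposure and outcome betas are resampled from normal
#' distributions centred on the observed values with the reported SEs,
#' the weighted median is recomputed, and the SD across resamples is the
#' SE.
#'
#' @param h Harmonized instrument set with >= 3 rows.
#' @param n_boot Bootstrap replicates, >= 100 (default 5000).
#' @param seed Integer seed for the bootstrap (required, so results are
#'   reproducible).
#' @return An `mr_estimate` row with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(h, n_boot = 5000, seed) {
  check_harmonized(h, 3L, "mr_weighted_median")
  if (n_boot < 100) stop("n_boot must be >= 100 for a stable bootstrap SE",
                         call. = FALSE)
  if (missing(seed)) stop("a bootstrap seed is required", call. = FALSE)
  est <- weighted_median_point(h$beta_outcome / h$beta_exposure, mr_weights(h))
  k <- nrow(h)
  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(k, h$beta_exposure, h$se_exposure)
      by <- stats::rnorm(k, h$beta_outcome, h$se_outcome)
      weighted_median_point(by / bx, bx^2 / h$se_outcome^2)
    }, numeric(1))
  })
  new_mr_estimate("weighted_median", est, stats::sd(boot), k)
}

#' Cochran's Q heterogeneity across instruments
#'
#' `Q = sum w_j (r_j - reference_beta)^2` over the per-SNP Wald ratios
#' with IVW weights, on k-1 degrees of freedom; the p-value is the
#' chi-square upper tail.  `i_squared = max(0, (Q - df)/Q) * 100` and
#' `tau_squared` is the DerSimonian-Laird moment estimate
#' `max(0, (Q - df) / (sum w - sum w^2 / sum w))`.  Large Q (small p)
#' indicates the per-SNP causal estimates are inconsistent, e.g. through
#' heterogeneous pleiotropy.
#'
#' @param h Harmonized instrument set with >= 2 rows.
#' @param reference_beta Pooled estimate the per-SNP ratios are compared
#'   against; defaults to the fixed-effect IVW estimate.
#' @return A list of class `heterogeneity_result`: `Q`, `df`, `pvalue`,
#'   `i_squared` (percent), `tau_squared`.
#' @export
cochran_q <- function(h, reference_beta = NULL) {
  check_harmonized(h, 2L, "cochran_q")
  w <- mr_weights(h)
  r <- h$beta_outcome / h$beta_exposure
  if (is.null(reference_beta)) reference_beta <- sum(w * r) / sum(w)
  Q <- sum(w * (r - reference_beta)^2)
  df <- nrow(h) - 1L
  structure(list(
    Q = Q,
    df = df,
    pvalue = stats::pchisq(Q, df, lower.tail = FALSE),
    i_squared = if (Q > 0) max(0, (Q - df) / Q) * 100 else 0,
    tau_squared = max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  ), class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f on %d df (p = %.3g), I^2 = %.1f%%, tau^2 = %.4g\n",
              x$Q, x$df, x$pvalue, x$i_squared, x$tau_squared))
  invisible(x)
}

#' Run several MR estimators on one instrument set
#'
#' Convenience wrapper returning one table row per requested method.
#'
#' @param h Harmonized instrument set.
#' @param methods Subset of `c("ivw", "weighted_median", "egger")`.
#' @param ivw_variant Passed to [mr_ivw()].
#' @param n_boot,seed Passed to [mr_weighted_median()].
#' @param egger_distribution Passed to [mr_egger()].
#' @return A data frame of `mr_estimate` rows.
#' @export
mr_estimate_all <- function(h, methods = c("ivw", "weighted_median", "egger"),
                            ivw_variant = "fixed", n_boot = 5000, seed = 1,
                            egger_distribution = "normal") {
  methods <- match.arg(methods, c("ivw", "weighted_median", "egger"),
                       several.ok = TRUE)
  rows <- lapply(methods, function(m) {
    switch(m,
      ivw = mr_ivw(h, variant = ivw_variant),
      weighted_median = mr_weighted_median(h, n_boot = n_boot, seed = seed),
      egger = mr_egger(h, distribution = egger_distribution)$slope)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
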