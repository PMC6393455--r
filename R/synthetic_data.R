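# Synthetic two-sample GWAS generator with known ground truth.
#
# Emulates the structure of a two-sample MR study of a standardized
# log-scale exposure (25OHD-like) on an ordinal/binary fatigue-like
# outcome: two disjoint cohorts, a small set of independent biallelic
# instruments jointly explaining ~5% of exposure variance (one dominant
# locus, as with GC for 25OHD), a 4-level ordinal outcome generated from
# a latent-logistic threshold model whose top category has ~6%
# prevalence, shared-confounder loadings, and optional per-SNP direct
# (pleiotropic) outcome effects.

#' Ordinal fatigue category labels, least to most frequent fatigue
#' @return Character vector of the four ordered category labels.
#' @export
fatigue_levels <- function() {
  c("not_at_all", "several_days", "more_than_half_days", "nearly_every_day")
}

#' Simulation configuration for the synthetic two-sample generator
#'
#' Defaults describe the emulated study conditions: 7 independent
#' biallelic SNPs jointly explaining 5% of the variance of a
#' standardized log-scale exposure, an outcome cohort whose 4-level
#' ordinal outcome has marginal category frequencies 47.31 / 40.98 /
#' 5.75 / 5.96 percent (top-category prevalence 0.0596), desk-scale
#' cohort sizes of 20,000 (exposure study) and 50,000 (outcome study),
#' and modest shared confounding.  `causal_beta` is the true effect of a
#' 1-SD *decrease* in the exposure on the outcome log-odds (the scale
#' every downstream MR estimate reports).  Per-SNP pleiotropic effects
#' are drawn from `N(pleiotropy_mean, pleiotropy_sd)` and applied per
#' exposure-decreasing allele, so a non-zero mean is directional in the
#' harmonized orientation.
#'
#' @param seed Integer seed; identical seed and configuration give
#'   bit-identical cohorts.
#' @param n_exposure,n_outcome Cohort sizes (disjoint samples).
#' @param n_snps Number of instruments (default 7).
#' @param maf_range Minor-allele-frequency range for the instruments.
#' @param target_r2 Exposure variance jointly explained by the
#'   instruments (default 0.05).
#' @param causal_beta True causal log-odds effect per 1-SD exposure
#'   decrease (default 0).
#' @param target_prevalence Top-category (case) proportion (default
#'   0.0596).
#' @param category_freqs Marginal frequencies of the four ordinal
#'   categories used to place the remaining latent thresholds.
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of per-SNP direct
#'   outcome effects (0, 0 = no pleiotropy).
#' @param confounder_effect_exposure,confounder_effect_outcome Loadings
#'   of a shared standard-normal confounder on the exposure (SD units)
#'   and on the outcome latent logit.
#' @param n_covariates Number of PC-like standard-normal nuisance
#'   covariates generated alongside sex and a centre-like factor.
#' @param snp_effect_weights Optional relative magnitudes of the per-SNP
#'   exposure effects (length `n_snps`); the default gives one dominant
#'   SNP carrying roughly a third of the explained variance.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_exposure = 20000,
                       n_outcome = 50000,
                       n_snps = 7,
                       maf_range = c(0.10, 0.45),
                       target_r2 = 0.05,
                       causal_beta = 0,
                       target_prevalence = 0.0596,
                       category_freqs = c(0.4731, 0.4098, 0.0575, 0.0596),
                       pleiotropy_mean = 0,
                       pleiotropy_sd = 0,
                       confounder_effect_exposure = 0.25,
                       confounder_effect_outcome = 0.25,
                       n_covariates = 3,
                       snp_effect_weights = NULL) {
  stopifnot(length(maf_range) == 2, maf_range[1] > 0, maf_range[2] < 0.5,
            maf_range[1] <= maf_range[2],
            target_r2 > 0, target_r2 < 1,
            target_prevalence > 0, target_prevalence < 1,
            length(category_freqs) == 4, all(category_freqs > 0),
            n_snps >= 1, n_exposure >= 10, n_outcome >= 10,
            pleiotropy_sd >= 0, n_covariates >= 0)
  if (target_r2 + confounder_effect_exposure^2 >= 1) {
    stop("infeasible configuration: target_r2 + confounder loading^2 ",
         "leaves no residual exposure variance", call. = FALSE)
  }
  if (is.null(snp_effect_weights)) {
    snp_effect_weights <- if (n_snps == 1) 1 else
      c(3, seq(1.2, 0.6, length.out = n_snps - 1))
  }
  stopifnot(length(snp_effect_weights) == n_snps, all(snp_effect_weights > 0))
  structure(list(
    seed = seed, n_exposure = n_exposure, n_outcome = n_outcome,
    n_snps = n_snps, maf_range = maf_range, target_r2 = target_r2,
    causal_beta = causal_beta, target_prevalence = target_prevalence,
    category_freqs = category_freqs / sum(category_freqs),
    pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
    confounder_effect_exposure = confounder_effect_exposure,
    confounder_effect_outcome = confounder_effect_outcome,
    n_covariates = n_covariates,
    snp_effect_weights = snp_effect_weights
  ), class = "sim_config")
}

# Non-palindromic allele pairs, sampled per SNP.
sample_allele_pairs <- function(k) {
  pairs <- rbind(c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
                 c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"))
  idx <- sample.int(nrow(pairs), k, replace = TRUE)
  pairs[idx, , drop = FALSE]
}

sim_genotypes <- function(n, maf) {
  k <- length(maf)
  g <- matrix(stats::rbinom(n * k, size = 2, prob = rep(maf, each = n)),
              nrow = n, ncol = k)
  g
}

sim_covariates <- function(n, n_covariates) {
  cov <- data.frame(
    sex = stats::rbinom(n, 1, 0.5),
    centre = factor(sample(paste0("centre_", 1:5), n, replace = TRUE))
  )
  if (n_covariates > 0) {
    pcs <- matrix(stats::rnorm(n * n_covariates), nrow = n)
    colnames(pcs) <- paste0("pc", seq_len(n_covariates))
    cov <- cbind(cov, as.data.frame(pcs))
  }
  cov
}

#' Simulate disjoint exposure and outcome cohorts with known truth
#'
#' Draws instrument frequencies, alleles and per-allele exposure effects
#' once (the per-SNP effects are scaled so the instruments jointly
#' explain `target_r2` of the exposure variance), then generates two
#' independent cohorts sharing those SNP parameters.  The exposure
#' cohort carries a continuous standardized exposure
#' `X = G + c_e U + e` with population variance 1; the outcome cohort
#' carries an ordinal outcome from a latent-logistic threshold model
#' with linear predictor
#' `eta = causal_beta * (-X) + sum_j delta_j g*_j + c_o U`
#' (`g*_j` the exposure-decreasing-allele dosage), whose intercepts
#' (thresholds) are solved numerically so the marginal category
#' frequencies match the configuration; in particular the top ("case")
#' category hits `target_prevalence`.  Dichotomizing at the top category
#' therefore yields an exactly logistic binary outcome.
#'
#' @param config A [sim_config()].
#' @return A list with elements `exposure` and `outcome`, each of class
#'   `synthetic_cohort`: `genotypes` (n x k dosage matrix, columns named
#'   by rsid), `exposure` (exposure cohort only), `outcome_ordinal`
#'   (ordered factor, outcome cohort only), `covariates`, `snp_info`
#'   (rsid, counted effect allele, other allele, maf), and `truth` (all
#'   generating parameters, including per-allele exposure effects and
#'   per-SNP pleiotropic effects).
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(as.integer(config$seed), {
    k <- config$n_snps
    maf <- stats::runif(k, config$maf_range[1], config$maf_range[2])
    alleles <- sample_allele_pairs(k)
    rsid <- sprintf("rs%07d", sample.int(9999999L, k))
    # Per-allele exposure effects: fixed relative magnitudes, random
    # signs (orientation to the decreasing allele is harmonize's job),
    # scaled so Var(G) = target_r2.
    sgn <- sample(c(-1, 1), k, replace = TRUE)
    var_geno <- 2 * maf * (1 - maf)
    scale <- sqrt(config$target_r2 / sum(config$snp_effect_weights^2 * var_geno))
    beta_snp <- sgn * config$snp_effect_weights * scale
    delta <- if (config$pleiotropy_sd == 0 && config$pleiotropy_mean == 0) {
      rep(0, k)
    } else {
      stats::rnorm(k, config$pleiotropy_mean, config$pleiotropy_sd)
    }

    ce <- config$confounder_effect_exposure
    co <- config$confounder_effect_outcome
    sd_noise <- sqrt(1 - config$target_r2 - ce^2)

    geno_mean <- sum(beta_snp * 2 * maf)  # centre the genetic value
    make_exposure_trait <- function(g, u) {
      as.vector(g %*% beta_snp) - geno_mean + ce * u +
        stats::rnorm(nrow(g), 0, sd_noise)
    }

    # --- exposure cohort ---
    g_x <- sim_genotypes(config$n_exposure, maf)
    colnames(g_x) <- rsid
    u_x <- stats::rnorm(config$n_exposure)
    x <- make_exposure_trait(g_x, u_x)
    cov_x <- sim_covariates(config$n_exposure, config$n_covariates)

    # --- outcome cohort (disjoint, independent draws) ---
    g_y <- sim_genotypes(config$n_outcome, maf)
    colnames(g_y) <- rsid
    u_y <- stats::rnorm(config$n_outcome)
    x_y <- make_exposure_trait(g_y, u_y)  # unobserved exposure analogue
    # Decreasing-allele dosage: the counted allele decreases the
    # exposure where beta_snp < 0, otherwise the other allele does.
    flip <- beta_snp > 0
    g_dec <- g_y
    g_dec[, flip] <- 2 - g_y[, flip, drop = FALSE]
    eta <- config$causal_beta * (-x_y) + as.vector(g_dec %*% delta) + co * u_y

    cum_targets <- c(
      sum(config$category_freqs[2:4]) -
        config$category_freqs[4] + config$target_prevalence,
      config$category_freqs[3] + config$target_prevalence,
      config$target_prevalence
    )
    thresholds <- vapply(cum_targets, function(p) {
      f <- function(t) mean(stats::plogis(eta - t)) - p
      lo <- min(eta) - 20; hi <- max(eta) + 20
      if (f(lo) < 0 || f(hi) > 0) {
        stop("infeasible prevalence/effect combination: cannot place a ",
             "latent threshold at cumulative probability ", signif(p, 4),
             call. = FALSE)
      }
      stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
    }, numeric(1))

    latent <- eta + stats::rlogis(config$n_outcome)
    cat_idx <- 1L + (latent > thresholds[1]) + (latent > thresholds[2]) +
      (latent > thresholds[3])
    outcome <- factor(fatigue_levels()[cat_idx], levels = fatigue_levels(),
                      ordered = TRUE)
    cov_y <- sim_covariates(config$n_outcome, config$n_covariates)

    snp_info <- data.frame(rsid = rsid, effect_allele = alleles[, 1],
                           other_allele = alleles[, 2], maf = maf,
                           stringsAsFactors = FALSE)
    truth <- list(config = config, maf = maf, rsid = rsid,
                  beta_snp = beta_snp, delta = delta,
                  thresholds = thresholds,
                  causal_beta = config$causal_beta)

    exposure_cohort <- structure(list(
      genotypes = g_x, exposure = x, outcome_ordinal = NULL,
      covariates = cov_x, snp_info = snp_info, truth = truth
    ), class = "synthetic_cohort")
    outcome_cohort <- structure(list(
      genotypes = g_y, exposure = NULL, outcome_ordinal = outcome,
      covariates = cov_y, snp_info = snp_info, truth = truth
    ), class = "synthetic_cohort")

    list(exposure = exposure_cohort, outcome = outcome_cohort)
  })
}

covariate_matrix <- function(cohort) {
  stats::model.matrix(~ ., data = cohort$covariates)[, -1, drop = FALSE]
}

#' Per-SNP linear-regression GWAS of a continuous trait
#'
#' Ordinary least squares of the trait on each SNP's dosage, optionally
#' adjusted for the cohort's covariates.  Monomorphic SNPs (no dosage
#' variation) have no defined effect and are dropped with a warning
#' naming them.
#'
#' @param cohort A `synthetic_cohort` with a continuous `exposure`.
#' @param covariates Adjust for sex, centre and PC-like covariates?
#' @param trait Optional trait vector overriding `cohort$exposure`
#'   (used for the continuous-outcome sensitivity analysis).
#' @return A [sumstats] set, one row per polymorphic SNP.
#' @export
gwas_continuous <- function(cohort, covariates = FALSE, trait = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  y <- if (is.null(trait)) cohort$exposure else trait
  if (is.null(y)) stop("cohort has no continuous trait", call. = FALSE)
  g <- cohort$genotypes
  stopifnot(length(y) == nrow(g))
  z <- if (covariates) covariate_matrix(cohort) else NULL
  k <- ncol(g)
  beta <- se <- pval <- numeric(k)
  mono <- logical(k)
  n <- nrow(g)
  for (j in seq_len(k)) {
    gj <- g[, j]
    if (stats::var(gj) == 0) { mono[j] <- TRUE; next }
    X <- if (is.null(z)) cbind(1, gj) else cbind(1, gj, z)
    fit <- stats::lm.fit(X, y)
    p <- ncol(X)
    resid_var <- sum(fit$residuals^2) / (n - p)
    R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
    xtx_inv <- chol2inv(R)
    beta[j] <- fit$coefficients[2]
    # an exactly collinear trait gives zero residual variance; keep the
    # SE strictly positive so the row remains a valid association
    se[j] <- max(sqrt(resid_var * xtx_inv[2, 2]), 1e-300)
    pval[j] <- 2 * stats::pt(-abs(beta[j] / se[j]), df = n - p)
  }
  if (any(mono)) {
    warning("monomorphic SNP(s) dropped: ",
            paste(cohort$snp_info$rsid[mono], collapse = ", "), call. = FALSE)
  }
  keep <- !mono
  info <- cohort$snp_info[keep, , drop = FALSE]
  sumstats(data.frame(
    rsid = info$rsid, effect_allele = info$effect_allele,
    other_allele = info$other_allele,
    eaf = colMeans(g[, keep, drop = FALSE]) / 2,
    beta = beta[keep], se = se[keep],
    pvalue = pmax(pval[keep], .Machine$double.xmin), n = n
  ), study_label = "synthetic continuous GWAS", trait = "exposure")
}

#' Per-SNP logistic-regression GWAS of the dichotomized ordinal outcome
#'
#' Dichotomizes the ordinal outcome at a category threshold (1 = at or
#' above the threshold) and fits a maximum-likelihood logistic
#' regression of case status on each SNP's dosage, optionally adjusted
#' for covariates, reporting Wald betas and SEs on the log-odds scale.
#' SNPs showing (quasi-)separation or non-convergence have no usable
#' Wald SE and are dropped with a warning naming them.
#'
#' @param cohort A `synthetic_cohort` with an ordinal outcome.
#' @param dichotomize_at Category at which to dichotomize (default the
#'   top category, `"nearly_every_day"`).
#' @param covariates Adjust for sex, centre and PC-like covariates?
#' @return A [sumstats] set, one row per usable SNP.
#' @export
gwas_logistic <- function(cohort, dichotomize_at = "nearly_every_day",
                          covariates = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (is.null(cohort$outcome_ordinal)) {
    stop("cohort has no ordinal outcome", call. = FALSE)
  }
  y <- dichotomize(cohort$outcome_ordinal, dichotomize_at)
  if (sum(y) == 0 || sum(y) == length(y)) {
    stop("dichotomization at '", dichotomize_at,
         "' leaves an empty outcome class", call. = FALSE)
  }
  g <- cohort$genotypes
  z <- if (covariates) covariate_matrix(cohort) else NULL
  k <- ncol(g)
  n <- nrow(g)
  beta <- se <- pval <- numeric(k)
  bad <- logical(k)
  fam <- stats::binomial()
  for (j in seq_len(k)) {
    gj <- g[, j]
    if (stats::var(gj) == 0) { bad[j] <- TRUE; next }
    X <- if (is.null(z)) cbind(1, gj) else cbind(1, gj, z)
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = fam,
                     control = stats::glm.control(epsilon = 1e-10,
                                                  maxit = 100)))
    p <- ncol(X)
    R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
    covmat <- tryCatch(chol2inv(R), error = function(e) NULL)
    bj <- fit$coefficients[2]
    sj <- if (is.null(covmat)) NA_real_ else sqrt(covmat[2, 2])
    if (!fit$converged || is.na(bj) || is.na(sj) || abs(bj) > 15 || sj > 50) {
      bad[j] <- TRUE; next  # separation or failed fit: no usable Wald SE
    }
    beta[j] <- bj; se[j] <- sj
    pval[j] <- 2 * stats::pnorm(-abs(bj / sj))
  }
  if (any(bad)) {
    warning("SNP(s) dropped (monomorphic, separated or non-converged): ",
            paste(cohort$snp_info$rsid[bad], collapse = ", "), call. = FALSE)
  }
  keep <- !bad
  info <- cohort$snp_info[keep, , drop = FALSE]
  sumstats(data.frame(
    rsid = info$rsid, effect_allele = info$effect_allele,
    other_allele = info$other_allele,
    eaf = colMeans(g[, keep, drop = FALSE]) / 2,
    beta = beta[keep], se = se[keep],
    pvalue = pmax(pval[keep], .Machine$double.xmin), n = n
  ), study_label = "synthetic case-control GWAS",
  trait = paste0("fatigue >= ", dichotomize_at))
}

#' Dichotomize an ordinal outcome at a category threshold
#'
#' Returns 1 for categories at or above the threshold, 0 below, along
#' with the full category frequency table (as an attribute `counts`) so
#' that alternative thresholds can be inspected.  Works on any ordered
#' factor; character input is interpreted on the canonical four fatigue
#' levels.
#'
#' @param outcome_ordinal Ordered factor (or character vector on the
#'   levels of [fatigue_levels()]).
#' @param threshold One of the factor's levels.
#' @return Integer 0/1 vector with attributes `counts` (named category
#'   counts), `proportion_case` (mean of the indicator) and
#'   `empty_case`/`empty_control` flags.
#' @export
dichotomize <- function(outcome_ordinal, threshold) {
  if (!is.factor(outcome_ordinal)) {
    bad <- setdiff(unique(outcome_ordinal), fatigue_levels())
    if (length(bad) > 0) {
      stop("unknown category label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    outcome_ordinal <- factor(outcome_ordinal, levels = fatigue_levels(),
                              ordered = TRUE)
  }
  levs <- levels(outcome_ordinal)
  if (!threshold %in% levs) {
    stop("unknown category label: ", threshold, call. = FALSE)
  }
  cut_at <- match(threshold, levs)
  y <- as.integer(as.integer(outcome_ordinal) >= cut_at)
  structure(y,
            counts = table(outcome_ordinal),
            proportion_case = mean(y),
            empty_case = sum(y) == 0,
            empty_control = all(y == 1))
}
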