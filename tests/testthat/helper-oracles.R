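# Independent oracles and fixture builders used across the test suite.
# Each oracle recomputes a quantity by a route different from the
# package implementation (matrix normal equations, explicit loops,
# Monte Carlo), so agreement is a genuine cross-check.

random_harmonized <- function(k = 7, seed = 1) {
  withr::with_seed(seed, {
    data.frame(
      rsid = sprintf("rs%06d", sample.int(999999, k)),
      effect_allele = sample(c("A", "G"), k, replace = TRUE),
      other_allele = "C",
      beta_exposure = runif(k, 0.02, 0.3),
      se_exposure = runif(k, 0.005, 0.03),
      beta_outcome = rnorm(k, 0, 0.05),
      se_outcome = runif(k, 0.01, 0.08),
      stringsAsFactors = FALSE
    )
  })
}

random_sumstats_df <- function(k = 50, seed = 1) {
  withr::with_seed(seed, {
    pairs <- expand.grid(a = c("A", "C", "G", "T"), b = c("A", "C", "G", "T"),
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$a != pairs$b, ]
    idx <- sample.int(nrow(pairs), k, replace = TRUE)
    data.frame(
      rsid = sprintf("rs%07d", sample.int(9999999, k)),
      effect_allele = pairs$a[idx],
      other_allele = pairs$b[idx],
      eaf = ifelse(runif(k) < 0.1, NA, runif(k, 0.01, 0.99)),
      beta = rnorm(k, 0, 0.1),
      se = runif(k, 1e-4, 0.1),
      pvalue = runif(k),
      n = sample.int(500000, k),
      stringsAsFactors = FALSE
    )
  })
}

# IVW as the slope of the weighted through-origin regression of outcome
# on exposure betas, weights 1/se_outcome^2 (algebraic identity route).
oracle_ivw_fixed <- function(h) {
  fit <- lm(beta_outcome ~ 0 + beta_exposure, data = h,
            weights = 1 / h$se_outcome^2)
  s <- summary(fit)
  beta <- unname(coef(fit)[1])
  # strip the residual-sd scaling to get the fixed-effect SE
  se <- unname(s$coefficients[1, 2]) / s$sigma
  list(beta = beta, se = se)
}

# MR-Egger via explicit weighted normal equations.
oracle_egger <- function(h) {
  X <- cbind(1, h$beta_exposure)
  W <- diag(1 / h$se_outcome^2)
  y <- h$beta_outcome
  XtWX <- t(X) %*% W %*% X
  coefs <- solve(XtWX, t(X) %*% W %*% y)
  resid <- y - X %*% coefs
  k <- nrow(h)
  sigma2 <- sum((resid^2) / h$se_outcome^2) / (k - 2)
  covm <- solve(XtWX) * max(1, sigma2)  # residual sd floored at 1
  list(intercept = coefs[1], slope = coefs[2],
       se_intercept = sqrt(covm[1, 1]), se_slope = sqrt(covm[2, 2]),
       sigma = sqrt(sigma2))
}

# Cochran's Q by an explicit loop.
oracle_q <- function(h, ref) {
  Q <- 0
  for (j in seq_len(nrow(h))) {
    w <- h$beta_exposure[j]^2 / h$se_outcome[j]^2
    r <- h$beta_outcome[j] / h$beta_exposure[j]
    Q <- Q + w * (r - ref)^2
  }
  Q
}

# DerSimonian-Laird meta-analysis, spelled out step by step.
oracle_dl_meta <- function(smd, se) {
  w <- 1 / se^2
  mu_f <- sum(w * smd) / sum(w)
  Q <- sum(w * (smd - mu_f)^2)
  df <- length(smd) - 1
  c_denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - df) / c_denom)
  w_re <- 1 / (se^2 + tau2)
  mu <- sum(w_re * smd) / sum(w_re)
  se_mu <- sqrt(1 / sum(w_re))
  list(pooled = mu, se = se_mu, Q = Q, tau2 = tau2,
       i2 = max(0, (Q - df) / Q) * 100,
       ci = mu + c(-1, 1) * qnorm(0.975) * se_mu)
}

# Logistic regression by hand-rolled Newton-Raphson (independent of
# stats::glm.fit's IRLS bookkeeping).
oracle_logistic <- function(X, y, tol = 1e-10, maxit = 50) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    grad <- t(X) %*% (y - mu)
    if (sqrt(sum(grad^2)) < tol) break
    H <- t(X) %*% (X * (mu * (1 - mu)))
    beta <- beta + as.vector(solve(H, grad))
  }
  # curvature at the converged estimate
  mu <- 1 / (1 + exp(-as.vector(X %*% beta)))
  H <- t(X) %*% (X * (mu * (1 - mu)))
  list(beta = beta, se = sqrt(diag(solve(H))))
}

# Present one underlying instrument in any of the 2^3 scrambles:
# exposure allele labels swapped, outcome allele labels swapped, and
# the overall sign of both studies' per-allele effects negated (i.e.
# the opposite allele is the exposure-decreasing one).
scrambled_pair <- function(truth, swap_exp, swap_out, negate) {
  ex_beta <- truth$ex_beta * (if (negate) -1 else 1)
  out_beta <- truth$out_beta * (if (negate) -1 else 1)
  exp_row <- data.frame(rsid = truth$rsid,
                        effect_allele = truth$a1, other_allele = truth$a2,
                        eaf = truth$eaf, beta = ex_beta, se = truth$ex_se,
                        pvalue = 1e-8, n = 10000,
                        stringsAsFactors = FALSE)
  out_row <- data.frame(rsid = truth$rsid,
                        effect_allele = truth$a1, other_allele = truth$a2,
                        eaf = truth$eaf, beta = out_beta, se = truth$out_se,
                        pvalue = 0.5, n = 50000,
                        stringsAsFactors = FALSE)
  swap <- function(row) {
    row[, c("effect_allele", "other_allele")] <-
      row[, c("other_allele", "effect_allele")]
    row$beta <- -row$beta
    row$eaf <- 1 - row$eaf
    row
  }
  if (swap_exp) exp_row <- swap(exp_row)
  if (swap_out) out_row <- swap(out_row)
  list(exposure = exp_row, outcome = out_row)
}
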