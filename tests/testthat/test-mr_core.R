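test_that("wald_ratio follows the definition and its delta-method SE holds up", {
  h <- random_harmonized(1, seed = 4)
  h$beta_exposure <- 0.5; h$beta_outcome <- 0.1; h$se_outcome <- 0.05
  est <- wald_ratio(h)
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.1)
  # null numerator
  h0 <- h; h0$beta_outcome <- 0
  expect_equal(wald_ratio(h0)$beta, 0)
  # undefined ratio
  hz <- h; hz$beta_exposure <- 0
  expect_error(wald_ratio(hz), "zero")
  # Monte-Carlo check of the first-order SE in the strong-instrument
  # regime (se_exposure / beta_exposure < 0.1)
  h$se_exposure <- 0.04
  mc <- withr::with_seed(99, {
    bx <- rnorm(1e5, h$beta_exposure, h$se_exposure)
    by <- rnorm(1e5, h$beta_outcome, h$se_outcome)
    sd(by / bx)
  })
  expect_equal(wald_ratio(h)$se, mc, tolerance = 0.05)
})

test_that("IVW equals hand-computed weighted means and the regression identity", {
  # two instruments, fully hand-computed
  h <- data.frame(rsid = c("a", "b"),
                  beta_exposure = c(0.2, 0.4), se_exposure = c(0.01, 0.01),
                  beta_outcome = c(0.03, 0.05), se_outcome = c(0.02, 0.04))
  w <- c(0.2^2 / 0.02^2, 0.4^2 / 0.04^2)
  r <- c(0.03 / 0.2, 0.05 / 0.4)
  est <- mr_ivw(h)
  expect_equal(est$beta, sum(w * r) / sum(w), tolerance = 1e-12)
  expect_equal(est$se, 1 / sqrt(sum(w)), tolerance = 1e-12)

  # degenerate consensus: all ratios equal
  hc <- random_harmonized(5, seed = 7)
  hc$beta_outcome <- 0.25 * hc$beta_exposure
  expect_equal(mr_ivw(hc)$beta, 0.25, tolerance = 1e-12)
  expect_equal(cochran_q(hc)$Q, 0, tolerance = 1e-18)

  # identity with the weighted through-origin regression, random sets
  for (seed in c(11, 12, 13)) {
    hr <- random_harmonized(7, seed = seed)
    o <- oracle_ivw_fixed(hr)
    est <- mr_ivw(hr)
    expect_equal(est$beta, o$beta, tolerance = 1e-10)
    expect_equal(est$se, o$se, tolerance = 1e-10)
  }
  expect_error(mr_ivw(h[1, ]), "wald_ratio")
})

test_that("multiplicative-random-effects IVW floors the scale at 1", {
  h <- random_harmonized(7, seed = 31)
  fixed <- mr_ivw(h, "fixed")
  mre <- mr_ivw(h, "multiplicative_random")
  expect_equal(fixed$beta, mre$beta)
  expect_gte(mre$se, fixed$se)
  # with Q/df <= 1 the two coincide
  hc <- h; hc$beta_outcome <- 0.1 * hc$beta_exposure
  expect_equal(mr_ivw(hc, "multiplicative_random")$se, mr_ivw(hc, "fixed")$se)
})

test_that("MR-Egger matches the weighted normal equations", {
  # noiseless line: exact intercept and slope
  h <- random_harmonized(6, seed = 17)
  h$beta_outcome <- 0.012 + 0.3 * h$beta_exposure
  eg <- mr_egger(h)
  expect_equal(eg$intercept, 0.012, tolerance = 1e-12)
  expect_equal(eg$slope$beta, 0.3, tolerance = 1e-12)
  # no-pleiotropy null: zero intercept
  h$beta_outcome <- 0.3 * h$beta_exposure
  expect_equal(mr_egger(h)$intercept, 0, tolerance = 1e-12)
  # random sets vs normal-equations oracle
  for (seed in c(23, 24, 25)) {
    hr <- random_harmonized(7, seed = seed)
    o <- oracle_egger(hr)
    eg <- mr_egger(hr)
    expect_equal(eg$slope$beta, o$slope, tolerance = 1e-10)
    expect_equal(eg$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(eg$slope$se, o$se_slope, tolerance = 1e-10)
    expect_equal(eg$intercept_se, o$se_intercept, tolerance = 1e-10)
  }
  expect_error(mr_egger(h[1:2, ]), "at least 3")
  # t reference gives larger p than normal for the same fit
  hr <- random_harmonized(7, seed = 26)
  expect_gte(mr_egger(hr, "t")$slope$pvalue,
             mr_egger(hr, "normal")$slope$pvalue)
})

test_that("weighted median interpolates the weighted CDF midpoints", {
  h <- data.frame(rsid = c("a", "b", "c"),
                  beta_exposure = c(0.1, 0.1, 0.1), se_exposure = rep(0.01, 3),
                  beta_outcome = c(0.01, 0.05, 0.02), se_outcome = rep(0.02, 3))
  est <- mr_weighted_median(h, n_boot = 200, seed = 1)
  expect_equal(est$beta, 0.02 / 0.1)  # equal weights: middle ratio

  # an instrument holding the central >50% of weight pins the estimate
  hw <- data.frame(rsid = c("a", "b", "c"),
                   beta_exposure = c(0.1, sqrt(0.6) * 0.1 / sqrt(0.2), 0.1),
                   se_exposure = rep(0.01, 3),
                   beta_outcome = NA, se_outcome = rep(0.02, 3))
  # ratios 0.1 < 0.3 < 0.5 with weights 0.2, 0.6, 0.2
  hw$beta_outcome <- c(0.1, 0.3, 0.5) * hw$beta_exposure
  est <- mr_weighted_median(hw, n_boot = 200, seed = 1)
  expect_equal(est$beta, 0.3)

  expect_error(mr_weighted_median(h, n_boot = 50, seed = 1), "n_boot")
  expect_error(mr_weighted_median(h, n_boot = 200), "seed")
})

test_that("the bootstrap SE is self-consistent across bootstrap sizes", {
  h <- random_harmonized(7, seed = 41)
  se1 <- mr_weighted_median(h, n_boot = 2000, seed = 5)$se
  se2 <- mr_weighted_median(h, n_boot = 20000, seed = 6)$se
  expect_lt(abs(se1 - se2) / se2, 0.10)
  # seeded: identical call, identical result
  expect_identical(mr_weighted_median(h, n_boot = 500, seed = 9)$se,
                   mr_weighted_median(h, n_boot = 500, seed = 9)$se)
})

test_that("Cochran's Q, I^2 and tau^2 follow their definitions", {
  h <- data.frame(rsid = c("a", "b"),
                  beta_exposure = c(0.2, 0.4), se_exposure = c(0.01, 0.01),
                  beta_outcome = c(0.06, 0.04), se_outcome = c(0.02, 0.04))
  ref <- mr_ivw(h)$beta
  het <- cochran_q(h)
  expect_equal(het$Q, oracle_q(h, ref), tolerance = 1e-12)
  expect_equal(het$df, 1L)
  expect_equal(het$pvalue, pchisq(het$Q, 1, lower.tail = FALSE))
  expect_equal(het$i_squared, max(0, (het$Q - 1) / het$Q) * 100)
  # identical ratios: no heterogeneity
  hc <- random_harmonized(4, seed = 51)
  hc$beta_outcome <- -0.1 * hc$beta_exposure
  het0 <- cochran_q(hc)
  expect_equal(het0$Q, 0, tolerance = 1e-20)
  expect_equal(het0$i_squared, 0)
  expect_equal(het0$tau_squared, 0)
  # random set against the loop oracle
  hr <- random_harmonized(7, seed = 52)
  expect_equal(cochran_q(hr)$Q, oracle_q(hr, mr_ivw(hr)$beta),
               tolerance = 1e-10)
})

test_that("estimators are order-equivariant and sign-equivariant", {
  h <- random_harmonized(7, seed = 61)
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  hp <- h[perm, ]
  expect_equal(mr_ivw(hp)$beta, mr_ivw(h)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(hp)$slope$beta, mr_egger(h)$slope$beta,
               tolerance = 1e-12)
  expect_equal(cochran_q(hp)$Q, cochran_q(h)$Q, tolerance = 1e-12)
  expect_equal(mr_weighted_median(hp, 200, seed = 3)$beta,
               mr_weighted_median(h, 200, seed = 3)$beta, tolerance = 1e-12)

  hn <- h; hn$beta_outcome <- -h$beta_outcome
  expect_equal(mr_ivw(hn)$beta, -mr_ivw(h)$beta, tolerance = 1e-12)
  expect_equal(mr_ivw(hn)$se, mr_ivw(h)$se, tolerance = 1e-12)
  expect_equal(mr_egger(hn)$slope$beta, -mr_egger(h)$slope$beta,
               tolerance = 1e-12)
  expect_equal(mr_egger(hn)$slope$se, mr_egger(h)$slope$se, tolerance = 1e-12)
  expect_equal(mr_weighted_median(hn, 200, seed = 3)$beta,
               -mr_weighted_median(h, 200, seed = 3)$beta, tolerance = 1e-12)
})

test_that("estimates expose a consistent odds-ratio scale", {
  h <- random_harmonized(7, seed = 71)
  est <- mr_ivw(h)
  expect_lt(est$ci_low, est$ci_high)
  expect_equal(est$or, exp(est$beta))
  expect_equal(est$or_ci_low, exp(est$ci_low))
  expect_equal(est$or_ci_high, exp(est$ci_high))
  tab <- mr_estimate_all(h, seed = 2, n_boot = 200)
  expect_equal(tab$method, c("ivw_fixed", "weighted_median", "egger_slope"))
})
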