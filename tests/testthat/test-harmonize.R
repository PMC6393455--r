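make_set <- function(rows, label = "s") {
  sumstats(do.call(rbind, rows), study_label = label)
}

test_that("allele matching and decreasing-allele orientation chain signs correctly", {
  # exposure A/G with beta -0.06 (A decreases the exposure); outcome
  # reported on effect allele G with beta +0.02.  Matching flips the
  # outcome to -0.02 on allele A; A is already the decreasing allele so
  # the orientation step only rewrites the exposure beta as a magnitude.
  exposure <- make_set(list(data.frame(
    rsid = "rs1", effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = -0.06, se = 0.01, pvalue = 1e-9, n = 1000)))
  outcome <- make_set(list(data.frame(
    rsid = "rs1", effect_allele = "G", other_allele = "A", eaf = 0.7,
    beta = 0.02, se = 0.03, pvalue = 0.5, n = 5000)))
  h <- harmonize(exposure, outcome)
  expect_equal(h$effect_allele, "A")
  expect_equal(h$beta_exposure, 0.06)
  expect_equal(h$beta_outcome, -0.02)
  expect_equal(attr(h, "report")$n_flipped, 1L)

  # already oriented to the decreasing allele: identity, nothing flipped
  h2 <- harmonize(
    make_set(list(data.frame(
      rsid = "rs1", effect_allele = "A", other_allele = "G", eaf = 0.3,
      beta = -0.06, se = 0.01, pvalue = 1e-9, n = 1000))),
    make_set(list(data.frame(
      rsid = "rs1", effect_allele = "A", other_allele = "G", eaf = 0.3,
      beta = -0.02, se = 0.03, pvalue = 0.5, n = 5000))))
  expect_equal(h2$effect_allele, "A")
  expect_equal(h2$beta_exposure, 0.06)
  expect_equal(h2$beta_outcome, -0.02)
  expect_equal(attr(h2, "report")$n_flipped, 0L)
})

test_that("harmonization recovers the truth under all 8 per-SNP scrambles", {
  truth <- list(rsid = "rs42", a1 = "A", a2 = "G", eaf = 0.3,
                ex_beta = -0.08, ex_se = 0.01, out_beta = 0.025,
                out_se = 0.03)
  expected_ratio <- -truth$out_beta / truth$ex_beta
  for (swap_exp in c(FALSE, TRUE)) {
    for (swap_out in c(FALSE, TRUE)) {
      for (negate in c(FALSE, TRUE)) {
        pair <- scrambled_pair(truth, swap_exp, swap_out, negate)
        h <- harmonize(sumstats(pair$exposure), sumstats(pair$outcome))
        expect_equal(nrow(h), 1)
        expect_equal(h$beta_exposure, abs(truth$ex_beta))
        expect_equal(h$beta_outcome / h$beta_exposure, expected_ratio)
        expect_true(h$effect_allele %in% c(truth$a1, truth$a2))
      }
    }
  }
})

test_that("the product beta_exposure * beta_outcome is flip-invariant", {
  withr::with_seed(3, {
    for (i in 1:20) {
      truth <- list(rsid = "rsX", a1 = "T", a2 = "C", eaf = runif(1, .05, .95),
                    ex_beta = rnorm(1, 0, 0.1), ex_se = 0.01,
                    out_beta = rnorm(1, 0, 0.05), out_se = 0.02)
      if (abs(truth$ex_beta) < 1e-4) next
      prods <- c()
      for (se in c(FALSE, TRUE)) for (so in c(FALSE, TRUE)) {
        pair <- scrambled_pair(truth, se, so, negate = FALSE)
        h <- harmonize(sumstats(pair$exposure), sumstats(pair$outcome))
        prods <- c(prods, h$beta_exposure * h$beta_outcome)
      }
      expect_equal(max(prods) - min(prods), 0, tolerance = 1e-14)
    }
  })
})

test_that("harmonization is idempotent", {
  exposure <- sumstats(random_sumstats_df(k = 10, seed = 21))
  outcome0 <- random_sumstats_df(k = 10, seed = 22)
  outcome0$rsid <- exposure$rsid
  outcome0$effect_allele <- exposure$effect_allele
  outcome0$other_allele <- exposure$other_allele
  outcome <- sumstats(outcome0)
  h1 <- harmonize(exposure, outcome)
  # re-present the harmonized set as exposure/outcome studies
  exp2 <- sumstats(data.frame(
    rsid = h1$rsid, effect_allele = h1$effect_allele,
    other_allele = h1$other_allele, eaf = h1$eaf_exposure,
    beta = -h1$beta_exposure, se = h1$se_exposure, pvalue = 1e-8,
    n = 1000))
  out2 <- sumstats(data.frame(
    rsid = h1$rsid, effect_allele = h1$effect_allele,
    other_allele = h1$other_allele, eaf = h1$eaf_outcome,
    beta = h1$beta_outcome, se = h1$se_outcome, pvalue = 0.5, n = 1000))
  h2 <- harmonize(exp2, out2)
  expect_equal(h2$beta_exposure, h1$beta_exposure)
  expect_equal(h2$beta_outcome, h1$beta_outcome)
  expect_equal(h2$effect_allele, h1$effect_allele)
  expect_equal(attr(h2, "report")$n_flipped, 0L)
})

test_that("mismatched allele pairs are dropped and reported", {
  exposure <- make_set(list(data.frame(
    rsid = "rs1", effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = -0.06, se = 0.01, pvalue = 1e-9, n = 1000)))
  outcome <- make_set(list(data.frame(
    rsid = "rs1", effect_allele = "A", other_allele = "C", eaf = 0.3,
    beta = 0.02, se = 0.03, pvalue = 0.5, n = 5000)))
  h0 <- harmonize(exposure, outcome)
  expect_equal(nrow(h0), 0)
  expect_equal(attr(h0, "report")$n_dropped_unmatched, 1L)
  # with a second, matching SNP the mismatch is dropped, not fatal
  exposure2 <- make_set(list(
    data.frame(rsid = "rs1", effect_allele = "A", other_allele = "G",
               eaf = 0.3, beta = -0.06, se = 0.01, pvalue = 1e-9, n = 1000),
    data.frame(rsid = "rs2", effect_allele = "T", other_allele = "C",
               eaf = 0.2, beta = -0.03, se = 0.01, pvalue = 1e-9, n = 1000)))
  outcome2 <- make_set(list(
    data.frame(rsid = "rs1", effect_allele = "A", other_allele = "C",
               eaf = 0.3, beta = 0.02, se = 0.03, pvalue = 0.5, n = 5000),
    data.frame(rsid = "rs2", effect_allele = "T", other_allele = "C",
               eaf = 0.2, beta = 0.01, se = 0.03, pvalue = 0.5, n = 5000)))
  h <- harmonize(exposure2, outcome2)
  rep <- attr(h, "report")
  expect_equal(nrow(h), 1)
  expect_equal(rep$n_dropped_unmatched, 1L)
  expect_equal(rep$dropped_rsids, "rs1")
  expect_equal(rep$n_input, rep$n_retained + length(rep$dropped_rsids))
})

test_that("palindromic SNPs follow the configured policy", {
  pal_exp <- function(eaf) make_set(list(data.frame(
    rsid = "rs9", effect_allele = "A", other_allele = "T", eaf = eaf,
    beta = -0.05, se = 0.01, pvalue = 1e-9, n = 1000)))
  pal_out <- function(eaf, beta = 0.02) make_set(list(data.frame(
    rsid = "rs9", effect_allele = "A", other_allele = "T", eaf = eaf,
    beta = beta, se = 0.03, pvalue = 0.5, n = 5000)))

  expect_no_warning(h <- harmonize(pal_exp(0.2), pal_out(0.2),
                                   palindrome_policy = "drop"))
  expect_equal(nrow(h), 0)
  expect_equal(attr(h, "report")$n_dropped_palindromic, 1L)

  # concordant frequencies: keep, no strand flip
  h <- harmonize(pal_exp(0.2), pal_out(0.2))
  expect_equal(nrow(h), 1)
  expect_equal(h$beta_outcome, 0.02)
  # discordant frequencies: strand flip
  h <- harmonize(pal_exp(0.2), pal_out(0.8))
  expect_equal(h$beta_outcome, -0.02)
  # ambiguous frequency near 0.5, or missing: dropped
  expect_equal(nrow(harmonize(pal_exp(0.2), pal_out(0.5))), 0)
  expect_equal(nrow(harmonize(pal_exp(NA), pal_out(0.2))), 0)
})

test_that("rescale_external_beta matches the closed-form slope", {
  target <- data.frame(rsid = "rsT", beta = 0.10, se = 0.02)
  src <- data.frame(rsid = paste0("rs", 1:4), beta = c(0.05, 0.1, -0.02, 0.08))
  ref <- src; ref$beta <- 2 * src$beta
  out <- rescale_external_beta(target, src, ref)
  expect_equal(out$beta, 0.20)
  expect_equal(out$se, 0.04)
  # slope 1 when reference equals source
  out1 <- rescale_external_beta(target, src, src)
  expect_equal(out1$beta, target$beta)
  expect_equal(out1$se, target$se)
  # noisy case against independent sum-based slope, z-score preserved
  withr::with_seed(8, {
    src2 <- data.frame(rsid = paste0("rs", 1:6), beta = rnorm(6, 0, 0.1))
    ref2 <- src2
    ref2$beta <- 1.7 * src2$beta + rnorm(6, 0, 0.01)
  })
  slope <- sum(src2$beta * ref2$beta) / sum(src2$beta^2)
  out2 <- rescale_external_beta(target, src2, ref2)
  expect_equal(out2$beta, target$beta * slope, tolerance = 1e-12)
  expect_equal(out2$se, target$se * slope, tolerance = 1e-12)
  expect_equal(out2$beta / out2$se, target$beta / target$se,
               tolerance = 1e-12)
  # error cases
  expect_error(rescale_external_beta(target, src[1, ], ref[1, ]),
               "at least 2")
  zero <- src; zero$beta <- 0
  expect_error(rescale_external_beta(target, zero, ref), "zero")
})
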