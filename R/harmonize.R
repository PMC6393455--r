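# Effect-allele harmonization for two-sample MR.
#
# Orientation convention: after matching outcome alleles to the exposure
# study, every instrument is re-oriented so its effect allele is the
# exposure-DECREASING allele.  beta_exposure is stored as the positive
# magnitude of the per-allele decrease, so downstream MR slopes read as
# log-odds per 1-SD *decrease* in the exposure.

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome study's effect alleles to the exposure study's,
#' then orients every instrument to the exposure-decreasing allele.  For
#' each SNP present in both sets: if the outcome's effect allele equals
#' the exposure's other allele, the outcome beta is sign-flipped (and its
#' eaf complemented); SNPs whose unordered allele pairs disagree are
#' dropped and reported.  Palindromic SNPs (A/T, C/G) are strand
#' ambiguous: under `"drop"` they are removed; under `"infer_by_eaf"`
#' the strand is resolved by comparing effect-allele frequencies, and
#' SNPs with a missing eaf in either study, or with either eaf within
#' `eaf_window` of 0.5, are dropped as unresolvable.
#'
#' Finally, any instrument whose (matched) exposure beta is positive has
#' its alleles swapped so the effect allele is the decreasing one;
#' `beta_exposure` in the result is always > 0, on the per-decreasing-
#' allele scale, and `beta_outcome` is negated whenever that swap occurs.
#'
#' @param exposure,outcome [sumstats] sets; instruments are the
#'   intersection of their rsids.
#' @param palindrome_policy `"infer_by_eaf"` (default) or `"drop"`.
#' @param eaf_window Half-width of the ambiguity zone around eaf 0.5
#'   within which palindromic SNPs cannot be strand-resolved (default
#'   0.08, i.e. eaf in 0.42-0.58 is ambiguous).
#' @return A data frame of class `mr_harmonized` with columns `rsid`,
#'   `effect_allele`, `other_allele`, `beta_exposure`, `se_exposure`,
#'   `eaf_exposure`, `beta_outcome`, `se_outcome`, `eaf_outcome`, plus a
#'   `report` attribute (class `harmonization_report`) with counts of
#'   flipped and dropped SNPs.
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("infer_by_eaf", "drop"),
                      eaf_window = 0.08) {
  stopifnot(inherits(exposure, "sumstats") || is.data.frame(exposure),
            inherits(outcome, "sumstats") || is.data.frame(outcome))
  palindrome_policy <- match.arg(palindrome_policy)
  if (nrow(exposure) == 0 || nrow(outcome) == 0) {
    stop("both summary-statistics sets must be non-empty", call. = FALSE)
  }

  shared <- intersect(exposure$rsid, outcome$rsid)
  if (length(shared) == 0) stop("no shared rsids between studies", call. = FALSE)
  exp_df <- as.data.frame(exposure)[match(shared, exposure$rsid), ]
  out_df <- as.data.frame(outcome)[match(shared, outcome$rsid), ]

  k <- length(shared)
  keep <- rep(TRUE, k)
  drop_reason <- rep(NA_character_, k)
  n_flipped <- 0L

  beta_out <- out_df$beta
  eaf_out <- out_df$eaf

  for (j in seq_len(k)) {
    ea_x <- exp_df$effect_allele[j]; oa_x <- exp_df$other_allele[j]
    ea_y <- out_df$effect_allele[j]; oa_y <- out_df$other_allele[j]
    same <- (ea_y == ea_x && oa_y == oa_x)
    swapped <- (ea_y == oa_x && oa_y == ea_x)
    if (!same && !swapped) {
      keep[j] <- FALSE; drop_reason[j] <- "allele_mismatch"; next
    }
    pal <- is_palindromic(ea_x, oa_x)
    if (pal && palindrome_policy == "drop") {
      keep[j] <- FALSE; drop_reason[j] <- "palindromic"; next
    }
    # Align the outcome to the exposure's allele labels.
    if (swapped) {
      beta_out[j] <- -beta_out[j]
      if (!is.na(eaf_out[j])) eaf_out[j] <- 1 - eaf_out[j]
      n_flipped <- n_flipped + 1L
    }
    if (pal) {
      # Labels cannot distinguish strands for a palindromic pair, so the
      # label alignment above may silently be a strand flip.  Resolve by
      # frequency: concordant effect-allele frequencies (same side of
      # 0.5) mean the alignment is right; discordant means the outcome
      # is on the opposite strand and the sign must be flipped back.
      fx <- exp_df$eaf[j]
      fy <- eaf_out[j]
      if (is.na(fx) || is.na(fy) ||
          abs(fx - 0.5) < eaf_window || abs(fy - 0.5) < eaf_window) {
        keep[j] <- FALSE; drop_reason[j] <- "palindromic_ambiguous"; next
      }
      if ((fx < 0.5) != (fy < 0.5)) {
        beta_out[j] <- -beta_out[j]
        eaf_out[j] <- 1 - fy
        n_flipped <- n_flipped + 1L
      }
    }
  }

  h <- data.frame(
    rsid = shared,
    effect_allele = exp_df$effect_allele,
    other_allele = exp_df$other_allele,
    beta_exposure = exp_df$beta,
    se_exposure = exp_df$se,
    eaf_exposure = exp_df$eaf,
    beta_outcome = beta_out,
    se_outcome = out_df$se,
    eaf_outcome = eaf_out,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(h) <- NULL

  # Orient to the exposure-decreasing allele: where the current effect
  # allele raises the exposure, swap alleles (negating both betas and
  # complementing frequencies), then store beta_exposure as magnitude.
  raise <- h$beta_exposure > 0
  if (any(raise)) {
    ea <- h$effect_allele[raise]
    h$effect_allele[raise] <- h$other_allele[raise]
    h$other_allele[raise] <- ea
    h$beta_outcome[raise] <- -h$beta_outcome[raise]
    h$eaf_exposure[raise] <- 1 - h$eaf_exposure[raise]
    h$eaf_outcome[raise] <- 1 - h$eaf_outcome[raise]
  }
  h$beta_exposure <- abs(h$beta_exposure)
  if (any(h$beta_exposure == 0)) {
    zero <- h$rsid[h$beta_exposure == 0]
    h <- h[h$beta_exposure > 0, , drop = FALSE]
    warning("dropped instrument(s) with zero exposure beta: ",
            paste(zero, collapse = ", "), call. = FALSE)
    drop_reason[match(zero, shared)] <- "zero_exposure_beta"
    keep[match(zero, shared)] <- FALSE
  }

  report <- structure(list(
    n_input = k,
    n_retained = nrow(h),
    n_flipped = n_flipped,
    n_dropped_palindromic = sum(drop_reason %in%
                                c("palindromic", "palindromic_ambiguous"),
                                na.rm = TRUE),
    n_dropped_unmatched = sum(drop_reason == "allele_mismatch", na.rm = TRUE),
    dropped_rsids = shared[!keep],
    drop_reasons = stats::setNames(drop_reason[!keep], shared[!keep])
  ), class = "harmonization_report")
  stopifnot(report$n_input == report$n_retained + length(report$dropped_rsids))

  structure(h, class = c("mr_harmonized", "data.frame"), report = report)
}

#' @export
print.harmonization_report <- function(x, ...) {
  cat(sprintf(paste0("Harmonization: %d input SNP(s), %d retained, ",
                     "%d sign-flipped,\n  %d dropped palindromic, ",
                     "%d dropped allele-mismatch\n"),
              x$n_input, x$n_retained, x$n_flipped,
              x$n_dropped_palindromic, x$n_dropped_unmatched))
  if (length(x$dropped_rsids) > 0) {
    cat("  dropped:", paste(x$dropped_rsids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Rescale an externally sourced association onto a reference GWAS scale
#'
#' When one instrument's effect estimate comes from a different GWAS than
#' the others (here, rs117913124 is only available from an earlier
#' 25OHD meta-analysis), its beta and SE are mapped onto the reference
#' scale by regressing the reference study's betas on the source study's
#' betas across the SNPs shared between them, and multiplying the target
#' beta and SE by the fitted slope.  The regression is least squares
#' through the origin: both scales measure the same standardized quantity
#' and must agree at zero.  Multiplying beta and SE by the same slope
#' leaves the z-score (beta/se) unchanged.
#'
#' @param target A single-row [sumstats]-style data frame (or list) with
#'   `beta` and `se` to rescale.
#' @param shared_source,shared_reference Data frames with a `beta` column
#'   for the same >= 2 rsids in the same order and allele orientation, on
#'   the source and reference scales respectively.
#' @return `target` with `beta` and `se` multiplied by the fitted slope.
#' @export
rescale_external_beta <- function(target, shared_source, shared_reference) {
  if (NROW(shared_source) != NROW(shared_reference)) {
    stop("shared_source and shared_reference must pair the same SNPs",
         call. = FALSE)
  }
  if (NROW(shared_source) < 2) {
    stop("need at least 2 shared SNPs to fit the rescaling slope",
         call. = FALSE)
  }
  if (!is.null(shared_source$rsid) && !is.null(shared_reference$rsid) &&
      !identical(as.character(shared_source$rsid),
                 as.character(shared_reference$rsid))) {
    stop("shared_source and shared_reference must list the same rsids ",
         "in the same order", call. = FALSE)
  }
  x <- as.numeric(shared_source$beta)
  y <- as.numeric(shared_reference$beta)
  if (anyNA(x) || anyNA(y)) stop("shared betas must be non-missing", call. = FALSE)
  if (sum(x^2) == 0) stop("source betas are all zero; slope undefined",
                          call. = FALSE)
  slope <- sum(x * y) / sum(x^2)
  target$beta <- target$beta * slope
  target$se <- target$se * slope
  target
}
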