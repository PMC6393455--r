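# Canonical on-disk dialect for GWAS summary statistics: tab-separated,
# header row, columns rsid, effect_allele, other_allele, eaf, beta, se,
# pvalue, n; missing values written as "NA".

SUMSTATS_COLUMNS <- c("rsid", "effect_allele", "other_allele", "eaf",
                      "beta", "se", "pvalue", "n")

#' Construct a summary-statistics set
#'
#' A `sumstats` object is a data frame with one row per SNP and the
#' canonical columns `rsid`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `pvalue`, `n`, carrying a study label and trait name as
#' attributes.  Exposure-study betas are interpreted as change per effect
#' allele in SD units of the standardized log-scale exposure (e.g.
#' standardized log 25OHD); binary-outcome-study betas are log-odds per
#' effect allele.
#'
#' @param df Data frame containing the canonical columns (extra columns
#'   are dropped).
#' @param study_label Short label for the study the statistics come from.
#' @param trait Name of the trait analysed.
#' @return An object of class `sumstats`.
#' @export
sumstats <- function(df, study_label = "study", trait = "trait") {
  missing_cols <- setdiff(SUMSTATS_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[, SUMSTATS_COLUMNS]
  df$rsid <- as.character(df$rsid)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue")) df[[col]] <- as.numeric(df[[col]])
  df$n <- as.integer(round(as.numeric(df$n)))
  validate_sumstats(df)
  rownames(df) <- NULL
  structure(df, class = c("sumstats", "data.frame"),
            study_label = study_label, trait = trait)
}

# Row-level invariant checks; errors name the offending row and field.
validate_sumstats <- function(df) {
  row_fail <- function(rows, field, why) {
    if (any(rows)) {
      stop(sprintf("invalid %s in row(s) %s: %s", field,
                   paste(which(rows), collapse = ", "), why), call. = FALSE)
    }
  }
  dup <- duplicated(df$rsid)
  if (any(dup)) {
    stop("duplicate rsid(s): ", paste(unique(df$rsid[dup]), collapse = ", "),
         call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  row_fail(!df$effect_allele %in% bases, "effect_allele",
           "must be a single base A/C/G/T")
  row_fail(!df$other_allele %in% bases, "other_allele",
           "must be a single base A/C/G/T")
  row_fail(df$effect_allele == df$other_allele, "alleles",
           "effect and other allele must differ")
  row_fail(is.na(df$beta), "beta", "must be present and numeric")
  row_fail(is.na(df$se) | df$se <= 0, "se", "must be > 0")
  row_fail(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1), "eaf",
           "must lie in [0, 1]")
  row_fail(!is.na(df$pvalue) & (df$pvalue <= 0 | df$pvalue > 1), "pvalue",
           "must lie in (0, 1]")
  row_fail(!is.na(df$n) & df$n <= 0, "n", "must be a positive integer")
  invisible(df)
}

#' Read GWAS summary statistics
#'
#' Reads a tab-separated summary-statistics file with a header row into a
#' validated [sumstats] set.  Files in other dialects are handled through
#' `column_map`, which renames source columns onto the canonical names.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param column_map Optional named character vector mapping canonical
#'   names to the file's column names, e.g. `c(rsid = "SNP", beta = "b")`.
#'   Unmapped canonical names are looked up directly.
#' @param study_label,trait Metadata attached to the returned set.
#' @return A [sumstats] object; row order follows the file.
#' @export
read_sumstats <- function(path, column_map = NULL, study_label = NULL,
                          trait = "trait") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           na.strings = c("NA", ""),
                           check.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), SUMSTATS_COLUMNS)
    if (length(bad) > 0) {
      stop("unknown canonical column(s) in column_map: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw)) {
        stop("mapped column not found in file: ", src, call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  missing_cols <- setdiff(SUMSTATS_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(study_label)) study_label <- basename(path)
  sumstats(raw, study_label = study_label, trait = trait)
}

#' Write GWAS summary statistics
#'
#' Writes a [sumstats] set in the canonical dialect: tab-separated,
#' header `rsid effect_allele other_allele eaf beta se pvalue n`, missing
#' values as `NA`.  Numeric fields are written with enough digits that a
#' write/read round trip reproduces the set.
#'
#' @param x A [sumstats] object with at least one row.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sumstats <- function(x, path) {
  stopifnot(inherits(x, "sumstats"))
  if (nrow(x) == 0) stop("refusing to write an empty summary-statistics set",
                         call. = FALSE)
  out <- as.data.frame(x)
  for (col in c("eaf", "beta", "se", "pvalue")) {
    out[[col]] <- ifelse(is.na(out[[col]]), NA,
                         formatC(out[[col]], digits = 12, format = "g"))
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA",
                       fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("could not write ", path, ": ", conditionMessage(ok),
                        call. = FALSE)
  invisible(path)
}

#' Seven-SNP vitamin D instrument fixture (synthetic effect sizes)
#'
#' Returns the bundled instrument table for the seven independent
#' genome-wide-significant 25OHD-associated SNPs (rs3755967, rs12785878,
#' rs10741657, rs17216707, rs117913124, rs8018720, rs10745742).  The
#' rsids are the real instruments; the effect sizes, frequencies and
#' alleles are synthetic stand-ins on the standardized log-25OHD scale
#' (one dominant GC-locus-like SNP, jointly explaining roughly 5% of
#' exposure variance), because the source per-SNP estimates are not
#' redistributable with the package.  Intended for examples and pipeline
#' exercises, not for inference about vitamin D.
#'
#' @return A [sumstats] object with 7 rows.
#' @export
vitd_instruments_synthetic <- function() {
  path <- system.file("extdata", "vitd_instruments_synthetic.tsv",
                      package = "vitdmr", mustWork = TRUE)
  read_sumstats(path, study_label = "synthetic 25OHD GWAS",
                trait = "standardized log 25OHD")
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %d SNP(s)\n  study: %s\n  trait: %s\n",
              nrow(x), attr(x, "study_label"), attr(x, "trait")))
  print.data.frame(x, ...)
  invisible(x)
}
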