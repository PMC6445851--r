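#' Additive-model eQTL regression for one SNP-gene pair
#'
#' Ordinary least squares of expression on genotype dosage (0/1/2 minor
#' alleles) with intercept; the association P-value is the two-sided
#' t-test on the dosage slope. A constant genotype makes the pair
#' untestable: it is flagged in the returned record rather than raising,
#' so batch scans keep going.
#'
#' @param genotypes Numeric vector of 0/1/2 dosages.
#' @param expression Numeric vector, same length (>= 3).
#' @param snp,gene Identifiers recorded in the output.
#' @param tissue Tissue label (free text).
#' @return One-row data.frame: `snp`, `gene`, `slope`, `p`, `tissue`,
#'   `untestable`.
#' @export
additive_eqtl_regression <- function(genotypes, expression,
                                     snp = NA_character_,
                                     gene = NA_character_,
                                     tissue = "whole blood") {
  stopifnot(length(genotypes) == length(expression),
            length(genotypes) >= 3L)
  rec <- data.frame(snp = snp, gene = gene, slope = NA_real_,
                    p = NA_real_, tissue = tissue, untestable = FALSE,
                    stringsAsFactors = FALSE)
  if (length(unique(genotypes)) < 2L) {
    rec$untestable <- TRUE
    return(rec)
  }
  fit <- summary(lm(expression ~ genotypes))$coefficients
  rec$slope <- fit["genotypes", "Estimate"]
  rec$p <- fit["genotypes", "Pr(>|t|)"]
  rec
}

#' Filter eQTL records at a nominal P-value threshold
#'
#' Keeps records with `p < p_max` (strict), preserving input order, and
#' returns the distinct target-gene list alongside. No multiple-testing
#' correction is applied at this stage: GWAS SNPs and their true targets
#' need not reach stringent eQTL significance, so a nominal threshold is
#' used deliberately.
#'
#' @param records data.frame of eQTL records with columns `snp`, `gene`,
#'   `p`.
#' @param p_max Threshold in (0, 1], default 0.05.
#' @return List with `records` (the filtered rows, input order) and
#'   `genes` (distinct genes, first-seen order).
#' @export
filter_eqtl <- function(records, p_max = 0.05) {
  stopifnot(p_max > 0, p_max <= 1)
  keep <- !is.na(records$p) & records$p < p_max
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, genes = unique(out$gene))
}
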