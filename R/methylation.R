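#' Covariate-adjusted methylation-QTL regression
#'
#' OLS of a probe's M-values on genotype dosage plus sex, age and 10
#' genotype-derived principal components (13 predictors + intercept);
#' the reported P-value is the two-sided t-test on the genotype slope.
#' Designs with too few degrees of freedom, a constant genotype, or rank
#' deficiency are flagged untestable with a diagnostic instead of
#' raising, so probe scans keep going.
#'
#' @param m_values Numeric vector of M-values (log2
#'   methylated/unmethylated ratio) for one probe.
#' @param genotypes Numeric 0/1/2 dosage vector, same subjects.
#' @param covariates data.frame with columns `sex`, `age`,
#'   `PC1`..`PC10`.
#' @param snp,probe,gene Identifiers recorded in the output.
#' @return One-row data.frame: `snp`, `probe`, `gene`, `slope`, `p`,
#'   `untestable`, `note`.
#' @export
meqtl_regression <- function(m_values, genotypes, covariates,
                             snp = NA_character_, probe = NA_character_,
                             gene = NA_character_) {
  need <- c("sex", "age", sprintf("PC%d", 1:10))
  stopifnot(length(m_values) == length(genotypes),
            nrow(covariates) == length(genotypes),
            all(need %in% names(covariates)))
  rec <- data.frame(snp = snp, probe = probe, gene = gene,
                    slope = NA_real_, p = NA_real_, untestable = FALSE,
                    note = "", stringsAsFactors = FALSE)
  n_pred <- 13L  # genotype + sex + age + 10 PCs
  if (length(m_values) <= n_pred + 1L) {
    rec$untestable <- TRUE
    rec$note <- sprintf("n = %d too small for %d predictors + intercept",
                        length(m_values), n_pred)
    return(rec)
  }
  if (length(unique(genotypes)) < 2L) {
    rec$untestable <- TRUE
    rec$note <- "constant genotype"
    return(rec)
  }
  df <- cbind(data.frame(M = m_values, G = genotypes),
              covariates[, need])
  fit <- lm(M ~ ., data = df)
  if (fit$rank < n_pred + 1L) {
    rec$untestable <- TRUE
    rec$note <- sprintf("rank-deficient design (rank %d of %d)",
                        fit$rank, n_pred + 1L)
    return(rec)
  }
  co <- summary(fit)$coefficients
  rec$slope <- co["G", "Estimate"]
  rec$p <- co["G", "Pr(>|t|)"]
  rec
}

#' Scan SNP x probe pairs within target genes
#'
#' Builds the test set "each SNP against every methylation probe in its
#' target gene(s)" from the target table and the probe-to-gene map, and
#' runs [meqtl_regression()] on each pair.
#'
#' @param pairs Target table (`snp`, `gene` columns) from
#'   [build_target_table()].
#' @param m_values Subjects x probes M-value matrix.
#' @param genotypes Subjects x SNPs dosage matrix.
#' @param covariates Covariate data.frame (see [meqtl_regression()]).
#' @param probe_map data.frame `probe`, `gene`.
#' @return data.frame of meQTL records, one per tested pair.
#' @export
run_meqtl_scan <- function(pairs, m_values, genotypes, covariates,
                           probe_map) {
  tests <- merge(unique(pairs[, c("snp", "gene")]), probe_map,
                 by = "gene", sort = FALSE)
  tests <- tests[tests$snp %in% colnames(genotypes) &
                   tests$probe %in% colnames(m_values), , drop = FALSE]
  if (!nrow(tests))
    return(data.frame(snp = character(), probe = character(),
                      gene = character(), slope = numeric(),
                      p = numeric(), untestable = logical(),
                      note = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(seq_len(nrow(tests)), function(i) {
    meqtl_regression(m_values[, tests$probe[i]],
                     genotypes[, tests$snp[i]], covariates,
                     snp = tests$snp[i], probe = tests$probe[i],
                     gene = tests$gene[i])
  }))
  rownames(out) <- NULL
  out
}

#' Experiment-wide Bonferroni cutoff
#'
#' `alpha / n_tests`, with a 2-significant-figure display form in the
#' conventional `m x 10^e` notation (e.g. 0.05/144 displays as
#' `"3.5 x 10^-4"`).
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return List with `cutoff` (exact value) and `display` (string).
#' @export
bonferroni_cutoff <- function(alpha = 0.05, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  cutoff <- alpha / n_tests
  s <- signif(cutoff, 2)
  e <- floor(log10(s))
  mant <- s / 10^e
  display <- if (e == 0) format(mant) else
    sprintf("%s x 10^%d", format(mant), e)
  list(cutoff = cutoff, display = display)
}

#' Count meQTL records below an experiment-wide cutoff
#'
#' Strict `p < cutoff`; the qualifying records are flagged in a
#' `significant` column.
#'
#' @param records data.frame of meQTL records with a `p` column.
#' @param cutoff Positive threshold.
#' @return List with `n` (count) and `records` (input with the
#'   `significant` flag).
#' @export
count_significant <- function(records, cutoff) {
  stopifnot(cutoff > 0)
  records$significant <- !is.na(records$p) & records$p < cutoff
  list(n = sum(records$significant), records = records)
}
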