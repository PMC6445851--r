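#' Build the SNP-gene target table
#'
#' Intersects the three lines of evidence into one row per (SNP, gene)
#' pair: the pair must have an eQTL association with `p < eqtl_p_max`,
#' and the gene must be differentially expressed with
#' `PFP < pfp_max` and `|FC| > fc_min` (all strict). A gene reached by
#' several SNPs keeps one row per SNP. Rows are sorted by chromosome
#' then position; distinct-gene and distinct-SNP counts are attached as
#' attributes `n_genes` / `n_snps`.
#'
#' @param gwas_snps data.frame with `snp`, `chr`, `pos` (1-based),
#'   `gwas_p`.
#' @param eqtl_records data.frame with `snp`, `gene`, `p`.
#' @param deg_results data.frame with `gene`, `pfp` (or
#'   `pfp_up`/`pfp_down`), `fc`.
#' @param locations Optional data.frame `snp`, `gene`, `location`
#'   (5prime/3prime/intron/exon) read from annotation.
#' @param eqtl_p_max,pfp_max,fc_min Thresholds (defaults 0.05, 0.05,
#'   1.2).
#' @return data.frame of target pairs: `snp`, `chr`, `pos`, `gene`,
#'   `location`, `gwas_p`, `eqtl_p`, `pfp`, `fc`.
#' @export
build_target_table <- function(gwas_snps, eqtl_records, deg_results,
                               locations = NULL,
                               eqtl_p_max = 0.05, pfp_max = 0.05,
                               fc_min = 1.2) {
  if (is.null(deg_results$pfp)) {
    stopifnot(!is.null(deg_results$pfp_up), !is.null(deg_results$pfp_down))
    deg_results$pfp <- pmin(deg_results$pfp_up, deg_results$pfp_down)
  }
  unknown_snp <- setdiff(eqtl_records$snp, gwas_snps$snp)
  if (length(unknown_snp))
    stop("eQTL records reference SNPs absent from the GWAS table: ",
         paste(unique(unknown_snp), collapse = ", "))
  eq <- eqtl_records[!is.na(eqtl_records$p) &
                       eqtl_records$p < eqtl_p_max, , drop = FALSE]
  deg <- deg_results[!is.na(deg_results$pfp) &
                       deg_results$pfp < pfp_max &
                       abs(deg_results$fc) > fc_min, , drop = FALSE]
  m_deg <- match(eq$gene, deg$gene)
  keep <- !is.na(m_deg)
  eq <- eq[keep, , drop = FALSE]
  m_deg <- m_deg[keep]
  m_snp <- match(eq$snp, gwas_snps$snp)
  out <- data.frame(snp = eq$snp,
                    chr = gwas_snps$chr[m_snp],
                    pos = gwas_snps$pos[m_snp],
                    gene = eq$gene,
                    location = rep(NA_character_, nrow(eq)),
                    gwas_p = gwas_snps$gwas_p[m_snp],
                    eqtl_p = eq$p,
                    pfp = deg$pfp[m_deg],
                    fc = deg$fc[m_deg],
                    stringsAsFactors = FALSE)
  if (!is.null(locations)) {
    ml <- match(paste(out$snp, out$gene),
                paste(locations$snp, locations$gene))
    out$location <- locations$location[ml]
  }
  out <- out[!duplicated(paste(out$snp, out$gene)), , drop = FALSE]
  out <- out[order(out$chr, out$pos, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_pairs") <- nrow(out)
  attr(out, "n_genes") <- length(unique(out$gene))
  attr(out, "n_snps") <- length(unique(out$snp))
  out
}

#' Count up- and down-regulated target genes
#'
#' Per distinct gene (a gene reached by several SNPs is counted once):
#' up if its signed fold change is positive, down otherwise.
#'
#' @param pairs Target table from [build_target_table()].
#' @return Named integer vector `c(up = ..., down = ...)`.
#' @export
classify_direction <- function(pairs) {
  g <- pairs[!duplicated(pairs$gene), , drop = FALSE]
  c(up = sum(g$fc > 0), down = sum(g$fc < 0))
}

#' Annotate SNPs with overlapping histone-mark intervals
#'
#' Intervals follow the BED convention (0-based, half-open `[start,
#' end)`); SNP positions are 1-based. A SNP at 1-based position p
#' overlaps an interval iff `start <= p - 1 < end` on the same
#' chromosome — the 1-based/0-based conversion happens here and only
#' here. All overlapping labels are attached, `"none"` when there is no
#' overlap.
#'
#' @param pairs Target table with `snp`, `chr`, `pos` columns.
#' @param intervals data.frame with `chr`, `start`, `end`, `label`
#'   (0-based half-open; `start < end` enforced).
#' @return `pairs` with a `histone` column (comma-separated labels).
#' @export
annotate_histone_overlap <- function(pairs, intervals) {
  if (nrow(intervals) && any(intervals$start >= intervals$end))
    stop("malformed interval: start >= end")
  if (!nrow(pairs)) {
    pairs$histone <- character(0)
    return(pairs)
  }
  snp_gr <- GenomicRanges::GRanges(
    seqnames = as.character(pairs$chr),
    ranges = IRanges::IRanges(start = pairs$pos, width = 1L))
  hit_labels <- rep("none", nrow(pairs))
  if (nrow(intervals)) {
    # BED 0-based half-open -> 1-based closed; the only coordinate shift
    int_gr <- GenomicRanges::GRanges(
      seqnames = as.character(intervals$chr),
      ranges = IRanges::IRanges(start = intervals$start + 1L,
                                end = intervals$end))
    ov <- GenomicRanges::findOverlaps(snp_gr, int_gr)
    if (length(ov)) {
      q <- S4Vectors::queryHits(ov)
      s <- S4Vectors::subjectHits(ov)
      o <- order(q, s)  # labels reported in input interval order
      lab <- tapply(intervals$label[s[o]], q[o],
                    function(x) paste(unique(x), collapse = ","))
      hit_labels[as.integer(names(lab))] <- lab
    }
  }
  pairs$histone <- hit_labels
  pairs
}
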