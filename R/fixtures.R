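#' Packaged result-table fixtures
#'
#' Machine-readable transcriptions of the two published summary tables
#' shipped with the package: `"table1"`, the 13 SNP-target-gene pairs in
#' neutrophils with their GWAS/eQTL P-values, PFP, signed fold change,
#' histone-mark and methylation annotations; and `"table2"`, the 4 KEGG
#' pathways enriched in the first-order PPI network (Total, Expected,
#' Hits, P-value, FDR and permutation empirical P-value).
#'
#' @param name `"table1"` or `"table2"`.
#' @return data.frame of the requested fixture.
#' @export
generate_fixture <- function(name) {
  valid <- c(table1 = "table1_target_genes.tsv",
             table2 = "table2_pathways.tsv")
  if (length(name) != 1L || !name %in% names(valid))
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; valid fixtures: ", paste(names(valid), collapse = ", "))
  path <- system.file("extdata", valid[[name]],
                      package = "gwastargets", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Demonstration simulation configuration
#'
#' A [sim_config()] wired so the synthetic pipeline has a known answer:
#' the first `n_targets` genes are planted as eQTL targets of the GWAS
#' SNPs (13 SNP-gene pairs over 10 SNPs when `n_targets = 11`, two SNPs
#' regulating two genes each), planted as differentially expressed with
#' fold changes 1.3-1.7 in both directions, and carry methylation probes
#' with four planted meQTL slopes. The interactome is seeded so a
#' planted pathway overlaps the targets' first-order neighborhood.
#'
#' @param seed Master seed.
#' @param n_targets Number of planted target genes.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config` whose `eqtl_effects`, `planted_de` and
#'   `meqtl_effects` are pre-wired.
#' @export
demo_config <- function(seed = 1L, n_targets = 11L, ...) {
  base <- sim_config(seed = seed, ...)
  genes <- gene_universe(base)[seq_len(n_targets)]
  snps <- snp_ids(base)
  # two SNPs get a second target, mirroring shared-locus pairs
  snp_of <- snps[pmin(seq_len(n_targets), base$n_snps)]
  extra <- if (n_targets >= 4L && base$n_snps >= 2L)
    data.frame(snp = snps[1:2], gene = genes[c(n_targets - 1L, n_targets)],
               slope = 0.6) else NULL
  eqtl <- rbind(data.frame(snp = snp_of[seq_len(min(n_targets,
                                                    base$n_snps))],
                           gene = genes[seq_len(min(n_targets,
                                                    base$n_snps))],
                           slope = 0.6),
                extra)
  dirs <- rep(c("up", "down"), length.out = n_targets)
  de <- data.frame(gene = genes,
                   fc = rep(c(1.5, 1.4, 1.7, 1.3), length.out = n_targets),
                   direction = dirs)
  n_meth <- max(base$n_meth_genes, n_targets)
  probes <- sprintf("cg%08d", ((seq_len(min(4L, n_targets)) - 1L) *
                                 base$n_probes_per_gene) + 1L)
  meqtl <- data.frame(snp = snp_of[seq_len(min(4L, n_targets))],
                      probe = probes, slope = 0.8)
  cfg <- sim_config(seed = seed, planted_de = de, eqtl_effects = eqtl,
                    meqtl_effects = meqtl, n_meth_genes = n_meth, ...)
  cfg
}
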