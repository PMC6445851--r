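#' Simulation configuration for the synthetic pipeline inputs
#'
#' Collects every knob of the synthetic-data generator into a validated
#' configuration object. All randomness downstream flows from `seed` via
#' named sub-streams, so a fixed configuration yields byte-identical
#' outputs.
#'
#' Defaults emulate the study design the pipeline is built around: two
#' case/control expression studies totalling 36 cases and 26 controls
#' (split 18/13 per study; the per-study split is a free parameter),
#' log-normal intensity noise on the log2 scale, common variants in
#' Hardy-Weinberg equilibrium, roughly 11 methylation probes per gene, a
#' scale-free interactome and a pathway collection with one optionally
#' planted enriched set.
#'
#' @param seed Integer master seed.
#' @param n_genes Number of genes in the universe (symbols `G0001...`).
#' @param n_studies Number of expression studies.
#' @param n_cases,n_controls Integer vectors of per-study sample counts
#'   (length `n_studies`).
#' @param planted_de `NULL` or a data.frame with columns `gene`, `fc`
#'   (true fold change, >= 1) and `direction` (`"up"`/`"down"`).
#' @param noise_sd Gaussian noise SD on the log2 intensity scale.
#' @param n_snps Number of GWAS SNPs.
#' @param n_subjects Number of genotyped subjects (genotype/methylation
#'   cohort).
#' @param maf Minor-allele frequency in (0, 0.5]; scalar or per-SNP.
#' @param eqtl_effects `NULL` or data.frame with columns `snp`, `gene`,
#'   `slope` (expression change per allele).
#' @param n_probes_per_gene Methylation probes simulated per gene.
#' @param n_meth_genes Number of genes carrying methylation probes.
#' @param meqtl_effects `NULL` or data.frame with columns `snp`, `probe`,
#'   `slope` (M-value change per allele).
#' @param meth_noise_sd Gaussian noise SD on the M-value scale.
#' @param meth_intercept Baseline M-value.
#' @param sex_effect,age_effect,pc_effects Covariate effects on M-values
#'   (`pc_effects` has length 10).
#' @param interactome_size Number of interactome nodes (<= `n_genes`).
#' @param attachment Edges added per node by preferential attachment.
#' @param n_pathways Number of pathway gene sets.
#' @param pathway_size_range Integer `c(min, max)` pathway size.
#' @param planted_pathway_size Size of the planted enriched pathway
#'   (0 disables planting).
#' @param planted_pathway_overlap How many planted-pathway members are
#'   drawn from the first-order neighborhood of the seed genes.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 1000L,
                       n_studies = 2L,
                       n_cases = c(18L, 18L),
                       n_controls = c(13L, 13L),
                       planted_de = NULL,
                       noise_sd = 0.3,
                       n_snps = 10L,
                       n_subjects = 200L,
                       maf = 0.3,
                       eqtl_effects = NULL,
                       n_probes_per_gene = 11L,
                       n_meth_genes = min(11L, n_genes),
                       meqtl_effects = NULL,
                       meth_noise_sd = 0.5,
                       meth_intercept = 0,
                       sex_effect = 0.1,
                       age_effect = 0.01,
                       pc_effects = rep(0, 10),
                       interactome_size = min(400L, n_genes),
                       attachment = 2L,
                       n_pathways = 50L,
                       pathway_size_range = c(min(10L, interactome_size),
                                              min(150L, interactome_size)),
                       planted_pathway_size = min(15L, interactome_size),
                       planted_pathway_overlap =
                         min(10L, planted_pathway_size)) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_studies = as.integer(n_studies),
              n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              planted_de = planted_de, noise_sd = noise_sd,
              n_snps = as.integer(n_snps),
              n_subjects = as.integer(n_subjects), maf = maf,
              eqtl_effects = eqtl_effects,
              n_probes_per_gene = as.integer(n_probes_per_gene),
              n_meth_genes = as.integer(n_meth_genes),
              meqtl_effects = meqtl_effects,
              meth_noise_sd = meth_noise_sd,
              meth_intercept = meth_intercept,
              sex_effect = sex_effect, age_effect = age_effect,
              pc_effects = pc_effects,
              interactome_size = as.integer(interactome_size),
              attachment = as.integer(attachment),
              n_pathways = as.integer(n_pathways),
              pathway_size_range = as.integer(pathway_size_range),
              planted_pathway_size = as.integer(planted_pathway_size),
              planted_pathway_overlap = as.integer(planted_pathway_overlap))
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(length(seed) == 1L, n_genes > 0L, n_studies > 0L,
              length(n_cases) == n_studies,
              length(n_controls) == n_studies,
              all(n_cases > 0L), all(n_controls > 0L),
              noise_sd >= 0, n_snps > 0L, n_subjects > 0L,
              all(maf > 0), all(maf <= 0.5),
              n_probes_per_gene > 0L, n_meth_genes > 0L,
              n_meth_genes <= n_genes,
              meth_noise_sd >= 0, length(pc_effects) == 10L,
              interactome_size >= attachment, attachment >= 1L,
              interactome_size <= n_genes,
              n_pathways > 0L, length(pathway_size_range) == 2L,
              pathway_size_range[1] >= 1L,
              pathway_size_range[2] >= pathway_size_range[1],
              pathway_size_range[2] <= interactome_size,
              planted_pathway_size >= 0L,
              planted_pathway_overlap <= planted_pathway_size)
    if (!is.null(planted_de)) {
      stopifnot(is.data.frame(planted_de),
                all(c("gene", "fc", "direction") %in% names(planted_de)),
                all(planted_de$fc >= 1),
                all(planted_de$direction %in% c("up", "down")))
    }
  })
  cfg
}

#' Synthetic gene universe
#'
#' Fixed synthetic gene symbols `G0001`, `G0002`, ... shared by every
#' generator, standing in for a genome annotation.
#'
#' @param config A [sim_config()].
#' @return Character vector of length `config$n_genes`.
#' @export
gene_universe <- function(config) {
  sprintf("G%04d", seq_len(config$n_genes))
}

#' Synthetic SNP identifiers
#' @param config A [sim_config()].
#' @return Character vector of rs-style ids, length `config$n_snps`.
#' @export
snp_ids <- function(config) {
  sprintf("rs%06d", 100000L + seq_len(config$n_snps))
}

#' Generate labeled case/control expression studies
#'
#' Simulates, per study, a genes-by-samples positive intensity matrix.
#' Intensities are built on the log2 scale (per-gene baseline uniform on
#' 6..12, Gaussian noise of SD `noise_sd`, plus `log2(fc)` added to case
#' samples of planted DE genes, with sign from their direction) and then
#' exponentiated, so downstream log2 preprocessing is exercised. Planted
#' genes therefore have a case/control geometric-mean ratio equal to the
#' planted fold change in expectation.
#'
#' @param config A [sim_config()].
#' @return List of [expression_study()] objects, length `n_studies`.
#' @export
generate_expression_studies <- function(config) {
  genes <- gene_universe(config)
  shift <- setNames(numeric(config$n_genes), genes)
  if (!is.null(config$planted_de)) {
    pd <- config$planted_de
    missing <- setdiff(pd$gene, genes)
    if (length(missing))
      stop("planted_de genes outside universe: ",
           paste(missing, collapse = ", "))
    shift[pd$gene] <- log2(pd$fc) * ifelse(pd$direction == "up", 1, -1)
  }
  withr::with_seed(stream_seed(config$seed, "expression"), {
    lapply(seq_len(config$n_studies), function(s) {
      nc <- config$n_cases[s]; nk <- config$n_controls[s]
      n <- nc + nk
      mu <- runif(config$n_genes, 6, 12)
      m <- matrix(mu, config$n_genes, n) +
        matrix(rnorm(config$n_genes * n, sd = config$noise_sd),
               config$n_genes, n)
      labels <- c(rep("case", nc), rep("control", nk))
      m[, labels == "case"] <- m[, labels == "case"] + shift
      dimnames(m) <- list(genes,
                          sprintf("ST%d_%s%02d", s, substr(labels, 1, 4),
                                  c(seq_len(nc), seq_len(nk))))
      expression_study(sprintf("study%d", s), 2^m, labels)
    })
  })
}

#' Generate an additive-coded genotype matrix
#'
#' Subjects-by-SNPs matrix of 0/1/2 minor-allele counts drawn
#' `Binomial(2, maf)` per SNP, i.e. Hardy-Weinberg equilibrium genotype
#' frequencies `(1-p)^2, 2p(1-p), p^2`.
#'
#' @param config A [sim_config()]; `maf` may be scalar or per-SNP.
#' @return Integer matrix `n_subjects` x `n_snps` with subject rownames
#'   and SNP colnames.
#' @export
generate_genotypes <- function(config) {
  maf <- rep_len(config$maf, config$n_snps)
  withr::with_seed(stream_seed(config$seed, "genotypes"), {
    g <- vapply(maf, function(p) rbinom(config$n_subjects, 2L, p),
                integer(config$n_subjects))
    g <- matrix(g, nrow = config$n_subjects)
    dimnames(g) <- list(sprintf("I%04d", seq_len(config$n_subjects)),
                        snp_ids(config))
    g
  })
}

#' Generate methylation M-values with covariates
#'
#' Simulates `n_meth_genes * n_probes_per_gene` probe columns whose
#' M-values (log2 methylated/unmethylated ratio) follow
#' `M = intercept + slope * G + sex + age + 10 PCs + noise`, with planted
#' genotype slopes taken from `config$meqtl_effects` and covariate effects
#' from the config. Covariates (sex in 0/1, age in years, PC1..PC10) are
#' returned alongside, together with the probe-to-gene map.
#'
#' @param config A [sim_config()].
#' @param genotypes Matrix from [generate_genotypes()] (same subjects).
#' @return List with `m_values` (subjects x probes matrix), `covariates`
#'   (data.frame) and `probe_map` (data.frame probe/gene).
#' @export
generate_methylation <- function(config, genotypes) {
  if (nrow(genotypes) != config$n_subjects)
    stop("genotype matrix rows do not match n_subjects")
  genes <- gene_universe(config)[seq_len(config$n_meth_genes)]
  probe_map <- data.frame(
    probe = sprintf("cg%08d", seq_len(config$n_meth_genes *
                                        config$n_probes_per_gene)),
    gene = rep(genes, each = config$n_probes_per_gene),
    stringsAsFactors = FALSE)
  slopes <- setNames(numeric(nrow(probe_map)), probe_map$probe)
  slope_snp <- setNames(rep(NA_character_, nrow(probe_map)),
                        probe_map$probe)
  if (!is.null(config$meqtl_effects)) {
    me <- config$meqtl_effects
    stopifnot(all(c("snp", "probe", "slope") %in% names(me)))
    bad <- setdiff(me$probe, probe_map$probe)
    if (length(bad)) stop("meqtl_effects probes not simulated: ",
                          paste(bad, collapse = ", "))
    if (!all(me$snp %in% colnames(genotypes)))
      stop("meqtl_effects SNP absent from genotype matrix")
    slopes[me$probe] <- me$slope
    slope_snp[me$probe] <- me$snp
  }
  n <- config$n_subjects
  withr::with_seed(stream_seed(config$seed, "methylation"), {
    covariates <- data.frame(
      sex = rbinom(n, 1L, 0.5),
      age = runif(n, 5, 18))
    pcs <- matrix(rnorm(n * 10L), n, 10L,
                  dimnames = list(NULL, sprintf("PC%d", 1:10)))
    covariates <- cbind(covariates, as.data.frame(pcs))
    rownames(covariates) <- rownames(genotypes)
    base <- config$meth_intercept +
      config$sex_effect * covariates$sex +
      config$age_effect * covariates$age +
      drop(pcs %*% config$pc_effects)
    m <- vapply(seq_len(nrow(probe_map)), function(j) {
      g <- if (is.na(slope_snp[j])) 0 else genotypes[, slope_snp[j]]
      base + slopes[j] * g + rnorm(n, sd = config$meth_noise_sd)
    }, numeric(n))
    m <- matrix(m, nrow = n,
                dimnames = list(rownames(genotypes), probe_map$probe))
    list(m_values = m, covariates = covariates, probe_map = probe_map)
  })
}

#' Generate a scale-free synthetic interactome
#'
#' Undirected, simple, connected protein-interaction graph grown by
#' preferential attachment (Barabasi-Albert, `attachment` edges per new
#' node), with nodes labeled by gene symbols sampled from the gene
#' universe.
#'
#' @param config A [sim_config()].
#' @return An `igraph` object with a `name` vertex attribute.
#' @export
generate_interactome <- function(config) {
  if (config$interactome_size < 2L)
    stop("interactome_size must be at least 2")
  withr::with_seed(stream_seed(config$seed, "interactome"), {
    g <- igraph::sample_pa(config$interactome_size, power = 1,
                           m = config$attachment, directed = FALSE,
                           algorithm = "psumtree")
    igraph::V(g)$name <- sample(gene_universe(config),
                                config$interactome_size)
    g
  })
}

#' Generate a pathway collection, optionally with one planted enriched set
#'
#' Draws `n_pathways` gene sets uniformly from the interactome node set
#' (the pathway-annotated universe). When planting is enabled, one
#' additional set of size `planted_pathway_size` takes
#' `planted_pathway_overlap` members from the first-order neighborhood of
#' `seeds` and the rest uniformly, so the enrichment stage should flag it
#' far above chance.
#'
#' @param config A [sim_config()].
#' @param interactome Graph from [generate_interactome()].
#' @param seeds Character vector of seed genes (required when planting).
#' @return A [pathway_db()] whose universe is the interactome node set.
#'   The planted set, if any, is named `"PW_PLANTED"`.
#' @export
generate_pathways <- function(config, interactome, seeds = NULL) {
  universe <- igraph::V(interactome)$name
  rng <- config$pathway_size_range
  if (rng[2] > length(universe))
    stop("pathway_size_range exceeds the gene universe")
  withr::with_seed(stream_seed(config$seed, "pathways"), {
    sets <- lapply(seq_len(config$n_pathways), function(i) {
      sz <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
      sample(universe, sz)
    })
    names(sets) <- sprintf("PW%03d", seq_len(config$n_pathways))
    if (config$planted_pathway_size > 0L) {
      if (is.null(seeds) || !length(seeds))
        stop("planting a pathway requires seed genes")
      fon <- first_order_network(interactome, seeds)
      nb <- intersect(igraph::V(fon$graph)$name, universe)
      k <- min(config$planted_pathway_overlap, length(nb))
      planted <- c(sample(nb, k),
                   sample(setdiff(universe, nb),
                          config$planted_pathway_size - k))
      sets <- c(sets, list(PW_PLANTED = planted))
    }
    pathway_db(sets, universe)
  })
}

#' Generate a synthetic GWAS SNP table
#'
#' rsID, chromosome, 1-based position and GWAS P-value for each SNP
#' (positions uniform per chromosome; P-values log-uniform between 1e-6
#' and 1e-15, i.e. genome-wide-suggestive to genome-wide-significant).
#'
#' @param config A [sim_config()].
#' @return data.frame with columns `snp`, `chr`, `pos`, `gwas_p`.
#' @export
generate_gwas_snps <- function(config) {
  withr::with_seed(stream_seed(config$seed, "gwas"), {
    data.frame(snp = snp_ids(config),
               chr = sample(1:22, config$n_snps, replace = TRUE),
               pos = sample.int(2e8L, config$n_snps),
               gwas_p = 10^-runif(config$n_snps, 6, 15),
               stringsAsFactors = FALSE)
  })
}

#' Generate an eQTL association table by simulation + regression
#'
#' For each (SNP, gene) pair in `config$eqtl_effects` — plus `n_null`
#' random null pairs — simulates per-subject expression
#' `slope * G + noise` on an independent cohort and runs
#' [additive_eqtl_regression()], yielding a GTEx-portal-style association
#' table.
#'
#' @param config A [sim_config()].
#' @param genotypes Matrix from [generate_genotypes()].
#' @param n_null Number of additional null (slope 0) pairs.
#' @param tissue Tissue label attached to each record.
#' @return data.frame of eQTL records (`snp`, `gene`, `slope`, `p`,
#'   `tissue`).
#' @export
generate_eqtl_table <- function(config, genotypes, n_null = 20L,
                                tissue = "whole blood") {
  eff <- config$eqtl_effects
  if (is.null(eff))
    eff <- data.frame(snp = character(), gene = character(),
                      slope = numeric())
  withr::with_seed(stream_seed(config$seed, "eqtl"), {
    if (n_null > 0L) {
      null <- data.frame(
        snp = sample(snp_ids(config), n_null, replace = TRUE),
        gene = sample(gene_universe(config), n_null, replace = TRUE),
        slope = 0)
      eff <- rbind(eff[, c("snp", "gene", "slope")], null)
    }
    recs <- lapply(seq_len(nrow(eff)), function(i) {
      g <- genotypes[, eff$snp[i]]
      e <- eff$slope[i] * g + rnorm(length(g))
      additive_eqtl_regression(g, e, snp = eff$snp[i],
                               gene = eff$gene[i], tissue = tissue)
    })
    do.call(rbind, recs)
  })
}

#' Generate histone-mark intervals as BED-style data
#'
#' Produces 0-based half-open intervals on the SNPs' chromosomes, with a
#' controllable subset placed to cover SNP positions (emulating
#' enhancer/promoter chromatin-state calls around risk loci) and the rest
#' placed at random.
#'
#' @param config A [sim_config()].
#' @param gwas_snps data.frame from [generate_gwas_snps()].
#' @param cover Indices of SNPs whose position must fall inside one
#'   generated interval.
#' @param n_random Number of additional random intervals.
#' @param labels Pool of mark_state labels to draw from.
#' @return data.frame with columns `chr`, `start`, `end`, `label`
#'   (0-based, half-open).
#' @export
generate_histone_intervals <- function(config, gwas_snps,
                                       cover = integer(),
                                       n_random = 50L,
                                       labels = c("H3K4me1_Enh",
                                                  "H3K4me3_Pro",
                                                  "H3K27ac_Enh")) {
  withr::with_seed(stream_seed(config$seed, "histone"), {
    covered <- if (length(cover)) {
      pos0 <- gwas_snps$pos[cover] - 1L  # 1-based SNP -> 0-based point
      data.frame(chr = gwas_snps$chr[cover],
                 start = pos0 - sample.int(500L, length(cover)),
                 end = pos0 + sample.int(500L, length(cover)),
                 label = sample(labels, length(cover), replace = TRUE))
    } else NULL
    start <- sample.int(2e8L, n_random)
    rand <- data.frame(chr = sample(gwas_snps$chr, n_random,
                                    replace = TRUE),
                       start = start,
                       end = start + sample(200:2000, n_random,
                                            replace = TRUE),
                       label = sample(labels, n_random, replace = TRUE))
    out <- rbind(covered, rand)
    out[order(out$chr, out$start), , drop = FALSE]
  })
}
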