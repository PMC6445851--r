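test_that("expression generator honors shapes, labels and determinism", {
  cfg <- sim_config(seed = 1, n_genes = 100, n_studies = 2,
                    n_cases = c(5, 5), n_controls = c(5, 5))
  st <- generate_expression_studies(cfg)
  expect_length(st, 2)
  for (s in st) {
    expect_identical(dim(s$values), c(100L, 10L))
    expect_identical(table(s$labels), table(c(rep("case", 5),
                                              rep("control", 5))))
    expect_true(all(s$values > 0))
  }
  st2 <- generate_expression_studies(cfg)
  expect_identical(st, st2)
})

test_that("zero-noise planted fold change is reproduced exactly", {
  pd <- data.frame(gene = c("G0003", "G0007"), fc = c(2.0, 1.5),
                   direction = c("up", "down"))
  cfg <- sim_config(seed = 3, n_genes = 10, n_studies = 1, n_cases = 4,
                    n_controls = 4, planted_de = pd, noise_sd = 0)
  s <- generate_expression_studies(cfg)[[1]]
  gm <- function(x) exp(mean(log(x)))
  ratio <- apply(s$values, 1, function(v)
    gm(v[s$labels == "case"]) / gm(v[s$labels == "control"]))
  expect_equal(unname(ratio["G0003"]), 2.0, tolerance = 1e-12)
  expect_equal(unname(ratio["G0007"]), 1 / 1.5, tolerance = 1e-12)
  expect_equal(unname(ratio["G0001"]), 1.0, tolerance = 1e-12)
})

test_that("genotypes follow Hardy-Weinberg binomial frequencies", {
  cfg <- sim_config(seed = 2, n_subjects = 10000, n_snps = 1, maf = 0.5)
  g <- generate_genotypes(cfg)
  expect_true(all(g %in% 0:2))
  freq <- tabulate(g + 1L, nbins = 3) / 10000
  expected <- c(0.25, 0.5, 0.25)
  sd3 <- 3 * sqrt(expected * (1 - expected) / 10000)
  expect_true(all(abs(freq - expected) < sd3))
  # degenerate maf: essentially monomorphic
  cfg0 <- sim_config(seed = 2, n_subjects = 100, n_snps = 1, maf = 1e-9)
  expect_true(all(generate_genotypes(cfg0) == 0))
  expect_identical(generate_genotypes(cfg), g)
  expect_error(sim_config(maf = 0.7), "maf")
  expect_error(sim_config(maf = 0))
})

test_that("methylation generator follows the planted linear model", {
  cfg <- sim_config(seed = 4, n_subjects = 50, n_snps = 2,
                    n_meth_genes = 4, n_probes_per_gene = 11,
                    meth_noise_sd = 0, sex_effect = 0, age_effect = 0,
                    meth_intercept = 1.5)
  g <- generate_genotypes(cfg)
  meth <- generate_methylation(cfg, g)
  expect_identical(ncol(meth$m_values), 44L)  # 4 genes x 11 probes
  expect_identical(nrow(meth$probe_map), 44L)
  # zero slopes, zero covariate effects, zero noise -> constant columns
  expect_true(all(abs(meth$m_values - 1.5) < 1e-12))
  # planted slope with no noise is exactly linear in dosage
  cfg2 <- sim_config(seed = 4, n_subjects = 50, n_snps = 2,
                     n_meth_genes = 2, meth_noise_sd = 0,
                     sex_effect = 0, age_effect = 0,
                     meqtl_effects = data.frame(
                       snp = snp_ids(sim_config(n_snps = 2))[1],
                       probe = "cg00000001", slope = 0.8))
  m2 <- generate_methylation(cfg2, generate_genotypes(cfg2))
  expect_equal(unname(m2$m_values[, "cg00000001"]),
               unname(0.8 * generate_genotypes(cfg2)[, 1]),
               tolerance = 1e-12)
  expect_error(generate_methylation(cfg, g[1:10, ]), "n_subjects")
})

test_that("interactome is simple, connected and follows the attachment recurrence", {
  cfg <- sim_config(seed = 5, n_genes = 200, interactome_size = 100,
                    attachment = 2)
  g <- generate_interactome(cfg)
  expect_equal(igraph::vcount(g), 100)
  # each node past the first attaches min(m, existing) edges
  expect_equal(igraph::ecount(g), 1 + 2 * 98)
  expect_true(igraph::is_simple(g))
  expect_true(igraph::is_connected(g))
  expect_identical(igraph::as_edgelist(g),
                   igraph::as_edgelist(generate_interactome(cfg)))
  cfg2 <- sim_config(seed = 5, n_genes = 10, interactome_size = 2,
                     attachment = 1, pathway_size_range = c(1L, 2L))
  expect_equal(igraph::ecount(generate_interactome(cfg2)), 1)
})

test_that("pathway generator respects sizes, universe and GMT round-trip", {
  cfg <- sim_config(seed = 6, n_genes = 300, interactome_size = 150,
                    n_pathways = 50, pathway_size_range = c(10L, 100L),
                    planted_pathway_size = 0)
  g <- generate_interactome(cfg)
  db <- generate_pathways(cfg, g)
  expect_length(db$sets, 50)
  expect_true(all(lengths(db$sets) >= 10 & lengths(db$sets) <= 100))
  expect_true(all(unlist(db$sets) %in% igraph::V(g)$name))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(db, path)
  db2 <- read_gmt(path, universe = db$universe)
  expect_identical(db2$sets, db$sets)
})

test_that("random draws of query genes match the hypergeometric null", {
  cfg <- sim_config(seed = 8, n_genes = 200, interactome_size = 200,
                    n_pathways = 5, pathway_size_range = c(30L, 30L),
                    planted_pathway_size = 0)
  db <- generate_pathways(cfg, generate_interactome(cfg))
  set.seed(42)
  draws <- 20L
  hits <- replicate(500, length(intersect(sample(db$universe, draws),
                                          db$sets[[1]])))
  k <- 0:min(30, draws)
  expected <- 500 * dhyper(k, 30, 170, draws)
  keep <- expected >= 1
  obs <- tabulate(hits + 1L, nbins = length(k))
  chi <- sum((obs[keep] - expected[keep])^2 / expected[keep])
  p <- pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("serialized outputs are byte-identical under a fixed config", {
  cfg <- demo_config(seed = 11, n_genes = 50, n_studies = 1,
                     n_cases = 3, n_controls = 3, n_subjects = 30,
                     interactome_size = 40, n_pathways = 5,
                     pathway_size_range = c(5L, 10L),
                     planted_pathway_size = 8L,
                     planted_pathway_overlap = 5L, n_targets = 5L)
  render <- function() {
    d <- withr::local_tempdir()
    write_study_tsv(generate_expression_studies(cfg)[[1]],
                    file.path(d, "study.tsv"))
    g <- generate_genotypes(cfg)
    write_tsv(as.data.frame(g), file.path(d, "geno.tsv"))
    write_edges(generate_interactome(cfg), file.path(d, "edges.tsv"))
    write_bed(generate_histone_intervals(cfg, generate_gwas_snps(cfg)),
              file.path(d, "marks.bed"))
    lapply(list.files(d, full.names = TRUE), readLines)
  }
  expect_identical(render(), render())
})
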