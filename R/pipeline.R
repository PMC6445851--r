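#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]. Either `sim` (a
#' [sim_config()]; the synthetic generator then produces every input) or
#' `inputs` (named file paths) must be supplied.
#'
#' @param seed Integer master seed for every stochastic stage.
#' @param out_dir Output directory (created if absent).
#' @param sim Optional [sim_config()] for a fully synthetic run.
#' @param inputs Optional named list of paths: `studies` (character
#'   vector of study TSVs, see [read_study_tsv()]), `gwas_snps`,
#'   `eqtl_table`, `genotypes`, `m_values`, `covariates`, `probe_map`,
#'   `edges`, `gmt`, `bed`, `locations`.
#' @param eqtl_p,pfp,fc,enrich_fdr,alpha Stage thresholds (defaults
#'   0.05, 0.05, 1.2, 0.05, 0.05).
#' @param B Rank-product permutation rounds (default 100).
#' @param R Enrichment resampling rounds (default 100).
#' @param cap Pairwise-comparison cap per study (default 50).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("gwastargets_"),
                            sim = NULL, inputs = NULL,
                            eqtl_p = 0.05, pfp = 0.05, fc = 1.2,
                            enrich_fdr = 0.05, alpha = 0.05,
                            B = 100L, R = 100L, cap = 50L) {
  stopifnot(eqtl_p > 0, eqtl_p <= 1, pfp > 0, fc > 0,
            enrich_fdr > 0, enrich_fdr <= 1, alpha > 0, alpha < 1,
            B >= 1L, R >= 1L)
  if (is.null(sim) && is.null(inputs))
    stop("provide either a sim config or input paths")
  if (!is.null(inputs)) {
    missing <- !vapply(unlist(inputs), file.exists, logical(1))
    if (any(missing))
      stop("input path(s) do not exist: ",
           paste(unlist(inputs)[missing], collapse = ", "))
  }
  structure(list(seed = as.integer(seed), out_dir = out_dir, sim = sim,
                 inputs = inputs, eqtl_p = eqtl_p, pfp = pfp, fc = fc,
                 enrich_fdr = enrich_fdr, alpha = alpha,
                 B = as.integer(B), R = as.integer(R),
                 cap = as.integer(cap)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `inputs`
#' is a nested mapping of paths, resolved relative to the YAML file.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$inputs)) {
    y$inputs <- lapply(y$inputs, function(p)
      ifelse(startsWith(p, "/"), p, file.path(dirname(path), p)))
  }
  if (!is.null(y$sim) && !inherits(y$sim, "sim_config")) {
    if (!is.null(y$sim$planted_de))
      y$sim$planted_de <- as.data.frame(y$sim$planted_de)
    if (!is.null(y$sim$eqtl_effects))
      y$sim$eqtl_effects <- as.data.frame(y$sim$eqtl_effects)
    if (!is.null(y$sim$meqtl_effects))
      y$sim$meqtl_effects <- as.data.frame(y$sim$meqtl_effects)
    y$sim <- do.call(sim_config, y$sim)
  }
  do.call(pipeline_config, y)
}

fmt_sci <- function(x) {
  ifelse(is.na(x), "", formatC(x, format = "E", digits = 2))
}

#' Run the end-to-end target-gene pipeline
#'
#' Stages: (1) load or simulate inputs; (2) preprocess expression
#' studies (log2 + quantile normalization); (3) rank-product
#' meta-analysis with permutation PFP; (4) eQTL filtering at the nominal
#' threshold; (5) SNP-gene integration with histone-interval annotation;
#' (6) methylation-QTL scan with the experiment-wide Bonferroni cutoff;
#' (7) first-order PPI network, hypergeometric pathway enrichment with
#' BH FDR, and permutation empirical pathway P-values. A stage failure
#' aborts with the stage name. Writes `target_table.tsv`,
#' `enrichment.tsv`, `meqtl.tsv`, `rankprod.tsv`, `network_edges.tsv`
#' and `run_log.txt` under `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stderr logging.
#' @return Invisible list with all stage results (`target_table`,
#'   `enrichment`, `meqtl`, `rankprod`, `network`, `counts`, `files`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  t0 <- proc.time()[["elapsed"]]
  log_msg <- function(...) {
    line <- sprintf("[%7.2fs] %s", proc.time()[["elapsed"]] - t0,
                    sprintf(...))
    writeLines(line, log_con)
    if (!quiet) message(line)
  }
  stage <- function(name, expr) {
    log_msg("stage %s", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  log_msg("gwastargets %s | seed %d | R %s",
          as.character(utils::packageVersion("gwastargets")),
          config$seed, R.version.string)

  dat <- stage("load_inputs", {
    if (!is.null(config$sim)) {
      cfg <- config$sim
      studies <- generate_expression_studies(cfg)
      genotypes <- generate_genotypes(cfg)
      meth <- generate_methylation(cfg, genotypes)
      gwas <- generate_gwas_snps(cfg)
      eqtl <- generate_eqtl_table(cfg, genotypes)
      graph <- generate_interactome(cfg)
      seeds0 <- unique(cfg$eqtl_effects$gene) %||%
        gene_universe(cfg)[1:5]
      pathways <- generate_pathways(cfg, graph, seeds0)
      bed <- generate_histone_intervals(cfg, gwas, cover = c(3L, 5L))
      list(studies = studies, genotypes = genotypes,
           m_values = meth$m_values, covariates = meth$covariates,
           probe_map = meth$probe_map, gwas = gwas, eqtl = eqtl,
           graph = graph, pathways = pathways, bed = bed,
           locations = NULL)
    } else {
      inp <- config$inputs
      list(studies = lapply(inp$studies, read_study_tsv),
           genotypes = as.matrix(read.delim(inp$genotypes,
                                            row.names = 1L)),
           m_values = as.matrix(read.delim(inp$m_values,
                                           row.names = 1L)),
           covariates = read.delim(inp$covariates, row.names = 1L),
           probe_map = read_tsv(inp$probe_map),
           gwas = read_tsv(inp$gwas_snps),
           eqtl = read_eqtl_table(inp$eqtl_table),
           graph = read_edges(inp$edges),
           pathways = read_gmt(inp$gmt),
           bed = read_bed(inp$bed),
           locations = if (!is.null(inp$locations))
             read_tsv(inp$locations) else NULL)
    }
  })

  studies <- stage("preprocess", lapply(dat$studies, preprocess_study))

  rp <- stage("rankprod",
              rank_product_analysis(studies, cap = config$cap,
                                    B = config$B, seed = config$seed))
  degs <- filter_degs(rp, pfp_max = config$pfp, fc_min = config$fc)
  log_msg("rankprod: %d/%d genes pass PFP < %g & |FC| > %g",
          nrow(degs), nrow(rp), config$pfp, config$fc)

  eq <- stage("eqtl", filter_eqtl(dat$eqtl, p_max = config$eqtl_p))
  log_msg("eqtl: %d associations, %d distinct genes at p < %g",
          nrow(eq$records), length(eq$genes), config$eqtl_p)

  target <- stage("integrate", {
    tt <- build_target_table(dat$gwas, eq$records, degs,
                             locations = dat$locations,
                             eqtl_p_max = config$eqtl_p,
                             pfp_max = config$pfp, fc_min = config$fc)
    annotate_histone_overlap(tt, dat$bed)
  })
  dir_counts <- classify_direction(target)
  log_msg("integration: %d pairs, %d genes (%d up / %d down), %d SNPs",
          nrow(target), attr(target, "n_genes"), dir_counts[["up"]],
          dir_counts[["down"]], attr(target, "n_snps"))

  meqtl <- stage("methylation", {
    recs <- run_meqtl_scan(target, dat$m_values, dat$genotypes,
                           dat$covariates, dat$probe_map)
    tested <- sum(!recs$untestable)
    cut <- bonferroni_cutoff(config$alpha, max(tested, 1L))
    cs <- count_significant(recs, cut$cutoff)
    log_msg("methylation: %d pairs tested, cutoff %s, %d significant",
            tested, cut$display, cs$n)
    list(records = cs$records, cutoff = cut, n_significant = cs$n,
         n_tested = tested)
  })

  net <- stage("network_enrichment", {
    seeds <- unique(target$gene)
    if (!length(seeds)) {
      log_msg("network: no target genes; skipping enrichment")
      NULL
    } else {
      ne <- network_enrichment(dat$graph, dat$pathways, seeds,
                               fdr_max = config$enrich_fdr,
                               R = config$R, seed = config$seed)
      log_msg("network: %d nodes, %d significant pathways",
              igraph::vcount(ne$network$graph),
              sum(ne$enrichment$fdr < config$enrich_fdr))
      ne
    }
  })

  files <- stage("report", {
    tt_out <- target
    tt_out$gwas_p_display <- fmt_sci(tt_out$gwas_p)
    tt_out$eqtl_p_display <- fmt_sci(tt_out$eqtl_p)
    tt_out$pfp_display <- fmt_sci(tt_out$pfp)
    f <- c(target_table = file.path(config$out_dir, "target_table.tsv"),
           meqtl = file.path(config$out_dir, "meqtl.tsv"),
           rankprod = file.path(config$out_dir, "rankprod.tsv"))
    write_tsv(tt_out, f[["target_table"]])
    mq <- meqtl$records
    mq$p_display <- fmt_sci(mq$p)
    write_tsv(mq, f[["meqtl"]])
    write_tsv(rp, f[["rankprod"]])
    if (!is.null(net)) {
      en <- net$enrichment
      en$p_display <- fmt_sci(en$p)
      en$fdr_display <- fmt_sci(en$fdr)
      f[["enrichment"]] <- file.path(config$out_dir, "enrichment.tsv")
      write_tsv(en, f[["enrichment"]])
      f[["network_edges"]] <- file.path(config$out_dir,
                                        "network_edges.tsv")
      write_edges(net$network$graph, f[["network_edges"]])
    }
    f
  })
  log_msg("done")

  invisible(list(target_table = target, direction_counts = dir_counts,
                 enrichment = if (!is.null(net)) net$enrichment,
                 network = if (!is.null(net)) net$network,
                 meqtl = meqtl, rankprod = rp, degs = degs,
                 eqtl = eq, files = files, log = log_path))
}
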