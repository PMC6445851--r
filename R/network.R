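#' Pathway database with background universe
#'
#' Named gene sets plus the background universe against which enrichment
#' is evaluated. Sets must be non-empty and contained in the universe.
#' The default universe for this pipeline is the set of interactome
#' genes carrying at least one pathway annotation (configurable — see
#' the enrichment functions).
#'
#' @param sets Named list of character vectors.
#' @param universe Character vector of background genes.
#' @return Object of class `pathway_db`.
#' @export
pathway_db <- function(sets, universe) {
  stopifnot(is.list(sets), length(sets) > 0L,
            !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, unique)
  if (any(lengths(sets) == 0L)) stop("empty pathway set")
  outside <- setdiff(unlist(sets), universe)
  if (length(outside))
    stop("pathway genes outside the universe: ",
         paste(head(outside, 5), collapse = ", "))
  structure(list(sets = sets, universe = unique(universe)),
            class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("<pathway_db> %d sets (sizes %d-%d), universe %d genes\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets)),
              length(x$universe)))
  invisible(x)
}

#' Build an interactome graph from an edge list
#'
#' Undirected simple graph: self-loops and duplicate edges are removed.
#'
#' @param edges data.frame whose first two columns are gene symbols.
#' @return An `igraph` object.
#' @export
interactome_from_edges <- function(edges) {
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
  igraph::simplify(g)
}

#' First-order interaction subnetwork around seed genes
#'
#' Nodes are the seeds present in the interactome plus all their direct
#' interactors; edges are every interactome edge among those nodes
#' (induced subgraph). Seeds absent from the interactome are reported,
#' not silently dropped; present seeds without interactors are retained
#' as isolated nodes.
#'
#' @param interactome `igraph` interactome with named vertices.
#' @param seeds Non-empty character vector of seed genes.
#' @return List with `graph` (the subnetwork), `roles` (named
#'   `"seed"`/`"interactor"` per node) and `missing` (seeds not in the
#'   interactome).
#' @export
first_order_network <- function(interactome, seeds) {
  if (!length(seeds)) stop("empty seed list")
  seeds <- unique(seeds)
  present <- intersect(seeds, igraph::V(interactome)$name)
  missing <- setdiff(seeds, present)
  if (!length(present)) {
    return(list(graph = igraph::make_empty_graph(directed = FALSE),
                roles = setNames(character(0), character(0)),
                missing = missing))
  }
  nb <- unique(names(unlist(igraph::ego(interactome, order = 1L,
                                        nodes = present))))
  sub <- igraph::induced_subgraph(interactome, nb)
  roles <- setNames(ifelse(igraph::V(sub)$name %in% present,
                           "seed", "interactor"),
                    igraph::V(sub)$name)
  list(graph = sub, roles = roles, missing = missing)
}

#' Hypergeometric pathway enrichment of a gene list
#'
#' For each pathway, the upper-tail hypergeometric probability of
#' observing at least the attained overlap: population = background
#' universe, successes = pathway size in the universe (`Total`), draws =
#' the query genes present in the universe. `Expected = Total x draws /
#' |universe|`.
#'
#' @param genes Character vector (e.g. first-order network nodes);
#'   intersected with the universe before testing.
#' @param pathways A [pathway_db()].
#' @return data.frame with `pathway`, `total`, `expected`, `hits`, `p`,
#'   ordered as in the database.
#' @export
hypergeom_enrich <- function(genes, pathways) {
  stopifnot(inherits(pathways, "pathway_db"))
  universe <- pathways$universe
  draws <- length(intersect(unique(genes), universe))
  n_univ <- length(universe)
  rows <- lapply(names(pathways$sets), function(nm) {
    set <- pathways$sets[[nm]]
    total <- length(set)
    hits <- length(intersect(genes, set))
    p <- phyper(hits - 1L, total, n_univ - total, draws,
                lower.tail = FALSE)
    data.frame(pathway = nm, total = total,
               expected = total * draws / n_univ, hits = hits, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `adj_i = min_{j >= i} (p_(j) * m / j)` capped at 1, returned in input
#' order. `m` is the total number of tests, which may exceed the length
#' of `p` when only the smallest P-values of a larger family are passed
#' in.
#'
#' @param p Numeric vector of P-values in [0, 1].
#' @param m Total number of tests (default `length(p)`).
#' @return Adjusted values, same order as `p`.
#' @export
bh_fdr <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), m >= length(p))
  p.adjust(p, method = "BH", n = m)
}

#' Format a permutation empirical P-value
#'
#' `b/R` as a number; when the pathway never recurs (`b = 0`) the
#' conventional censored token `"<1/R"` is rendered (e.g. `"<0.01"` at
#' R = 100).
#'
#' @param b Number of significant resamples.
#' @param R Number of resamples.
#' @return Character scalar.
#' @export
format_empirical_p <- function(b, R) {
  if (b == 0) paste0("<", format(signif(1 / R, 2))) else format(b / R)
}

#' Permutation-derived empirical pathway P-values
#'
#' Repeats the whole network-enrichment analysis on R random gene lists
#' of the observed size: each resample draws `list_size` genes uniformly
#' without replacement, rebuilds the first-order network, reruns
#' hypergeometric enrichment and BH adjustment, and records the pathways
#' with `FDR < fdr_max`. A pathway's empirical P is `b/R`, the fraction
#' of resamples in which it comes out significant; `b = 0` is rendered
#' `"<1/R"`.
#'
#' Random lists are drawn from the pathway-annotated universe by default
#' so the null matches the enrichment background; set
#' `draw_from = "interactome"` to draw from all interactome genes
#' instead.
#'
#' @param interactome `igraph` interactome.
#' @param pathways A [pathway_db()].
#' @param observed data.frame from [hypergeom_enrich()] for the real
#'   seed list (only its `pathway` column is used; pass `NULL` to
#'   report every pathway).
#' @param list_size Size of each random seed list.
#' @param R Number of resamples (default 100).
#' @param fdr_max Within-resample significance threshold (default 0.05).
#' @param seed Integer seed.
#' @param draw_from `"universe"` (pathway-annotated genes) or
#'   `"interactome"`.
#' @return data.frame `pathway`, `b`, `empirical_p` (numeric `b/R`) and
#'   `empirical_display` (with the `"<1/R"` convention).
#' @export
empirical_pathway_pvalues <- function(interactome, pathways,
                                      observed = NULL, list_size,
                                      R = 100L, fdr_max = 0.05,
                                      seed = 1L,
                                      draw_from = c("universe",
                                                    "interactome")) {
  stopifnot(R >= 1L, list_size >= 1L)
  draw_from <- match.arg(draw_from)
  pool <- if (draw_from == "universe") pathways$universe
          else igraph::V(interactome)$name
  if (list_size > length(pool))
    stop("list_size exceeds the sampling universe")
  target <- if (is.null(observed)) names(pathways$sets)
            else observed$pathway
  b <- setNames(integer(length(target)), target)
  withr::with_seed(stream_seed(seed, "resample"), {
    for (r in seq_len(R)) {
      rand <- sample(pool, list_size)
      fon <- first_order_network(interactome, rand)
      enr <- hypergeom_enrich(igraph::V(fon$graph)$name, pathways)
      enr$fdr <- bh_fdr(enr$p)
      sig <- enr$pathway[enr$fdr < fdr_max]
      hit <- intersect(target, sig)
      b[hit] <- b[hit] + 1L
    }
  })
  data.frame(pathway = target, b = unname(b),
             empirical_p = unname(b) / R,
             empirical_display = vapply(unname(b), format_empirical_p,
                                        character(1), R = R),
             stringsAsFactors = FALSE)
}

#' End-to-end network enrichment for a seed gene list
#'
#' Convenience wrapper: first-order network, hypergeometric enrichment,
#' BH FDR over all tested pathways, and (optionally) permutation
#' empirical P-values for the significant pathways.
#'
#' @inheritParams empirical_pathway_pvalues
#' @param seeds Character vector of target genes.
#' @param empirical Whether to run the permutation stage.
#' @return List with `network` (from [first_order_network()]) and
#'   `enrichment` (data.frame with `fdr` and, for significant rows,
#'   empirical columns).
#' @export
network_enrichment <- function(interactome, pathways, seeds,
                               fdr_max = 0.05, R = 100L, seed = 1L,
                               empirical = TRUE,
                               draw_from = c("universe",
                                             "interactome")) {
  fon <- first_order_network(interactome, seeds)
  enr <- hypergeom_enrich(igraph::V(fon$graph)$name, pathways)
  enr$fdr <- bh_fdr(enr$p)
  enr <- enr[order(enr$p), , drop = FALSE]
  rownames(enr) <- NULL
  if (empirical) {
    sig <- enr[enr$fdr < fdr_max, , drop = FALSE]
    emp <- empirical_pathway_pvalues(interactome, pathways, sig,
                                     list_size = length(unique(seeds)),
                                     R = R, fdr_max = fdr_max,
                                     seed = seed,
                                     draw_from = match.arg(draw_from))
    enr <- merge(enr, emp, by = "pathway", all.x = TRUE, sort = FALSE)
    enr <- enr[order(enr$p), , drop = FALSE]
    rownames(enr) <- NULL
  }
  list(network = fon, enrichment = enr)
}
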