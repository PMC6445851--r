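#' Per-study case-vs-control pairwise comparisons
#'
#' The rank-product statistic for two unpaired classes is built on
#' single-sample comparisons: a case x control sample pair within a
#' study yields one per-gene log2 fold-change vector (case minus
#' control). Under `scheme = "disjoint"` (the default) each sample is
#' used in at most one pair per study — a seeded random 1:1 matching of
#' cases to controls — so comparisons are mutually independent under the
#' null, which is what the within-comparison permutation null of
#' [estimate_pfp()] assumes. `scheme = "all"` enumerates every case x
#' control pair instead (comparisons then share samples and are
#' correlated). Pairs are capped at `cap` seeded random pairs per study;
#' comparisons are pooled across studies with their study of origin
#' recorded, genes restricted to those shared by all studies.
#'
#' @param studies List of [expression_study()] objects on the log2 scale.
#' @param cap Maximum comparisons per study (`Inf` for no cap).
#' @param seed Integer seed for the pair subsample.
#' @param scheme `"disjoint"` (1:1 matching, independent comparisons) or
#'   `"all"` (every case x control pair).
#' @return List with `fc` (genes x comparisons matrix of log2 fold
#'   changes) and `study` (integer study of origin per comparison).
#' @export
pairwise_comparisons <- function(studies, cap = 50L, seed = 1L,
                                 scheme = c("disjoint", "all")) {
  stopifnot(length(studies) >= 1L)
  scheme <- match.arg(scheme)
  genes <- Reduce(intersect, lapply(studies, function(s)
    rownames(s$values)))
  if (!length(genes)) stop("studies share no genes")
  withr::with_seed(stream_seed(seed, "pairs"), {
    per_study <- lapply(seq_along(studies), function(s) {
      st <- studies[[s]]
      ca <- case_cols(st); co <- control_cols(st)
      if (!length(ca) || !length(co))
        stop(sprintf("study '%s' lacks a %s class", st$study_id,
                     if (!length(ca)) "case" else "control"))
      if (scheme == "all") {
        pairs <- expand.grid(case = ca, control = co)
      } else {
        k <- min(length(ca), length(co))
        pairs <- data.frame(case = sample(ca)[seq_len(k)],
                            control = sample(co)[seq_len(k)])
      }
      if (nrow(pairs) > cap)
        pairs <- pairs[sample.int(nrow(pairs), cap), , drop = FALSE]
      v <- st$values[genes, , drop = FALSE]
      fc <- v[, pairs$case, drop = FALSE] - v[, pairs$control, drop = FALSE]
      colnames(fc) <- sprintf("%s_c%d", st$study_id, seq_len(nrow(pairs)))
      fc
    })
    fc <- do.call(cbind, per_study)
    rownames(fc) <- genes
    list(fc = fc,
         study = rep(seq_along(studies),
                     vapply(per_study, ncol, integer(1))))
  })
}

rank_matrix <- function(fc, direction = c("up", "down")) {
  direction <- match.arg(direction)
  apply(fc, 2L, function(x)
    rank(if (direction == "up") -x else x, ties.method = "average"))
}

#' Rank product across comparisons
#'
#' Within each comparison genes are ranked by log2 fold change
#' (descending for `"up"`, ascending for `"down"`; ties receive
#' mid-ranks), and the rank product of gene g over k comparisons is the
#' geometric mean rank `RP_g = (prod_c r_gc)^(1/k)`. A small RP means the
#' gene is consistently at the extreme of every comparison.
#'
#' @param fc Genes x comparisons matrix of log2 fold changes (all
#'   comparisons over the same genes), or a precomputed rank matrix via
#'   `ranks`.
#' @param direction `"up"` or `"down"`.
#' @param ranks Optional precomputed rank matrix (overrides `fc`).
#' @return Named numeric vector of per-gene RP values in `[1, n_genes]`.
#' @export
rank_product <- function(fc, direction = c("up", "down"), ranks = NULL) {
  if (is.null(ranks)) {
    stopifnot(ncol(fc) >= 1L)
    ranks <- rank_matrix(fc, match.arg(direction))
  }
  rp <- exp(rowMeans(log(ranks)))
  names(rp) <- rownames(ranks)
  rp
}

#' Permutation-estimated proportion of false positives (PFP)
#'
#' For b = 1..B the observed rank vector of every comparison is permuted
#' uniformly (and independently across comparisons — for pooled
#' multi-study comparisons this permutes within, never across, studies),
#' yielding null rank products. With `x(g)` the count of null genes with
#' RP at or below gene g's observed RP, `E[x](g) = x(g)/B` and
#' `PFP(g) = E[x](g) / rank(g)` where genes are ranked by observed RP
#' ascending. PFP estimates the expected proportion of false positives
#' among genes called at g's threshold; values are reported untruncated,
#' together with a monotone step-down cumulative-minimum variant.
#'
#' @param observed_rp Named vector of observed rank products.
#' @param ranks Observed rank matrix (genes x comparisons) whose columns
#'   are permuted under the null.
#' @param B Number of permutation rounds (>= 1).
#' @param seed Integer seed.
#' @return data.frame with `gene`, `rp`, `e_x` (expected null count),
#'   `pfp` and `pfp_mono`.
#' @export
estimate_pfp <- function(observed_rp, ranks, B = 100L, seed = 1L) {
  stopifnot(B >= 1L, nrow(ranks) == length(observed_rp))
  n <- length(observed_rp)
  k <- ncol(ranks)
  counts <- numeric(n)
  ord <- order(observed_rp)
  obs_sorted <- observed_rp[ord]
  withr::with_seed(stream_seed(seed, "pfp"), {
    for (b in seq_len(B)) {
      null_ranks <- apply(ranks, 2L, sample)
      null_rp <- exp(rowMeans(log(matrix(null_ranks, n, k))))
      counts <- counts + findInterval(obs_sorted, sort(null_rp))
    }
  })
  e_x <- counts / B
  pos <- rank(obs_sorted, ties.method = "max")
  pfp_sorted <- e_x / pos
  pfp_mono <- rev(cummin(rev(pfp_sorted)))
  gene <- names(observed_rp) %||% as.character(seq_len(n))
  out <- data.frame(gene = gene[ord], rp = unname(obs_sorted),
                    e_x = e_x, pfp = pfp_sorted, pfp_mono = pfp_mono,
                    stringsAsFactors = FALSE)
  out <- out[order(ord), , drop = FALSE]  # back to input gene order
  rownames(out) <- NULL
  out
}

#' Signed fold change pooled across studies
#'
#' Per study the case/control ratio of geometric-mean intensities equals
#' `2^(mean log2 case - mean log2 control)`; per-study log2 ratios are
#' pooled by unweighted mean over the studies containing the gene, giving
#' a ratio r reported on the symmetric signed scale: `FC = r` when
#' `r >= 1`, else `-1/r` (so +/-1.2 thresholds are symmetric and
#' `r = 1 -> FC = 1`).
#'
#' @param studies List of log2-scale [expression_study()] objects.
#' @param genes Genes to report; default all genes present anywhere.
#' @return Named numeric vector of signed fold changes.
#' @export
signed_fold_change <- function(studies, genes = NULL) {
  all_genes <- unique(unlist(lapply(studies, function(s)
    rownames(s$values))))
  genes <- genes %||% all_genes
  absent <- setdiff(genes, all_genes)
  if (length(absent))
    stop("gene(s) absent from every study: ",
         paste(absent, collapse = ", "))
  d <- vapply(genes, function(g) {
    per <- vapply(studies, function(s) {
      if (!g %in% rownames(s$values)) return(NA_real_)
      mean(s$values[g, case_cols(s)]) - mean(s$values[g, control_cols(s)])
    }, numeric(1))
    mean(per, na.rm = TRUE)
  }, numeric(1))
  r <- 2^d
  setNames(ifelse(r >= 1, r, -1 / r), genes)
}

#' Full rank-product meta-analysis of case/control studies
#'
#' Runs [pairwise_comparisons()], evaluates [rank_product()] and
#' [estimate_pfp()] separately for up- and down-regulation, and attaches
#' the pooled [signed_fold_change()].
#'
#' @param studies List of log2-scale [expression_study()] objects.
#' @param cap Comparison cap per study (see [pairwise_comparisons()]).
#' @param B Permutation rounds for the PFP estimate.
#' @param seed Integer seed covering pair subsampling and permutations.
#' @param scheme Comparison scheme (see [pairwise_comparisons()]).
#' @return data.frame with one row per shared gene: `gene`, `rp_up`,
#'   `rp_down`, `pfp_up`, `pfp_down`, `pfp_up_mono`, `pfp_down_mono`,
#'   `fc`, `direction` (side with the smaller PFP) and `k` (number of
#'   comparisons).
#' @export
rank_product_analysis <- function(studies, cap = 50L, B = 100L,
                                  seed = 1L,
                                  scheme = c("disjoint", "all")) {
  cmp <- pairwise_comparisons(studies, cap = cap, seed = seed,
                              scheme = match.arg(scheme))
  res <- list()
  for (dir in c("up", "down")) {
    ranks <- rank_matrix(cmp$fc, dir)
    rp <- rank_product(ranks = ranks)
    res[[dir]] <- estimate_pfp(rp, ranks, B = B, seed = seed)
  }
  fc <- signed_fold_change(studies, rownames(cmp$fc))
  data.frame(gene = rownames(cmp$fc),
             rp_up = res$up$rp, rp_down = res$down$rp,
             pfp_up = res$up$pfp, pfp_down = res$down$pfp,
             pfp_up_mono = res$up$pfp_mono,
             pfp_down_mono = res$down$pfp_mono,
             fc = unname(fc),
             direction = ifelse(res$up$pfp <= res$down$pfp, "up", "down"),
             k = ncol(cmp$fc),
             stringsAsFactors = FALSE)
}

#' Call differentially expressed genes
#'
#' Keeps genes with `min(pfp_up, pfp_down) < pfp_max` (strict) and
#' `|FC| > fc_min` (strict); the reported direction comes from the
#' smaller-PFP side, and genes significant in both directions are flagged
#' inconsistent.
#'
#' @param results data.frame from [rank_product_analysis()].
#' @param pfp_max PFP threshold (default 0.05).
#' @param fc_min Absolute fold-change threshold (default 1.2).
#' @return Subset of `results` with columns `pfp` (the minimum side),
#'   `direction` and `inconsistent` added.
#' @export
filter_degs <- function(results, pfp_max = 0.05, fc_min = 1.2) {
  stopifnot(pfp_max > 0, fc_min > 0)
  pfp <- pmin(results$pfp_up, results$pfp_down)
  keep <- pfp < pfp_max & abs(results$fc) > fc_min
  out <- results[keep, , drop = FALSE]
  out$pfp <- pfp[keep]
  out$direction <- ifelse(out$pfp_up <= out$pfp_down, "up", "down")
  out$inconsistent <- out$pfp_up < pfp_max & out$pfp_down < pfp_max
  rownames(out) <- NULL
  out
}
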