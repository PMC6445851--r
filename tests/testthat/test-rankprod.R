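test_that("pairwise comparisons enumerate case x control pairs per study", {
  s1 <- toy_log2_study(n_genes = 10, n_case = 2, n_control = 3, seed = 1,
                       id = "s1")
  s2 <- toy_log2_study(n_genes = 10, n_case = 3, n_control = 3, seed = 2,
                       id = "s2")
  cmp <- pairwise_comparisons(list(s1), cap = Inf, scheme = "all")
  expect_identical(ncol(cmp$fc), 6L)  # 2 x 3
  cmp2 <- pairwise_comparisons(list(s1, s2), cap = Inf, scheme = "all")
  expect_identical(ncol(cmp2$fc), 15L)  # 6 + 9
  expect_identical(cmp2$study, rep(1:2, c(6L, 9L)))
  # a sampled subset is reproducible under the seed
  a <- pairwise_comparisons(list(s1, s2), cap = 4L, seed = 7,
                            scheme = "all")
  b <- pairwise_comparisons(list(s1, s2), cap = 4L, seed = 7,
                            scheme = "all")
  expect_identical(a, b)
  expect_identical(ncol(a$fc), 8L)
  # fold changes really are case minus control differences
  expect_equal(cmp$fc[, 1],
               s1$values[, case_cols(s1)[1]] -
                 s1$values[, control_cols(s1)[1]])
  # disjoint matching uses each sample at most once per study
  d <- pairwise_comparisons(list(s1, s2), cap = Inf)
  expect_identical(ncol(d$fc), 5L)  # min(2,3) + min(3,3)
  expect_identical(d, pairwise_comparisons(list(s1, s2), cap = Inf))
  one_class <- study_from_matrix(matrix(1:4, 2, 2),
                                 c("case", "case"))
  expect_error(pairwise_comparisons(list(one_class)), "control class")
})

test_that("rank product is the geometric mean of within-comparison ranks", {
  # gene ranked 1 everywhere attains the minimum RP of 1
  fc <- cbind(c(5, 1, 0), c(4, 2, 1), c(9, 3, 1))
  rownames(fc) <- c("best", "mid", "low")
  rp <- rank_product(fc, "up")
  expect_equal(unname(rp["best"]), 1)
  # ranks (2, 3, 6) -> 36^(1/3)
  ranks <- cbind(c(2, 1, 3), c(3, 1, 2), c(6, 1, 2))
  rownames(ranks) <- c("g1", "g2", "g3")
  expect_equal(unname(rank_product(ranks = ranks)["g1"]), 36^(1 / 3),
               tolerance = 1e-12)
  # ties get mid-ranks
  fc_t <- cbind(c(2, 2, 1))
  rownames(fc_t) <- paste0("g", 1:3)
  r <- rank_product(fc_t, "up")
  expect_equal(unname(r[1:2]), c(1.5, 1.5))
  # down-direction ranks ascending
  expect_equal(unname(rank_product(cbind(c(-3, 0, 2)), "down")),
               c(1, 2, 3))
})

test_that("rank product is invariant to monotone transformations of fold changes", {
  withr::with_seed(5, fc <- matrix(rnorm(60), 20, 3))
  rownames(fc) <- sprintf("g%02d", 1:20)
  for (dir in c("up", "down")) {
    base <- rank_product(fc, dir)
    expect_equal(rank_product(3 * fc + 1, dir), base)
    expect_equal(rank_product(exp(fc), dir), base)
    expect_equal(rank_product(fc^3, dir), base)
  }
})

test_that("PFP matches the exhaustive permutation oracle at tiny n", {
  # 3 genes, k = 2; observed: gene A ranked 1 in both comparisons
  ranks <- cbind(c(1, 2, 3), c(1, 3, 2))
  rownames(ranks) <- c("A", "B", "C")
  obs <- rank_product(ranks = ranks)
  # exhaustive null over all (3!)^2 = 36 within-comparison permutations
  exhaust <- function(obs_rp) {
    counts <- numeric(length(obs_rp))
    for (i in seq_len(nrow(perms3))) {
      for (j in seq_len(nrow(perms3))) {
        null_rp <- sqrt(perms3[i, ] * perms3[j, ])
        counts <- counts + vapply(obs_rp, function(o)
          sum(null_rp <= o), numeric(1))
      }
    }
    e_x <- counts / 36
    e_x / rank(obs_rp, ties.method = "max")
  }
  oracle <- exhaust(obs)
  expect_equal(unname(oracle["A"]), 1 / 3, tolerance = 1e-12)
  est <- estimate_pfp(obs, ranks, B = 10000L, seed = 1)
  expect_identical(est$gene, c("A", "B", "C"))
  expect_true(all(abs(est$pfp - unname(oracle)) < 0.05))
  # determinism under the seed
  expect_identical(est, estimate_pfp(obs, ranks, B = 10000L, seed = 1))
  expect_error(estimate_pfp(obs, ranks, B = 0L), "B >= 1")
})

test_that("worst-ranked genes carry PFP of at least one", {
  n <- 6
  ranks <- cbind(1:n, 1:n)
  rownames(ranks) <- paste0("g", 1:n)
  obs <- rank_product(ranks = ranks)
  est <- estimate_pfp(obs, ranks, B = 200L, seed = 2)
  expect_gte(est$pfp[n], 1)
  # the monotone variant never exceeds the raw estimate downstream
  ord <- order(est$rp)
  expect_true(all(diff(est$pfp_mono[ord]) >= -1e-12))
  expect_true(all(est$pfp_mono <= est$pfp + 1e-12))
})

test_that("signed fold change follows the reciprocal-sign convention", {
  # one gene doubled, one halved, one flat; zero noise
  shift <- c(1, -1, 0)  # log2 shifts for cases
  st <- toy_log2_study(n_genes = 3, shift = shift, seed = 3)
  fc <- signed_fold_change(list(st))
  expect_equal(unname(fc), c(2, -2, 1), tolerance = 1e-12)
  # pooling across studies is the unweighted mean of log2 ratios
  st2 <- toy_log2_study(n_genes = 3, shift = c(3, -3, 0), seed = 4,
                        id = "s2")
  pooled <- signed_fold_change(list(st, st2))
  expect_equal(unname(pooled[1]), 2^2, tolerance = 1e-12)
  expect_error(signed_fold_change(list(st), genes = "nope"),
               "absent from every study")
})

test_that("DEG filter applies strict PFP and fold-change thresholds", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    rp_up = 1, rp_down = 1,
                    pfp_up = c(0.03, 0.03, 0.05, 0.2),
                    pfp_down = c(0.5, 0.9, 0.9, 0.01),
                    fc = c(1.3, 1.1, 1.5, -1.25),
                    stringsAsFactors = FALSE)
  out <- filter_degs(res)
  expect_identical(out$gene, c("a", "d"))
  expect_identical(out$direction, c("up", "down"))
  # b fails FC (1.1 <= 1.2); c fails PFP (0.05 not < 0.05)
  expect_false("b" %in% out$gene)
  expect_false("c" %in% out$gene)
})

test_that("planted DE genes are recovered by the full meta-analysis", {
  pd <- data.frame(gene = sprintf("G%04d", 1:5), fc = 2.0,
                   direction = rep(c("up", "down"), length.out = 5))
  cfg <- sim_config(seed = 31, n_genes = 200, n_studies = 2,
                    n_cases = c(5, 5), n_controls = c(5, 5),
                    planted_de = pd, noise_sd = 0.3)
  studies <- lapply(generate_expression_studies(cfg), preprocess_study)
  res <- rank_product_analysis(studies, cap = 25L, B = 50L, seed = 31)
  degs <- filter_degs(res)
  expect_true(all(pd$gene %in% degs$gene))
  hit <- degs[match(pd$gene, degs$gene), ]
  expect_identical(hit$direction, pd$direction)
  expect_true(all(sign(hit$fc) == ifelse(pd$direction == "up", 1, -1)))
})
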