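# Small in-code builders shared across the suite.

study_from_matrix <- function(m, labels, id = "s1") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("G%04d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("%s_smp%d", id, seq_len(ncol(m)))
  expression_study(id, m, labels)
}

# deterministic two-class log2-scale study with optional planted shifts
toy_log2_study <- function(n_genes = 20, n_case = 3, n_control = 3,
                           shift = numeric(n_genes), noise_sd = 0,
                           seed = 1, id = "s1") {
  withr::with_seed(seed, {
    n <- n_case + n_control
    m <- matrix(8 + rnorm(n_genes * n, sd = noise_sd), n_genes, n)
    labels <- c(rep("case", n_case), rep("control", n_control))
    m[, labels == "case"] <- m[, labels == "case"] + shift
    study_from_matrix(m, labels, id)
  })
}

# all 6 permutations of 1:3, for exhaustive rank-product nulls
perms3 <- local({
  p <- expand.grid(a = 1:3, b = 1:3, c = 1:3)
  p <- p[apply(p, 1, function(x) length(unique(x)) == 3), ]
  unname(as.matrix(p))
})

# independent Tukey median-polish sweep (oracle; deliberately naive)
naive_median_polish <- function(x, tol = 1e-6, maxiter = 20) {
  overall <- 0
  re <- rep(0, nrow(x)); ce <- rep(0, ncol(x))
  r <- x
  for (i in seq_len(maxiter)) {
    rm_ <- apply(r, 1, median)
    r <- sweep(r, 1, rm_); re <- re + rm_
    d <- median(ce); ce <- ce - d; overall <- overall + d
    cm <- apply(r, 2, median)
    r <- sweep(r, 2, cm); ce <- ce + cm
    d <- median(re); re <- re - d; overall <- overall + d
    if (max(abs(c(rm_, cm))) < tol) break
  }
  list(overall = overall, row = re, col = ce, residuals = r)
}

# closed-form simple-OLS slope/p oracle via normal equations
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(x)
  rss <- sum((y - a - b * x)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  t <- b / se
  list(slope = b, p = 2 * pt(-abs(t), df = n - 2))
}

# exhaustive upper-tail hypergeometric p by enumerating all draws
hyper_enum <- function(n_univ, total, draws, hits) {
  universe <- seq_len(n_univ)
  inset <- universe <= total
  cmb <- utils::combn(n_univ, draws)
  mean(colSums(matrix(inset[cmb], nrow = draws)) >= hits)
}

# hand BH step-up
bh_oracle <- function(p, m = length(p)) {
  o <- order(p)
  adj <- p[o] * m / seq_along(p)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}
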