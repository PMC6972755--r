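# Shared fixture builders and independent oracles used across tests.

# Seven near-orthogonal temporal patterns (discrete-cosine shapes) over m
# conditions, `genes_per` genes each, plus Gaussian noise.  Orthogonality
# makes the planted modules genuinely distinct in correlation space.
make_temporal_patterns <- function(seed, n_patterns = 7, genes_per = 10,
                                   m = 9, sd = 0.25) {
  set.seed(seed)
  i <- seq_len(m)
  pats <- t(sapply(seq_len(n_patterns),
                   function(k) cos(pi * k * (i - 0.5) / m)))
  pats <- t(scale(t(pats)))
  p <- pats[rep(seq_len(n_patterns), each = genes_per), ] +
    matrix(rnorm(n_patterns * genes_per * m, sd = sd), ncol = m)
  rownames(p) <- sprintf("g%03d", seq_len(nrow(p)))
  attr(p, "truth") <- rep(seq_len(n_patterns), each = genes_per)
  p
}

# Adjusted Rand index between two labelings (independent of the package).
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  expected <- sum_i * sum_j / comb2(n)
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}

# Two centered vectors of length n with Pearson correlation exactly r
# (Gram-Schmidt construction).
make_pair_with_cor <- function(n, r, seed) {
  set.seed(seed)
  x <- rnorm(n)
  y0 <- rnorm(n)
  xc <- scale(x, scale = FALSE)[, 1]
  u <- xc / sqrt(sum(xc^2))
  y0c <- scale(y0, scale = FALSE)[, 1]
  v <- y0c - sum(y0c * u) * u
  v <- v / sqrt(sum(v^2))
  y <- r * u + sqrt(1 - r^2) * v
  cbind(x = x, y = y)
}

# Exact two-sided rank-sum p-value by full enumeration of group
# assignments (no ties assumed), mirroring the exact two-sided convention
# 2 * min(P(W <= w), P(W >= w)) capped at 1.
exact_wilcoxon_p <- function(va, vb) {
  pooled <- c(va, vb)
  n <- length(pooled)
  na <- length(va)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  splits <- combn(n, na)
  w_all <- apply(splits, 2, function(idx) {
    sum(rank(pooled)[idx]) - na * (na + 1) / 2
  })
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Exact two-sided Fisher p for a 2x2 table by hypergeometric enumeration:
# sum the probabilities of all tables (fixed margins) no more probable
# than the observed one.
exact_fisher_p <- function(tab) {
  a <- tab[1, 1]
  K <- sum(tab[1, ])
  k <- sum(tab[, 1])
  N <- sum(tab)
  lo <- max(0, k - (N - K))
  hi <- min(k, K)
  probs <- dhyper(lo:hi, K, N - K, k)
  p_obs <- dhyper(a, K, N - K, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Cells x genes dataset in which two disjoint gene blocks each share a
# latent factor (within-block correlation ~ rho^2); remaining genes are
# independent noise.  Two such datasets share correlation *structure*
# without sharing cells.
make_block_dataset <- function(n_cells = 100, n_genes = 10,
                               blocks = list(1:5, 6:9), rho = 0.9) {
  x <- matrix(rnorm(n_cells * n_genes), n_cells, n_genes,
              dimnames = list(NULL, paste0("g", seq_len(n_genes))))
  for (b in blocks) {
    shared <- rnorm(n_cells)
    for (j in b) x[, j] <- rho * shared + sqrt(1 - rho^2) * rnorm(n_cells)
  }
  x
}

# QC fixture at the standard droplet thresholds (200/4500 genes, 5%
# mitochondrial, 3-cell gene support), with expected surviving dimensions
# recomputed here by direct counting, independently of qc_filter().
make_qc_fixture <- function() {
  set.seed(404)
  n_genes <- 5000
  genes <- c(sprintf("MT-G%02d", 1:10), sprintf("G%04d", 1:(n_genes - 10)))
  cells <- sprintf("C%02d", 1:10)
  counts <- matrix(0L, n_genes, length(cells),
                   dimnames = list(genes, cells))
  fill <- function(cell, gene_idx, value = 1L) {
    counts[gene_idx, cell] <<- value
  }
  # C01: only 150 genes detected -> removed by the gene-count lower bound
  fill("C01", sample(11:n_genes, 150))
  # C02: 4600 genes detected -> removed by the upper bound
  fill("C02", sample(11:n_genes, 4600))
  # C03: 6% mitochondrial counts over 1000 genes -> removed by mito rule
  idx3 <- sample(11:n_genes, 1000)
  fill("C03", idx3)
  counts[1:3, "C03"] <- c(30L, 20L, 13L) # 63 mito of 1063 total = 5.9%
  # C04..C10: healthy cells sharing a common 400-gene block
  core <- sample(11:n_genes, 400)
  for (cell in sprintf("C%02d", 4:10)) {
    fill(cell, core, sample(1:5, 400, replace = TRUE))
    counts[4, cell] <- 1L # 4% mito at most; keeps cells under 5%
  }
  # one gene detected in exactly 2 surviving cells -> removed by support
  rare <- setdiff(11:n_genes, core)[1]
  counts[rare, c("C04", "C05")] <- 2L
  cm <- count_matrix(counts)

  # brute-force expected dimensions
  detected <- colSums(counts > 0)
  mito_frac <- colSums(counts[startsWith(genes, "MT-"), ]) /
    pmax(colSums(counts), 1)
  keep_cells <- detected >= 200 & detected <= 4500 & mito_frac <= 0.05
  surv <- counts[, keep_cells, drop = FALSE]
  keep_genes <- rowSums(surv > 0) >= 3
  list(cm = cm,
       expected_cells = sum(keep_cells),
       expected_genes = sum(keep_genes),
       rare_gene = genes[rare])
}
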