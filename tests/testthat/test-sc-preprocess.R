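test_that("knee-point cell calling recovers a planted real-cell count", {
  sim <- generate_barcode_reads(barcode_sim_config(
    n_real = 100, n_ambient = 900, real_read_mean = 1000,
    ambient_read_mean = 10, seed = 3))
  cc <- call_cells(sim$reads)
  expect_false(cc$no_knee)
  expect_true(abs(cc$n_selected - 100) <= 10)
  # called barcodes are overwhelmingly the planted real ones
  expect_gt(mean(cc$barcodes %in% sim$real_barcodes), 0.9)
})

test_that("degenerate read distributions are handled per contract", {
  flat <- setNames(rep(50, 100), sprintf("BC%03d", 1:100))
  cc <- call_cells(flat)
  expect_true(cc$no_knee)
  expect_equal(cc$n_selected, 100)
  expect_error(call_cells(setNames(1:5, paste0("B", 1:5))), "at least 10")
})

test_that("QC filtering applies each printed rule, in order, idempotently", {
  # small matrix with per-rule violations at scaled-down thresholds
  genes <- c("MT-X", sprintf("G%02d", 1:9))
  counts <- matrix(0L, 10, 5, dimnames = list(genes, paste0("C", 1:5)))
  counts[2:9, 1] <- 1L                       # C1: 8 genes, fine
  counts[2:3, 2] <- 1L                       # C2: 2 genes (< min 3)
  counts[2:9, 3] <- 1L                       # C3: fine
  counts[1, 4] <- 10L; counts[2:9, 4] <- 1L  # C4: mito 10/18 = 56%
  counts[2:10, 5] <- 1L                      # C5: fine; sole carrier of G09
  cm <- count_matrix(counts)
  thr <- qc_thresholds(min_genes_per_cell = 3, max_genes_per_cell = 9,
                       min_cells_per_gene = 2, max_mito_fraction = 0.05)
  res <- qc_filter(cm, thr)
  expect_equal(res$matrix$barcodes, c("C1", "C3", "C5"))
  expect_equal(res$report$n_cells_removed_gene_bounds, 1L)
  expect_equal(res$report$n_cells_removed_mito, 1L)
  # G09 detected only in C5 among survivors -> dropped; MT-X never
  # detected in survivors -> dropped
  expect_false(any(c("G09", "MT-X") %in% res$matrix$genes))
  expect_equal(res$report$n_genes_removed_support, 2L)

  res2 <- qc_filter(res$matrix, thr)
  expect_identical(res2$matrix$counts, res$matrix$counts)
  expect_equal(res2$report$n_cells_removed_gene_bounds +
                 res2$report$n_cells_removed_mito +
                 res2$report$n_genes_removed_support, 0L)
})

test_that("normalization scales to the median library and is
           proportion-invariant", {
  m <- matrix(c(1, 2, 3,
                2, 4, 6,
                5, 1, 0), nrow = 3,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  out <- normalize_log(m)
  # cells 1 and 2 are proportional -> identical normalized profiles
  expect_equal(out[, 1], out[, 2])
  # hand computation: libraries 6, 12, 6; median 6
  expect_equal(unname(out[, 1]), log1p(c(1, 2, 3)))
  expect_equal(unname(out[, 2]), log1p(c(2, 4, 6) * 6 / 12))
  expect_equal(unname(out[, 3]), log1p(c(5, 1, 0)))

  flat <- matrix(2, 3, 3, dimnames = dimnames(m))
  expect_true(all(normalize_log(flat) == log1p(2)))

  bad <- m; bad[, 2] <- 0
  expect_error(normalize_log(bad), "c2")
})

test_that("diffusion imputation matches an explicit matrix-power oracle", {
  set.seed(31)
  # two tight, well-separated clusters of 8 cells each
  n <- 16
  x <- rbind(g1 = c(rnorm(8, 0, 0.1), rnorm(8, 10, 0.1)),
             g2 = c(rnorm(8, 5, 0.1), rnorm(8, -5, 0.1)),
             g3 = rep(3, n)) # constant gene
  colnames(x) <- paste0("c", 1:n)
  cfg <- impute_config(k_neighbors = 3, diffusion_steps = 4)

  expect_equal(impute_diffusion(x, impute_config(3, 0)), x)

  out <- impute_diffusion(x, cfg)
  # oracle: build the symmetrized kNN transition matrix by explicit loops
  d <- as.matrix(dist(t(x)))
  adj <- matrix(FALSE, n, n)
  for (i in 1:n) adj[i, order(d[i, ])[1:4]] <- TRUE
  adj <- adj | t(adj)
  m <- adj / rowSums(adj)
  mt <- diag(n)
  for (s in 1:4) mt <- mt %*% m
  expected <- x %*% t(mt)
  dimnames(expected) <- dimnames(x)
  expect_equal(out, expected, tolerance = 1e-12)

  # constant gene is an eigenvector of the row-stochastic transition
  expect_equal(unname(out["g3", ]), rep(3, n))
  # large t: within-cluster values approach the cluster means
  deep <- impute_diffusion(x, impute_config(3, 50))
  expect_lt(max(abs(deep["g1", 1:8] - mean(deep["g1", 1:8]))), 0.05)
  expect_lt(max(abs(deep["g1", 9:16] - mean(deep["g1", 9:16]))), 0.05)

  expect_error(impute_diffusion(x, impute_config(k_neighbors = 16)),
               "smaller")
})

test_that("diffusion preserves per-gene means on a regular symmetric
           graph", {
  # cells on a circle: the symmetrized kNN graph is regular, so the
  # transition matrix is doubly stochastic and means are invariant
  n <- 12
  theta <- 2 * pi * (0:(n - 1)) / n
  x <- rbind(a = cos(theta), b = sin(theta), c = cos(2 * theta))
  colnames(x) <- paste0("c", 1:n)
  out <- impute_diffusion(x, impute_config(k_neighbors = 2,
                                           diffusion_steps = 5))
  expect_equal(rowMeans(out), rowMeans(x), tolerance = 1e-12)
})

test_that("midpoint marker partitioning follows its contract", {
  x <- rbind(a = c(0, 1), b = c(1, 0))
  colnames(x) <- c("cell1", "cell2")
  lab <- partition_by_marker_pair(x, "a", "b")
  expect_equal(as.character(lab),
               c("b_enriched_a_reduced", "a_enriched_b_reduced"))

  # markers rising together: no cell is on opposite sides of the two
  # midpoints, so both enriched classes stay empty
  y <- rbind(a = c(2, 2.1, 2.2), b = c(2, 2.1, 2.2))
  colnames(y) <- paste0("c", 1:3)
  lab2 <- partition_by_marker_pair(y, "a", "b")
  expect_true(all(lab2 == "intermediate"))

  z <- rbind(a = c(1, 1), b = c(0, 1))
  colnames(z) <- c("c1", "c2")
  expect_error(partition_by_marker_pair(z, "a", "b"), "zero")
  expect_error(partition_by_marker_pair(z, "a", "missing"), "not found")
})

test_that("partition classes are disjoint and cover all cells", {
  set.seed(77)
  for (rep in 1:5) {
    x <- matrix(rnorm(200), nrow = 4,
                dimnames = list(paste0("g", 1:4), paste0("c", 1:50)))
    lab <- partition_by_marker_pair(x, "g1", "g2")
    expect_length(lab, 50)
    expect_false(anyNA(lab))
    expect_equal(sum(table(lab)), 50)
  }
})

test_that("marker partitioning recovers planted branch states", {
  sim <- generate_timecourse_matrix(sc_sim_config(n_cells = 300,
                                                  n_genes = 60,
                                                  seed = 17))
  norm <- normalize_log(sim$matrix)
  imp <- impute_diffusion(norm, impute_config(k_neighbors = 15,
                                              diffusion_steps = 3))
  lab <- partition_by_marker_pair(imp, "gene001", "gene011")
  truth <- sim$states[colnames(imp)]
  branch <- truth %in% c("dc", "sndc")
  predicted <- as.character(lab[branch])
  expected <- ifelse(truth[branch] == "dc", "a_enriched_b_reduced",
                     "b_enriched_a_reduced")
  expect_gt(mean(predicted == expected), 0.9)
})

test_that("rank-sum marker tests match exact enumeration and the
           Bonferroni contract", {
  x <- rbind(g1 = c(1, 2, 3, 10, 11, 12))
  colnames(x) <- paste0("c", 1:6)
  res <- wilcoxon_markers(x, paste0("c", 1:3), paste0("c", 4:6))
  expect_equal(res$p_value, exact_wilcoxon_p(c(1, 2, 3), c(10, 11, 12)))
  expect_equal(res$p_value, 0.1) # 2 / choose(6, 3)
  expect_equal(res$p_adjusted, res$p_value) # single gene: m = 1
  expect_equal(res$direction, "down_in_a")

  # identical groups -> p = 1
  xx <- rbind(g1 = rep(c(5, 6, 7), 2), g2 = rep(1, 6))
  colnames(xx) <- paste0("c", 1:6)
  res2 <- wilcoxon_markers(xx, paste0("c", 1:3), paste0("c", 4:6))
  expect_equal(res2$p_value[1], 1)

  expect_error(wilcoxon_markers(x, paste0("c", 1:3), paste0("c", 3:6)),
               "overlap")
  expect_error(wilcoxon_markers(x, paste0("c", 1:2), paste0("c", 4:6)),
               "at least 3")
})

test_that("rank-sum p-values agree with enumeration for small groups", {
  set.seed(5)
  for (rep in 1:8) {
    na <- sample(3:6, 1)
    nb <- sample(3:6, 1)
    va <- round(rnorm(na, sd = 10), 3) # continuous, no ties
    vb <- round(rnorm(nb, sd = 10), 3)
    x <- rbind(g = c(va, vb))
    colnames(x) <- paste0("c", seq_len(na + nb))
    res <- wilcoxon_markers(x, paste0("c", 1:na),
                            paste0("c", na + 1:nb))
    expect_equal(res$p_value, exact_wilcoxon_p(va, vb), tolerance = 1e-12)
  }
})
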