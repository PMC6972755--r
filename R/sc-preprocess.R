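# Single-cell preprocessing: knee-point cell calling, QC filtering,
# normalization, graph-diffusion imputation, midpoint marker partitioning
# and rank-sum marker tests.

#' Call cells from a barcode read-count distribution (knee point)
#'
#' Barcodes are ordered by descending read count and the cumulative fraction
#' of reads is plotted against barcode rank.  The knee (inflection) point is
#' the rank with maximum perpendicular distance between the cumulative curve
#' and the chord joining its endpoints; barcodes at or before the knee are
#' called as cells, barcodes beyond it are treated as ambient RNA.
#'
#' @param read_counts named numeric vector of reads per barcode; at least 10
#'   barcodes with positive counts are required.
#' @param curvature_tol knee-prominence threshold: if the maximum
#'   perpendicular distance is below `curvature_tol` times the chord length
#'   the curve is deemed knee-free, all barcodes are returned and `no_knee`
#'   is set.  The default 0.25 separates smooth single-population read
#'   distributions (prominence about 0.05-0.15) from genuine cell/ambient
#'   mixtures (about 0.4 and above).
#' @return list of class `cell_call` with elements `barcodes` (selected, in
#'   descending read order), `knee_rank`, `no_knee` (logical) and
#'   `n_selected`.
#' @export
#' @examples
#' reads <- c(rep(1000, 100), rep(10, 900))
#' names(reads) <- paste0("BC", seq_along(reads))
#' call_cells(reads)$n_selected
call_cells <- function(read_counts, curvature_tol = 0.25) {
  if (is.null(names(read_counts))) {
    names(read_counts) <- sprintf("BC%06d", seq_along(read_counts))
  }
  read_counts <- read_counts[read_counts > 0]
  n <- length(read_counts)
  if (n < 10L) {
    stop("need at least 10 barcodes with positive read counts", call. = FALSE)
  }
  ord <- order(read_counts, decreasing = TRUE)
  sorted <- read_counts[ord]
  x <- seq_len(n) / n
  y <- cumsum(as.numeric(sorted)) / sum(as.numeric(sorted))
  # perpendicular distance from each point to the chord (x1,y1)-(xn,yn)
  dx <- x[n] - x[1L]
  dy <- y[n] - y[1L]
  chord_len <- sqrt(dx^2 + dy^2)
  dist <- abs(dy * (x - x[1L]) - dx * (y - y[1L])) / chord_len
  knee <- which.max(dist)
  if (dist[knee] < curvature_tol * chord_len) {
    return(structure(list(barcodes = names(sorted), knee_rank = NA_integer_,
                          no_knee = TRUE, n_selected = n),
                     class = "cell_call"))
  }
  structure(list(barcodes = names(sorted)[seq_len(knee)],
                 knee_rank = as.integer(knee), no_knee = FALSE,
                 n_selected = as.integer(knee)),
            class = "cell_call")
}

#' QC thresholds for count-matrix filtering
#'
#' Defaults follow common droplet practice: keep cells with at least 200 and
#' at most 4500 detected genes and at most 5% mitochondrial transcripts
#' (doublet / damaged-cell guards), and keep genes detected in at least 3
#' cells.
#'
#' @param min_genes_per_cell,max_genes_per_cell detected-gene bounds per
#'   cell (cells with fewer than `min` or more than `max` genes are
#'   removed).
#' @param min_cells_per_gene minimum number of surviving cells a gene must
#'   be detected in.
#' @param max_mito_fraction cells with a strictly greater mitochondrial
#'   count fraction are removed.
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes_per_cell = 200,
                          max_genes_per_cell = 4500,
                          min_cells_per_gene = 3,
                          max_mito_fraction = 0.05) {
  min_genes_per_cell <- check_count(min_genes_per_cell,
                                    "min_genes_per_cell")
  max_genes_per_cell <- check_count(max_genes_per_cell,
                                    "max_genes_per_cell")
  if (min_genes_per_cell >= max_genes_per_cell) {
    stop("`min_genes_per_cell` must be below `max_genes_per_cell`",
         call. = FALSE)
  }
  structure(list(min_genes_per_cell = min_genes_per_cell,
                 max_genes_per_cell = max_genes_per_cell,
                 min_cells_per_gene = check_count(min_cells_per_gene,
                                                  "min_cells_per_gene"),
                 max_mito_fraction = check_fraction(max_mito_fraction,
                                                    "max_mito_fraction")),
            class = "qc_thresholds")
}

#' Quality-control filtering of a count matrix
#'
#' Filters are applied in a fixed order: (1) remove cells whose detected
#' gene count falls outside \[`min_genes_per_cell`, `max_genes_per_cell`\];
#' (2) remove cells whose mitochondrial count fraction exceeds
#' `max_mito_fraction`; (3) remove genes detected in fewer than
#' `min_cells_per_gene` of the surviving cells.  The operation is
#' idempotent.
#'
#' @param cm a [count_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return list of class `qc_result` with `matrix` (filtered
#'   [count_matrix()], possibly empty, with a warning) and `report`
#'   (counts removed per rule plus surviving dimensions).
#' @export
qc_filter <- function(cm, thresholds = qc_thresholds()) {
  stopifnot(inherits(cm, "count_matrix"), inherits(thresholds,
                                                   "qc_thresholds"))
  counts <- cm$counts
  detected <- colSums(counts > 0L)
  keep_bounds <- detected >= thresholds$min_genes_per_cell &
    detected <= thresholds$max_genes_per_cell
  n_cells_gene_bounds <- sum(!keep_bounds)

  lib <- colSums(counts)
  mito_frac <- if (any(cm$mito)) {
    colSums(counts[cm$mito, , drop = FALSE]) / pmax(lib, 1L)
  } else {
    rep(0, ncol(counts))
  }
  keep_mito <- mito_frac <= thresholds$max_mito_fraction
  n_cells_mito <- sum(keep_bounds & !keep_mito)

  keep_cells <- keep_bounds & keep_mito
  surv <- counts[, keep_cells, drop = FALSE]
  support <- rowSums(surv > 0L)
  keep_genes <- support >= thresholds$min_cells_per_gene
  n_genes_support <- sum(!keep_genes)

  out <- surv[keep_genes, , drop = FALSE]
  if (ncol(out) == 0L || nrow(out) == 0L) {
    warning("QC filtering removed everything; returning an empty matrix",
            call. = FALSE)
  }
  fm <- structure(list(counts = out,
                       genes = cm$genes[keep_genes],
                       barcodes = cm$barcodes[keep_cells],
                       mito = cm$mito[keep_genes]),
                  class = "count_matrix")
  report <- list(
    n_cells_removed_gene_bounds = as.integer(n_cells_gene_bounds),
    n_cells_removed_mito = as.integer(n_cells_mito),
    n_genes_removed_support = as.integer(n_genes_support),
    n_genes_kept = nrow(out), n_cells_kept = ncol(out))
  structure(list(matrix = fm, report = report), class = "qc_result")
}

#' Library-size normalization with log transform
#'
#' Scales each cell's counts to the median library size of the matrix and
#' applies `log(1 + x)`.  Cells with proportional raw profiles map to
#' identical normalized profiles.
#'
#' @param cm a [count_matrix()] or a plain non-negative matrix (genes x
#'   cells with dimnames).
#' @return numeric matrix, genes x cells, same dimensions as the input.
#' @export
normalize_log <- function(cm) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("all-zero cell(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "), call. = FALSE)
  }
  target <- stats::median(lib)
  scaled <- sweep(counts, 2L, target / lib, `*`)
  log1p(scaled)
}

#' Configuration for graph-diffusion imputation
#'
#' A simple Markov-diffusion smoother over the cell k-nearest-neighbour
#' graph: a symmetrized binary kNN affinity (self-loops included) is row
#' normalized into a transition matrix and applied `diffusion_steps` times
#' to each gene's expression vector.  `diffusion_steps = 0` is the
#' identity.
#'
#' @param k_neighbors neighbours per cell (>= 1).
#' @param diffusion_steps number of diffusion steps t (>= 0).
#' @param distance metric for the cell-cell distances; `"euclidean"`
#'   (default) or `"manhattan"`.
#' @return object of class `impute_config`.
#' @export
impute_config <- function(k_neighbors = 15, diffusion_steps = 3,
                          distance = c("euclidean", "manhattan")) {
  structure(list(k_neighbors = check_count(k_neighbors, "k_neighbors",
                                           min = 1L),
                 diffusion_steps = check_count(diffusion_steps,
                                               "diffusion_steps"),
                 distance = match.arg(distance)),
            class = "impute_config")
}

#' Graph-diffusion imputation of a normalized expression matrix
#'
#' @param x numeric matrix, genes x cells (normalized expression).
#' @param config an [impute_config()]; `k_neighbors` must be below the
#'   number of cells.
#' @return smoothed matrix of the same dimensions.
#' @export
impute_diffusion <- function(x, config = impute_config()) {
  stopifnot(inherits(config, "impute_config"))
  x <- as.matrix(x)
  n <- ncol(x)
  if (config$k_neighbors >= n) {
    stop("`k_neighbors` must be smaller than the number of cells",
         call. = FALSE)
  }
  if (config$diffusion_steps == 0L) return(x)
  d <- as.matrix(stats::dist(t(x), method = config$distance))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[seq_len(config$k_neighbors + 1L)] # includes self
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  m <- adj / rowSums(adj)
  mt <- diag(n)
  for (s in seq_len(config$diffusion_steps)) mt <- mt %*% m
  out <- x %*% t(mt)
  dimnames(out) <- dimnames(x)
  out
}

#' Partition cells by a marker-gene pair at range-midpoint thresholds
#'
#' For each gene the threshold is the midpoint of its observed range on the
#' (imputed) matrix.  Cells above the `gene_a` threshold and below the
#' `gene_b` threshold are `a_enriched_b_reduced`; the symmetric class is
#' `b_enriched_a_reduced`; everything else is `intermediate`.  The classes
#' are disjoint and cover all cells.
#'
#' @param x numeric matrix, genes x cells (typically imputed expression).
#' @param gene_a,gene_b row identifiers of the two marker genes.
#' @return factor of cell labels (named by cell), with attribute
#'   `thresholds`.
#' @export
partition_by_marker_pair <- function(x, gene_a, gene_b) {
  x <- as.matrix(x)
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(x)) stop("gene not found: ", g, call. = FALSE)
  }
  a <- x[gene_a, ]
  b <- x[gene_b, ]
  thr <- c(a = (min(a) + max(a)) / 2, b = (min(b) + max(b)) / 2)
  if (diff(range(a)) == 0 || diff(range(b)) == 0) {
    stop("marker gene with zero expression range: midpoint undefined",
         call. = FALSE)
  }
  lab <- rep("intermediate", ncol(x))
  lab[a > thr["a"] & b < thr["b"]] <- "a_enriched_b_reduced"
  lab[b > thr["b"] & a < thr["a"]] <- "b_enriched_a_reduced"
  out <- factor(lab, levels = c("a_enriched_b_reduced",
                                "b_enriched_a_reduced", "intermediate"))
  names(out) <- colnames(x)
  attr(out, "thresholds") <- thr
  out
}

#' Rank-sum marker tests between two cell groups
#'
#' Two-sided Wilcoxon rank-sum test per gene with Bonferroni adjustment over
#' all tested genes.
#'
#' @param x numeric matrix, genes x cells.
#' @param cells_a,cells_b disjoint character vectors of cell identifiers
#'   (each group at least 3 cells).
#' @param alpha significance bound applied to the adjusted p-value.
#' @return data.frame with columns `gene`, `statistic` (W), `p_value`,
#'   `p_adjusted`, `direction` (`"up_in_a"` / `"down_in_a"` / `"equal"`,
#'   by mean difference) and `significant`.
#' @export
wilcoxon_markers <- function(x, cells_a, cells_b, alpha = 0.05) {
  x <- as.matrix(x)
  if (length(intersect(cells_a, cells_b)) > 0L) {
    stop("cell groups overlap", call. = FALSE)
  }
  missing <- setdiff(c(cells_a, cells_b), colnames(x))
  if (length(missing) > 0L) {
    stop("cells not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(cells_a) < 3L || length(cells_b) < 3L) {
    stop("each group needs at least 3 cells", call. = FALSE)
  }
  genes <- rownames(x)
  stat <- p <- numeric(length(genes))
  dir <- character(length(genes))
  for (i in seq_along(genes)) {
    va <- x[i, cells_a]
    vb <- x[i, cells_b]
    wt <- suppressWarnings(stats::wilcox.test(va, vb,
                                              alternative = "two.sided"))
    stat[i] <- unname(wt$statistic)
    p[i] <- wt$p.value
    md <- mean(va) - mean(vb)
    dir[i] <- if (md > 0) "up_in_a" else if (md < 0) "down_in_a" else "equal"
  }
  p_adj <- stats::p.adjust(p, method = "bonferroni")
  data.frame(gene = genes, statistic = stat, p_value = p,
             p_adjusted = p_adj, direction = dir,
             significant = p_adj <= alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}
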