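# Gene-pair correlation congruency between two single-cell datasets
# (e.g. an in vitro decidual time course and in vivo biopsies), with a
# permutation enrichment test and a hypergeometric overlap test, plus the
# marker-candidate filter over branch genes.

#' Pairwise correlation congruency between two datasets
#'
#' For every unordered pair of `top_genes`, the Pearson correlation across
#' cells is computed in each dataset and the two coefficients are summed.
#' The sum ranges from -2 to +2; a pair is congruent when the sum exceeds
#' `threshold` (positively co-regulated in both datasets) or falls below
#' `-threshold` (negatively co-regulated in both).  Self-pairs are reported
#' with sum exactly 2 but are excluded from enrichment; pairs involving a
#' zero-variance gene are flagged undefined and counted in the
#' `n_undefined` attribute.
#'
#' @param top_genes character vector of gene identifiers (e.g. the top 50
#'   branch genes of the decidual trajectory).
#' @param dataset_a,dataset_b numeric matrices, cells x genes (typically
#'   imputed expression), both covering `top_genes`; at least 3 cells each.
#' @param threshold congruency threshold on `|sum|` (default 1).
#' @return data.frame of class `congruency_scores` with columns `gene_a`,
#'   `gene_b`, `r_a`, `r_b`, `sum`, `congruent`, `defined`, `self`.
#' @export
#' @examples
#' set.seed(1)
#' a <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("g1", "g2", "g3")))
#' pairwise_congruency(colnames(a), a, a)
pairwise_congruency <- function(top_genes, dataset_a, dataset_b,
                                threshold = 1) {
  dataset_a <- as.matrix(dataset_a)
  dataset_b <- as.matrix(dataset_b)
  for (nm in list(a = dataset_a, b = dataset_b)) {
    if (nrow(nm) < 3L) stop("each dataset needs at least 3 cells (rows)",
                            call. = FALSE)
  }
  missing_a <- setdiff(top_genes, colnames(dataset_a))
  missing_b <- setdiff(top_genes, colnames(dataset_b))
  if (length(missing_a) || length(missing_b)) {
    stop("genes missing from dataset(s): ",
         paste(unique(c(missing_a, missing_b)), collapse = ", "),
         call. = FALSE)
  }
  g <- as.character(top_genes)
  ra <- suppressWarnings(stats::cor(dataset_a[, g, drop = FALSE]))
  rb <- suppressWarnings(stats::cor(dataset_b[, g, drop = FALSE]))
  idx <- which(upper.tri(ra, diag = TRUE), arr.ind = TRUE)
  ga <- g[idx[, 1L]]
  gb <- g[idx[, 2L]]
  r_a <- ra[idx]
  r_b <- rb[idx]
  self <- idx[, 1L] == idx[, 2L]
  s <- r_a + r_b
  s[self] <- 2 # exact by contract, immune to numerical fuzz
  defined <- !is.na(r_a) & !is.na(r_b)
  congruent <- defined & !self & (s > threshold | s < -threshold)
  out <- data.frame(gene_a = ga, gene_b = gb, r_a = r_a, r_b = r_b,
                    sum = s, congruent = congruent, defined = defined,
                    self = self, stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "threshold") <- threshold
  attr(out, "n_undefined") <- sum(!defined & !self)
  class(out) <- c("congruency_scores", "data.frame")
  out
}

# congruent fraction among defined, non-self pairs
.congruent_fraction <- function(ra, rb, threshold) {
  ut <- upper.tri(ra)
  s <- (ra + rb)[ut]
  mean(abs(s) > threshold, na.rm = TRUE)
}

#' Enrichment of congruent gene pairs over a permutation null
#'
#' Tests whether the observed fraction of congruent pairs between
#' `dataset_a` and `dataset_b` is larger than expected when the two
#' correlation structures are unrelated.  The null shuffles the gene labels
#' of `dataset_b` `n_perm` times and recomputes the congruent fraction;
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @inheritParams pairwise_congruency
#' @param n_perm number of permutations (a warning is issued below 100).
#' @param seed integer seed for the permutations.
#' @return list of class `congruency_enrichment` with `observed_fraction`,
#'   `null_fractions`, `p_value`, `n_pairs`, `n_congruent`.
#' @export
congruency_enrichment <- function(top_genes, dataset_a, dataset_b,
                                  threshold = 1, n_perm = 999,
                                  seed = NULL) {
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  if (n_perm < 100L) warning("n_perm < 100 gives a coarse p-value",
                             call. = FALSE)
  scores <- pairwise_congruency(top_genes, dataset_a, dataset_b,
                                threshold = threshold)
  pairs <- scores[!scores$self & scores$defined, ]
  if (nrow(pairs) < 10L) {
    stop("need at least 10 defined gene pairs", call. = FALSE)
  }
  g <- as.character(top_genes)
  ra <- suppressWarnings(stats::cor(dataset_a[, g, drop = FALSE]))
  rb <- suppressWarnings(stats::cor(dataset_b[, g, drop = FALSE]))
  observed <- .congruent_fraction(ra, rb, threshold)
  null_frac <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      perm <- sample.int(length(g))
      .congruent_fraction(ra, rb[perm, perm], threshold)
    }, numeric(1))
  })
  p <- (1 + sum(null_frac >= observed)) / (1 + n_perm)
  structure(list(observed_fraction = observed, null_fractions = null_frac,
                 p_value = p, n_pairs = nrow(pairs),
                 n_congruent = sum(pairs$congruent), threshold = threshold,
                 n_perm = n_perm),
            class = "congruency_enrichment")
}

#' @export
print.congruency_enrichment <- function(x, ...) {
  cat(sprintf(paste0("<congruency_enrichment> %d/%d pairs congruent ",
                     "(%.1f%%), permutation p = %.4g (n_perm = %d)\n"),
              x$n_congruent, x$n_pairs, 100 * x$observed_fraction,
              x$p_value, x$n_perm))
  invisible(x)
}

#' Hypergeometric overlap test for pairs congruent in two evaluations
#'
#' When congruency is evaluated against two in vivo days separately, the
#' number of pairs congruent on *both* days can be compared with the
#' chance overlap of the two congruent sets.  With `N` pairs defined in both
#' score sets, `K` congruent in the first and `k` congruent in the second,
#' the observed overlap `q` is tested against the upper tail of
#' Hypergeometric(N, K, k).
#'
#' @param scores_1,scores_2 two [pairwise_congruency()] results over the
#'   same gene list.
#' @return list with `n_pairs`, `n_congruent_1`, `n_congruent_2`,
#'   `n_overlap`, `expected_overlap` and `p_value`.
#' @export
congruency_overlap_test <- function(scores_1, scores_2) {
  stopifnot(inherits(scores_1, "congruency_scores"),
            inherits(scores_2, "congruency_scores"))
  key <- function(s) paste(s$gene_a, s$gene_b, sep = "\r")
  s1 <- scores_1[!scores_1$self & scores_1$defined, ]
  s2 <- scores_2[!scores_2$self & scores_2$defined, ]
  common <- intersect(key(s1), key(s2))
  n <- length(common)
  if (n < 10L) stop("need at least 10 pairs defined in both score sets",
                    call. = FALSE)
  c1 <- key(s1)[s1$congruent]
  c2 <- key(s2)[s2$congruent]
  K <- sum(c1 %in% common)
  k <- sum(c2 %in% common)
  q <- length(intersect(intersect(c1, c2), common))
  p <- stats::phyper(q - 1, K, n - K, k, lower.tail = FALSE)
  list(n_pairs = n, n_congruent_1 = K, n_congruent_2 = k, n_overlap = q,
       expected_overlap = K * k / n, p_value = p)
}

#' Rank branch genes by between-state effect size (convenience)
#'
#' A simple ranking of candidate branch genes for synthetic data: the
#' absolute difference in mean normalized expression between the two branch
#' states, largest first.
#'
#' @param x numeric matrix, genes x cells (normalized expression).
#' @param states character/factor of cell states named by cell, with levels
#'   including `state_a` and `state_b`.
#' @param state_a,state_b the two diverging states (defaults `"dc"`,
#'   `"sndc"`).
#' @param n_top how many genes to return.
#' @return character vector of gene identifiers.
#' @export
rank_branch_genes <- function(x, states, state_a = "dc", state_b = "sndc",
                              n_top = 50) {
  x <- as.matrix(x)
  states <- states[colnames(x)]
  ma <- rowMeans(x[, states == state_a, drop = FALSE])
  mb <- rowMeans(x[, states == state_b, drop = FALSE])
  ord <- order(abs(ma - mb), decreasing = TRUE)
  rownames(x)[ord][seq_len(min(n_top, nrow(x)))]
}

#' Criteria for the biopsy-marker candidate filter
#'
#' A candidate biopsy marker of diverging decidual states should be
#' strongly enriched in stromal cells relative to every other endometrial
#' cell type, essentially unregulated across the cycle in glandular
#' epithelium, and temporally regulated in the stroma across the luteal
#' phase.
#'
#' @param stromal_enrichment_min_lfc minimum log2 fold-change of stromal
#'   over every other cell type (default 1).
#' @param stromal_enrichment_alpha adjusted-p bound for the stromal
#'   enrichment rank-sum tests (default 0.05).
#' @param epithelial_regulation_max_fc maximum allowed max/min temporal
#'   fold-change in the epithelial time course (default 1.5).
#' @param temporal_profile_rule required stromal temporal profile:
#'   `"changing"` (max/min fold-change must exceed
#'   `epithelial_regulation_max_fc`), `"increasing"` / `"decreasing"`
#'   (direction of last vs first condition) or `"any"`.
#' @return object of class `marker_criteria`.
#' @export
marker_criteria <- function(stromal_enrichment_min_lfc = 1,
                            stromal_enrichment_alpha = 0.05,
                            epithelial_regulation_max_fc = 1.5,
                            temporal_profile_rule = c("changing",
                                                      "increasing",
                                                      "decreasing",
                                                      "any")) {
  stopifnot(epithelial_regulation_max_fc > 0)
  structure(list(
    stromal_enrichment_min_lfc = stromal_enrichment_min_lfc,
    stromal_enrichment_alpha = check_fraction(stromal_enrichment_alpha,
                                              "stromal_enrichment_alpha"),
    epithelial_regulation_max_fc = epithelial_regulation_max_fc,
    temporal_profile_rule = match.arg(temporal_profile_rule)),
    class = "marker_criteria")
}

# max/min temporal fold-change with a pseudocount guard
.temporal_fc <- function(v, pseudocount = 1) {
  (max(v) + pseudocount) / (min(v) + pseudocount)
}

#' Filter branch genes down to biopsy-marker candidates
#'
#' Sequential filters over `branch_genes`: (1) stromal enrichment --
#' significantly higher in the stromal cell type than in every other cell
#' type (rank-sum test, Bonferroni) with log2 fold-change at or above the
#' bound; (2) epithelial non-regulation -- max/min temporal fold-change in
#' the epithelial time course at or below the bound; (3) stromal temporal
#' profile matching `temporal_profile_rule`.  The audit records the first
#' filter that removed each gene.
#'
#' @param branch_genes character vector of candidate genes.
#' @param celltype_expression named list of genes x cells expression
#'   matrices (linear scale), one per cell type; must include
#'   `stromal_type`.
#' @param epithelial_timecourse,stromal_timecourse numeric matrices,
#'   genes x ordered conditions (linear scale), covering `branch_genes`.
#' @param criteria a [marker_criteria()].
#' @param stromal_type name of the stromal element of
#'   `celltype_expression` (default `"EnSC"`).
#' @param pseudocount added to means before fold-changes.
#' @return list with `markers` (surviving genes ranked by their weakest
#'   stromal log2 fold-change, descending) and `audit` (per-gene filter
#'   outcomes and `removed_by`).
#' @export
select_candidate_markers <- function(branch_genes, celltype_expression,
                                     epithelial_timecourse,
                                     stromal_timecourse,
                                     criteria = marker_criteria(),
                                     stromal_type = "EnSC",
                                     pseudocount = 1) {
  stopifnot(inherits(criteria, "marker_criteria"))
  branch_genes <- as.character(branch_genes)
  if (length(branch_genes) == 0L) {
    return(list(markers = character(0),
                audit = data.frame(gene = character(0))))
  }
  if (!stromal_type %in% names(celltype_expression)) {
    stop("`celltype_expression` lacks the stromal type '", stromal_type,
         "'", call. = FALSE)
  }
  for (nm in names(celltype_expression)) {
    miss <- setdiff(branch_genes, rownames(celltype_expression[[nm]]))
    if (length(miss)) stop("genes missing from cell type ", nm, ": ",
                           paste(miss, collapse = ", "), call. = FALSE)
  }
  for (tc in list(epithelial_timecourse, stromal_timecourse)) {
    miss <- setdiff(branch_genes, rownames(tc))
    if (length(miss)) stop("genes missing from time course: ",
                           paste(miss, collapse = ", "), call. = FALSE)
  }

  stromal <- celltype_expression[[stromal_type]][branch_genes, ,
                                                 drop = FALSE]
  others <- celltype_expression[setdiff(names(celltype_expression),
                                        stromal_type)]
  pass1 <- rep(TRUE, length(branch_genes))
  min_lfc <- rep(Inf, length(branch_genes))
  for (other in others) {
    other <- other[branch_genes, , drop = FALSE]
    combined <- cbind(stromal, other)
    colnames(combined) <- sprintf("c%05d", seq_len(ncol(combined)))
    res <- wilcoxon_markers(combined,
                            cells_a = colnames(combined)[
                              seq_len(ncol(stromal))],
                            cells_b = colnames(combined)[
                              ncol(stromal) + seq_len(ncol(other))],
                            alpha = criteria$stromal_enrichment_alpha)
    lfc <- log2((rowMeans(stromal) + pseudocount) /
                  (rowMeans(other) + pseudocount))
    ok <- res$significant & lfc >= criteria$stromal_enrichment_min_lfc
    pass1 <- pass1 & ok
    min_lfc <- pmin(min_lfc, lfc)
  }

  epi_fc <- apply(epithelial_timecourse[branch_genes, , drop = FALSE], 1L,
                  .temporal_fc, pseudocount = pseudocount)
  pass2 <- epi_fc <= criteria$epithelial_regulation_max_fc

  str_tc <- stromal_timecourse[branch_genes, , drop = FALSE]
  pass3 <- switch(criteria$temporal_profile_rule,
    any = rep(TRUE, length(branch_genes)),
    increasing = str_tc[, ncol(str_tc)] > str_tc[, 1L],
    decreasing = str_tc[, ncol(str_tc)] < str_tc[, 1L],
    changing = apply(str_tc, 1L, .temporal_fc,
                     pseudocount = pseudocount) >
      criteria$epithelial_regulation_max_fc)

  removed_by <- rep(NA_character_, length(branch_genes))
  removed_by[!pass1] <- "stromal_enrichment"
  removed_by[pass1 & !pass2] <- "epithelial_regulation"
  removed_by[pass1 & pass2 & !pass3] <- "temporal_profile"
  surv_idx <- which(pass1 & pass2 & pass3)
  survivors <- branch_genes[surv_idx][order(min_lfc[surv_idx],
                                            decreasing = TRUE)]
  audit <- data.frame(gene = branch_genes, pass_stromal = pass1,
                      pass_epithelial = pass2, pass_temporal = pass3,
                      min_stromal_lfc = min_lfc, removed_by = removed_by,
                      stringsAsFactors = FALSE, row.names = NULL)
  list(markers = survivors, audit = audit)
}
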