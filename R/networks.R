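# Co-expression module discovery: k-means with a Pearson-correlation
# metric, and a leave-one-condition-out figure of merit (FOM) to choose k.

#' Configuration for co-expression module discovery
#'
#' @param k_range candidate cluster numbers for the FOM scan (default 1:20;
#'   values of `k` at or above the number of genes are capped).
#' @param metric profile distance; only `"pearson"` (1 - Pearson
#'   correlation) is supported.
#' @param max_iterations Lloyd iteration cap per k-means run (default 50).
#' @param n_restarts random restarts; the run with the lowest
#'   within-cluster distance sum is kept.
#' @param seed integer seed making module assignment deterministic.
#' @return object of class `network_config`.
#' @export
network_config <- function(k_range = 1:20, metric = "pearson",
                           max_iterations = 50, n_restarts = 10,
                           seed = 1L) {
  metric <- match.arg(metric, "pearson")
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1L)) stop("`k_range` must be >= 1", call. = FALSE)
  structure(list(k_range = k_range, metric = metric,
                 max_iterations = check_count(max_iterations,
                                              "max_iterations", min = 1L),
                 n_restarts = check_count(n_restarts, "n_restarts",
                                          min = 1L),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "network_config")
}

# Center and unit-normalize rows, so that 1 - cor(x, y) equals
# 0.5 * ||zx - zy||^2 and correlation k-means becomes spherical k-means.
.profile_z <- function(p) {
  ctr <- p - rowMeans(p)
  nrm <- sqrt(rowSums(ctr^2))
  list(z = ctr / nrm, flat = nrm == 0)
}

# Spherical k-means (cosine similarity) on unit rows; returns assignment,
# objective (= sum of 1 - cor) and the per-iteration objective trace.
.kmeans_corr_once <- function(z, k, max_iterations) {
  n <- nrow(z)
  # k-means++ style init on correlation distance
  centers <- matrix(0, k, ncol(z))
  first <- sample.int(n, 1L)
  centers[1L, ] <- z[first, ]
  if (k > 1L) {
    d2 <- 1 - as.vector(z %*% centers[1L, ])
    d2 <- pmax(d2, 0)
    for (j in 2:k) {
      pick <- if (sum(d2) > 0) sample.int(n, 1L, prob = d2) else
        sample.int(n, 1L)
      centers[j, ] <- z[pick, ]
      d2 <- pmin(d2, pmax(1 - as.vector(z %*% centers[j, ]), 0))
    }
  }
  normalize <- function(m) {
    nn <- sqrt(rowSums(m^2))
    nn[nn == 0] <- 1
    m / nn
  }
  centers <- normalize(centers)
  assign_old <- rep(0L, n)
  trace <- numeric(0)
  for (it in seq_len(max_iterations)) {
    sim <- z %*% t(centers)
    assign <- max.col(sim, ties.method = "first")
    # re-seed empty clusters with the worst-fitted gene
    for (j in seq_len(k)) {
      if (!any(assign == j)) {
        worst <- which.min(sim[cbind(seq_len(n), assign)])
        centers[j, ] <- z[worst, ]
        assign[worst] <- j
        sim[worst, ] <- 0
        sim[worst, j] <- 1
      }
    }
    trace <- c(trace, sum(1 - sim[cbind(seq_len(n), assign)]))
    if (all(assign == assign_old)) break
    assign_old <- assign
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(z[assign == j, , drop = FALSE])
    }
    centers <- normalize(centers)
  }
  sim <- z %*% t(centers)
  obj <- sum(1 - sim[cbind(seq_len(n), assign)])
  list(assignment = assign, objective = obj, trace = c(trace, obj),
       centers = centers)
}

#' k-means co-expression modules with a Pearson-correlation metric
#'
#' Genes are clustered on the correlation distance `1 - cor(profile,
#' centroid)`, Lloyd iterations capped at `max_iterations`, best of
#' `n_restarts` by within-cluster distance sum.  Assignments are invariant
#' to positive affine rescaling of individual gene profiles.  Genes with a
#' constant profile (undefined correlation) are placed in module `0`
#' ("flat") and reported via the `flat_genes` attribute.
#'
#' @param p numeric matrix, genes x conditions, with row names.
#' @param k number of modules (1 <= k <= number of non-flat genes).
#' @param config a [network_config()].
#' @return named integer vector mapping gene to module (1..k; 0 for flat
#'   genes), with attributes `objective` (within-cluster sum of
#'   1 - correlation), `objective_trace` (per-iteration, best restart) and
#'   `flat_genes`.
#' @export
kmeans_modules <- function(p, k, config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  p <- as.matrix(p)
  if (is.null(rownames(p))) rownames(p) <- sprintf("g%04d", seq_len(nrow(p)))
  if (ncol(p) < 2L) stop("need at least 2 conditions", call. = FALSE)
  zs <- .profile_z(p)
  z <- zs$z[!zs$flat, , drop = FALSE]
  n <- nrow(z)
  k <- check_count(k, "k", min = 1L)
  if (k > n) stop("`k` exceeds the number of non-constant genes",
                  call. = FALSE)
  best <- NULL
  with_seed(config$seed, {
    for (r in seq_len(config$n_restarts)) {
      fit <- .kmeans_corr_once(z, k, config$max_iterations)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
  })
  out <- integer(nrow(p))
  names(out) <- rownames(p)
  out[!zs$flat] <- best$assignment
  out[zs$flat] <- 0L
  attr(out, "objective") <- best$objective
  attr(out, "objective_trace") <- best$trace
  attr(out, "flat_genes") <- rownames(p)[zs$flat]
  out
}

#' Figure-of-merit curve for choosing the number of modules
#'
#' For each candidate `k`, every condition is left out in turn, the genes
#' are clustered on the remaining conditions, and the root-mean-square
#' deviation of the left-out condition's values from their cluster means is
#' recorded.  The aggregate FOM for `k` is the sum over left-out conditions,
#' divided by the cluster-count adjustment factor `sqrt((n - k) / n)`
#' (n = number of genes), which removes the trivial decrease of the raw
#' FOM with growing k.  The suggested `k` is the elbow of the adjusted
#' curve: the `k` with the largest second difference.
#'
#' @param p numeric matrix, genes x conditions (>= 3 conditions).
#' @param config a [network_config()]; `k_range` values at or above the
#'   number of genes are skipped with a warning.
#' @return data.frame of class `fom_curve` with columns `k` and `fom`, and
#'   attribute `suggested_k`.
#' @export
fom_curve <- function(p, config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  p <- as.matrix(p)
  if (is.null(rownames(p))) rownames(p) <- sprintf("g%04d", seq_len(nrow(p)))
  m <- ncol(p)
  if (m < 3L) stop("need at least 3 conditions", call. = FALSE)
  n <- nrow(p)
  ks <- config$k_range
  if (any(ks >= n)) {
    warning("skipping k >= number of genes", call. = FALSE)
    ks <- ks[ks < n]
  }
  if (length(ks) == 0L) stop("no usable k in `k_range`", call. = FALSE)
  fom <- numeric(length(ks))
  with_seed(config$seed, {
    inner <- network_config(k_range = config$k_range,
                            max_iterations = config$max_iterations,
                            n_restarts = config$n_restarts, seed = NULL)
    for (i in seq_along(ks)) {
      k <- ks[i]
      tot <- 0
      for (e in seq_len(m)) {
        mods <- kmeans_modules(p[, -e, drop = FALSE], k, inner)
        mu <- tapply(p[, e], mods, mean)
        pred <- mu[as.character(mods)]
        tot <- tot + sqrt(mean((p[, e] - pred)^2))
      }
      fom[i] <- tot / sqrt((n - k) / n)
    }
  })
  suggested <- if (length(ks) >= 3L) {
    d2 <- fom[seq_len(length(ks) - 2L)] - 2 * fom[seq(2L, length(ks) - 1L)] +
      fom[seq(3L, length(ks))]
    ks[which.max(d2) + 1L]
  } else {
    ks[which.min(fom)]
  }
  out <- data.frame(k = ks, fom = fom)
  attr(out, "suggested_k") <- as.integer(suggested)
  class(out) <- c("fom_curve", "data.frame")
  out
}

#' @export
print.fom_curve <- function(x, ...) {
  cat(sprintf("<fom_curve> k = %d..%d, suggested k = %d\n",
              min(x$k), max(x$k), attr(x, "suggested_k")))
  print.data.frame(x, ...)
  invisible(x)
}
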