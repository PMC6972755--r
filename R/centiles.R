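# Day-normalized percentile reference curves.
#
# Percentiles are always percentiles of *expression*: for qPCR markers the
# dCt value (target Ct - L19 Ct; lower dCt = higher expression) is negated
# into an expression score before ranking, so a low SCARA5 percentile means
# low SCARA5 expression.  The empirical quantile function uses midrank
# (Hazen) plotting positions (rank - 0.5)/n with linear interpolation and
# clamps to 0/100 outside the reference range.

# Pool per-day sample groups until every group reaches `min_per_day`.
# Deficient groups merge with the nearest neighbouring group by day
# distance (ties -> the earlier day).  Returns a list of groups, each with
# `days` (covered days) and `scores`.
.pool_days <- function(by_day, min_per_day) {
  groups <- lapply(names(by_day), function(d) {
    list(days = as.integer(d), scores = by_day[[d]])
  })
  repeat {
    sizes <- vapply(groups, function(g) length(g$scores), integer(1))
    deficient <- which(sizes < min_per_day)
    if (length(deficient) == 0L) break
    if (length(groups) == 1L) {
      stop("reference too small: a day group cannot reach min_per_day ",
           "even after pooling", call. = FALSE)
    }
    i <- deficient[which.min(sizes[deficient])][1L]
    gap <- vapply(seq_along(groups), function(j) {
      if (j == i) return(Inf)
      min(abs(outer(groups[[i]]$days, groups[[j]]$days, `-`)))
    }, numeric(1))
    # nearest group; on ties prefer the one containing the earlier day
    cand <- which(gap == min(gap))
    j <- cand[which.min(vapply(cand, function(jj) min(groups[[jj]]$days),
                               numeric(1)))]
    groups[[j]] <- list(days = sort(c(groups[[i]]$days, groups[[j]]$days)),
                        scores = c(groups[[i]]$scores, groups[[j]]$scores))
    groups[[i]] <- NULL
  }
  groups
}

# One empirical curve: sorted scores + Hazen plotting positions with
# midrank tie handling.
.make_curve <- function(scores, days) {
  scores <- sort(as.numeric(scores))
  n <- length(scores)
  pos <- (rank(scores, ties.method = "average") - 0.5) / n
  ux <- unique(scores)
  upos <- vapply(ux, function(v) pos[match(v, scores)], numeric(1))
  list(scores = scores, n = n, days = as.integer(days),
       knots_x = ux, knots_p = upos)
}

.curve_percentile <- function(curve, score) {
  kx <- curve$knots_x
  kp <- curve$knots_p
  out <- numeric(length(score))
  if (length(kx) == 1L) {
    out[score < kx] <- 0
    out[score > kx] <- 100
    out[score == kx] <- 100 * kp
    return(out)
  }
  out <- 100 * stats::approx(kx, kp, xout = score, rule = 2)$y
  out[score < kx[1L]] <- 0
  out[score > kx[length(kx)]] <- 100
  out
}

#' Build per-day percentile reference curves from qPCR dCt values
#'
#' For each gene and cycle day the reference dCt values are converted to
#' expression scores (`score = -dct`) and sorted into an empirical quantile
#' function.  Days with fewer than `min_per_day` samples are pooled with the
#' nearest neighbouring day (ties towards the earlier day); pooling is
#' recorded in the curve metadata.
#'
#' @param ref data.frame with columns `subject_id`, `lh_day`, `gene`,
#'   `dct`.  Each (subject, gene) pair may appear once.
#' @param min_per_day minimum reference samples per day group (default 20).
#' @param days supported day range (default 6:11, days after the LH surge).
#' @return object of class `centile_curves`.
#' @export
#' @examples
#' ref <- generate_reference_table(cohort_sim_config(), n_per_day = 30)
#' curves <- build_centile_curves(ref)
#' percentile_of(curves, "SCARA5", lh_day = 8, value = 7.5)
build_centile_curves <- function(ref, min_per_day = 20, days = 6:11) {
  stopifnot(all(c("subject_id", "lh_day", "gene", "dct") %in%
                  colnames(ref)))
  min_per_day <- check_count(min_per_day, "min_per_day", min = 1L)
  if (anyDuplicated(ref[, c("subject_id", "gene")])) {
    stop("duplicated (subject_id, gene) rows in reference table",
         call. = FALSE)
  }
  if (!all(ref$lh_day %in% days)) {
    stop("reference contains days outside the supported range",
         call. = FALSE)
  }
  curves <- list()
  pooling <- list()
  for (g in unique(ref$gene)) {
    sub <- ref[ref$gene == g, ]
    by_day <- split(-sub$dct, sub$lh_day) # expression score = -dct
    groups <- .pool_days(by_day, min_per_day)
    curves[[g]] <- list()
    for (grp in groups) {
      cv <- .make_curve(grp$scores, grp$days)
      for (d in grp$days) curves[[g]][[as.character(d)]] <- cv
      if (length(grp$days) > 1L) {
        pooling[[length(pooling) + 1L]] <- data.frame(
          gene = g, days = paste(grp$days, collapse = "+"),
          n = cv$n, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(curves = curves, orientation = "dct",
                 min_per_day = min_per_day, days = as.integer(days),
                 pooling = if (length(pooling)) do.call(rbind, pooling)),
            class = "centile_curves")
}

#' Build a per-day uNK-cell percentage reference curve set
#'
#' Same empirical-quantile machinery as [build_centile_curves()], oriented
#' so that a higher uNK percentage maps to a higher percentile.
#'
#' @param ref data.frame with columns `subject_id`, `lh_day`, `unk_pct`.
#' @inheritParams build_centile_curves
#' @return object of class `centile_curves` holding a single `"uNK"` curve
#'   per day.
#' @export
build_unk_curves <- function(ref, min_per_day = 20, days = 6:11) {
  stopifnot(all(c("subject_id", "lh_day", "unk_pct") %in% colnames(ref)))
  min_per_day <- check_count(min_per_day, "min_per_day", min = 1L)
  if (anyDuplicated(ref$subject_id)) {
    stop("duplicated subject_id rows in uNK reference table", call. = FALSE)
  }
  if (!all(ref$lh_day %in% days)) {
    stop("reference contains days outside the supported range",
         call. = FALSE)
  }
  by_day <- split(ref$unk_pct, ref$lh_day) # score = uNK percentage itself
  groups <- .pool_days(by_day, min_per_day)
  curves <- list(uNK = list())
  pooling <- list()
  for (grp in groups) {
    cv <- .make_curve(grp$scores, grp$days)
    for (d in grp$days) curves$uNK[[as.character(d)]] <- cv
    if (length(grp$days) > 1L) {
      pooling[[length(pooling) + 1L]] <- data.frame(
        gene = "uNK", days = paste(grp$days, collapse = "+"), n = cv$n,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(curves = curves, orientation = "value",
                 min_per_day = min_per_day, days = as.integer(days),
                 pooling = if (length(pooling)) do.call(rbind, pooling)),
            class = "centile_curves")
}

#' Day-normalized percentile of a measurement
#'
#' Maps a value to its percentile (0-100) on the reference curve for its
#' gene and cycle day.  For dCt-oriented curve sets the value is a dCt and
#' is negated into an expression score first, so the percentile is a
#' percentile of expression; for value-oriented sets (uNK) the value is
#' used directly.  Queries outside the reference range clamp to 0 or 100.
#' Vectorized over `lh_day` and `value`.
#'
#' @param curves a `centile_curves` object.
#' @param gene gene identifier (or `"uNK"`).
#' @param lh_day integer day(s) after the LH surge.
#' @param value dCt value(s) or uNK percentage(s), matching `lh_day`.
#' @return numeric percentile(s) in \[0, 100\].
#' @export
percentile_of <- function(curves, gene, lh_day, value) {
  stopifnot(inherits(curves, "centile_curves"))
  if (!gene %in% names(curves$curves)) {
    stop("unknown gene: ", gene, call. = FALSE)
  }
  if (length(lh_day) == 1L) lh_day <- rep(lh_day, length(value))
  stopifnot(length(lh_day) == length(value))
  score <- if (curves$orientation == "dct") -value else value
  out <- numeric(length(value))
  for (d in unique(lh_day)) {
    cv <- curves$curves[[gene]][[as.character(d)]]
    if (is.null(cv)) stop("no reference curve for day ", d, call. = FALSE)
    idx <- lh_day == d
    out[idx] <- .curve_percentile(cv, score[idx])
  }
  out
}

#' uNK-cell percentage from per-image CD56+/stromal counts
#'
#' The uNK-cell percentage of a biopsy is the number of CD56+ cells per 100
#' stromal cells, averaged over the (by default three) scored images.
#'
#' @param cd56_counts,stromal_counts equal-length integer vectors of
#'   per-image cell counts; every stromal count must be at least 1.
#' @param n_images expected number of images (default 3); set `NULL` to
#'   skip the check.
#' @return the averaged uNK percentage.
#' @export
#' @examples
#' unk_percentage(c(10, 30, 12), c(200, 150, 120)) # mean of 5, 20, 10
unk_percentage <- function(cd56_counts, stromal_counts, n_images = 3) {
  stopifnot(length(cd56_counts) == length(stromal_counts))
  if (!is.null(n_images) && length(cd56_counts) != n_images) {
    stop(sprintf("expected %d images, got %d", n_images,
                 length(cd56_counts)), call. = FALSE)
  }
  if (any(stromal_counts < 1)) {
    stop("every image needs at least 1 stromal cell", call. = FALSE)
  }
  if (any(cd56_counts < 0)) stop("negative CD56 count", call. = FALSE)
  mean(100 * cd56_counts / stromal_counts)
}

#' Day-normalized uNK-cell percentile
#'
#' @param curves a `centile_curves` set built with [build_unk_curves()].
#' @param lh_day integer day(s) after the LH surge.
#' @param unk_pct uNK percentage(s) from [unk_percentage()].
#' @return numeric percentile(s) in \[0, 100\]; higher uNK abundance maps
#'   to a higher percentile.
#' @export
unk_percentile <- function(curves, lh_day, unk_pct) {
  stopifnot(inherits(curves, "centile_curves"),
            curves$orientation == "value")
  percentile_of(curves, "uNK", lh_day, unk_pct)
}

#' Serialize / deserialize percentile curve sets as JSON
#'
#' The full sorted reference scores and metadata are stored at full
#' precision, so a written-then-read curve set reproduces identical
#' percentiles.
#'
#' @param curves a `centile_curves` object.
#' @param path JSON file path.
#' @return `read_curves()` returns the `centile_curves` object.
#' @export
write_curves <- function(curves, path) {
  stopifnot(inherits(curves, "centile_curves"))
  ser <- list(orientation = curves$orientation,
              min_per_day = curves$min_per_day, days = curves$days,
              genes = lapply(curves$curves, function(per_day) {
                # deduplicate pooled curves shared between days
                lapply(per_day, function(cv) {
                  list(days = cv$days, scores = cv$scores)
                })
              }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  curves <- lapply(ser$genes, function(per_day) {
    lapply(per_day, function(cv) {
      .make_curve(as.numeric(cv$scores), as.integer(cv$days))
    })
  })
  structure(list(curves = curves, orientation = ser$orientation,
                 min_per_day = as.integer(ser$min_per_day),
                 days = as.integer(ser$days), pooling = NULL),
            class = "centile_curves")
}

#' @export
print.centile_curves <- function(x, ...) {
  genes <- names(x$curves)
  cat(sprintf("<centile_curves> %s; days %s; genes: %s\n",
              if (x$orientation == "dct") "expression scores from dCt"
              else "direct values",
              paste(range(x$days), collapse = "-"),
              paste(genes, collapse = ", ")))
  if (!is.null(x$pooling)) {
    cat("pooled day groups:\n")
    print(x$pooling)
  }
  invisible(x)
}
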