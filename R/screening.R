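# Rule-based classification of decidual-pathway defects from day-normalized
# percentiles, percentile-sum binning, and cohort contingency statistics.

#' Defect classification rule set
#'
#' Thresholds (percentiles) defining the three decidual-pathway defects:
#' * decidualization failure: SCARA5 <= low AND DIO2 <= low;
#' * excessive decidual senescence: SCARA5 <= low AND DIO2 >= high;
#' * uNK-cell deficiency: uNK <= low AND both markers strictly between low
#'   and high.
#' Boundary conventions are literal: the low threshold is inclusive for the
#' first two rules, the high threshold inclusive for senescence, and the
#' marker window of the uNK rule is strictly interior.
#'
#' @param low_threshold,high_threshold percentiles with
#'   `0 < low < high < 100`; defaults 30 and 70.
#' @return object of class `defect_rules`.
#' @export
defect_rules <- function(low_threshold = 30, high_threshold = 70) {
  if (!(low_threshold > 0 && low_threshold < high_threshold &&
        high_threshold < 100)) {
    stop("need 0 < low_threshold < high_threshold < 100", call. = FALSE)
  }
  structure(list(low_threshold = low_threshold,
                 high_threshold = high_threshold),
            class = "defect_rules")
}

# Vectorized rule engine shared by classify_defect and the cohort
# generator's rejection sampler.  The three regions are disjoint by
# construction (the first two require scara5 <= low, the third requires
# scara5 strictly above low), so at most one rule can fire.
classify_defect_vec <- function(scara5, dio2, unk, low, high) {
  out <- rep("none", length(scara5))
  out[scara5 <= low & dio2 <= low] <- "decid_failure"
  out[scara5 <= low & dio2 >= high] <- "excess_senescence"
  out[unk <= low & scara5 > low & scara5 < high &
        dio2 > low & dio2 < high] <- "unk_deficiency"
  out
}

#' Classify a subject's percentiles into a decidual-pathway defect
#'
#' @param scara5_pct,dio2_pct,unk_pct day-normalized percentiles in
#'   \[0, 100\] (vectors of equal length are accepted).
#' @param rules a [defect_rules()].
#' @return data.frame with columns `label` (factor over `decid_failure`,
#'   `excess_senescence`, `unk_deficiency`, `none`) and `aberrant`
#'   (`label != "none"`).
#' @export
#' @examples
#' classify_defect(25, 75, 50) # excessive decidual senescence
classify_defect <- function(scara5_pct, dio2_pct, unk_pct,
                            rules = defect_rules()) {
  stopifnot(inherits(rules, "defect_rules"))
  p <- c(scara5_pct, dio2_pct, unk_pct)
  if (anyNA(p) || any(p < 0 | p > 100)) {
    stop("percentiles must lie in [0, 100]", call. = FALSE)
  }
  n <- length(scara5_pct)
  stopifnot(length(dio2_pct) == n, length(unk_pct) == n)
  lab <- classify_defect_vec(scara5_pct, dio2_pct, unk_pct,
                             rules$low_threshold, rules$high_threshold)
  lab <- factor(lab, levels = c("decid_failure", "excess_senescence",
                                "unk_deficiency", "none"))
  data.frame(label = lab, aberrant = lab != "none")
}

#' Binning scheme on the SCARA5 + uNK percentile sum
#'
#' Subjects are binned by the sum of their SCARA5 and uNK percentiles
#' (range 0-200; DIO2 does not enter the sum).  Bins are half-open
#' `[lo, hi)` except the top bin, which is closed at 200.  The default is
#' four equal-width bins with edges at 50, 100 and 150.
#'
#' @param edges strictly increasing interior bin boundaries in (0, 200).
#' @return object of class `bin_scheme` with `edges` and `n_bins`.
#' @export
bin_scheme <- function(edges = c(50, 100, 150)) {
  edges <- as.numeric(edges)
  if (any(diff(edges) <= 0) || any(edges <= 0) || any(edges >= 200)) {
    stop("`edges` must be strictly increasing within (0, 200)",
         call. = FALSE)
  }
  structure(list(edges = edges, n_bins = length(edges) + 1L),
            class = "bin_scheme")
}

#' Bin a subject by the sum of SCARA5 and uNK percentiles
#'
#' @inheritParams classify_defect
#' @param bins a [bin_scheme()].
#' @return integer bin index in `1..n_bins` (1 = lowest percentile sum).
#' @export
bin_percentile_sum <- function(scara5_pct, unk_pct, bins = bin_scheme()) {
  stopifnot(inherits(bins, "bin_scheme"))
  p <- c(scara5_pct, unk_pct)
  if (anyNA(p) || any(p < 0 | p > 100)) {
    stop("percentiles must lie in [0, 100]", call. = FALSE)
  }
  s <- scara5_pct + unk_pct
  findInterval(s, c(0, bins$edges, 200 + 1e-9), rightmost.closed = FALSE)
}

#' Contingency table and test for per-subject categories across groups
#'
#' Builds the category x group count table and tests homogeneity: 2 x 2
#' tables use the two-sided Fisher's exact test (exact hypergeometric
#' enumeration, as implemented in [stats::fisher.test()]) and report the
#' conditional odds-ratio estimate; larger tables use the chi-squared test
#' without continuity correction.
#'
#' @param categories per-subject category labels (>= 2 distinct values).
#' @param groups per-subject group labels (both groups must be non-empty).
#' @return list of class `cohort_contingency` with `table`, `method`,
#'   `p_value`, `odds_ratio` (2 x 2 only), `statistic` and `df` (chi-squared
#'   only).
#' @export
cohort_contingency <- function(categories, groups) {
  stopifnot(length(categories) == length(groups))
  categories <- factor(categories)
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2L) {
    stop("both groups must be present", call. = FALSE)
  }
  categories <- droplevels(categories)
  groups <- droplevels(groups)
  if (nlevels(categories) < 2L) {
    stop("need at least 2 categories", call. = FALSE)
  }
  tab <- table(category = categories, group = groups)
  if (all(dim(tab) == c(2L, 2L))) {
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    structure(list(table = tab, method = "fisher", p_value = ft$p.value,
                   odds_ratio = unname(ft$estimate), statistic = NA_real_,
                   df = NA_integer_),
              class = "cohort_contingency")
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    structure(list(table = tab, method = "chisq", p_value = ct$p.value,
                   odds_ratio = NA_real_,
                   statistic = unname(ct$statistic),
                   df = unname(ct$parameter)),
              class = "cohort_contingency")
  }
}

#' @export
print.cohort_contingency <- function(x, ...) {
  print(x$table)
  cat(sprintf("%s test: p = %.4g\n",
              if (x$method == "fisher") "Fisher's exact" else "chi-squared",
              x$p_value))
  invisible(x)
}

#' Screen a cohort of subjects for decidual-pathway defects
#'
#' Applies [classify_defect()] and [bin_percentile_sum()] to every subject
#' and summarises the cohort: per-group defect frequencies, aberrant
#' incidence, per-bin group composition, a Fisher test on aberrant status
#' by group, per-defect chi-squared tests, and a Fisher test comparing the
#' lowest against the highest percentile-sum bin.
#'
#' @param samples data.frame with columns `subject_id`, `group` (values
#'   `"control"` / `"rpl"`), `scara5_pct`, `dio2_pct`, `unk_pct`.
#' @param rules a [defect_rules()].
#' @param bins a [bin_scheme()].
#' @return list of class `decidual_screen` with `per_subject` (the input
#'   plus `label`, `aberrant`, `bin`) and `summary`.
#' @export
screen_cohort <- function(samples, rules = defect_rules(),
                          bins = bin_scheme()) {
  need <- c("subject_id", "group", "scara5_pct", "dio2_pct", "unk_pct")
  stopifnot(all(need %in% colnames(samples)))
  if (nrow(samples) == 0L) stop("empty cohort", call. = FALSE)
  if (anyDuplicated(samples$subject_id)) {
    stop("duplicate subject_id", call. = FALSE)
  }
  calls <- classify_defect(samples$scara5_pct, samples$dio2_pct,
                           samples$unk_pct, rules)
  per_subject <- cbind(samples, calls)
  per_subject$bin <- bin_percentile_sum(samples$scara5_pct,
                                        samples$unk_pct, bins)

  group <- factor(per_subject$group)
  defect_table <- table(label = per_subject$label, group = group)
  group_n <- table(group)
  defect_freq <- sweep(defect_table, 2L, as.numeric(group_n), `/`)
  aberrant_incidence <- vapply(split(per_subject$aberrant, group),
                               function(x) 100 * mean(x), numeric(1))

  bin_table <- table(bin = factor(per_subject$bin,
                                  levels = seq_len(bins$n_bins)),
                     group = group)
  bin_composition <- 100 * prop.table(bin_table, margin = 1L)

  try_test <- function(expr) tryCatch(expr, error = function(e) NULL)
  aberrant_test <- try_test(cohort_contingency(per_subject$aberrant,
                                               group))
  defect_tests <- lapply(
    stats::setNames(nm = c("decid_failure", "excess_senescence",
                           "unk_deficiency")),
    function(d) {
      try_test({
        tab <- table(factor(per_subject$label == d, c(FALSE, TRUE)), group)
        ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        list(table = tab, p_value = ct$p.value,
             statistic = unname(ct$statistic))
      })
    })
  extreme <- per_subject$bin %in% c(1L, bins$n_bins)
  extreme_bin_test <- try_test(
    cohort_contingency(per_subject$bin[extreme], group[extreme]))

  summary <- list(group_sizes = group_n, defect_table = defect_table,
                  defect_freq = defect_freq,
                  aberrant_incidence = aberrant_incidence,
                  bin_table = bin_table, bin_composition = bin_composition,
                  aberrant_test = aberrant_test,
                  defect_tests = defect_tests,
                  extreme_bin_test = extreme_bin_test)
  structure(list(per_subject = per_subject, summary = summary,
                 rules = rules, bins = bins),
            class = "decidual_screen")
}

#' @export
print.decidual_screen <- function(x, ...) {
  s <- x$summary
  cat("<decidual_screen>\n")
  cat("Defect counts by group:\n")
  print(s$defect_table)
  cat("\nAberrant incidence (%):\n")
  print(round(s$aberrant_incidence, 1))
  if (!is.null(s$aberrant_test)) {
    cat(sprintf("\nAberrant vs group, Fisher p = %.4g\n",
                s$aberrant_test$p_value))
  }
  cat("\nPercentile-sum bins (group %):\n")
  print(round(s$bin_composition, 1))
  invisible(x)
}

#' Write a screening report to disk
#'
#' Writes the per-subject table as TSV and the cohort summary as JSON.
#'
#' @param screen a `decidual_screen` from [screen_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_screen_report <- function(screen, dir) {
  stopifnot(inherits(screen, "decidual_screen"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(screen$per_subject,
                     file.path(dir, "per_subject.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  s <- screen$summary
  out <- list(
    group_sizes = as.list(s$group_sizes),
    aberrant_incidence_pct = as.list(s$aberrant_incidence),
    defect_table = as.data.frame(s$defect_table),
    bin_table = as.data.frame(s$bin_table),
    aberrant_fisher_p = if (!is.null(s$aberrant_test))
      s$aberrant_test$p_value,
    defect_chisq_p = lapply(s$defect_tests, function(t)
      if (!is.null(t)) t$p_value),
    extreme_bin_fisher_p = if (!is.null(s$extreme_bin_test))
      s$extreme_bin_test$p_value)
  jsonlite::write_json(out, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
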