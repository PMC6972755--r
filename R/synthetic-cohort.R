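# Synthetic cohort generator.
#
# Subjects carry a latent decidual-pathway class (normal, decidualization
# failure, excessive senescence, uNK deficiency).  The class is realised in
# percentile space -- e.g. a decidualization-failure subject draws both
# marker percentiles uniformly on [0, 30] -- and then inverted through the
# day-specific generative quantile function to a dCt value, so the screening
# rules are recoverable by construction.

DEFAULT_CLASSES <- c("decid_failure", "excess_senescence", "unk_deficiency")

#' Default per-day dCt distribution for the marker genes
#'
#' The generative model for qPCR delta-Ct (target Ct minus L19 reference Ct;
#' lower dCt = higher expression) is Normal per gene per cycle day, with a
#' day-varying mean so that SCARA5 expression rises across the implantation
#' window (dCt falls) while DIO2, a senescence-associated transcript, rises
#' more gently towards the late-luteal phase.  Values are arbitrary but
#' fixed; they set the scale on which percentile curves are built.
#'
#' @return data.frame with columns `gene`, `lh_day`, `mean_dct`, `sd_dct`.
#' @export
default_day_effects <- function() {
  days <- 6:11
  rbind(
    data.frame(gene = "SCARA5", lh_day = days,
               mean_dct = seq(9.5, 6.0, length.out = length(days)),
               sd_dct = 1.5),
    data.frame(gene = "DIO2", lh_day = days,
               mean_dct = seq(8.0, 6.0, length.out = length(days)),
               sd_dct = 1.5)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' @param n_control,n_rpl number of subjects in the control and recurrent
#'   pregnancy loss (RPL) arms.  Defaults mirror a 90/89 clinical cohort.
#' @param prevalence_by_group named list with elements `control` and `rpl`,
#'   each a named numeric vector of latent-class probabilities over
#'   `decid_failure`, `excess_senescence`, `unk_deficiency`.  Probabilities
#'   must be in \[0, 1\] and sum to at most 1; the remainder is the `normal`
#'   class.  Defaults give an aberrant incidence of 14% in controls and 44%
#'   in RPL.
#' @param lh_day_range integer vector of supported biopsy days after the LH
#'   surge (default 6:11, the implantation window).
#' @param day_effects data.frame as [default_day_effects()].
#' @param unk_reference length-2 numeric `c(mean, sd)` of the generative
#'   Normal distribution of the uNK-cell percentage (CD56+ cells per 100
#'   stromal cells).
#' @param low_threshold,high_threshold percentile thresholds defining the
#'   latent-class regions (must match the screening rule set for end-to-end
#'   recovery; defaults 30 and 70).
#' @param seed integer seed; identical config + seed reproduces the cohort
#'   exactly.
#' @return An object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_control = 90, n_rpl = 89,
                              prevalence_by_group = list(
                                control = c(decid_failure = 0.05,
                                            excess_senescence = 0.04,
                                            unk_deficiency = 0.05),
                                rpl = c(decid_failure = 0.08,
                                        excess_senescence = 0.16,
                                        unk_deficiency = 0.20)),
                              lh_day_range = 6:11,
                              day_effects = default_day_effects(),
                              unk_reference = c(mean = 8, sd = 2.5),
                              low_threshold = 30, high_threshold = 70,
                              seed = 1L) {
  n_control <- check_count(n_control, "n_control")
  n_rpl <- check_count(n_rpl, "n_rpl")
  if (!is.list(prevalence_by_group) ||
      !all(c("control", "rpl") %in% names(prevalence_by_group))) {
    stop("`prevalence_by_group` must be a list with elements ",
         "'control' and 'rpl'", call. = FALSE)
  }
  for (g in c("control", "rpl")) {
    p <- prevalence_by_group[[g]]
    p <- p[DEFAULT_CLASSES]
    p[is.na(p)] <- 0
    names(p) <- DEFAULT_CLASSES
    if (any(p < 0) || any(p > 1) || sum(p) > 1 + 1e-12) {
      stop("class prevalences must lie in [0,1] and sum to at most 1",
           call. = FALSE)
    }
    prevalence_by_group[[g]] <- p
  }
  if (length(lh_day_range) < 1L) stop("`lh_day_range` must be non-empty",
                                      call. = FALSE)
  stopifnot(all(c("gene", "lh_day", "mean_dct", "sd_dct") %in%
                  colnames(day_effects)))
  if (!all(lh_day_range %in% day_effects$lh_day)) {
    stop("`day_effects` must cover every day in `lh_day_range`",
         call. = FALSE)
  }
  stopifnot(length(unk_reference) == 2L, all(unk_reference > 0))
  if (!(low_threshold > 0 && low_threshold < high_threshold &&
        high_threshold < 100)) {
    stop("need 0 < low_threshold < high_threshold < 100", call. = FALSE)
  }
  structure(list(n_control = n_control, n_rpl = n_rpl,
                 prevalence_by_group = prevalence_by_group,
                 lh_day_range = as.integer(lh_day_range),
                 day_effects = day_effects,
                 unk_reference = c(mean = unname(unk_reference[1L]),
                                   sd = unname(unk_reference[2L])),
                 low_threshold = low_threshold,
                 high_threshold = high_threshold,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

# Draw latent-class-conditional true percentiles (expression scale) for one
# subject.  `normal` is rejection-sampled from the complement of the three
# defect regions, so a zero-prevalence cohort is aberrant-free by
# construction.
draw_class_percentiles <- function(class, low, high) {
  runif_open <- function(lo, hi) {
    # avoid the measure-zero endpoints so quantile inversion stays finite
    stats::qunif(stats::runif(1L, 1e-9, 1 - 1e-9), lo, hi)
  }
  if (class == "decid_failure") {
    c(scara5 = runif_open(0, low), dio2 = runif_open(0, low),
      unk = runif_open(0, 100))
  } else if (class == "excess_senescence") {
    c(scara5 = runif_open(0, low), dio2 = runif_open(high, 100),
      unk = runif_open(0, 100))
  } else if (class == "unk_deficiency") {
    c(scara5 = runif_open(low, high), dio2 = runif_open(low, high),
      unk = runif_open(0, low))
  } else {
    repeat {
      p <- c(scara5 = runif_open(0, 100), dio2 = runif_open(0, 100),
             unk = runif_open(0, 100))
      lab <- classify_defect_vec(p[["scara5"]], p[["dio2"]], p[["unk"]],
                                 low, high)
      if (lab == "none") return(p)
    }
  }
}

#' Generate a synthetic control/RPL cohort with planted defect classes
#'
#' Each subject receives a latent class drawn from the per-group prevalences,
#' true percentiles drawn from the class-conditional region (e.g.
#' decidualization failure: both marker percentiles uniform on
#' \[0, `low_threshold`\]), and observable values obtained by inverting the
#' percentiles through the generative per-day quantile functions.  uNK
#' abundance is emitted as three raw (CD56+, stromal) image count pairs, so
#' the uNK quantification step is exercised downstream.
#'
#' @param config a [cohort_sim_config()].
#' @return A list of class `cohort_sim` with elements
#'   * `cohort`: data.frame with columns `subject_id`, `group`, `lh_day`,
#'     `dct_scara5`, `dct_dio2`, `cd56_1`, `stromal_1`, ..., `stromal_3`;
#'   * `truth`: sidecar data.frame with the hidden class and the true
#'     generative percentiles per subject.
#' @export
#' @examples
#' sim <- generate_cohort(cohort_sim_config(n_control = 5, n_rpl = 5))
#' head(sim$cohort)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  with_seed(config$seed, {
    n <- config$n_control + config$n_rpl
    group <- rep(c("control", "rpl"), c(config$n_control, config$n_rpl))
    subject_id <- sprintf("S%04d", seq_len(n))
    lh_day <- sample(config$lh_day_range, n, replace = TRUE)

    classes <- character(n)
    pct <- matrix(NA_real_, n, 3,
                  dimnames = list(NULL, c("scara5", "dio2", "unk")))
    for (i in seq_len(n)) {
      prev <- config$prevalence_by_group[[group[i]]]
      classes[i] <- sample(c(DEFAULT_CLASSES, "normal"), 1L,
                           prob = c(prev, 1 - sum(prev)))
      pct[i, ] <- draw_class_percentiles(classes[i], config$low_threshold,
                                         config$high_threshold)
    }

    de <- config$day_effects
    dct_for <- function(gene, day, p) {
      row <- de[de$gene == gene & de$lh_day == day, ]
      # expression score = -dct ~ Normal(-mean_dct, sd); invert percentile
      row$mean_dct - row$sd_dct * stats::qnorm(p / 100)
    }
    dct_scara5 <- dct_dio2 <- numeric(n)
    for (i in seq_len(n)) {
      dct_scara5[i] <- dct_for("SCARA5", lh_day[i], pct[i, "scara5"])
      dct_dio2[i] <- dct_for("DIO2", lh_day[i], pct[i, "dio2"])
    }

    unk_target <- stats::qnorm(pct[, "unk"] / 100,
                               mean = config$unk_reference["mean"],
                               sd = config$unk_reference["sd"])
    unk_target <- pmax(unk_target, 0.05)
    stromal <- matrix(sample(150:350, 3L * n, replace = TRUE), n, 3)
    cd56 <- round(unk_target / 100 * stromal)

    cohort <- data.frame(
      subject_id = subject_id, group = group, lh_day = lh_day,
      dct_scara5 = dct_scara5, dct_dio2 = dct_dio2,
      cd56_1 = cd56[, 1], stromal_1 = stromal[, 1],
      cd56_2 = cd56[, 2], stromal_2 = stromal[, 2],
      cd56_3 = cd56[, 3], stromal_3 = stromal[, 3],
      stringsAsFactors = FALSE)
    truth <- data.frame(
      subject_id = subject_id, truth_class = classes,
      scara5_pct = pct[, "scara5"], dio2_pct = pct[, "dio2"],
      unk_pct = pct[, "unk"], stringsAsFactors = FALSE)
    structure(list(cohort = cohort, truth = truth, config = config),
              class = "cohort_sim")
  })
}

#' Generate a synthetic qPCR reference table for percentile curves
#'
#' Draws `n_per_day` subjects per cycle day from the generative per-day dCt
#' distributions of `config`, for both marker genes, in the long format
#' expected by [build_centile_curves()].
#'
#' @param config a [cohort_sim_config()] (only `day_effects` and
#'   `lh_day_range` are used).
#' @param n_per_day subjects per day (default 42, a realistic per-day
#'   reference depth).
#' @param seed integer seed.
#' @return data.frame with columns `subject_id`, `lh_day`, `gene`, `dct`.
#' @export
generate_reference_table <- function(config, n_per_day = 42, seed = 1L) {
  stopifnot(inherits(config, "cohort_sim_config"))
  n_per_day <- check_count(n_per_day, "n_per_day", min = 1L)
  with_seed(seed, {
    out <- list()
    for (day in config$lh_day_range) {
      ids <- sprintf("REF_d%d_%04d", day, seq_len(n_per_day))
      for (gene in unique(config$day_effects$gene)) {
        row <- config$day_effects[config$day_effects$gene == gene &
                                    config$day_effects$lh_day == day, ]
        out[[length(out) + 1L]] <- data.frame(
          subject_id = ids, lh_day = day, gene = gene,
          dct = stats::rnorm(n_per_day, row$mean_dct, row$sd_dct),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

#' Generate a synthetic uNK-cell percentage reference table
#'
#' @inheritParams generate_reference_table
#' @return data.frame with columns `subject_id`, `lh_day`, `unk_pct`.
#' @export
generate_unk_reference <- function(config, n_per_day = 42, seed = 1L) {
  stopifnot(inherits(config, "cohort_sim_config"))
  n_per_day <- check_count(n_per_day, "n_per_day", min = 1L)
  with_seed(seed, {
    out <- list()
    for (day in config$lh_day_range) {
      vals <- stats::rnorm(n_per_day, config$unk_reference["mean"],
                           config$unk_reference["sd"])
      out[[length(out) + 1L]] <- data.frame(
        subject_id = sprintf("UNKREF_d%d_%04d", day, seq_len(n_per_day)),
        lh_day = day, unk_pct = pmax(vals, 0.01),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Write / read a simulated cohort as TSV files
#'
#' Writes `cohort.tsv` and the ground-truth sidecar `truth.tsv` into `dir`.
#'
#' @param sim a `cohort_sim` from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `read_cohort_tsv()` returns a list with `cohort` and `truth`
#'   data.frames (`truth` is `NULL` when the sidecar is absent).
#' @export
write_cohort_tsv <- function(sim, dir) {
  stopifnot(inherits(sim, "cohort_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(sim$cohort, file.path(dir, "cohort.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(dir) {
  cohort <- utils::read.delim(file.path(dir, "cohort.tsv"),
                              stringsAsFactors = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    utils::read.delim(truth_path, stringsAsFactors = FALSE)
  }
  list(cohort = cohort, truth = truth)
}
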