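# Synthetic single-cell data: branch-structured negative-binomial count
# matrices with two planted gene modules, and barcode read-count
# distributions with an ambient background for testing knee-point cell
# calling.

#' Configuration for the branch-structured count-matrix simulator
#'
#' Cells occupy one of three states along a bifurcating decidual
#' trajectory: `dc` (decidual cells), `sndc` (senescent decidual cells) and
#' `trunk` (pre-branch cells).  Genes assigned to the `dc_module` have
#' elevated mean expression in `dc` cells and `sndc_module` genes in `sndc`
#' cells; all other genes are state-independent background.
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param module_assignment named character vector mapping gene identifiers
#'   to `"dc_module"`, `"sndc_module"` or `"background"`.  `NULL` (default)
#'   names genes `gene001`, ... and assigns the first 10 to the DC module and
#'   the next 10 to the snDC module.  Referencing an unknown gene is an
#'   error.
#' @param branch_proportions length-3 numeric, fractions of cells in the
#'   `dc`, `sndc` and `trunk` states; must sum to 1.  The default
#'   `c(0.78, 0.13, 0.09)` reproduces the day-6 composition of the in vitro
#'   decidual time course (78% DC, 13% snDC).
#' @param nb_dispersion negative-binomial dispersion phi (> 0); counts have
#'   variance `mu + phi * mu^2`.
#' @param dropout_rate probability that an observed count is zeroed
#'   (independent Bernoulli dropout applied after the NB draw).
#' @param library_size mean total counts per cell.
#' @param module_fold fold elevation of module genes in their own state.
#' @param seed integer seed.
#' @return object of class `sc_sim_config`.
#' @export
sc_sim_config <- function(n_cells = 500, n_genes = 100,
                          module_assignment = NULL,
                          branch_proportions = c(dc = 0.78, sndc = 0.13,
                                                 trunk = 0.09),
                          nb_dispersion = 0.3, dropout_rate = 0.2,
                          library_size = 2000, module_fold = 8,
                          seed = 1L) {
  n_cells <- check_count(n_cells, "n_cells", min = 1L)
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  genes <- sprintf("gene%03d", seq_len(n_genes))
  if (is.null(module_assignment)) {
    module_assignment <- stats::setNames(rep("background", n_genes), genes)
    module_assignment[seq_len(min(10L, n_genes))] <- "dc_module"
    if (n_genes > 10L) {
      module_assignment[11:min(20L, n_genes)] <- "sndc_module"
    }
  } else {
    if (is.null(names(module_assignment))) {
      stop("`module_assignment` must be named by gene", call. = FALSE)
    }
    unknown <- setdiff(names(module_assignment), genes)
    if (length(unknown) > 0L) {
      stop("module_assignment references unknown genes: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    bad <- setdiff(unique(module_assignment),
                   c("dc_module", "sndc_module", "background"))
    if (length(bad) > 0L) {
      stop("unknown module labels: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    full <- stats::setNames(rep("background", n_genes), genes)
    full[names(module_assignment)] <- module_assignment
    module_assignment <- full
  }
  branch_proportions <- unlist(branch_proportions)
  if (length(branch_proportions) != 3L || any(branch_proportions < 0) ||
      abs(sum(branch_proportions) - 1) > 1e-8) {
    stop("`branch_proportions` must be 3 non-negative fractions summing to 1",
         call. = FALSE)
  }
  names(branch_proportions) <- c("dc", "sndc", "trunk")
  structure(list(n_cells = n_cells, n_genes = n_genes, genes = genes,
                 module_assignment = module_assignment,
                 branch_proportions = branch_proportions,
                 nb_dispersion = check_positive(nb_dispersion,
                                                "nb_dispersion"),
                 dropout_rate = check_fraction(dropout_rate, "dropout_rate"),
                 library_size = check_positive(library_size, "library_size"),
                 module_fold = check_positive(module_fold, "module_fold"),
                 seed = as.integer(seed)),
            class = "sc_sim_config")
}

#' Simulate a branch-structured gene-by-cell count matrix
#'
#' Counts are drawn negative-binomially around state-dependent means (module
#' genes elevated `module_fold`-fold in their own branch state), scaled so
#' expected per-cell totals equal `library_size`, then zeroed by independent
#' Bernoulli dropout.
#'
#' @param config an [sc_sim_config()].
#' @return list of class `sc_sim` with `matrix` (a [count_matrix()]),
#'   `states` (ground-truth state per cell, named by barcode) and `config`.
#' @export
#' @examples
#' sim <- generate_timecourse_matrix(sc_sim_config(n_cells = 50))
#' table(sim$states)
generate_timecourse_matrix <- function(config) {
  stopifnot(inherits(config, "sc_sim_config"))
  with_seed(config$seed, {
    n <- config$n_cells
    states <- sample(names(config$branch_proportions), n, replace = TRUE,
                     prob = config$branch_proportions)
    barcodes <- sprintf("CELL%04d", seq_len(n))
    names(states) <- barcodes

    # per-gene relative weight per state
    w <- matrix(1, config$n_genes, 3,
                dimnames = list(config$genes, c("dc", "sndc", "trunk")))
    w[config$module_assignment == "dc_module", "dc"] <- config$module_fold
    w[config$module_assignment == "sndc_module", "sndc"] <- config$module_fold

    counts <- matrix(0L, config$n_genes, n,
                     dimnames = list(config$genes, barcodes))
    size <- 1 / config$nb_dispersion
    for (s in c("dc", "sndc", "trunk")) {
      idx <- which(states == s)
      if (length(idx) == 0L) next
      mu <- config$library_size * w[, s] / sum(w[, s])
      draws <- stats::rnbinom(length(mu) * length(idx), mu = mu, size = size)
      counts[, idx] <- matrix(as.integer(draws), config$n_genes,
                              length(idx))
    }
    if (config$dropout_rate > 0) {
      keep <- stats::rbinom(length(counts), 1L,
                            1 - config$dropout_rate) == 1L
      counts[!keep] <- 0L
    }
    structure(list(matrix = count_matrix(counts), states = states,
                   config = config),
              class = "sc_sim")
  })
}

#' Configuration for the barcode read-count simulator
#'
#' Emulates the ranked barcode read distribution of a droplet experiment:
#' `n_real` cell-containing barcodes with reads around `real_read_mean` and
#' `n_ambient` ambient-RNA barcodes around a much lower `ambient_read_mean`.
#'
#' @param n_real,n_ambient barcode counts.
#' @param real_read_mean,ambient_read_mean mean reads per barcode; must
#'   satisfy `real_read_mean > ambient_read_mean > 0`.
#' @param seed integer seed.
#' @return object of class `barcode_sim_config`.
#' @export
barcode_sim_config <- function(n_real = 800, n_ambient = 7200,
                               real_read_mean = 2000,
                               ambient_read_mean = 20, seed = 1L) {
  n_real <- check_count(n_real, "n_real")
  n_ambient <- check_count(n_ambient, "n_ambient")
  real_read_mean <- check_positive(real_read_mean, "real_read_mean")
  ambient_read_mean <- check_positive(ambient_read_mean,
                                      "ambient_read_mean")
  if (real_read_mean <= ambient_read_mean) {
    stop("`real_read_mean` must exceed `ambient_read_mean`", call. = FALSE)
  }
  structure(list(n_real = n_real, n_ambient = n_ambient,
                 real_read_mean = real_read_mean,
                 ambient_read_mean = ambient_read_mean,
                 seed = as.integer(seed)),
            class = "barcode_sim_config")
}

#' Simulate per-barcode read counts with ambient background
#'
#' Real barcodes draw reads log-normally around `real_read_mean` (moderate
#' cell-to-cell spread); ambient barcodes draw negative-binomially around
#' `ambient_read_mean`.  All counts are at least 1.
#'
#' @param config a [barcode_sim_config()].
#' @return list of class `barcode_sim` with `reads` (named integer vector)
#'   and `real_barcodes` (ground-truth character vector).
#' @export
generate_barcode_reads <- function(config) {
  stopifnot(inherits(config, "barcode_sim_config"))
  with_seed(config$seed, {
    real_bc <- if (config$n_real > 0) {
      sprintf("REAL%05d", seq_len(config$n_real))
    } else character(0)
    amb_bc <- if (config$n_ambient > 0) {
      sprintf("AMB%05d", seq_len(config$n_ambient))
    } else character(0)
    real <- if (config$n_real > 0) {
      stats::rlnorm(config$n_real,
                    meanlog = log(config$real_read_mean) - 0.25^2 / 2,
                    sdlog = 0.25)
    } else numeric(0)
    amb <- if (config$n_ambient > 0) {
      stats::rnbinom(config$n_ambient, mu = config$ambient_read_mean,
                     size = 2)
    } else numeric(0)
    reads <- pmax(round(c(real, amb)), 1)
    names(reads) <- c(real_bc, amb_bc)
    structure(list(reads = as.integer(reads) |>
                     stats::setNames(names(reads)),
                   real_barcodes = real_bc, config = config),
              class = "barcode_sim")
  })
}
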