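# End-to-end convenience: cohort table -> day-normalized percentiles.

#' Day-normalized percentiles for every subject of a cohort table
#'
#' Converts a cohort table (as produced by [generate_cohort()] or read with
#' [read_cohort_tsv()]) into the percentile triple used by the screening
#' rules: SCARA5 and DIO2 dCt values are mapped through the marker
#' percentile curves for the subject's cycle day, and the uNK percentage is
#' computed from the three image count pairs with [unk_percentage()] and
#' mapped through the uNK reference curves.
#'
#' @param cohort data.frame with columns `subject_id`, `group`, `lh_day`,
#'   `dct_scara5`, `dct_dio2`, `cd56_1`, `stromal_1`, ..., `stromal_3`.
#' @param marker_curves a `centile_curves` set from
#'   [build_centile_curves()] covering `SCARA5` and `DIO2`.
#' @param unk_curves a `centile_curves` set from [build_unk_curves()].
#' @return data.frame with columns `subject_id`, `group`, `scara5_pct`,
#'   `dio2_pct`, `unk_pct`, ready for [screen_cohort()].
#' @export
#' @examples
#' cfg <- cohort_sim_config(n_control = 20, n_rpl = 20)
#' sim <- generate_cohort(cfg)
#' curves <- build_centile_curves(generate_reference_table(cfg, 40))
#' unk_curves <- build_unk_curves(generate_unk_reference(cfg, 40))
#' pct <- cohort_percentiles(sim$cohort, curves, unk_curves)
#' head(pct)
cohort_percentiles <- function(cohort, marker_curves, unk_curves) {
  need <- c("subject_id", "group", "lh_day", "dct_scara5", "dct_dio2",
            "cd56_1", "stromal_1", "cd56_2", "stromal_2", "cd56_3",
            "stromal_3")
  stopifnot(all(need %in% colnames(cohort)))
  scara5_pct <- percentile_of(marker_curves, "SCARA5", cohort$lh_day,
                              cohort$dct_scara5)
  dio2_pct <- percentile_of(marker_curves, "DIO2", cohort$lh_day,
                            cohort$dct_dio2)
  unk_pct_raw <- vapply(seq_len(nrow(cohort)), function(i) {
    unk_percentage(
      c(cohort$cd56_1[i], cohort$cd56_2[i], cohort$cd56_3[i]),
      c(cohort$stromal_1[i], cohort$stromal_2[i], cohort$stromal_3[i]))
  }, numeric(1))
  unk_pct <- unk_percentile(unk_curves, cohort$lh_day, unk_pct_raw)
  data.frame(subject_id = cohort$subject_id, group = cohort$group,
             scara5_pct = scara5_pct, dio2_pct = dio2_pct,
             unk_pct = unk_pct, unk_percentage = unk_pct_raw,
             stringsAsFactors = FALSE)
}
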