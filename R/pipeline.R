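#' Run the full MeD-seq methylation-scoring pipeline on a simulated cohort
#'
#' Processes every sample's reads to per-site counts, summarizes them into
#' 2 kb TSS windows, applies the 75% presence filter and
#' normalization + square-root transform, identifies DMRs between patients
#' and HBDs with the moderated t-test, intersects them with the literature
#' marker list to form the panel, scores all samples against the HBD
#' reference with the Z-squared-sum score, calls positivity at the HBD
#' cutoff, and fits univariate Cox models of watchful-waiting time and PFS
#' on score positivity.
#'
#' @param sim output of [simulate_cohort()] (with reads).
#' @param genome the `lpnpi_genome` used for the simulation.
#' @param markers literature marker regions: BED-like data.frame or BED
#'   path, as for [intersect_markers()].
#' @param fdr_threshold DMR selection threshold (strict), default 0.1.
#' @param min_fraction presence-filter fraction, default 0.75.
#' @param scale normalization constant, default 1e6.
#' @param adapter adapter sequence to trim.
#' @return list with `matrix` (transformed `region_matrix`), `dmr` (full
#'   moderated-t table), `dmr_ids`, `panel`, `scoring` (from
#'   [score_cohort()]), `clinical` (with `score`, `score_positive`
#'   columns), `cox_ww`, `cox_pfs` (`cox_fit` or `NULL` when positivity
#'   does not vary), and per-sample `qc`.
#' @export
run_medseq_pipeline <- function(sim, genome, markers, fdr_threshold = 0.1,
                                min_fraction = 0.75, scale = 1e6,
                                adapter = medseq_adapter()) {
  stopifnot(!is.null(sim$reads))
  processed <- lapply(names(sim$reads), function(s) {
    process_sample(sim$reads[[s]], genome, sample_id = s, adapter = adapter)
  })
  names(processed) <- names(sim$reads)
  counts <- lapply(processed, `[[`, "counts")

  regions <- build_tss_windows(genome)
  rm_raw <- summarize_regions(counts, regions)
  rm_f <- presence_filter(rm_raw, min_fraction)
  rm_t <- normalize_and_sqrt(rm_f, scale)

  is_hbd <- rownames(rm_t$values) %in% sim$hbd_ids
  groups <- factor(ifelse(is_hbd, "HBD", "patient"),
                   levels = c("HBD", "patient"))
  dmr <- moderated_t(rm_t, groups)
  dmr_ids <- select_dmrs(dmr, fdr_threshold)
  panel <- intersect_markers(
    rm_t$regions[rm_t$regions$region_id %in% dmr_ids, , drop = FALSE],
    markers
  )
  if (nrow(panel) == 0L) stop("empty marker panel: no DMR overlaps a literature marker")

  scoring <- score_cohort(rm_t, sim$hbd_ids, panel)
  clinical <- sim$clinical
  idx <- match(clinical$patient_id, scoring$scores$sample_id)
  clinical$score <- scoring$scores$score[idx]
  clinical$score_positive <- scoring$scores$positive[idx]

  fit_or_null <- function(times, events) {
    if (length(unique(clinical$score_positive)) < 2L ||
        sum(events) < 1L) return(NULL)
    cox_univariate(times, events, clinical$score_positive,
                   name = "methylation score positive")
  }
  list(
    matrix = rm_t, dmr = dmr, dmr_ids = dmr_ids, panel = panel,
    scoring = scoring, clinical = clinical,
    cox_ww = fit_or_null(clinical$ww_time, clinical$ww_event),
    cox_pfs = fit_or_null(clinical$pfs_time, clinical$pfs_event),
    qc = data.frame(
      sample_id = names(processed),
      pass_fraction = vapply(processed, `[[`, 0, "pass_fraction"),
      filtered_reads = vapply(counts, `[[`, 0L, "total_filtered_reads"),
      mismatches = vapply(counts, `[[`, 0L, "n_mismatch"),
      row.names = NULL, stringsAsFactors = FALSE
    )
  )
}
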