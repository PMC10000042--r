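# Summarization of per-site counts into 2 kb TSS windows, the 75% presence
# filter, and normalization + square-root transform.

#' Build 2 kb windows around transcription start sites
#'
#' Each TSS yields the strand-ignorant window `[pos - 1000, pos + 1000)`
#' (0-based half-open). Windows overhanging the chromosome are clipped and
#' flagged; TSSs outside the genome are skipped with a warning.
#'
#' @param tss data.frame with `id`, `chrom`, `pos`, `strand` (as in an
#'   `lpnpi_genome`), or an `lpnpi_genome` itself.
#' @param genome_length chromosome length used for clipping (taken from the
#'   genome when one is supplied).
#' @param halfwidth half window width, default 1000 bp.
#' @return object of class `region_set`: data.frame with `region_id`,
#'   `chrom`, `start`, `end`, `tss_id`, `clipped`.
#' @export
build_tss_windows <- function(tss, genome_length = NULL, halfwidth = 1000L) {
  if (inherits(tss, "lpnpi_genome")) {
    genome_length <- tss$length
    tss <- tss$tss
  }
  stopifnot(!is.null(genome_length), all(c("id", "chrom", "pos") %in% names(tss)))
  bad <- tss$pos < 0 | tss$pos >= genome_length
  if (any(bad)) {
    warning(sprintf("%d TSS outside genome bounds skipped", sum(bad)))
    tss <- tss[!bad, , drop = FALSE]
  }
  start <- tss$pos - halfwidth
  end <- tss$pos + halfwidth
  clipped <- start < 0 | end > genome_length
  out <- data.frame(
    region_id = paste0("r_", tss$id), chrom = tss$chrom,
    start = pmax(0L, start), end = pmin(genome_length, end),
    tss_id = tss$id, clipped = clipped, stringsAsFactors = FALSE
  )
  class(out) <- c("region_set", "data.frame")
  out
}

#' Convert a region set (or BED-like data.frame) to GRanges
#' @param regions data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @export
regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
}

#' Summarize per-site counts into a raw region matrix
#'
#' A cell is the sum of counts of LpnPI sites whose position falls in the
#' region's half-open interval. Overlapping windows each count shared
#' sites; sites in no region are dropped and counted.
#'
#' @param count_tables list of `site_count_table`s (one per sample, shared
#'   site coordinates).
#' @param regions a `region_set`.
#' @return object of class `region_matrix`: list with `values` (samples x
#'   regions integer matrix), `state = "raw"`, `totals` (per-sample filtered
#'   read counts), `regions`, `n_dropped_site_counts` (reads at sites
#'   outside every region, per sample).
#' @export
summarize_regions <- function(count_tables, regions) {
  stopifnot(length(count_tables) > 0L)
  site_pos <- count_tables[[1L]]$site_pos
  for (ct in count_tables) stopifnot(identical(ct$site_pos, site_pos))
  sites_gr <- GenomicRanges::GRanges(
    regions$chrom[1L], IRanges::IRanges(start = site_pos + 1L, width = 1L)
  )
  hits <- GenomicRanges::findOverlaps(sites_gr, regions_to_granges(regions))
  si <- S4Vectors::queryHits(hits)
  ri <- S4Vectors::subjectHits(hits)
  in_any <- seq_along(site_pos) %in% si

  sample_ids <- vapply(count_tables, `[[`, "", "sample_id")
  vals <- matrix(0L, nrow = length(count_tables), ncol = nrow(regions),
                 dimnames = list(sample_ids, regions$region_id))
  dropped <- integer(length(count_tables))
  for (s in seq_along(count_tables)) {
    cnt <- count_tables[[s]]$counts
    vals[s, ] <- as.integer(
      tapply(cnt[si], factor(ri, levels = seq_len(nrow(regions))), sum,
             default = 0L)
    )
    dropped[s] <- sum(cnt[!in_any])
  }
  structure(
    list(values = vals, state = "raw",
         totals = stats::setNames(
           vapply(count_tables, `[[`, 0L, "total_filtered_reads"), sample_ids),
         regions = regions,
         n_dropped_site_counts = stats::setNames(dropped, sample_ids),
         state_history = "raw"),
    class = "region_matrix"
  )
}

#' @export
print.region_matrix <- function(x, ...) {
  cat(sprintf("<region_matrix> %d samples x %d regions, state: %s\n",
              nrow(x$values), ncol(x$values), x$state))
  invisible(x)
}

#' Presence filter: keep regions with data in enough samples
#'
#' Keeps regions with a nonzero raw count in at least `min_fraction` of all
#' samples (comparison is `>=`, so a region present in exactly 75% of
#' samples passes the default). Idempotent.
#'
#' @param matrix a raw `region_matrix`.
#' @param min_fraction minimum fraction of samples with data, default 0.75.
#' @return filtered `region_matrix`.
#' @export
presence_filter <- function(matrix, min_fraction = 0.75) {
  stopifnot(inherits(matrix, "region_matrix"))
  if (matrix$state != "raw") stop("presence_filter expects a raw matrix")
  frac <- colMeans(matrix$values > 0)
  keep <- frac >= min_fraction
  if (!any(keep)) stop("presence filter removed every region")
  matrix$values <- matrix$values[, keep, drop = FALSE]
  matrix$regions <- matrix$regions[keep, , drop = FALSE]
  matrix$state_history <- c(matrix$state_history, "presence_filtered")
  matrix
}

#' Normalize to filter totals and apply the square-root transform
#'
#' Each raw count is scaled to `scale * raw / total_filtered_reads` for its
#' sample -- the totals are the numbers of reads passing the LpnPI filter,
#' not the matrix row sums -- and the square root is taken to reduce
#' skewness.
#'
#' @param matrix a `region_matrix` in raw state.
#' @param scale normalization constant, default 1e6 (counts per million
#'   filter-passing reads).
#' @return `region_matrix` with `state = "sqrt"`.
#' @export
normalize_and_sqrt <- function(matrix, scale = 1e6) {
  stopifnot(inherits(matrix, "region_matrix"))
  if (matrix$state != "raw") stop("normalize_and_sqrt expects a raw matrix")
  if (any(matrix$totals <= 0)) {
    stop(sprintf("samples with zero filtered reads: %s",
                 paste(names(matrix$totals)[matrix$totals <= 0],
                       collapse = ", ")))
  }
  matrix$values <- sqrt(scale * sweep(matrix$values, 1L, matrix$totals, "/"))
  matrix$state <- "sqrt"
  matrix$state_history <- c(matrix$state_history, "normalized", "sqrt")
  matrix
}

#' Write a region matrix (and its totals sidecar) as TSV
#' @param matrix a `region_matrix`.
#' @param path output TSV (header row of region ids, index column of sample
#'   ids); totals are written next to it as `<path>.totals.tsv`.
#' @export
write_region_matrix <- function(matrix, path) {
  df <- data.frame(sample_id = rownames(matrix$values), matrix$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(matrix$totals),
               total_filtered_reads = matrix$totals),
    paste0(path, ".totals.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
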