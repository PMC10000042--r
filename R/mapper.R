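# Unique read placement: a built-in exact mapper for synthetic genomes plus
# SAM/BAM ingestion for externally aligned reads.

# every k-mer of the genome in positional order; cached in an environment
# attribute so repeated mapping against the same genome object extracts the
# substrings once per read length
.genome_kmers <- function(genome, k) {
  key <- sprintf(".kmer_%d_%d", k, genome$length)
  cache <- attr(genome, "kmer_cache")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  L <- genome$length
  kmers <- if (k > L) character(0) else {
    starts <- 1:(L - k + 1L)
    substring(genome$sequence, starts, starts + k - 1L)
  }
  if (!is.null(cache)) cache[[key]] <- kmers
  kmers
}

#' Place reads on a genome by exact unique occurrence
#'
#' The built-in mapper places a read if and only if its sequence occurs
#' exactly once in the genome across both strands; reads with multiple hits
#' are dropped as ambiguous, reads with none as unmapped, mirroring the
#' "unambiguously mapped reads" rule. Alternatively an external SAM/BAM
#' file is ingested, keeping records that are mapped, not
#' secondary/supplementary, with MAPQ >= `min_mapq`.
#'
#' @param reads data.frame with `read_id`, `sequence`; ignored when `sam`
#'   is given except to restrict to the listed read ids (pass `NULL` to
#'   keep every SAM record).
#' @param genome an `lpnpi_genome`.
#' @param sam optional path to a SAM or BAM file.
#' @param min_mapq MAPQ threshold operationalizing unique placement for the
#'   SAM path.
#' @return list with `placements` (data.frame `read_id`, `pos` 0-based,
#'   `strand`, `length`), `n_ambiguous`, `n_unmapped`.
#' @export
place_reads <- function(reads, genome, sam = NULL, min_mapq = 20L) {
  stopifnot(inherits(genome, "lpnpi_genome"))
  if (!is.null(sam)) {
    return(.place_from_sam(sam, reads, min_mapq))
  }
  seqs <- reads$sequence
  lens <- nchar(seqs)
  pos <- rep(NA_integer_, length(seqs))
  strand <- rep(NA_character_, length(seqs))
  n_amb <- 0L
  n_unm <- 0L
  for (k in sort(unique(lens))) {
    kmers <- .genome_kmers(genome, k)
    sel <- which(lens == k)
    sq <- seqs[sel]
    rc <- rev_comp(sq)
    uq <- unique(c(sq, rc))
    # hash the small query set, scan the genome k-mers once
    m <- match(kmers, uq)
    hit <- which(!is.na(m))
    cnt <- tabulate(m[hit], nbins = length(uq))
    first <- rep(NA_integer_, length(uq))
    first[rev(m[hit])] <- rev(hit)            # earliest occurrence survives
    fi <- match(sq, uq)
    ri <- match(rc, uq)
    nf <- cnt[fi]
    nr <- cnt[ri]
    tot <- nf + nr
    n_unm <- n_unm + sum(tot == 0L)
    n_amb <- n_amb + sum(tot > 1L)
    uf <- tot == 1L & nf == 1L
    ur <- tot == 1L & nr == 1L
    pos[sel[uf]] <- first[fi[uf]] - 1L        # 0-based
    strand[sel[uf]] <- "+"
    pos[sel[ur]] <- first[ri[ur]] - 1L
    strand[sel[ur]] <- "-"
  }
  keep <- !is.na(pos)
  list(
    placements = data.frame(read_id = reads$read_id[keep], pos = pos[keep],
                            strand = strand[keep], length = lens[keep],
                            stringsAsFactors = FALSE),
    n_ambiguous = n_amb, n_unmapped = n_unm
  )
}

.place_from_sam <- function(sam, reads = NULL, min_mapq = 20L) {
  path <- sam
  if (grepl("\\.sam$", sam, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "mapq", "qwidth"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  )
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  ok <- !is.na(b$mapq) & b$mapq >= min_mapq
  if (!is.null(reads)) ok <- ok & b$qname %in% reads$read_id
  n_total <- if (is.null(reads)) length(b$qname) else nrow(reads)
  placements <- data.frame(
    read_id = b$qname[ok],
    pos = b$pos[ok] - 1L,                      # SAM is 1-based
    strand = ifelse(bitwAnd(b$flag[ok], 16L) > 0L, "-", "+"),
    length = b$qwidth[ok],
    stringsAsFactors = FALSE
  )
  list(placements = placements,
       n_ambiguous = sum(!is.na(b$mapq) & b$mapq < min_mapq),
       n_unmapped = n_total - length(b$qname))
}

#' Assign placed reads to individual LpnPI sites
#'
#' Each placed read increments exactly one site: among the genome's indexed
#' sites lying at a window-compliant offset from either read end, the one
#' closest to the read's 5' end (strand-aware) is chosen. Placed reads with
#' no site at a compliant offset are counted as mismatches and not tallied.
#'
#' @param placements output of [place_reads()] (the `placements` element or
#'   the full list).
#' @param genome an `lpnpi_genome`.
#' @param sample_id sample label stored in the result.
#' @param total_filtered_reads number of reads that passed the LpnPI filter
#'   for this sample (recorded for normalization downstream).
#' @param window inclusive site-offset window, default `c(13, 17)`.
#' @return object of class `site_count_table`: list with `sample_id`,
#'   `site_pos` (all genome site positions), `counts` (parallel integer),
#'   `total_filtered_reads`, `n_mismatch`.
#' @export
count_sites <- function(placements, genome, sample_id = "sample",
                        total_filtered_reads = NULL, window = c(13L, 17L)) {
  if (is.list(placements) && !is.data.frame(placements) &&
      !is.null(placements$placements)) {
    placements <- placements$placements
  }
  site_pos <- genome$sites$pos
  counts <- integer(length(site_pos))
  n_mis <- 0L
  if (is.null(total_filtered_reads)) total_filtered_reads <- nrow(placements)
  p <- placements$pos
  l <- placements$length
  # index ranges of sites inside the 5'- and 3'-end offset windows
  a5 <- findInterval(p + window[1] - 0.5, site_pos)
  b5 <- findInterval(p + window[2] + 0.5, site_pos)
  a3 <- findInterval(p + l - 1L - window[2] - 0.5, site_pos)
  b3 <- findInterval(p + l - 1L - window[1] + 0.5, site_pos)
  minus <- placements$strand == "-"
  for (j in seq_len(nrow(placements))) {
    k <- unique(c(seq_len(b5[j] - a5[j]) + a5[j],
                  seq_len(b3[j] - a3[j]) + a3[j]))
    if (length(k) == 0L) { n_mis <- n_mis + 1L; next }
    d5 <- if (minus[j]) p[j] + l[j] - 1L - site_pos[k] else site_pos[k] - p[j]
    chosen <- k[order(d5, site_pos[k])][1L]
    counts[chosen] <- counts[chosen] + 1L
  }
  structure(
    list(sample_id = sample_id, site_pos = site_pos, counts = counts,
         total_filtered_reads = as.integer(total_filtered_reads),
         n_mismatch = n_mis),
    class = "site_count_table"
  )
}

#' @export
print.site_count_table <- function(x, ...) {
  cat(sprintf("<site_count_table> %s: %d sites, %d counted reads (of %d filtered), %d mismatches\n",
              x$sample_id, length(x$site_pos), sum(x$counts),
              x$total_filtered_reads, x$n_mismatch))
  invisible(x)
}

#' Process one sample's reads to per-site counts
#'
#' Convenience wrapper running adapter trimming, the LpnPI filter, unique
#' placement and per-site counting in the fixed order of the assay.
#'
#' @param reads a `medseq_reads` object or data.frame (`read_id`, `sequence`).
#' @param genome an `lpnpi_genome`.
#' @param sample_id sample label.
#' @param adapter adapter to trim.
#' @param window LpnPI filter window.
#' @return list with `counts` (a `site_count_table`), `filter` (per-read
#'   results), `placement_stats` (`n_ambiguous`, `n_unmapped`),
#'   `pass_fraction`.
#' @export
process_sample <- function(reads, genome, sample_id = "sample",
                           adapter = medseq_adapter(), window = c(13L, 17L)) {
  if (inherits(reads, "medseq_reads")) reads <- reads$reads
  trimmed <- trim_adapter(reads$sequence, adapter)
  keep <- !trimmed$discarded
  rd <- data.frame(read_id = reads$read_id[keep],
                   sequence = trimmed$sequence[keep],
                   stringsAsFactors = FALSE)
  filt <- lpnpi_filter(rd, window)
  passed <- rd[filt$passed, , drop = FALSE]
  pl <- place_reads(passed, genome)
  ct <- count_sites(pl$placements, genome, sample_id = sample_id,
                    total_filtered_reads = nrow(passed), window = window)
  list(counts = ct, filter = filt,
       placement_stats = list(n_ambiguous = pl$n_ambiguous,
                              n_unmapped = pl$n_unmapped),
       pass_fraction = mean(filt$passed))
}
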