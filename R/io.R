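# File-format interfaces: FASTA/FASTQ via Biostrings, BED via rtracklayer-free
# GRanges conversion helpers, SAM via Rsamtools (plus a minimal writer for
# simulator ground truth), tab-delimited tables via base R.

#' Write a synthetic genome as FASTA
#' @param genome an `lpnpi_genome`.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  seq <- Biostrings::DNAStringSet(genome$sequence)
  names(seq) <- genome$name
  Biostrings::writeXStringSet(seq, path)
  invisible(path)
}

#' Read a single-chromosome FASTA back into an `lpnpi_genome`
#' @param path FASTA file.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stopifnot(length(seqs) == 1L)
  sequence <- as.character(seqs[[1]])
  structure(
    list(name = sub("\\s.*$", "", names(seqs)[1]), sequence = sequence,
         length = nchar(sequence), sites = scan_lpnpi_sites(sequence),
         tss = data.frame(id = character(), chrom = character(),
                          pos = integer(), strand = character())),
    class = "lpnpi_genome",
    kmer_cache = new.env(parent = emptyenv())
  )
}

#' Write simulated reads as FASTQ (fixed Phred-33 quality)
#' @param x a `medseq_reads` object or data.frame with `read_id`, `sequence`.
#' @param path output file (uncompressed).
#' @export
write_fastq <- function(x, path) {
  reads <- if (inherits(x, "medseq_reads")) x$reads else x
  seq <- Biostrings::DNAStringSet(reads$sequence)
  names(seq) <- reads$read_id
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(seq, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read FASTQ into a read table
#' @param path FASTQ file (gz-aware).
#' @return data.frame with `read_id`, `sequence`.
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub("\\s.*$", "", names(seqs)),
             sequence = as.character(seqs), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Write regions as BED (0-based half-open)
#'
#' @param regions data.frame with `chrom`, `start`, `end` and optionally a
#'   name column (`region_id` or `name`) and `strand`.
#' @param path output file.
#' @export
write_bed <- function(regions, path) {
  nm <- if (!is.null(regions$region_id)) regions$region_id
        else if (!is.null(regions$name)) regions$name
        else sprintf("region%04d", seq_len(nrow(regions)))
  out <- data.frame(regions$chrom, regions$start, regions$end, nm,
                    0L,
                    if (!is.null(regions$strand)) regions$strand else ".")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file (BED3/4/6) into a data.frame
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `name`, and `strand` when present.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(x)[1:3] <- c("chrom", "start", "end")
  if (ncol(x) >= 4L) names(x)[4] <- "name"
  if (ncol(x) >= 6L) names(x)[6] <- "strand"
  x
}

#' Write a clinical table as tab-delimited text
#' @param clinical data.frame.
#' @param path output file.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a tab-delimited clinical table
#' @param path file written by [write_clinical()] or compatible.
#' @export
read_clinical <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write read placements as a minimal SAM file
#'
#' Ground-truth alignments from the simulator (or the built-in exact mapper)
#' serialized as unpaired SAM records with MAPQ 60, suitable for the SAM
#' ingestion path of [place_reads()].
#'
#' @param placements data.frame with `read_id`, `pos` (0-based), `strand`,
#'   `sequence`.
#' @param genome the `lpnpi_genome` the placements refer to.
#' @param path output `.sam` file.
#' @export
write_sam <- function(placements, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", genome$name, genome$length)), con)
  if (nrow(placements) > 0L) {
    flag <- ifelse(placements$strand == "-", 16L, 0L)
    seq <- placements$sequence
    seq[placements$strand == "-"] <- rev_comp(seq[placements$strand == "-"])
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                       placements$read_id, flag, genome$name,
                       placements$pos + 1L, nchar(seq), seq,
                       strrep("I", nchar(seq))), con)
  }
  invisible(path)
}

#' Write a per-site count table as TSV
#' @param table a `site_count_table`.
#' @param path output file; columns `site_pos`, `count` plus a header
#'   comment carrying the sample id and totals.
#' @export
write_site_counts <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_id=%s total_filtered_reads=%d n_mismatch=%d",
                     table$sample_id, table$total_filtered_reads,
                     table$n_mismatch), con)
  utils::write.table(
    data.frame(site_pos = table$site_pos, count = table$counts),
    con, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a per-site count table written by [write_site_counts()]
#' @param path TSV file.
#' @export
read_site_counts <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  kv <- strsplit(meta, "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  x <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  structure(
    list(sample_id = unname(vals["sample_id"]),
         site_pos = as.integer(x$site_pos),
         counts = as.integer(x$count),
         total_filtered_reads = as.integer(vals["total_filtered_reads"]),
         n_mismatch = as.integer(vals["n_mismatch"])),
    class = "site_count_table"
  )
}
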