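# Read-level MeD-seq processing: adapter trimming and the LpnPI
# restriction-site filter.

#' Trim a fixed adapter from reads
#'
#' Removes the longest read suffix (or prefix, for `end = "5prime"`) that
#' exactly matches a prefix of the adapter, requiring at least
#' `min_overlap` matching bases; the match is repeated to a fixed point so
#' trimming is idempotent. Reads trimmed to length 0 are flagged discarded.
#'
#' @param sequences character vector of read sequences.
#' @param adapter adapter sequence (non-empty).
#' @param end which read end carries the adapter.
#' @param min_overlap minimum adapter prefix length considered a match.
#' @return data.frame with `sequence` (trimmed), `trimmed_bp`, `discarded`.
#' @export
trim_adapter <- function(sequences, adapter = medseq_adapter(),
                         end = c("3prime", "5prime"), min_overlap = 3L) {
  stopifnot(is.character(adapter), nchar(adapter) >= 1L)
  end <- match.arg(end)
  seqs <- sequences
  alen <- nchar(adapter)
  repeat {
    len <- nchar(seqs)
    cut <- integer(length(seqs))
    ks <- seq(min(alen, max(len)), min_overlap)
    for (k in ks) {
      idx <- which(cut == 0L & len >= k)
      if (length(idx) == 0L) next
      piece <- if (end == "3prime") {
        substr(seqs[idx], len[idx] - k + 1L, len[idx])
      } else {
        substr(seqs[idx], 1L, k)
      }
      hit <- piece == substr(adapter, 1L, k)
      cut[idx[hit]] <- k
    }
    if (all(cut == 0L)) break
    idx <- which(cut > 0L)
    seqs[idx] <- if (end == "3prime") {
      substr(seqs[idx], 1L, len[idx] - cut[idx])
    } else {
      substr(seqs[idx], cut[idx] + 1L, len[idx])
    }
  }
  data.frame(sequence = seqs, trimmed_bp = nchar(sequences) - nchar(seqs),
             discarded = nchar(seqs) == 0L, stringsAsFactors = FALSE)
}

# All recognized-base positions (0-based) of LpnPI contexts in each sequence,
# both strands, as a list of sorted integer vectors. Each pattern carries the
# recognized-base offsets for its plus- and minus-strand reading (a CpG has
# recognized cytosines on both strands).
.context_positions <- function(sequences) {
  subj <- Biostrings::DNAStringSet(sequences)
  variants <- list(list("GCGC", c(1L, 2L)),
                   list("CCG", c(1L, 2L)),
                   list("CGG", c(0L, 1L)))
  n <- length(sequences)
  acc <- vector("list", n)
  for (v in variants) {
    st <- Biostrings::startIndex(Biostrings::vmatchPattern(v[[1]], subj))
    for (j in seq_len(n)) {
      sj <- st[[j]]
      if (is.null(sj) || length(sj) == 0L) next
      acc[[j]] <- c(acc[[j]], sj - 1L + v[[2]][1L], sj - 1L + v[[2]][2L])
    }
  }
  lapply(acc, function(v) if (is.null(v)) integer(0) else sort(unique(v)))
}

#' LpnPI restriction-site read filter
#'
#' A read passes when an LpnPI recognition context (GCGC, CCG or CGG, either
#' strand) places its recognized cytosine between `window[1]` and
#' `window[2]` bp (inclusive, 0-based gap) from the 5' or the 3' read end.
#' Only reads produced by LpnPI digestion show this geometry, so the filter
#' separates on-target from off-target reads. When several positions
#' comply, the one closest to the 5' end is reported.
#'
#' @param reads data.frame with `read_id`, `sequence` (or a `medseq_reads`).
#' @param window inclusive offset window in bp, default `c(13, 17)`.
#' @return data.frame with `read_id`, `passed`, `site_offset` (distance to
#'   the nearest read end; NA when failed), `end` (`"5prime"`/`"3prime"`),
#'   and `site_read_pos` (0-based position of the recognized base in the
#'   read).
#' @export
lpnpi_filter <- function(reads, window = c(13L, 17L)) {
  if (inherits(reads, "medseq_reads")) reads <- reads$reads
  stopifnot(all(c("read_id", "sequence") %in% names(reads)),
            length(window) == 2L, window[1] <= window[2])
  seqs <- reads$sequence
  len <- nchar(seqs)
  pos <- .context_positions(seqs)

  n <- length(seqs)
  passed <- logical(n)
  offset <- rep(NA_integer_, n)
  endv <- rep(NA_character_, n)
  rpos <- rep(NA_integer_, n)
  for (j in seq_len(n)) {
    p <- pos[[j]]
    if (length(p) == 0L) next
    d5 <- p
    d3 <- len[j] - 1L - p
    ok <- (d5 >= window[1] & d5 <= window[2]) |
          (d3 >= window[1] & d3 <= window[2])
    if (!any(ok)) next
    k <- which(ok)[1L]                      # closest to the 5' end
    passed[j] <- TRUE
    rpos[j] <- p[k]
    if (d5[k] <= d3[k]) {
      offset[j] <- d5[k]; endv[j] <- "5prime"
    } else {
      offset[j] <- d3[k]; endv[j] <- "3prime"
    }
    # report the window-compliant distance (nearest end may be off-window
    # when only the far end complies)
    if (!(offset[j] >= window[1] && offset[j] <= window[2])) {
      if (d5[k] >= window[1] && d5[k] <= window[2]) {
        offset[j] <- d5[k]; endv[j] <- "5prime"
      } else {
        offset[j] <- d3[k]; endv[j] <- "3prime"
      }
    }
  }
  data.frame(read_id = reads$read_id, passed = passed, site_offset = offset,
             end = endv, site_read_pos = rpos, stringsAsFactors = FALSE)
}
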