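#' Simulate MeD-seq reads from a genome and a mixed methylome
#'
#' Each simulated cfDNA molecule is a copy of the synthetic chromosome whose
#' CpGs are methylated independently with probability
#' `(1 - tumor_fraction) * baseline + tumor_fraction * tumor` (paired
#' plus/minus sites of a CpG share one draw, as CpG methylation is
#' symmetric). Molecules are digested with [digest()] and every emitted
#' 32 bp fragment becomes a 50 bp single-end read: the plus-strand fragment
#' sequence followed by a fixed 18 bp adapter, so the recognized cytosine
#' lies 16 bp from the fragment-side read end (inside the 13-17 bp
#' restriction-site filter window). Optionally a fraction of off-target
#' reads is drawn uniformly from site-free genome sequence to exercise the
#' filter.
#'
#' The number of molecules is calibrated so that the expected on-target read
#' count of a fully healthy sample (`tumor_fraction = 0`) equals `depth`;
#' hypermethylated tumor content then yields proportionally more reads, as
#' in the real assay where read yield tracks methylation.
#'
#' @param genome an `lpnpi_genome`.
#' @param methylome a `methylome` for the same genome.
#' @param tumor_fraction per-sample tumor fraction in [0, 1].
#' @param depth expected on-target (filter-passing) reads for a healthy
#'   sample; must be positive.
#' @param seed integer seed; output is deterministic given the seed.
#' @param off_target_fraction fraction of total reads drawn from site-free
#'   sequence (no adapter, never LpnPI-derived).
#' @param read_length read length in bp (default 50).
#' @param adapter adapter sequence appended after the fragment.
#' @return object of class `medseq_reads`: list with `reads` (data.frame
#'   `read_id`, `sequence`), `truth` (data.frame `read_id`, `on_target`,
#'   `origin` 0-based fragment start, `site_pos`), and `counters`
#'   (`n_molecules`, `n_blocked`, `n_edge_dropped`, `n_on_target`,
#'   `n_off_target`).
#' @export
simulate_reads <- function(genome, methylome, tumor_fraction, depth,
                           seed = 1L, off_target_fraction = 0,
                           read_length = 50L, adapter = medseq_adapter()) {
  stopifnot(inherits(genome, "lpnpi_genome"), inherits(methylome, "methylome"))
  if (!is.numeric(depth) || length(depth) != 1L || depth <= 0) {
    stop("`depth` must be a positive count")
  }
  stopifnot(tumor_fraction >= 0, tumor_fraction <= 1,
            off_target_fraction >= 0, off_target_fraction < 1)
  f <- tumor_fraction
  p_eff <- (1 - f) * methylome$baseline + f * methylome$tumor

  grp <- site_cpg_groups(genome)
  rep_idx <- match(seq_len(max(grp)), grp)     # one representative per CpG
  p_eff_g <- p_eff[rep_idx]
  p_base_g <- methylome$baseline[rep_idx]
  site_pos <- genome$sites$pos
  n_grp <- length(rep_idx)
  n_mol <- max(1L, as.integer(round(depth / sum(p_base_g))))

  with_seed(seed, {
    frag_starts <- vector("list", n_mol)
    frag_sites <- vector("list", n_mol)
    n_blocked <- 0L
    n_edge <- 0L
    for (i in seq_len(n_mol)) {
      meth_g <- stats::runif(n_grp) < p_eff_g
      dig <- digest(site_pos, meth_g[grp], genome$length)
      frag_starts[[i]] <- dig$fragments$start
      frag_sites[[i]] <- dig$fragments$site_pos
      n_blocked <- n_blocked + dig$n_blocked
      n_edge <- n_edge + dig$n_edge_dropped
    }
    starts <- unlist(frag_starts)
    sites <- unlist(frag_sites)
    n_on <- length(starts)

    pad <- substr(adapter, 1L, read_length - 32L)
    on_seq <- paste0(substring(genome$sequence, starts + 1L, starts + 32L), pad)
    on_ids <- sprintf("on_%06d", seq_len(n_on))

    n_off <- if (off_target_fraction > 0) {
      as.integer(round(n_on * off_target_fraction / (1 - off_target_fraction)))
    } else 0L
    off_seq <- character(0)
    off_ids <- character(0)
    off_starts <- integer(0)
    if (n_off > 0L) {
      cand <- 0:(genome$length - read_length)
      hi <- findInterval(cand + read_length - 1L, site_pos)
      lo <- findInterval(cand - 1L, site_pos)
      allowed <- cand[hi == lo]             # read window contains no site
      off_starts <- sample(allowed, n_off, replace = TRUE)
      off_seq <- substring(genome$sequence, off_starts + 1L,
                           off_starts + read_length)
      flip <- stats::runif(n_off) < 0.5
      if (any(flip)) off_seq[flip] <- rev_comp(off_seq[flip])
      off_ids <- sprintf("off_%06d", seq_len(n_off))
    }

    structure(
      list(
        reads = data.frame(read_id = c(on_ids, off_ids),
                           sequence = c(on_seq, off_seq),
                           stringsAsFactors = FALSE),
        truth = data.frame(
          read_id = c(on_ids, off_ids),
          on_target = rep(c(TRUE, FALSE), c(n_on, n_off)),
          origin = c(starts, off_starts),
          site_pos = c(sites, rep(NA_integer_, n_off)),
          stringsAsFactors = FALSE
        ),
        counters = list(n_molecules = n_mol, n_blocked = n_blocked,
                        n_edge_dropped = n_edge, n_on_target = n_on,
                        n_off_target = n_off)
      ),
      class = "medseq_reads"
    )
  })
}

#' @export
print.medseq_reads <- function(x, ...) {
  cat(sprintf("<medseq_reads> %d reads (%d on-target, %d off-target), %d molecules\n",
              nrow(x$reads), x$counters$n_on_target, x$counters$n_off_target,
              x$counters$n_molecules))
  invisible(x)
}
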