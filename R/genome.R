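# Synthetic genome with indexed LpnPI recognition sites and TSS annotation.
#
# LpnPI binds (hydroxy)methylated cytosines in the contexts GmCGC, CmCG and
# mCGG. All three contexts contain a CpG dinucleotide, and each CpG carries
# the recognized cytosine on both strands (plus-strand CmCG pairs with
# minus-strand mCGG at the complementary G, and GmCGC is its own reverse
# complement), so recognition sites always occur in plus/minus pairs one
# base apart.

# plus-strand text patterns and the 0-based offset of the recognized base
# within the match, for both strands
.lpnpi_patterns <- function() {
  data.frame(
    pattern = c("GCGC", "CCG", "CGG", "GCGC", "CGG", "CCG"),
    offset  = c(1L,     1L,    0L,    2L,     1L,    2L),
    strand  = c("+",    "+",   "+",   "-",    "-",   "-"),
    context = c("GCGC", "CCG", "CGG", "GCGC", "CCG", "CGG"),
    stringsAsFactors = FALSE
  )
}

#' Scan a sequence for LpnPI recognition sites
#'
#' Finds every occurrence of the LpnPI recognition contexts GCGC, CCG and
#' CGG on both strands and reports the 0-based position of the recognized
#' cytosine (for minus-strand sites, the position of the complementary base
#' on the plus strand). Overlapping occurrences are found; when several
#' contexts designate the same position, one site is reported with context
#' priority GCGC, CCG, CGG.
#'
#' @param sequence character scalar of A/C/G/T (N allowed; never matches).
#' @return data.frame with columns `pos` (0-based, strictly increasing),
#'   `strand`, `context`.
#' @export
scan_lpnpi_sites <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0L)
  pats <- .lpnpi_patterns()
  hits <- vector("list", nrow(pats))
  for (i in seq_len(nrow(pats))) {
    m <- gregexpr(paste0("(?=", pats$pattern[i], ")"), sequence, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    hits[[i]] <- data.frame(
      pos = as.integer(m) - 1L + pats$offset[i],
      strand = pats$strand[i], context = pats$context[i],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, hits)
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(pos = integer(), strand = character(),
                      context = character(), stringsAsFactors = FALSE))
  }
  # context priority for duplicate positions (e.g. CCGG designates the same
  # cytosine as CCG and CGG)
  pri <- match(out$context, c("GCGC", "CCG", "CGG"))
  out <- out[order(out$pos, pri), , drop = FALSE]
  out <- out[!duplicated(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# CpG-free random background: no CG dinucleotide means no LpnPI context,
# so every recognition site in the synthetic genome is planted on purpose.
.random_cpg_free <- function(n) {
  x <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
              prob = c(0.3, 0.2, 0.2, 0.3))
  repeat {
    bad <- which(x[-n] == "C" & x[-1L] == "G")
    if (length(bad) == 0L) break
    x[bad + 1L] <- sample(c("A", "C", "T"), length(bad), replace = TRUE)
  }
  x
}

#' Simulate a synthetic genome for LpnPI digestion experiments
#'
#' Builds a single synthetic chromosome (`chrS`) whose background sequence is
#' CpG-free, so LpnPI recognition contexts occur only where they are planted:
#' a fixed number of recognition sites spread symmetrically around each
#' transcription start site. TSSs are placed at the centre of consecutive
#' `spacing`-bp blocks, so 2 kb TSS windows never overlap.
#'
#' @param n_tss number of transcription start sites (>= 1).
#' @param spacing distance in bp between consecutive TSSs (>= 4000 so that
#'   2 kb windows cannot be forced to overlap).
#' @param seed integer seed; the genome is deterministic given the seed.
#' @param sites_per_tss recognition sites planted per TSS window.
#' @param tss_site_span bp span around each TSS over which sites are spread.
#' @return an object of class `lpnpi_genome`: list with `name`, `sequence`,
#'   `length`, `sites` (as from [scan_lpnpi_sites()]) and `tss`
#'   (data.frame `id`, `chrom`, `pos` 0-based, `strand`).
#' @export
simulate_genome <- function(n_tss, spacing = 5000L, seed = 1L,
                            sites_per_tss = 12L, tss_site_span = 1600L) {
  if (!is.numeric(n_tss) || length(n_tss) != 1L || n_tss < 1) {
    stop("`n_tss` must be a positive count")
  }
  stopifnot(spacing >= 4000, sites_per_tss >= 1, tss_site_span < spacing)
  n_tss <- as.integer(n_tss)
  spacing <- as.integer(spacing)
  L <- n_tss * spacing

  with_seed(seed, {
    chars <- .random_cpg_free(L)
    tss_pos <- as.integer(round((seq_len(n_tss) - 0.5) * spacing))
    tss_strand <- rep(c("+", "-"), length.out = n_tss)

    motifs <- c("GCGC", "CCG", "CGG")
    motif_off <- c(GCGC = 1L, CCG = 1L, CGG = 0L)
    offs <- as.integer(round(seq(-tss_site_span / 2, tss_site_span / 2,
                                 length.out = sites_per_tss)))
    for (t in tss_pos) {
      mots <- sample(motifs, sites_per_tss, replace = TRUE)
      for (j in seq_len(sites_per_tss)) {
        p <- t + offs[j]                       # intended recognized cytosine
        pad <- c("T", strsplit(mots[j], "")[[1]], "T")
        start <- p - motif_off[[mots[j]]] - 1L # 0-based start of padded motif
        chars[(start + 1L):(start + length(pad))] <- pad
      }
    }
    sequence <- paste(chars, collapse = "")
    sites <- scan_lpnpi_sites(sequence)
    structure(
      list(
        name = "chrS",
        sequence = sequence,
        length = L,
        sites = sites,
        tss = data.frame(
          id = sprintf("tss%03d", seq_len(n_tss)), chrom = "chrS",
          pos = tss_pos, strand = tss_strand, stringsAsFactors = FALSE
        )
      ),
      class = "lpnpi_genome",
      kmer_cache = new.env(parent = emptyenv())
    )
  })
}

#' @export
print.lpnpi_genome <- function(x, ...) {
  cat(sprintf("<lpnpi_genome> %s: %d bp, %d LpnPI sites, %d TSS\n",
              x$name, x$length, nrow(x$sites), nrow(x$tss)))
  invisible(x)
}

# Pair each site with its CpG partner on the other strand; returns an
# integer group index per site row (paired sites share a group).
site_cpg_groups <- function(genome) {
  sites <- genome$sites
  grp <- seq_len(nrow(sites))
  minus <- which(sites$strand == "-")
  partner <- match(sites$pos[minus] - 1L, sites$pos)
  ok <- !is.na(partner) & sites$strand[partner] == "+"
  grp[minus[ok]] <- grp[partner[ok]]
  match(grp, unique(grp))
}

#' Construct baseline and tumor methylomes for a synthetic genome
#'
#' Assigns a per-site methylation probability for a healthy-leukocyte
#' baseline and for a tumor component. The two differ only at designated
#' marker TSS windows (plus optional Gaussian noise): hypermethylated
#' markers gain `effect`, hypomethylated markers lose it, clipped to [0,1].
#' Paired plus/minus sites of one CpG always share the same probability.
#'
#' @param genome an `lpnpi_genome`.
#' @param marker_tss character vector of TSS ids carrying a tumor effect.
#' @param baseline_prob baseline methylation probability at every site.
#' @param effect absolute probability shift at marker sites in the tumor.
#' @param direction `"hyper"` or `"hypo"`, recycled along `marker_tss`.
#' @param noise_sd SD of Gaussian noise added to tumor probabilities at
#'   non-marker sites (0 disables).
#' @param window_halfwidth half-width of the marker window around each TSS.
#' @param seed seed used only when `noise_sd > 0`.
#' @return object of class `methylome`: list with `baseline`, `tumor`
#'   (numeric per site) and `region_effects` (data.frame `tss_id`,
#'   `direction`, `effect`).
#' @export
make_methylome <- function(genome, marker_tss = character(),
                           baseline_prob = 0.1, effect = 0.8,
                           direction = "hyper", noise_sd = 0,
                           window_halfwidth = 1000L, seed = 1L) {
  stopifnot(inherits(genome, "lpnpi_genome"),
            baseline_prob >= 0, baseline_prob <= 1, effect >= 0)
  stopifnot(all(marker_tss %in% genome$tss$id))
  direction <- rep_len(direction, length(marker_tss))
  stopifnot(all(direction %in% c("hyper", "hypo")))

  base <- rep(baseline_prob, nrow(genome$sites))
  tum <- base
  for (i in seq_along(marker_tss)) {
    t <- genome$tss$pos[genome$tss$id == marker_tss[i]]
    in_win <- genome$sites$pos >= t - window_halfwidth &
      genome$sites$pos < t + window_halfwidth
    tum[in_win] <- if (direction[i] == "hyper") {
      pmin(1, base[in_win] + effect)
    } else {
      pmax(0, base[in_win] - effect)
    }
  }
  if (noise_sd > 0) {
    grp <- site_cpg_groups(genome)
    noise <- with_seed(seed, stats::rnorm(max(grp), 0, noise_sd))[grp]
    tum <- pmin(1, pmax(0, tum + noise))
  }
  # enforce equal probabilities within a CpG pair
  grp <- site_cpg_groups(genome)
  base <- stats::ave(base, grp)
  tum <- stats::ave(tum, grp)
  structure(
    list(
      baseline = base, tumor = tum,
      region_effects = data.frame(tss_id = marker_tss, direction = direction,
                                  effect = effect, stringsAsFactors = FALSE)
    ),
    class = "methylome"
  )
}
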