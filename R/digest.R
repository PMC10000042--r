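#' In silico LpnPI digestion of one DNA molecule
#'
#' LpnPI cuts 16 bp upstream of a (hydroxy)methylated recognized cytosine,
#' producing a 32 bp fragment that spans 16 bp on either side of the
#' cytosine. The enzyme is blocked by fragments shorter than 32 bp, which is
#' modelled as a left-to-right greedy scan: a cut is accepted only when the
#' recognized cytosine lies at least 32 bp from the previously accepted one.
#' Unmethylated sites never cut. Sites within 16 bp of a molecule end cannot
#' yield a full fragment; they are dropped and counted, not emitted.
#'
#' @param site_positions 0-based positions of recognized cytosines within the
#'   molecule, strictly increasing.
#' @param methylated logical vector parallel to `site_positions`.
#' @param molecule_length molecule length in bp.
#' @return list with `fragments` (data.frame `start`, `end` 0-based
#'   half-open, `site_pos`), and counters `n_blocked`, `n_edge_dropped`,
#'   `n_unmethylated`.
#' @export
digest <- function(site_positions, methylated, molecule_length) {
  stopifnot(length(site_positions) == length(methylated),
            molecule_length > 0)
  if (is.unsorted(site_positions, strictly = TRUE)) {
    stop("`site_positions` must be strictly increasing")
  }
  half <- 16L
  meth_pos <- site_positions[as.logical(methylated)]
  starts <- integer(0)
  sites <- integer(0)
  n_blocked <- 0L
  n_edge <- 0L
  prev <- -Inf
  for (p in meth_pos) {
    if (p - prev < 32L) {
      n_blocked <- n_blocked + 1L
    } else if (p < half || p + half > molecule_length) {
      n_edge <- n_edge + 1L
    } else {
      starts <- c(starts, p - half)
      sites <- c(sites, p)
      prev <- p
    }
  }
  list(
    fragments = data.frame(start = starts, end = starts + 32L,
                           site_pos = sites),
    n_blocked = n_blocked,
    n_edge_dropped = n_edge,
    n_unmethylated = length(site_positions) - length(meth_pos)
  )
}
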