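# internal helpers shared across modules

# Evaluate `code` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so no global state leaks.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive `n` independent sub-seeds from a master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

rev_comp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Default synthetic sequencing adapter
#'
#' 18 bp fixed adapter appended to each 32 bp digestion fragment so that
#' simulated reads are 50 bp, mirroring single-end short-read geometry.
#' @export
medseq_adapter <- function() "AGATCGGAAGAGCACACG"
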