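# Independent oracles and shared fixtures for the suite. Oracles use
# different routes than the package (Biostrings pattern matching, brute
# force, enumeration) so they check, not mirror, the implementation.

# -- shared small fixtures (built once per test run) -------------------------

fix <- local({
  cache <- new.env(parent = emptyenv())
  function(name, build) {
    if (is.null(cache[[name]])) cache[[name]] <- build()
    cache[[name]]
  }
})

fix_genome <- function() {
  fix("genome", function() simulate_genome(10, 5000, seed = 42))
}

fix_methylome <- function() {
  fix("methylome", function() {
    make_methylome(fix_genome(), marker_tss = c("tss003", "tss007"),
                   baseline_prob = 0.1, effect = 0.8)
  })
}

# -- sequence oracles (Biostrings route) -------------------------------------

# all recognized-base positions (0-based) via Biostrings::matchPattern
oracle_site_positions <- function(sequence) {
  subj <- Biostrings::DNAString(sequence)
  pats <- list(c("GCGC", 1L), c("CCG", 1L), c("CGG", 0L),
               c("GCGC", 2L), c("CGG", 1L), c("CCG", 2L))
  pos <- integer(0)
  for (p in pats) {
    m <- Biostrings::matchPattern(p[[1]], subj)
    if (length(m) > 0L) {
      pos <- c(pos, BiocGenerics::start(m) - 1L + as.integer(p[[2]]))
    }
  }
  sort(unique(pos))
}

# regex-scan oracle for recognized-base positions (overlap-aware lookahead)
oracle_regex_positions <- function(s) {
  pos <- integer(0)
  for (p in list(c("GCGC", 1L), c("GCGC", 2L), c("CCG", 1L), c("CCG", 2L),
                 c("CGG", 0L), c("CGG", 1L))) {
    m <- gregexpr(paste0("(?=", p[[1]], ")"), s, perl = TRUE)[[1]]
    if (m[1] != -1L) pos <- c(pos, as.integer(m) - 1L + as.integer(p[[2]]))
  }
  sort(unique(pos))
}

# filter oracle: does any recognized base sit 13-17 bp (0-based gap) from
# either read end? (regex route, independent of the package's matcher;
# gregexpr is vectorized over reads)
oracle_filter_pass <- function(sequences, window = c(13L, 17L)) {
  len <- nchar(sequences)
  pass <- logical(length(sequences))
  for (p in list(c("GCGC", 1L), c("GCGC", 2L), c("CCG", 1L), c("CCG", 2L),
                 c("CGG", 0L), c("CGG", 1L))) {
    ms <- gregexpr(paste0("(?=", p[[1]], ")"), sequences, perl = TRUE)
    off <- as.integer(p[[2]])
    for (j in seq_along(sequences)) {
      if (pass[j] || ms[[j]][1] == -1L) next
      d5 <- as.integer(ms[[j]]) - 1L + off
      d3 <- len[j] - 1L - d5
      pass[j] <- any((d5 >= window[1] & d5 <= window[2]) |
                     (d3 >= window[1] & d3 <= window[2]))
    }
  }
  pass
}

random_reads <- function(n, len = 50L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}

# -- statistics oracles ------------------------------------------------------

# ordinary pooled two-sample t-test, coded directly from the formula
oracle_pooled_t <- function(x1, x2) {
  n1 <- nrow(x1); n2 <- nrow(x2)
  s2 <- (colSums(sweep(x1, 2, colMeans(x1))^2) +
         colSums(sweep(x2, 2, colMeans(x2))^2)) / (n1 + n2 - 2)
  (colMeans(x2) - colMeans(x1)) / sqrt(s2 * (1 / n1 + 1 / n2))
}

# BH step-up computed from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(1, q)
  out
}

# Fisher exact by full enumeration over tables with fixed margins
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0L, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(a_range, r1, n - r1, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# hand-coded log-rank chi-square (no ties assumed handled via aggregation)
oracle_logrank_chi2 <- function(times, events, group) {
  g <- as.integer(factor(group)) - 1L
  ut <- sort(unique(times[events]))
  O <- E <- V <- 0
  for (t in ut) {
    at_risk <- times >= t
    d <- sum(events & times == t)
    d1 <- sum(events & times == t & g == 1L)
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1L)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Cox score statistic at beta = 0, Breslow form, binary/continuous covariate
oracle_cox_score_chi2 <- function(times, events, x) {
  ut <- sort(unique(times[events]))
  U <- I <- 0
  for (t in ut) {
    risk <- times >= t
    xb <- mean(x[risk])
    d <- sum(events & times == t)
    U <- U + sum(x[events & times == t]) - d * xb
    I <- I + d * mean((x[risk] - xb)^2)
  }
  U^2 / I
}

# Kaplan-Meier by direct product over event times
oracle_km <- function(times, events, at) {
  ut <- sort(unique(times[events]))
  vapply(at, function(tt) {
    s <- 1
    for (t in ut[ut <= tt]) {
      n <- sum(times >= t)
      d <- sum(events & times == t)
      s <- s * (1 - d / n)
    }
    s
  }, 0)
}

# exact two-sided Mann-Whitney p by enumeration of group assignments
oracle_mwu_exact_p <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v); nx <- length(x)
  idx <- utils::combn(n, nx)
  u_of <- function(sel) {
    xs <- all_v[sel]; ys <- all_v[-sel]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(nx))
  u_all <- apply(idx, 2, u_of)
  mu <- nx * (n - nx) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}
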