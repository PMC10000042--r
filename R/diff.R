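# Two-group differential methylation with an empirical-Bayes moderated
# t-statistic, BH false discovery rates, and intersection of significant
# regions with a literature marker list.

# Solve trigamma(x) = y by Newton iteration (monotone decreasing trigamma).
trigamma_inverse <- function(y) {
  stopifnot(all(y > 0))
  out <- numeric(length(y))
  big <- y > 1e7
  out[big] <- 1 / sqrt(y[big])
  small <- y < 1e-6
  out[small] <- 1 / y[small]
  mid <- !(big | small)
  if (any(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (max(abs(dif / x)) < 1e-10) break
    }
    out[mid] <- x
  }
  out
}

# Method-of-moments fit of a scaled F-distribution prior to per-region
# sample variances s2 on d degrees of freedom: returns prior df d0 and
# prior variance s02 (Smyth 2004).
fit_variance_prior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) return(list(df_prior = 0, var_prior = mean(s2[ok])))
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(d / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess spread in the log variances: infinite prior df, the
    # moderated variance collapses to the mean sample variance
    d0 <- Inf
    s02 <- mean(s2[ok])
  }
  list(df_prior = d0, var_prior = s02)
}

#' Empirical-Bayes moderated t-test per region
#'
#' For each region, computes the two-group mean difference and a moderated
#' t-statistic in which the pooled residual variance is shrunk towards a
#' prior estimated from all regions: the moderated variance is
#' `(d0 * s0^2 + d * s^2) / (d0 + d)` with the prior degrees of freedom
#' `d0` and prior variance `s0^2` obtained by method of moments on the log
#' sample variances. P-values come from a t-distribution with `d0 + d`
#' degrees of freedom. With `prior = "none"` (`d0 = 0`) the statistic is
#' the ordinary pooled two-sample t-test.
#'
#' @param matrix a `region_matrix` (transformed values) or plain samples x
#'   regions numeric matrix with dimnames.
#' @param group_labels factor (or coercible) of length `nsamples` with
#'   exactly two levels; the difference is level 2 minus level 1.
#' @param prior `"eb"` (empirical Bayes, default) or `"none"`.
#' @return data.frame with `region_id`, `mean_diff`, `t`, `p`, `q`, `s2`;
#'   attributes `df_prior`, `var_prior`, `df_residual`. Zero-variance
#'   regions with zero prior df get `p = NA`.
#' @export
moderated_t <- function(matrix, group_labels, prior = c("eb", "none")) {
  prior <- match.arg(prior)
  vals <- if (inherits(matrix, "region_matrix")) matrix$values else matrix
  g <- factor(group_labels)
  stopifnot(nlevels(g) == 2L, length(g) == nrow(vals))
  n1 <- sum(g == levels(g)[1L])
  n2 <- sum(g == levels(g)[2L])
  if (n1 < 2L || n2 < 2L) stop("need at least 2 samples per group")

  x1 <- vals[g == levels(g)[1L], , drop = FALSE]
  x2 <- vals[g == levels(g)[2L], , drop = FALSE]
  m1 <- colMeans(x1)
  m2 <- colMeans(x2)
  ss1 <- colSums(sweep(x1, 2L, m1)^2)
  ss2 <- colSums(sweep(x2, 2L, m2)^2)
  d <- n1 + n2 - 2L
  s2 <- (ss1 + ss2) / d
  diff <- m2 - m1
  c2 <- 1 / n1 + 1 / n2

  if (prior == "eb") {
    pri <- fit_variance_prior(s2, d)
    d0 <- pri$df_prior
    s02 <- pri$var_prior
  } else {
    d0 <- 0
    s02 <- 0
  }
  s2_tilde <- if (is.infinite(d0)) rep(s02, length(s2)) else {
    (d0 * s02 + d * s2) / (d0 + d)
  }
  df_total <- d0 + d
  tstat <- diff / sqrt(s2_tilde * c2)
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  degenerate <- s2_tilde <= 0 | !is.finite(tstat)
  tstat[degenerate & diff == 0] <- 0
  p[degenerate] <- NA_real_
  p[degenerate & diff == 0] <- NA_real_

  out <- data.frame(
    region_id = colnames(vals), mean_diff = diff, t = tstat, p = p,
    q = bh_fdr(p), s2 = s2, stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "df_prior") <- d0
  attr(out, "var_prior") <- s02
  attr(out, "df_residual") <- d
  out
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up BH adjustment with monotonicity enforcement; `NA` p-values are
#' excluded from the ranking and propagated as `NA`.
#'
#' @param p_values numeric vector in [0, 1] (NA allowed).
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  stopifnot(all(p_values[ok] >= 0 & p_values[ok] <= 1))
  q <- rep(NA_real_, length(p_values))
  q[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  q
}

#' Select differentially methylated regions at an FDR threshold
#'
#' @param results output of [moderated_t()].
#' @param fdr_threshold strict threshold: regions with `q < fdr_threshold`
#'   are returned (a region at exactly the threshold is excluded).
#' @return character vector of region ids.
#' @export
select_dmrs <- function(results, fdr_threshold = 0.1) {
  results$region_id[!is.na(results$q) & results$q < fdr_threshold]
}

#' Intersect DMRs with a literature marker list
#'
#' The marker panel consists of the DMR regions overlapping any literature
#' region by at least one base; the matched literature entry is recorded as
#' provenance.
#'
#' @param dmr_regions a `region_set` (or BED-like data.frame with
#'   `region_id`) restricted to significant regions.
#' @param literature_regions BED-like data.frame (`chrom`, `start`, `end`,
#'   `name`) or path to a BED file.
#' @return object of class `marker_panel`: data.frame with `region_id`,
#'   `source`; zero-overlap input yields an empty panel with a warning.
#' @export
intersect_markers <- function(dmr_regions, literature_regions) {
  if (is.character(literature_regions) && length(literature_regions) == 1L) {
    literature_regions <- read_bed(literature_regions)
  }
  if (is.null(literature_regions$name)) {
    literature_regions$name <- sprintf("marker%03d",
                                       seq_len(nrow(literature_regions)))
  }
  if (nrow(dmr_regions) == 0L || nrow(literature_regions) == 0L) {
    hits <- NULL
  } else {
    hits <- GenomicRanges::findOverlaps(
      regions_to_granges(dmr_regions),
      regions_to_granges(literature_regions),
      minoverlap = 1L
    )
  }
  if (is.null(hits) || length(hits) == 0L) {
    warning("no overlap between DMRs and literature markers: empty panel")
    out <- data.frame(region_id = character(), source = character(),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(
      region_id = dmr_regions$region_id[S4Vectors::queryHits(hits)],
      source = literature_regions$name[S4Vectors::subjectHits(hits)],
      stringsAsFactors = FALSE
    )
    out <- out[!duplicated(out$region_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("marker_panel", "data.frame")
  out
}
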