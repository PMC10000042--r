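# Reference-panel methylation score: per-region Z-scores of a sample
# against the healthy-blood-donor panel, squared and summed, with a
# positivity cutoff at the upper limit of the HBD 95% interval.

#' Reference statistics of the HBD panel
#'
#' Per panel region, the sample mean and sample standard deviation
#' (denominator n - 1) of the HBD samples' transformed values.
#'
#' @param hbd_matrix a `region_matrix` (or plain matrix with dimnames)
#'   containing only HBD samples, transformed state.
#' @param panel a `marker_panel`, or character vector of region ids.
#' @return object of class `reference_stats`: list with `region_id`, `mu`,
#'   `sigma`, `n_hbd`, `zero_sd` (flag per region).
#' @export
reference_stats <- function(hbd_matrix, panel) {
  vals <- if (inherits(hbd_matrix, "region_matrix")) hbd_matrix$values else hbd_matrix
  ids <- if (is.data.frame(panel)) panel$region_id else panel
  if (length(ids) == 0L) stop("empty marker panel")
  if (nrow(vals) < 2L) stop("need at least 2 HBD samples")
  missing <- setdiff(ids, colnames(vals))
  if (length(missing) > 0L) {
    stop(sprintf("panel regions absent from matrix: %s",
                 paste(missing, collapse = ", ")))
  }
  sub <- vals[, ids, drop = FALSE]
  mu <- colMeans(sub)
  sigma <- apply(sub, 2L, stats::sd)
  structure(
    list(region_id = ids, mu = mu, sigma = sigma, n_hbd = nrow(vals),
         zero_sd = sigma == 0),
    class = "reference_stats"
  )
}

#' Per-sample methylation score against the reference panel
#'
#' Z-scores `(x_r - mu_r) / sigma_r` per panel region, squared and summed.
#' Regions with zero reference SD contribute 0 and are reported, as do
#' panel regions missing from the sample (conservative: missing data can
#' only shrink the score).
#'
#' @param sample_vector named numeric vector of transformed values (or one
#'   row of a `region_matrix`).
#' @param ref a `reference_stats`.
#' @param sample_id label stored in the result.
#' @return object of class `score_result`: list with `sample_id`, `z`
#'   (named, NA for skipped regions), `score`, `n_regions_used`,
#'   `n_zero_sd`, `n_missing`.
#' @export
methylation_score <- function(sample_vector, ref, sample_id = "sample") {
  stopifnot(inherits(ref, "reference_stats"))
  x <- sample_vector[ref$region_id]
  names(x) <- ref$region_id
  missing <- is.na(x)
  if (all(missing)) stop("sample has no values for any panel region")
  usable <- !missing & !ref$zero_sd
  z <- rep(NA_real_, length(x))
  names(z) <- ref$region_id
  z[usable] <- (x[usable] - ref$mu[usable]) / ref$sigma[usable]
  structure(
    list(sample_id = sample_id, z = z, score = sum(z[usable]^2),
         n_regions_used = sum(usable), n_zero_sd = sum(ref$zero_sd),
         n_missing = sum(missing)),
    class = "score_result"
  )
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("<score_result> %s: S = %.3f over %d regions (%d zero-SD, %d missing)\n",
              x$sample_id, x$score, x$n_regions_used, x$n_zero_sd, x$n_missing))
  invisible(x)
}

#' Leave-one-out scores of the HBD panel itself
#'
#' Each HBD is scored against the reference statistics of the remaining
#' n - 1 HBDs, avoiding the deflation that scoring a sample against a panel
#' containing itself would cause.
#'
#' @param hbd_matrix `region_matrix` (or plain matrix) of HBD samples.
#' @param panel a `marker_panel` or region-id vector.
#' @return named numeric vector of scores.
#' @export
hbd_loo_scores <- function(hbd_matrix, panel) {
  vals <- if (inherits(hbd_matrix, "region_matrix")) hbd_matrix$values else hbd_matrix
  if (nrow(vals) < 3L) stop("leave-one-out scoring needs at least 3 HBDs")
  out <- vapply(seq_len(nrow(vals)), function(i) {
    ref <- reference_stats(vals[-i, , drop = FALSE], panel)
    methylation_score(vals[i, ], ref, rownames(vals)[i])$score
  }, 0)
  stats::setNames(out, rownames(vals))
}

#' Positivity threshold from HBD scores
#'
#' The cutoff is the upper limit of the 95% interval of the HBD score
#' distribution: `mean + 1.96 * sd`.
#'
#' @param hbd_scores numeric vector of HBD methylation scores (>= 2).
#' @return threshold T.
#' @export
positivity_threshold <- function(hbd_scores) {
  stopifnot(length(hbd_scores) >= 2L)
  s <- stats::sd(hbd_scores)
  if (s == 0) {
    warning("constant HBD scores: threshold equals their mean")
    return(mean(hbd_scores))
  }
  mean(hbd_scores) + 1.96 * s
}

#' Call methylation positivity
#'
#' @param score methylation score(s) S.
#' @param threshold cutoff T from [positivity_threshold()].
#' @return logical: `TRUE` iff `S > T` (a score exactly at the cutoff is
#'   negative).
#' @export
call_positive <- function(score, threshold) {
  score > threshold
}

#' Score every sample of a matrix against an HBD reference
#'
#' @param matrix `region_matrix` with all samples (transformed state).
#' @param hbd_ids sample ids forming the reference panel.
#' @param panel `marker_panel` or region-id vector.
#' @return list with `scores` (data.frame `sample_id`, `n_regions_used`,
#'   `score`, `threshold`, `positive`; HBD rows are leave-one-out),
#'   `threshold`, `ref` (full-panel `reference_stats`).
#' @export
score_cohort <- function(matrix, hbd_ids, panel) {
  vals <- if (inherits(matrix, "region_matrix")) matrix$values else matrix
  stopifnot(all(hbd_ids %in% rownames(vals)))
  hbd <- vals[hbd_ids, , drop = FALSE]
  other <- vals[setdiff(rownames(vals), hbd_ids), , drop = FALSE]
  ref <- reference_stats(hbd, panel)
  hbd_scores <- hbd_loo_scores(hbd, panel)
  thr <- positivity_threshold(hbd_scores)
  pt_scores <- vapply(rownames(other), function(s) {
    methylation_score(other[s, ], ref, s)$score
  }, 0)
  all_scores <- c(pt_scores, hbd_scores)
  scores <- data.frame(
    sample_id = names(all_scores),
    n_regions_used = sum(!ref$zero_sd),
    score = unname(all_scores),
    threshold = thr,
    positive = call_positive(unname(all_scores), thr),
    stringsAsFactors = FALSE
  )
  list(scores = scores, threshold = thr, ref = ref)
}
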