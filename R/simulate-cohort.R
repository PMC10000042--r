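#' Specify a synthetic cohort
#'
#' @param n_patients number of patients (positive).
#' @param n_hbd number of healthy blood donors; HBDs have tumor fraction 0.
#' @param tumor_fraction per-patient tumor fraction in [0, 1]; a scalar is
#'   recycled, `NULL` draws from Beta(0.8, 8) (mostly low circulating-tumor
#'   content, as expected in serum).
#' @param depth expected filter-passing reads per healthy sample.
#' @param hazard_coefficient log-hazard increase per SD of the survival
#'   covariate (a standardized `log1p(100 * tumor_fraction)`).
#' @param censoring_rate approximate fraction of censored observations.
#' @param seed integer master seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients, n_hbd, tumor_fraction = NULL,
                        depth = 2000, hazard_coefficient = log(2),
                        censoring_rate = 0.2, seed = 1L) {
  stopifnot(n_patients >= 1, n_hbd >= 1, depth > 0,
            censoring_rate >= 0, censoring_rate < 1)
  if (!is.null(tumor_fraction)) {
    tumor_fraction <- rep_len(tumor_fraction, n_patients)
    stopifnot(all(tumor_fraction >= 0), all(tumor_fraction <= 1))
  }
  structure(
    list(n_patients = as.integer(n_patients), n_hbd = as.integer(n_hbd),
         tumor_fraction = tumor_fraction, depth = depth,
         hazard_coefficient = hazard_coefficient,
         censoring_rate = censoring_rate, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Simulate a cfDNA cohort: reads plus clinical table
#'
#' Patients receive MeD-seq reads simulated at their tumor fraction and a
#' clinical record; HBDs receive reads at tumor fraction 0 and no clinical
#' row. Watchful-waiting and progression times are exponential with hazard
#' `h0 * exp(beta * x)` where `x` is the standardized `log1p(100 * f)`
#' transform of the tumor fraction (finite at f = 0) and `h0 = log(2) / 12`
#' (12-month median at the cohort centre). Censoring is independent
#' exponential, calibrated to the requested censoring rate.
#'
#' @param spec a [cohort_spec()].
#' @param genome an `lpnpi_genome`.
#' @param methylome a `methylome`.
#' @param generate_reads set `FALSE` to skip read simulation and return the
#'   clinical table only (fast path for survival-model checks).
#' @param off_target_fraction passed to [simulate_reads()].
#' @return list with `clinical` (data.frame, one row per patient),
#'   `reads` (named list of `medseq_reads`, patients then HBDs; `NULL` when
#'   `generate_reads = FALSE`), `sample_ids`, `hbd_ids`, and
#'   `tumor_fraction` (named, HBDs at 0).
#' @export
simulate_cohort <- function(spec, genome, methylome, generate_reads = TRUE,
                            off_target_fraction = 0) {
  stopifnot(inherits(spec, "cohort_spec"))
  np <- spec$n_patients
  nh <- spec$n_hbd
  pt_ids <- sprintf("PT%03d", seq_len(np))
  hbd_ids <- sprintf("HBD%02d", seq_len(nh))

  with_seed(spec$seed, {
    f <- spec$tumor_fraction
    if (is.null(f)) f <- stats::rbeta(np, 0.8, 8)
    x <- log1p(100 * f)
    xs <- if (stats::sd(x) > 0) as.numeric(scale(x)) else rep(0, np)
    h0 <- log(2) / 12
    lam <- h0 * exp(spec$hazard_coefficient * xs)
    pfs_t <- stats::rexp(np, lam)
    ww_t <- stats::rexp(np, lam)
    if (spec$censoring_rate > 0) {
      hc <- h0 * spec$censoring_rate / (1 - spec$censoring_rate)
      cens_pfs <- stats::rexp(np, hc)
      cens_ww <- stats::rexp(np, hc)
    } else {
      cens_pfs <- cens_ww <- rep(Inf, np)
    }
    clinical <- data.frame(
      patient_id = pt_ids,
      ww_time = pmin(ww_t, cens_ww),
      ww_event = ww_t <= cens_ww,
      pfs_time = pmin(pfs_t, cens_pfs),
      pfs_event = pfs_t <= cens_pfs,
      imdc = sample(0:2, np, replace = TRUE, prob = c(10, 10, 13)),
      organ_sites = 1L + stats::rpois(np, 1.5),
      lesion_sum = round(stats::rgamma(np, shape = 2, scale = 2.5), 1),
      age = pmin(86L, pmax(44L, as.integer(round(stats::rnorm(np, 66, 8))))),
      sex = sample(c("M", "F"), np, replace = TRUE, prob = c(26, 7)),
      tumor_fraction = f,
      stringsAsFactors = FALSE
    )
  })

  reads <- NULL
  if (generate_reads) {
    seeds <- derive_seeds(spec$seed, np + nh)
    fr <- c(stats::setNames(clinical$tumor_fraction, pt_ids),
            stats::setNames(rep(0, nh), hbd_ids))
    reads <- lapply(seq_along(fr), function(i) {
      simulate_reads(genome, methylome, tumor_fraction = fr[[i]],
                     depth = spec$depth, seed = seeds[i],
                     off_target_fraction = off_target_fraction)
    })
    names(reads) <- names(fr)
  }

  list(
    clinical = clinical,
    reads = reads,
    sample_ids = c(pt_ids, hbd_ids),
    hbd_ids = hbd_ids,
    tumor_fraction = c(stats::setNames(clinical$tumor_fraction, pt_ids),
                       stats::setNames(rep(0, nh), hbd_ids))
  )
}
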