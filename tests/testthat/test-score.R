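ref_matrix <- function(n = 10L, k = 6L, seed = 1L, mu = 0, sd = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * k, mu, sd), nrow = n,
              dimnames = list(sprintf("HBD%02d", seq_len(n)),
                              sprintf("g%02d", seq_len(k))))
  X
}

test_that("reference statistics are per-region sample mean and SD (n-1)", {
  X <- matrix(c(1, 3, 2, 2), nrow = 2,
              dimnames = list(c("h1", "h2"), c("gA", "gB")))
  rs <- reference_stats(X, c("gA", "gB"))
  expect_equal(unname(rs$mu["gA"]), 2)
  expect_equal(unname(rs$sigma["gA"]), sqrt(2))
  # constant region flagged zero-SD
  expect_true(rs$zero_sd[["gB"]])
  expect_error(reference_stats(X[1, , drop = FALSE], "gA"), "2 HBD")
  expect_error(reference_stats(X, character(0)), "empty")

  # two-pass result equals a streaming (Welford) oracle
  Y <- ref_matrix(12L, 8L, seed = 3)
  rs2 <- reference_stats(Y, colnames(Y))
  welford <- apply(Y, 2, function(v) {
    v <- unname(v)
    m <- 0; m2 <- 0
    for (i in seq_along(v)) {
      d <- v[i] - m
      m <- m + d / i
      m2 <- m2 + d * (v[i] - m)
    }
    c(mean = m, sd = sqrt(m2 / (length(v) - 1)))
  })
  expect_equal(unname(rs2$mu), unname(welford["mean", ]), tolerance = 1e-12)
  expect_equal(unname(rs2$sigma), unname(welford["sd", ]), tolerance = 1e-12)
})

test_that("the methylation score is the sum of squared Z-scores", {
  X <- ref_matrix(10L, 5L, seed = 4)
  rs <- reference_stats(X, colnames(X))
  # a sample at the HBD means scores exactly 0
  expect_equal(methylation_score(rs$mu, rs)$score, 0)
  # one region at z = 2, all others at the mean -> S = 4
  x <- rs$mu
  x["g03"] <- rs$mu["g03"] + 2 * rs$sigma["g03"]
  expect_equal(methylation_score(x, rs)$score, 4, tolerance = 1e-12)
  # zero-SD regions contribute 0 and are reported
  X2 <- X; X2[, "g01"] <- 7
  rs2 <- reference_stats(X2, colnames(X2))
  sc <- methylation_score(stats::setNames(rep(100, 5), colnames(X2)), rs2)
  expect_equal(sc$n_zero_sd, 1L)
  expect_equal(sc$n_regions_used, 4L)
  # missing panel regions contribute 0, all-missing is an error
  x_missing <- x[c("g01", "g02")]
  sc2 <- methylation_score(x_missing, rs)
  expect_equal(sc2$n_missing, 3L)
  expect_error(methylation_score(c(zz = 1), rs), "no values")
})

test_that("the score is invariant under per-region affine rescaling", {
  X <- ref_matrix(10L, 6L, seed = 5)
  rs <- reference_stats(X, colnames(X))
  set.seed(6)
  x <- stats::setNames(rnorm(6, 1, 2), colnames(X))
  s0 <- methylation_score(x, rs)$score
  a <- runif(6, 0.5, 3); b <- rnorm(6)
  Xr <- sweep(sweep(X, 2, a, "*"), 2, b, "+")
  rsr <- reference_stats(Xr, colnames(X))
  sr <- methylation_score(stats::setNames(a * x + b, colnames(X)), rsr)$score
  expect_equal(sr, s0, tolerance = 1e-10)
})

test_that("mean score of null samples matches the analytic expectation", {
  n <- 10L; k <- 8L
  set.seed(8)
  S <- replicate(1000, {
    ref <- matrix(rnorm(n * k), n, dimnames = list(NULL, sprintf("g%02d", 1:k)))
    rs <- reference_stats(ref, colnames(ref))
    x <- stats::setNames(rnorm(k), colnames(ref))
    methylation_score(x, rs)$score
  })
  # E[z^2] = (1 + 1/n)(n-1)/(n-3) per region for a sample from the same
  # normal population as the n-donor reference
  analytic <- k * (1 + 1 / n) * (n - 1) / (n - 3)
  expect_equal(mean(S), analytic, tolerance = 0.15)
})

test_that("the positivity cutoff is mean + 1.96 SD of HBD scores", {
  expect_equal(positivity_threshold(c(0, 10)), 5 + 1.96 * sqrt(50))
  expect_equal(positivity_threshold(c(0, 10)), 18.859, tolerance = 1e-3)
  expect_warning(t_const <- positivity_threshold(c(3, 3, 3)), "constant")
  expect_equal(t_const, 3)
  # translation equivariance
  s <- c(1, 4, 2, 8)
  expect_equal(positivity_threshold(s + 5), positivity_threshold(s) + 5)
  # boundary decision: a score exactly at the cutoff is negative
  expect_false(call_positive(5, 5))
  expect_true(call_positive(5 + 1e-9, 5))
})

test_that("null positivity rate at the computed cutoff stays below 10%", {
  n <- 10L; k <- 6L
  set.seed(12)
  ref <- ref_matrix(n, k, seed = 12)
  hbd_scores <- hbd_loo_scores(ref, colnames(ref))
  thr <- positivity_threshold(hbd_scores)
  rs <- reference_stats(ref, colnames(ref))
  fresh <- replicate(1000, {
    methylation_score(stats::setNames(rnorm(k), colnames(ref)), rs)$score
  })
  expect_lte(mean(call_positive(fresh, thr)), 0.10)
})

test_that("leave-one-out HBD scoring avoids self-reference", {
  X <- ref_matrix(10L, 6L, seed = 9)
  loo <- hbd_loo_scores(X, colnames(X))
  expect_equal(names(loo), rownames(X))
  # scoring each HBD against a panel containing itself deflates the score
  rs_all <- reference_stats(X, colnames(X))
  self <- vapply(rownames(X), function(i) {
    methylation_score(X[i, ], rs_all)$score
  }, 0)
  expect_gt(mean(loo), mean(self))
  expect_error(hbd_loo_scores(X[1:2, ], colnames(X)), "at least 3")
})

test_that("median score increases with tumor fraction in simulated cohorts", {
  g <- fix_genome(); m <- fix_methylome()
  marker_regions <- paste0("r_", m$region_effects$tss_id)
  regions <- build_tss_windows(g)
  fractions <- c(0, 0.01, 0.05, 0.2)
  per_f <- lapply(seq_along(fractions), function(i) {
    lapply(1:6, function(j) {
      r <- simulate_reads(g, m, fractions[i], depth = 600,
                          seed = 1000L * i + j)
      process_sample(r, g, sprintf("f%d_%d", i, j))$counts
    })
  })
  all_ct <- do.call(c, per_f)
  rm <- normalize_and_sqrt(summarize_regions(all_ct, regions))
  hbd_rows <- rownames(rm$values)[1:6]           # the f = 0 samples
  rs <- reference_stats(rm$values[hbd_rows, ], marker_regions)
  med <- vapply(seq_along(fractions), function(i) {
    ids <- sprintf("f%d_%d", i, 1:6)
    stats::median(vapply(ids, function(s) {
      methylation_score(rm$values[s, ], rs, s)$score
    }, 0))
  }, 0)
  expect_true(all(diff(med) >= 0))
})

test_that("strong tumor fractions are recovered with high sensitivity and specificity", {
  g <- fix_genome(); m <- fix_methylome()
  marker_regions <- paste0("r_", m$region_effects$tss_id)
  regions <- build_tss_windows(g)
  res <- vapply(1:20, function(rep) {
    seeds <- 5000L + rep * 20L + 1:9
    hbd_ct <- lapply(1:5, function(j) {
      process_sample(simulate_reads(g, m, 0, 500, seed = seeds[j]), g,
                     sprintf("h%d", j))$counts
    })
    pos_ct <- lapply(1:4, function(j) {
      process_sample(simulate_reads(g, m, 0.25, 500, seed = seeds[5 + j]), g,
                     sprintf("p%d", j))$counts
    })
    rm <- normalize_and_sqrt(summarize_regions(c(hbd_ct, pos_ct), regions))
    sc <- score_cohort(rm, sprintf("h%d", 1:5), marker_regions)
    hbd_pos <- sc$scores$positive[grepl("^h", sc$scores$sample_id)]
    pt_pos <- sc$scores$positive[grepl("^p", sc$scores$sample_id)]
    c(spec = mean(!hbd_pos), sens = mean(pt_pos))
  }, c(spec = 0, sens = 0))
  expect_gte(mean(res["sens", ]), 0.9)
  expect_gte(mean(res["spec", ]), 0.9)
})
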