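make_windows <- function(chrom, start, mean_delta, step = 1e4, ws = 1e6,
                         depth = 20) {
  data.frame(chrom = chrom, start = start, end = start + ws - 1,
             midpoint = start + ws / 2, n_snps = 10L,
             mean_index_high = 0.5, mean_index_low = 0.5,
             mean_delta = mean_delta, mean_depth = depth,
             stringsAsFactors = FALSE)
}

test_that("no window above its band means no region", {
  w <- make_windows("chr1", seq(1, 1e6, by = 1e4), mean_delta = 0.1)
  tab <- flat_ci_table(-0.3, 0.3)
  expect_equal(nrow(call_candidate_regions(w, tab, 0.99)), 0L)
})

test_that("a degenerate zero band makes every nonzero window significant", {
  starts <- seq(1, 1e6, by = 1e4)
  w <- rbind(make_windows("chr1", starts, 0.2),
             make_windows("chr2", starts, -0.2))
  tab <- flat_ci_table(0, 0)
  reg <- call_candidate_regions(w, tab, 0.99)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$chrom, c("chr1", "chr2"))
  expect_equal(reg$sign, c(1L, -1L))
  expect_equal(reg$start, c(1, 1))
  expect_equal(reg$n_windows, c(length(starts), length(starts)))
})

test_that("opposite-sign runs are never merged and gaps split regions", {
  starts <- seq(1, 30e4, by = 1e4)
  d <- rep(0, length(starts))
  d[3:5] <- 0.5
  d[6:8] <- -0.5       # adjacent but opposite sign: separate region
  d[20:22] <- 0.5      # separated by sub-threshold windows
  w <- make_windows("chr1", starts, d, ws = 1e4)  # tiling windows
  tab <- flat_ci_table(-0.3, 0.3)
  reg <- call_candidate_regions(w, tab, 0.99)
  expect_equal(nrow(reg), 3L)
  expect_equal(reg$sign, c(1L, -1L, 1L))
  expect_equal(reg$n_windows, c(3L, 3L, 3L))
  # minimum run length filters short runs
  reg4 <- call_candidate_regions(w, tab, 0.99, min_windows = 4L)
  expect_equal(nrow(reg4), 0L)
})

test_that("peak_delta reports the largest absolute member delta", {
  starts <- seq(1, 5e4, by = 1e4)
  w <- make_windows("chr1", starts, c(0.4, 0.6, 0.9, 0.5, 0.1), ws = 1e4)
  tab <- flat_ci_table(-0.3, 0.3)
  reg <- call_candidate_regions(w, tab, 0.99)
  expect_equal(reg$peak_delta, 0.9)
  expect_equal(reg$n_windows, 4L)
})

test_that("regions at the stricter level nest inside the looser level's regions", {
  expt <- simulate_bsa_experiment(small_params(seed = 301))
  cfg <- null_sim_config(pool_size = 15, depths = seq(5L, 60L, by = 5L),
                         n_iterations = 3000, seed = 302)
  tab <- build_ci_table(cfg)
  sc <- run_scan(variants = expt$variants,
                 chrom_lengths = small_params(1)$chrom_lengths,
                 ci_table = tab, quiet = TRUE)
  r95 <- call_candidate_regions(sc$windows, tab, 0.95)
  r99 <- call_candidate_regions(sc$windows, tab, 0.99)
  for (i in seq_len(nrow(r99))) {
    inside <- r95$chrom == r99$chrom[i] &
      r95$start <= r99$start[i] & r95$end >= r99$end[i]
    expect_true(any(inside))
  }
})

test_that("interval_length reproduces fine-mapping span arithmetic", {
  fm <- interval_length(39531980, 39626163)
  expect_identical(fm$bp, 94183)
  expect_identical(fm$kb, 94)
  expect_identical(interval_length(1000, 2000)$kb, 1)
  expect_identical(interval_length(36620000, 39770000)$bp, 3150000)
  expect_error(interval_length(10, 10), "strictly smaller")
  expect_error(interval_length(20, 10), "strictly smaller")
  # translation invariance
  expect_identical(interval_length(39531980 + 5e6, 39626163 + 5e6)$bp, 94183)
})

test_that("single-marker scan recovers exact and null fits", {
  set.seed(77)
  n <- 278
  g <- matrix(sample(0:2, n * 5, replace = TRUE,
                     prob = c(0.25, 0.5, 0.25)), ncol = 5)
  # perfect fit: phenotype equals dosage at marker 3
  res <- single_marker_scan(g, g[, 3])
  expect_equal(res$pve[3], 1)
  expect_true(all(res$pve >= 0 & res$pve <= 1))
  expect_true(all(res$lod >= 0))
  # constant phenotype: degenerate, all zero
  res0 <- single_marker_scan(g, rep(2, n))
  expect_true(all(res0$lod == 0) && all(res0$pve == 0))
  # pure noise: max PVE stays near zero
  res_null <- single_marker_scan(g, rnorm(n))
  expect_lt(max(res_null$pve), 0.06)
})

test_that("scan LOD and PVE agree with a linear-model oracle", {
  set.seed(78)
  n <- 278
  g <- matrix(sample(0:2, n * 3, replace = TRUE,
                     prob = c(0.25, 0.5, 0.25)), ncol = 3)
  y <- 0.8 * (g[, 2] - 1) + 0.4 * (g[, 2] == 1) + rnorm(n, 0, 1)
  res <- single_marker_scan(g, y)
  for (j in 1:3) {
    fit <- lm(y ~ factor(g[, j]))
    expect_equal(res$pve[j], summary(fit)$r.squared, tolerance = 1e-10)
    rss_full <- sum(residuals(fit)^2)
    rss_null <- sum((y - mean(y))^2)
    expect_equal(res$lod[j], (n / 2) * log10(rss_null / rss_full),
                 tolerance = 1e-10)
  }
})

test_that("PVE at a simulated causal marker matches the variance decomposition", {
  set.seed(79)
  n <- 278
  a <- 1; d <- 0.6; sigma <- 1
  g <- sample(0:2, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  y <- a * (g - 1) + d * (g == 1) + rnorm(n, 0, sigma)
  res <- single_marker_scan(matrix(g, ncol = 1), y)
  # empirical decomposition on the sample itself: between-class share of
  # total variance
  mu <- tapply(y, g, mean)
  between <- sum((mu[as.character(g)] - mean(y))^2)
  expect_equal(res$pve[1], between / sum((y - mean(y))^2), tolerance = 1e-10)
  # and near the theoretical F2 share a^2/2 + d^2/4 over total variance
  # (3 standard errors of a sample R^2 at n = 278 is about 0.14)
  theo <- (a^2 / 2 + d^2 / 4) / (a^2 / 2 + d^2 / 4 + sigma^2)
  expect_lt(abs(res$pve[1] - theo), 0.15)
})

test_that("BED export converts closed 1-based regions to half-open 0-based", {
  reg <- data.frame(chrom = "chr3", start = 36620001, end = 39770000,
                    level = 0.99, sign = 1L, peak_delta = 0.9, n_windows = 10L)
  path <- withr::local_tempfile(fileext = ".bed")
  write_regions_bed(reg, path)
  bed <- utils::read.table(path, sep = "\t")
  expect_equal(bed$V2, 36620000)
  expect_equal(bed$V3, 39770000)
})
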