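test_that("SNP-index hits its boundary definitions", {
  expect_equal(snp_index(20, 0), 0)   # all reads carry the reference allele
  expect_equal(snp_index(0, 20), 1)   # all reads carry the mutant allele
  expect_equal(snp_index(5, 5), 0.5)
  expect_error(snp_index(0, 0), "zero depth")
  expect_error(snp_index(-1, 5), ">= 0")
})

test_that("delta(SNP-index) is the high-minus-low difference", {
  expect_equal(delta_snp_index(1, 0), 1)
  expect_equal(delta_snp_index(0.42, 0.42), 0)
  expect_equal(delta_snp_index(0.3, 0.7), -0.4)
  expect_error(delta_snp_index(1.2, 0), "\\[0, 1\\]")
})

test_that("compute_indices matches a per-site brute-force recomputation", {
  v <- random_variants(50, seed = 10)
  v$high_ref <- v$high_ref + 1L; v$low_ref <- v$low_ref + 1L  # depth >= 1
  rec <- compute_indices(v)
  expect_equal(nrow(rec), nrow(v))
  for (i in seq_len(nrow(v))) {
    ih <- v$high_alt[i] / (v$high_ref[i] + v$high_alt[i])
    il <- v$low_alt[i] / (v$low_ref[i] + v$low_alt[i])
    expect_identical(rec$index_high[i], ih)
    expect_identical(rec$index_low[i], il)
    expect_identical(rec$delta[i], ih - il)
  }
  expect_equal(nrow(compute_indices(v[0, ])), 0L)
})

test_that("compute_indices names a zero-depth site in its error", {
  v <- pooled_variants("chr2", 123L, "A", "G", 0L, 0L, 5L, 5L, 30, 30)
  expect_error(compute_indices(v), "chr2:123")
})

test_that("single- and two-site windows have the expected means", {
  rec <- compute_indices(pooled_variants(
    "chr1", 500000L, "A", "G", 16L, 4L, 10L, 10L, 35, 35
  ))
  expect_equal(rec$delta, 0.2 - 0.5)
  rec$delta <- 0.2  # pin the member value; window means must echo it
  w <- sliding_window(rec, window_config(1e6, 1e4), c(chr1 = 2e6))
  expect_true(all(w$mean_delta == 0.2))
  expect_true(all(w$n_snps == 1L))
  # every emitted window must actually cover the site
  expect_true(all(w$start <= 5e5 & w$start + 1e6 - 1 >= 5e5))

  rec2 <- data.frame(chrom = "chr1", pos = c(400000L, 600000L),
                     index_high = c(0.6, 0.8), index_low = c(0.5, 0.5),
                     delta = c(0.1, 0.3), depth_high = c(20L, 20L),
                     depth_low = c(20L, 20L))
  w2 <- sliding_window(rec2, window_config(1e6, 1e4), c(chr1 = 2e6))
  both <- w2[w2$n_snps == 2L, ]
  expect_true(nrow(both) > 0)
  expect_true(all(abs(both$mean_delta - 0.2) < 1e-15))
})

test_that("window means agree with a quadratic brute-force oracle", {
  set.seed(42)
  n <- 200
  rec <- data.frame(
    chrom = "chr1", pos = sort(sample.int(3e6, n)),
    index_high = runif(n), index_low = runif(n),
    depth_high = rpois(n, 20) + 1L, depth_low = rpois(n, 20) + 1L
  )
  rec$delta <- rec$index_high - rec$index_low
  cfg <- window_config(1e6, 1e5)
  w <- sliding_window(rec, cfg, c(chr1 = 3e6))
  # O(sites x windows) oracle
  starts <- seq(1, 3e6, by = cfg$step)
  oracle <- lapply(starts, function(s) {
    inside <- rec$pos >= s & rec$pos <= s + cfg$window_size - 1
    if (!any(inside)) return(NULL)
    data.frame(start = s, n_snps = sum(inside),
               mean_delta = mean(rec$delta[inside]),
               mean_index_high = mean(rec$index_high[inside]),
               mean_depth = mean((rec$depth_high[inside] + rec$depth_low[inside]) / 2))
  })
  oracle <- do.call(rbind, oracle)
  expect_equal(w$start, oracle$start)
  expect_equal(w$n_snps, oracle$n_snps)
  expect_equal(w$mean_delta, oracle$mean_delta, tolerance = 1e-12)
  expect_equal(w$mean_index_high, oracle$mean_index_high, tolerance = 1e-12)
  expect_equal(w$mean_depth, oracle$mean_depth, tolerance = 1e-12)
})

test_that("window means are bounded by member extremes and swap-antisymmetric", {
  set.seed(7)
  n <- 150
  rec <- data.frame(
    chrom = "chr1", pos = sort(sample.int(2e6, n)),
    index_high = runif(n), index_low = runif(n),
    depth_high = rep(20L, n), depth_low = rep(20L, n)
  )
  rec$delta <- rec$index_high - rec$index_low
  w <- sliding_window(rec, window_config(5e5, 5e4), c(chr1 = 2e6))
  expect_true(all(w$mean_delta <= max(rec$delta) + 1e-12))
  expect_true(all(w$mean_delta >= min(rec$delta) - 1e-12))
  # reversing bulk labels negates every delta and every window mean exactly
  swap <- rec
  swap$index_high <- rec$index_low
  swap$index_low <- rec$index_high
  swap$delta <- -rec$delta
  ws <- sliding_window(swap, window_config(5e5, 5e4), c(chr1 = 2e6))
  expect_equal(ws$mean_delta, -w$mean_delta)
})

test_that("with step = window size the windows tile the chromosome", {
  set.seed(8)
  n <- 100
  rec <- data.frame(
    chrom = "chr1", pos = sort(sample.int(2e6, n)),
    index_high = runif(n), index_low = runif(n),
    depth_high = rep(10L, n), depth_low = rep(10L, n)
  )
  rec$delta <- rec$index_high - rec$index_low
  w <- sliding_window(rec, window_config(5e5, 5e5), c(chr1 = 2e6))
  expect_equal(sum(w$n_snps), n)  # every site in exactly one window
  expect_true(all(diff(w$start) %% 5e5 == 0))
})

test_that("sliding_window rejects unsorted input and unknown chromosomes", {
  rec <- data.frame(chrom = c("chr1", "chr1"), pos = c(2000L, 1000L),
                    index_high = c(0.5, 0.5), index_low = c(0.5, 0.5),
                    delta = c(0, 0), depth_high = c(10L, 10L),
                    depth_low = c(10L, 10L))
  expect_error(sliding_window(rec, window_config(), c(chr1 = 1e6)), "sorted")
  rec2 <- rec[order(rec$pos), ]
  expect_error(sliding_window(rec2, window_config(), c(chrX = 1e6)),
               "absent from chrom_lengths")
  split_blocks <- data.frame(chrom = c("chr1", "chr2", "chr1"),
                             pos = c(1L, 1L, 2L),
                             index_high = 0.5, index_low = 0.5, delta = 0,
                             depth_high = 10L, depth_low = 10L)
  expect_error(sliding_window(split_blocks, window_config(),
                              c(chr1 = 1e6, chr2 = 1e6)), "sorted")
})
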