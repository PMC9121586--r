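# Shared fixture builders: everything is generated in code at test time.

# Hand-built four-site table exercising each filter rule exactly once.
toy_filter_table <- function() {
  pooled_variants(
    chrom = rep("chr1", 4), pos = c(100L, 200L, 300L, 400L),
    ref = c("A", "C", "G", "T"), alt = c("C", "G", "T", "A"),
    high_ref = c(10L, 1L, 10L, 10L), high_alt = c(10L, 0L, 10L, 10L),
    low_ref = c(10L, 10L, 10L, 10L), low_alt = c(10L, 10L, 10L, 10L),
    bq = c(35, 35, 29, 35),   # site 3 fails base quality
    mq = c(29, 35, 35, 35)    # site 1 fails mapping quality; site 2 fails depth
  )
}

# Random variant tables for property-style checks.
random_variants <- function(n, seed) {
  set.seed(seed)
  pos <- sort(sample.int(1e6, n))
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  pooled_variants(
    chrom = rep("chr1", n), pos = pos, ref = ref, alt = unname(alt),
    high_ref = rpois(n, 8), high_alt = rpois(n, 8),
    low_ref = rpois(n, 8), low_alt = rpois(n, 8),
    bq = sample(20:45, n, replace = TRUE),
    mq = sample(20:45, n, replace = TRUE)
  )
}

# Small, fast experiment parameters for pipeline-level tests.
small_params <- function(seed, ...) {
  f2_sim_params(
    chrom_lengths = stats::setNames(rep(10e6, 3), paste0("chr", 1:3)),
    snp_spacing = 10e3, n_f2 = 120, qtl_chrom = "chr2", qtl_pos = 5e6,
    pool_size = 15, seed = seed, ...
  )
}

# Exact null distribution of delta(SNP-index) for tiny pools and depths:
# enumerate the pool dosage-sum distribution and the binomial read draws.
exact_null_delta_dist <- function(pool_size, depth,
                                  population = c("F2", "RIL", "BC1")) {
  population <- match.arg(population)
  s <- pool_size
  sum_support <- 0:(2 * s)
  sum_pmf <- switch(population,
    F2 = dbinom(sum_support, 2 * s, 0.5),
    RIL = ifelse(sum_support %% 2 == 0, dbinom(sum_support / 2, s, 0.5), 0),
    BC1 = ifelse(sum_support <= s, dbinom(sum_support, s, 0.5), 0)
  )
  p_alleles <- sum_support / (2 * s)
  # marginal pmf of one bulk's alt read count
  reads <- 0:depth
  read_pmf <- vapply(reads, function(i) {
    sum(sum_pmf * dbinom(i, depth, p_alleles))
  }, numeric(1))
  joint <- outer(read_pmf, read_pmf)
  delta <- outer(reads, reads, function(i, j) (i - j) / depth)
  agg <- tapply(as.vector(joint), as.vector(delta), sum)
  data.frame(delta = as.numeric(names(agg)), prob = as.numeric(agg))
}

# Minimal hand-made null band table for region-calling unit tests.
flat_ci_table <- function(lower, upper, depths = 1:100, level = 0.99) {
  out <- data.frame(depth = depths, level = level,
                    lower = lower, upper = upper)
  class(out) <- c("null_ci_table", class(out))
  out
}

# Write a small two-sample VCF from raw lines (independent of the package's
# own writer, for parser tests).
write_test_vcf <- function(path, data_lines) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSL\tQL",
    data_lines
  ), path)
  path
}
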