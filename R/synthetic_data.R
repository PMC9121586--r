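#' Parameters of the simulated bulked-segregant experiment
#'
#' Defaults emulate a cucumber-style design: two inbred parents differing in
#' pericarp color, seven 30-Mb chromosomes (2n = 2x = 14), an F2 of 278
#' plants segregating an incompletely dominant major color locus, extreme
#' bulks of 20 light and 20 dark individuals, and pooled short-read
#' sequencing at ~20x per site. The reference genome is identified with the
#' light parent, so the "mutant" (alt) allele at every site is the
#' dark-parent allele and the expected delta(SNP-index) in the QTL region
#' is positive.
#'
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param snp_spacing mean distance between parent-informative SNPs (bp);
#'   sites are laid down as a Poisson process with this mean gap.
#' @param cm_per_mb uniform recombination rate (centimorgan per megabase).
#' @param n_f2 F2 population size.
#' @param qtl_chrom,qtl_pos location of the planted QTL; a SNP is placed
#'   exactly at `qtl_pos`.
#' @param additive_effect additive effect a: phenotype shift per dark allele
#'   relative to the heterozygote midpoint.
#' @param dominance_effect dominance deviation d of the heterozygote
#'   (default 0.6 * a: the F1 leans toward the dark parent).
#' @param residual_sd residual phenotype SD (default 0.5, so the light
#'   homozygote class is fully separable while heterozygote and dark
#'   homozygote partially overlap — a nearly categorical visual trait).
#' @param pool_size individuals per bulk.
#' @param depth_mean mean per-site read depth of each pool.
#' @param seq_error per-read probability of reporting the wrong allele.
#' @param seed integer RNG seed.
#' @return a list of class `f2_sim_params`.
#' @export
f2_sim_params <- function(chrom_lengths = stats::setNames(rep(30e6, 7),
                                                          paste0("chr", 1:7)),
                          snp_spacing = 2000, cm_per_mb = 3.3,
                          n_f2 = 278, qtl_chrom = "chr3", qtl_pos = 20e6,
                          additive_effect = 1, dominance_effect = 0.6,
                          residual_sd = 0.5, pool_size = 20,
                          depth_mean = 20, seq_error = 0.001, seed = 1L) {
  stopifnot(all(chrom_lengths > 0), snp_spacing > 0, cm_per_mb >= 0,
            n_f2 >= 1, pool_size >= 1, depth_mean > 0,
            seq_error >= 0, seq_error < 0.5, residual_sd >= 0)
  if (!qtl_chrom %in% names(chrom_lengths)) {
    stop("qtl_chrom '", qtl_chrom, "' not among chromosome names")
  }
  if (qtl_pos < 1 || qtl_pos > chrom_lengths[[qtl_chrom]]) {
    stop("qtl_pos outside its chromosome")
  }
  structure(
    list(chrom_lengths = chrom_lengths, snp_spacing = snp_spacing,
         cm_per_mb = cm_per_mb, n_f2 = as.integer(n_f2),
         qtl_chrom = qtl_chrom, qtl_pos = qtl_pos,
         additive_effect = additive_effect,
         dominance_effect = dominance_effect,
         residual_sd = residual_sd, pool_size = as.integer(pool_size),
         depth_mean = depth_mean, seq_error = seq_error,
         seed = as.integer(seed)),
    class = "f2_sim_params"
  )
}

# Parental-origin alleles of `n` gametes at sorted positions `pos` on one
# chromosome: crossover count ~ Poisson(genetic length in Morgans),
# breakpoints uniform, no interference, starting phase equiprobable.
# Returns an n x length(pos) matrix of 0/1 (1 = dark-parent allele).
.simulate_gametes <- function(pos, chrom_len, cm_per_mb, n) {
  morgans <- chrom_len / 1e6 * cm_per_mb / 100
  out <- matrix(0L, nrow = n, ncol = length(pos))
  n_xo <- stats::rpois(n, morgans)
  phase <- stats::rbinom(n, 1L, 0.5)
  for (g in seq_len(n)) {
    if (n_xo[g] == 0L) {
      out[g, ] <- phase[g]
    } else {
      bp <- sort(stats::runif(n_xo[g], 0, chrom_len))
      out[g, ] <- (phase[g] + findInterval(pos, bp)) %% 2L
    }
  }
  out
}

#' Forward-simulate an F2 population
#'
#' Lays down parent-informative SNPs along each chromosome, generates every
#' F2 individual as the union of two recombinant gametes (Poisson crossover
#' process, uniform breakpoints, no interference), and assigns phenotypes
#' from the planted QTL: phenotype = a*(dosage - 1) + d*[dosage == 1] +
#' Normal(0, sigma). Dosage counts dark-parent (alt) alleles, so unlinked
#' markers segregate 1:2:1 over dosages 0/1/2.
#'
#' @param params an [f2_sim_params()] object.
#' @return a list with `genotypes` (integer matrix, individuals x SNPs,
#'   dark-allele dosage), `map` (data.frame `chrom, pos`, sorted),
#'   `phenotypes` (numeric), and `truth` (list: `qtl_chrom`, `qtl_pos`,
#'   `qtl_marker` column index of the causal SNP, `qtl_dosage`,
#'   `phenotypes`). Deterministic given `params$seed`.
#' @export
simulate_f2_population <- function(params = f2_sim_params()) {
  stopifnot(inherits(params, "f2_sim_params"))
  set.seed(params$seed)
  chroms <- names(params$chrom_lengths)
  # marker map: Poisson-process gaps with mean snp_spacing, QTL SNP inserted
  map_list <- lapply(chroms, function(ch) {
    len <- params$chrom_lengths[[ch]]
    n_exp <- ceiling(len / params$snp_spacing * 1.5) + 10
    gaps <- stats::rexp(n_exp, rate = 1 / params$snp_spacing)
    pos <- cumsum(gaps)
    pos <- unique(round(pos[pos <= len]))
    pos <- pos[pos >= 1]
    if (ch == params$qtl_chrom) pos <- sort(unique(c(pos, round(params$qtl_pos))))
    data.frame(chrom = ch, pos = as.integer(pos), stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, map_list)
  rownames(map) <- NULL
  n <- params$n_f2
  geno <- matrix(0L, nrow = n, ncol = nrow(map))
  col_off <- 0L
  for (ch in chroms) {
    pos <- map$pos[map$chrom == ch]
    g1 <- .simulate_gametes(pos, params$chrom_lengths[[ch]],
                            params$cm_per_mb, n)
    g2 <- .simulate_gametes(pos, params$chrom_lengths[[ch]],
                            params$cm_per_mb, n)
    geno[, col_off + seq_along(pos)] <- g1 + g2
    col_off <- col_off + length(pos)
  }
  qtl_marker <- which(map$chrom == params$qtl_chrom &
                        map$pos == round(params$qtl_pos))[1]
  dosage <- geno[, qtl_marker]
  a <- params$additive_effect
  d <- params$dominance_effect
  phen <- a * (dosage - 1) + d * (dosage == 1L) +
    stats::rnorm(n, 0, params$residual_sd)
  list(
    genotypes = geno, map = map, phenotypes = phen,
    truth = list(qtl_chrom = params$qtl_chrom,
                 qtl_pos = as.integer(round(params$qtl_pos)),
                 qtl_marker = qtl_marker, qtl_dosage = dosage,
                 phenotypes = phen)
  )
}

#' Select extreme-phenotype bulks
#'
#' High bulk: indices of the `pool_size` largest phenotypes; low bulk: the
#' `pool_size` smallest. Ties are broken by index order (stable sort), so
#' with a fully tied phenotype the low bulk takes the earliest indices and
#' the high bulk the latest; the bulks are disjoint by construction.
#'
#' @param phenotypes numeric vector (length >= 2 * pool_size).
#' @param pool_size individuals per bulk.
#' @return a list with integer index vectors `high` and `low`, each sorted.
#' @export
select_extreme_bulks <- function(phenotypes, pool_size) {
  n <- length(phenotypes)
  if (n < 2 * pool_size) {
    stop("need at least 2 * pool_size = ", 2 * pool_size,
         " phenotypes, got ", n)
  }
  ord <- order(phenotypes)  # stable: ties resolved by index order
  list(high = sort(ord[(n - pool_size + 1L):n]),
       low = sort(ord[seq_len(pool_size)]))
}

#' Simulate pooled short-read counts for the two bulks
#'
#' Per SNP and bulk: read depth ~ Poisson(`depth_mean`) truncated below at
#' 1; the bulk's true dark-allele frequency is p = (sum of member dosages) /
#' (2 * pool size); each read reports the dark (alt) allele with probability
#' p*(1 - seq_error) + (1 - p)*seq_error. Base and mapping qualities are
#' drawn at or above Phred 30 so default filtering keeps all sites. Alleles
#' are arbitrary distinct nucleotides per site. Randomness continues the
#' caller's RNG stream (the experiment-level seed is set once by
#' [simulate_f2_population()]).
#'
#' @param genotypes_high,genotypes_low integer dosage matrices (bulk members
#'   x SNPs) for the dark and light bulk.
#' @param map data.frame `chrom, pos` matching the genotype columns.
#' @param params an [f2_sim_params()] object.
#' @return a `pooled_variants` table sorted by (chrom, pos).
#' @export
simulate_pool_reads <- function(genotypes_high, genotypes_low, map, params) {
  stopifnot(inherits(params, "f2_sim_params"),
            ncol(genotypes_high) == nrow(map),
            ncol(genotypes_low) == nrow(map))
  m <- nrow(map)
  pool2 <- 2L * nrow(genotypes_high)
  e <- params$seq_error
  draw <- function(geno) {
    p <- colSums(geno) / pool2
    p_obs <- p * (1 - e) + (1 - p) * e
    depth <- pmax(stats::rpois(m, params$depth_mean), 1L)
    alt <- stats::rbinom(m, depth, p_obs)
    cbind(ref = depth - alt, alt = alt)
  }
  hi <- draw(genotypes_high)
  lo <- draw(genotypes_low)
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1L), character(1))
  pooled_variants(
    chrom = map$chrom, pos = map$pos, ref = ref, alt = unname(alt),
    high_ref = hi[, "ref"], high_alt = hi[, "alt"],
    low_ref = lo[, "ref"], low_alt = lo[, "alt"],
    bq = 30 + stats::rpois(m, 5), mq = 30 + stats::rpois(m, 5)
  )
}

#' Run the full simulated bulked-segregant experiment
#'
#' Composes [simulate_f2_population()], [select_extreme_bulks()] and
#' [simulate_pool_reads()] under a single seed and returns the
#' pipeline-ready variant table together with the ground truth needed for
#' recovery tests.
#'
#' @param params an [f2_sim_params()] object.
#' @param keep_genotypes retain the full F2 genotype matrix in the result
#'   (needed for marker scans; drop to save memory).
#' @return a list: `variants` (pooled_variants), `map`, `phenotypes`,
#'   `truth` (with bulk index vectors `high_bulk`, `low_bulk` added), and
#'   optionally `genotypes`.
#' @export
simulate_bsa_experiment <- function(params = f2_sim_params(),
                                    keep_genotypes = FALSE) {
  pop <- simulate_f2_population(params)
  bulks <- select_extreme_bulks(pop$phenotypes, params$pool_size)
  variants <- simulate_pool_reads(
    pop$genotypes[bulks$high, , drop = FALSE],
    pop$genotypes[bulks$low, , drop = FALSE],
    pop$map, params
  )
  truth <- pop$truth
  truth$high_bulk <- bulks$high
  truth$low_bulk <- bulks$low
  out <- list(variants = variants, map = pop$map,
              phenotypes = pop$phenotypes, truth = truth)
  if (keep_genotypes) out$genotypes <- pop$genotypes
  out
}

#' Write pooled variants as a two-sample VCF
#'
#' Emits a plain-text VCF 4.2 with per-sample `AD` allelic depths, the site
#' base quality in `QUAL` and the mapping quality in `INFO/MQ` — the exact
#' dialect [parse_pooled_vcf()] reads, so a write/parse round trip
#' reproduces every count and quality.
#'
#' @param variants a `pooled_variants` table.
#' @param path output path.
#' @param high_sample,low_sample sample names to write (defaults `"SL"` dark
#'   and `"QL"` light).
#' @return the path, invisibly.
#' @export
write_fixture_vcf <- function(variants, path,
                              high_sample = "SL", low_sample = "QL") {
  variants <- validate_pooled_variants(variants)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=bsascan-simulated",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           high_sample, "\t", low_sample)
  )
  body <- character(0)
  if (nrow(variants)) {
    body <- sprintf("%s\t%d\t.\t%s\t%s\t%.10g\t.\tMQ=%.10g\tAD\t%d,%d\t%d,%d",
                    variants$chrom, variants$pos, variants$ref, variants$alt,
                    variants$bq, variants$mq,
                    variants$high_ref, variants$high_alt,
                    variants$low_ref, variants$low_alt)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
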