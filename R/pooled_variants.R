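#' Construct a pooled-variant table
#'
#' A pooled-variant table is the atom of a bulked-segregant scan: one row per
#' biallelic SNP, carrying per-bulk reference/alternate read counts for the
#' high (dark) and low (light) phenotype pools plus site-level quality
#' metadata. All downstream statistics (SNP-index, delta(SNP-index)) are
#' computed from these counts.
#'
#' @param chrom character vector of chromosome identifiers.
#' @param pos integer vector of 1-based genomic coordinates (bp).
#' @param ref,alt single-character reference and alternate (mutant) alleles;
#'   the alternate allele is the one carried by the non-reference parent.
#' @param high_ref,high_alt read counts for the high (dark) bulk.
#' @param low_ref,low_alt read counts for the low (light) bulk.
#' @param bq Phred-scaled site base quality.
#' @param mq Phred-scaled RMS mapping quality.
#'
#' @return A `data.frame` of class `pooled_variants`, sorted by
#'   (`chrom`, `pos`), with the nine columns named above.
#' @seealso [parse_pooled_vcf()], [read_site_table()], [filter_snps()]
#' @export
pooled_variants <- function(chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            high_ref = integer(), high_alt = integer(),
                            low_ref = integer(), low_alt = integer(),
                            bq = numeric(), mq = numeric()) {
  x <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    high_ref = as.integer(high_ref), high_alt = as.integer(high_alt),
    low_ref = as.integer(low_ref), low_alt = as.integer(low_alt),
    bq = as.numeric(bq), mq = as.numeric(mq),
    stringsAsFactors = FALSE
  )
  x <- x[order(x$chrom, x$pos), , drop = FALSE]
  rownames(x) <- NULL
  validate_pooled_variants(x)
}

#' Validate a pooled-variant table
#'
#' Checks the structural invariants: positive 1-based coordinates,
#' single-nucleotide alleles in A/C/G/T with `ref != alt`, non-negative
#' counts and qualities.
#'
#' @param x a candidate pooled-variant table.
#' @return `x`, with class `pooled_variants` prepended, invisibly unchanged.
#' @export
validate_pooled_variants <- function(x) {
  needed <- c("chrom", "pos", "ref", "alt", "high_ref", "high_alt",
              "low_ref", "low_alt", "bq", "mq")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    stop("pooled-variant table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(x)) {
    if (any(x$pos < 1L)) stop("positions must be 1-based (pos >= 1)")
    ok_allele <- function(a) a %in% c("A", "C", "G", "T")
    if (!all(ok_allele(x$ref)) || !all(ok_allele(x$alt))) {
      stop("alleles must be single characters in {A,C,G,T}")
    }
    if (any(x$ref == x$alt)) stop("ref and alt alleles must differ")
    cnt <- as.matrix(x[c("high_ref", "high_alt", "low_ref", "low_alt")])
    if (any(cnt < 0L)) stop("read counts must be non-negative")
    if (any(x$bq < 0 | x$mq < 0, na.rm = TRUE)) {
      stop("quality values must be non-negative")
    }
  }
  class(x) <- unique(c("pooled_variants", class(x)))
  x
}

#' Quality-filter thresholds for pooled SNPs
#'
#' Sites are *kept* when base quality >= `min_base_quality`, mapping quality
#' >= `min_mapping_quality`, and read depth >= `min_depth` in both bulks.
#' The defaults reproduce the conventional BSA-seq exclusion of sites with
#' base quality below 30, depth below 2x, or mapping quality below 30.
#'
#' @param min_base_quality minimum Phred base quality (default 30).
#' @param min_depth minimum per-bulk read depth (default 2). The depth rule is
#'   applied per bulk: SNP-index is undefined for a zero-depth pool, so both
#'   pools must reach the threshold.
#' @param min_mapping_quality minimum Phred mapping quality (default 30).
#' @return a list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_base_quality = 30, min_depth = 2,
                              min_mapping_quality = 30) {
  stopifnot(min_base_quality >= 0, min_depth >= 0, min_mapping_quality >= 0)
  structure(
    list(min_base_quality = min_base_quality,
         min_depth = min_depth,
         min_mapping_quality = min_mapping_quality),
    class = "filter_thresholds"
  )
}

#' Filter pooled SNPs on quality and depth
#'
#' Retains exactly the sites satisfying all three predicates of
#' [filter_thresholds()] (thresholds are inclusive-keep: "< 30 excluded"
#' means ">= 30 kept"); input order is preserved. The number of sites failing
#' each rule is tallied (a site may fail several rules and is counted in each
#' tally) and attached as the `filter_tally` attribute, also retrievable via
#' [filter_tally()].
#'
#' @param variants a `pooled_variants` table.
#' @param thresholds a [filter_thresholds()] object.
#' @param quiet suppress the key=value log lines.
#' @return the retained `pooled_variants` subset, with attribute
#'   `filter_tally = c(bq=, depth=, mq=)`.
#' @export
filter_snps <- function(variants, thresholds = filter_thresholds(),
                        quiet = FALSE) {
  variants <- validate_pooled_variants(variants)
  stopifnot(inherits(thresholds, "filter_thresholds"))
  depth_high <- variants$high_ref + variants$high_alt
  depth_low <- variants$low_ref + variants$low_alt
  pass_bq <- variants$bq >= thresholds$min_base_quality
  pass_mq <- variants$mq >= thresholds$min_mapping_quality
  pass_depth <- depth_high >= thresholds$min_depth &
    depth_low >= thresholds$min_depth
  keep <- pass_bq & pass_mq & pass_depth
  tally <- c(bq = sum(!pass_bq), depth = sum(!pass_depth), mq = sum(!pass_mq))
  if (!quiet) {
    message(sprintf("filter_snps: kept=%d excluded_bq=%d excluded_depth=%d excluded_mq=%d",
                    sum(keep), tally[["bq"]], tally[["depth"]], tally[["mq"]]))
  }
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_tally") <- tally
  out
}

#' @rdname filter_snps
#' @param x a table returned by [filter_snps()].
#' @export
filter_tally <- function(x) attr(x, "filter_tally")

#' Parse a two-sample pooled VCF
#'
#' Reads a VCF 4.x file holding the two bulk samples, keeps biallelic SNP
#' lines and returns them as a [pooled_variants()] table sorted by
#' (chrom, pos). Per-bulk depths are taken from the per-sample `AD` allelic
#' depths, never from the `DP` field. Site base quality is the VCF `QUAL`
#' column and mapping quality the `INFO/MQ` field (both required on retained
#' lines). Multiallelic and indel lines are skipped; the skip count is
#' attached as attribute `n_skipped` and logged.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param high_sample,low_sample sample names of the high (dark) and low
#'   (light) bulk; both must be present in the VCF header.
#' @param quiet suppress log lines.
#' @return a `pooled_variants` table with attribute `n_skipped`.
#' @export
parse_pooled_vcf <- function(path, high_sample, low_sample, quiet = FALSE) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  for (s in c(high_sample, low_sample)) {
    if (!s %in% samples) {
      stop("sample '", s, "' not present in VCF header (found: ",
           paste(samples, collapse = ", "), ")")
    }
  }
  fix <- vcf@fix  # always a character matrix, even for 0 or 1 rows
  if (is.null(fix) || nrow(fix) == 0L) {
    out <- pooled_variants()
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  snp_like <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")
  keep <- snp_like(fix$REF) & snp_like(fix$ALT)
  n_skipped <- sum(!keep)
  if (!quiet) {
    message(sprintf("parse_pooled_vcf: sites=%d skipped_non_biallelic_snp=%d",
                    nrow(fix), n_skipped))
  }
  if (!any(keep)) {
    out <- pooled_variants()
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = "MQ")))
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  idx <- which(keep)
  parse_ad <- function(cell, line) {
    if (is.na(cell) || !nzchar(cell)) {
      stop("missing AD allelic depths at VCF data line ", line)
    }
    parts <- suppressWarnings(as.integer(strsplit(cell, ",", fixed = TRUE)[[1]]))
    if (length(parts) != 2L || anyNA(parts)) {
      stop("malformed AD field '", cell, "' at VCF data line ", line)
    }
    parts
  }
  if (is.null(ad)) stop("VCF has no per-sample AD allelic-depth field")
  hi <- vapply(idx, function(i) parse_ad(ad[i, high_sample], i), integer(2))
  lo <- vapply(idx, function(i) parse_ad(ad[i, low_sample], i), integer(2))
  if (anyNA(qual[idx])) {
    stop("missing QUAL (site base quality) at VCF data line ",
         idx[which(is.na(qual[idx]))[1]])
  }
  if (anyNA(mq[idx])) {
    stop("missing INFO/MQ (mapping quality) at VCF data line ",
         idx[which(is.na(mq[idx]))[1]])
  }
  out <- pooled_variants(
    chrom = fix$CHROM[idx], pos = as.integer(fix$POS[idx]),
    ref = fix$REF[idx], alt = fix$ALT[idx],
    high_ref = hi[1, ], high_alt = hi[2, ],
    low_ref = lo[1, ], low_alt = lo[2, ],
    bq = qual[idx], mq = mq[idx]
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read a tab-separated site table
#'
#' Alternative input route for callers without VCFs: a TSV with header
#' `chrom pos ref alt high_ref high_alt low_ref low_alt bq mq`.
#'
#' @param path path to the TSV file.
#' @return a `pooled_variants` table.
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) stop("site table not found: ", path)
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "#")
  do.call(pooled_variants, x[c("chrom", "pos", "ref", "alt", "high_ref",
                               "high_alt", "low_ref", "low_alt", "bq", "mq")])
}
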