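#' SNP-index of a bulk at one site
#'
#' The SNP-index is the proportion of reads covering a site that carry the
#' non-reference (mutant) allele: 0 when every read matches the reference,
#' 1 when every read carries the mutant allele.
#'
#' @param ref_count,alt_count reference / alternate read counts (vectorised).
#' @return numeric vector of proportions in \[0, 1\].
#' @export
snp_index <- function(ref_count, alt_count) {
  if (any(ref_count < 0 | alt_count < 0)) stop("read counts must be >= 0")
  depth <- ref_count + alt_count
  if (any(depth == 0)) {
    stop("SNP-index undefined at zero depth (site index ",
         which(depth == 0)[1], "); filter such sites first")
  }
  alt_count / depth
}

#' Delta(SNP-index) between the two bulks
#'
#' The scan statistic: SNP-index of the high (dark) bulk minus SNP-index of
#' the low (light) bulk. Near 0 at loci unlinked to the trait; approaches
#' +1/-1 where extreme bulks are fixed for opposite parental alleles.
#'
#' @param index_high,index_low per-bulk SNP-index values in \[0, 1\].
#' @return numeric vector in \[-1, 1\].
#' @export
delta_snp_index <- function(index_high, index_low) {
  if (any(index_high < 0 | index_high > 1 | index_low < 0 | index_low > 1)) {
    stop("SNP-index values must lie in [0, 1]")
  }
  index_high - index_low
}

#' Per-site SNP-index records for a scan
#'
#' Applies [snp_index()] to both bulks of every site and forms the
#' per-site delta. Input must already be depth-filtered so both bulks cover
#' every site.
#'
#' @param variants a `pooled_variants` table with depth >= 1 in both bulks.
#' @return a `data.frame` of class `snp_index_records` with columns
#'   `chrom, pos, index_high, index_low, delta, depth_high, depth_low`,
#'   one row per input site in the same order.
#' @export
compute_indices <- function(variants) {
  variants <- validate_pooled_variants(variants)
  if (!nrow(variants)) {
    out <- data.frame(chrom = character(), pos = integer(),
                      index_high = numeric(), index_low = numeric(),
                      delta = numeric(), depth_high = integer(),
                      depth_low = integer(), stringsAsFactors = FALSE)
    class(out) <- c("snp_index_records", class(out))
    return(out)
  }
  depth_high <- variants$high_ref + variants$high_alt
  depth_low <- variants$low_ref + variants$low_alt
  bad <- which(depth_high == 0 | depth_low == 0)
  if (length(bad)) {
    stop("zero-depth bulk at ", variants$chrom[bad[1]], ":",
         variants$pos[bad[1]], "; apply filter_snps() first")
  }
  ih <- snp_index(variants$high_ref, variants$high_alt)
  il <- snp_index(variants$low_ref, variants$low_alt)
  out <- data.frame(
    chrom = variants$chrom, pos = variants$pos,
    index_high = ih, index_low = il,
    delta = delta_snp_index(ih, il),
    depth_high = depth_high, depth_low = depth_low,
    stringsAsFactors = FALSE
  )
  class(out) <- c("snp_index_records", class(out))
  out
}

#' Sliding-window configuration
#'
#' @param window_size window width in bp (default 1 Mb).
#' @param step window increment in bp (default 10 kb).
#' @return a list of class `window_config`.
#' @export
window_config <- function(window_size = 1e6, step = 1e4) {
  stopifnot(window_size > 0, step > 0, step <= window_size)
  structure(list(window_size = as.numeric(window_size),
                 step = as.numeric(step)),
            class = "window_config")
}

#' Sliding-window means of SNP-index statistics
#'
#' Windows are anchored at coordinate 1 on each chromosome and advance by
#' `step`: starts 1, 1+step, 1+2*step, ... while the start lies within the
#' chromosome. A site at `pos` belongs to the 1-based closed interval
#' \[start, start + window_size - 1\]. Each emitted window carries the
#' unweighted arithmetic means of its member sites; windows containing no
#' site are omitted. `midpoint` (start + window_size/2, clipped to the
#' chromosome end) is the plotting coordinate, and `mean_depth` — the mean
#' over member sites of the per-site average of the two bulk depths — is the
#' representative depth used to look up the null confidence band.
#'
#' @param records a `snp_index_records` table sorted by (chrom, pos).
#' @param cfg a [window_config()].
#' @param chrom_lengths named numeric vector mapping every chromosome present
#'   in `records` to its length in bp.
#' @return a `data.frame` of class `window_stats` with columns `chrom, start,
#'   end, midpoint, n_snps, mean_index_high, mean_index_low, mean_delta,
#'   mean_depth`.
#' @export
sliding_window <- function(records, cfg = window_config(), chrom_lengths) {
  stopifnot(inherits(cfg, "window_config"))
  chroms <- unique(records$chrom)
  unknown <- setdiff(chroms, names(chrom_lengths))
  if (length(unknown)) {
    stop("chromosome(s) absent from chrom_lengths: ",
         paste(unknown, collapse = ", "))
  }
  if (nrow(records) && anyDuplicated(rle(records$chrom)$values)) {
    stop("records must be sorted by (chrom, pos): chromosome blocks split")
  }
  ws <- cfg$window_size
  step <- cfg$step
  res <- vector("list", length(chroms))
  for (k in seq_along(chroms)) {
    ch <- chroms[k]
    r <- records[records$chrom == ch, , drop = FALSE]
    if (is.unsorted(r$pos)) stop("records must be sorted by (chrom, pos)")
    clen <- chrom_lengths[[ch]]
    starts <- seq(1, clen, by = step)
    pos <- r$pos
    # window [s, s+ws-1]: member sites via cumulative sums over sorted pos
    i_lo <- findInterval(starts - 1, pos)     # sites with pos <= s-1
    i_hi <- findInterval(starts + ws - 1, pos) # sites with pos <= s+ws-1
    n <- i_hi - i_lo
    keep <- n > 0L
    if (!any(keep)) next
    cs <- function(v) cumsum(c(0, v))
    cs_ih <- cs(r$index_high); cs_il <- cs(r$index_low)
    cs_d <- cs(r$delta)
    cs_dp <- cs((r$depth_high + r$depth_low) / 2)
    s <- starts[keep]
    lo1 <- i_lo[keep] + 1L  # cumsum index of the last site before the window
    hi1 <- i_hi[keep] + 1L  # cumsum index of the last site inside the window
    nk <- n[keep]
    res[[k]] <- data.frame(
      chrom = ch,
      start = s,
      end = pmin(s + ws - 1, clen),
      midpoint = pmin(s + ws / 2, clen),
      n_snps = nk,
      mean_index_high = (cs_ih[hi1] - cs_ih[lo1]) / nk,
      mean_index_low = (cs_il[hi1] - cs_il[lo1]) / nk,
      mean_delta = (cs_d[hi1] - cs_d[lo1]) / nk,
      mean_depth = (cs_dp[hi1] - cs_dp[lo1]) / nk,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      midpoint = numeric(), n_snps = integer(),
                      mean_index_high = numeric(), mean_index_low = numeric(),
                      mean_delta = numeric(), mean_depth = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  class(out) <- c("window_stats", class(out))
  out
}

#' Write a window table as TSV
#'
#' @param windows a `window_stats` table.
#' @param path output path.
#' @export
write_windows <- function(windows, path) {
  utils::write.table(windows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
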