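#' Call candidate QTL regions from windowed delta(SNP-index)
#'
#' A window is significant when its `mean_delta` exceeds the upper bound, or
#' falls below the lower bound, of the null band looked up at the window's
#' `mean_depth` (see [lookup_ci()]). Maximal runs of
#' overlapping-or-adjacent significant windows of the same sign on one
#' chromosome are merged into a region; significance requires sign
#' consistency throughout, which prevents merging opposite-effect artifacts.
#'
#' @param windows a `window_stats` table sorted by (chrom, start).
#' @param table a `null_ci_table` covering the relevant depths.
#' @param level coverage level of the band to use (e.g. 0.99 for the
#'   P < 0.01 threshold).
#' @param min_windows minimum run length for a reported region (default 1,
#'   i.e. a single isolated significant window qualifies).
#' @return a `data.frame` with one row per region: `chrom, start, end, level,
#'   sign, peak_delta, n_windows`. `peak_delta` is the maximum absolute
#'   `mean_delta` among member windows.
#' @export
call_candidate_regions <- function(windows, table, level = 0.99,
                                   min_windows = 1L) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      level = numeric(), sign = integer(),
                      peak_delta = numeric(), n_windows = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(windows)) return(empty)
  band <- lookup_ci(table, windows$mean_depth, level)
  if (is.null(dim(band))) band <- matrix(band, nrow = 1,
                                         dimnames = list(NULL, c("lower", "upper")))
  sig <- ifelse(windows$mean_delta > band[, "upper"], 1L,
                ifelse(windows$mean_delta < band[, "lower"], -1L, 0L))
  regions <- list()
  n <- nrow(windows)
  i <- 1L
  while (i <= n) {
    if (sig[i] == 0L) { i <- i + 1L; next }
    j <- i
    while (j < n &&
           sig[j + 1L] == sig[i] &&
           windows$chrom[j + 1L] == windows$chrom[i] &&
           windows$start[j + 1L] <= windows$end[j] + 1) {
      j <- j + 1L
    }
    if (j - i + 1L >= min_windows) {
      mem <- i:j
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = windows$chrom[i],
        start = min(windows$start[mem]),
        end = max(windows$end[mem]),
        level = level,
        sign = sig[i],
        peak_delta = max(abs(windows$mean_delta[mem])),
        n_windows = j - i + 1L,
        stringsAsFactors = FALSE
      )
    }
    i <- j + 1L
  }
  if (!length(regions)) return(empty)
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  out
}

#' Span between two flanking markers
#'
#' Marker-to-marker distance as the simple coordinate difference, with the
#' conventional rounding to whole kilobases used when quoting fine-mapping
#' intervals (e.g. markers at 39,531,980 and 39,626,163 bp span 94,183 bp,
#' quoted as a 94-kb interval).
#'
#' @param left_pos,right_pos 1-based positions of the flanking markers;
#'   `left_pos` must be strictly smaller.
#' @return a list with `bp` (exact span) and `kb` (span rounded to the
#'   nearest integer kilobase).
#' @export
interval_length <- function(left_pos, right_pos) {
  if (any(left_pos >= right_pos)) {
    stop("left_pos must be strictly smaller than right_pos")
  }
  bp <- right_pos - left_pos
  list(bp = bp, kb = round(bp / 1000))
}

#' Single-marker LOD / PVE scan
#'
#' For each marker, fits genotype-class means to the phenotype by least
#' squares and compares against the grand-mean null:
#' LOD = (n/2) * log10(RSS_null / RSS_full) and
#' PVE = 1 - RSS_full / RSS_null. This is the standard single-marker
#' regression scan; it makes no use of a linkage map and is intended for
#' synthetic-data validation, not as a substitute for multiple-QTL mapping.
#'
#' @param genotypes integer matrix, individuals x markers, with allele
#'   dosages in \{0, 1, 2\} (absent classes are allowed at any marker).
#' @param phenotypes numeric vector, one value per individual, no missing
#'   values.
#' @return a `data.frame` with columns `marker, lod, pve`, one row per
#'   marker (marker names from `colnames(genotypes)` when present). A
#'   constant phenotype yields LOD 0 and PVE 0 everywhere; a marker whose
#'   class means fit the phenotype perfectly yields PVE 1 and infinite LOD.
#' @export
single_marker_scan <- function(genotypes, phenotypes) {
  genotypes <- as.matrix(genotypes)
  n <- length(phenotypes)
  stopifnot(nrow(genotypes) == n, !anyNA(phenotypes))
  m <- ncol(genotypes)
  rss_null <- sum((phenotypes - mean(phenotypes))^2)
  lod <- numeric(m)
  pve <- numeric(m)
  if (rss_null > 0) {
    for (j in seq_len(m)) {
      g <- genotypes[, j]
      cls <- g + 1L
      cnt <- tabulate(cls, nbins = 3L)
      sums <- vapply(1:3, function(k) sum(phenotypes[cls == k]), numeric(1))
      mu <- ifelse(cnt > 0, sums / pmax(cnt, 1L), 0)
      fitted <- mu[cls]
      rss_full <- sum((phenotypes - fitted)^2)
      lod[j] <- (n / 2) * log10(rss_null / rss_full)
      pve[j] <- 1 - rss_full / rss_null
    }
  }
  marker <- colnames(genotypes)
  if (is.null(marker)) marker <- paste0("m", seq_len(m))
  data.frame(marker = marker, lod = lod, pve = pve, stringsAsFactors = FALSE)
}

#' Export regions as BED
#'
#' Converts the internal 1-based closed intervals to BED's 0-based
#' half-open convention (start - 1, end).
#'
#' @param regions a [call_candidate_regions()] result.
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = format(regions$start - 1, scientific = FALSE, trim = TRUE),
                    end = format(regions$end, scientific = FALSE, trim = TRUE),
                    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
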