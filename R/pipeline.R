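#' Run the full bulked-segregant scan
#'
#' Composes the stages: parse (optional) -> quality filter -> per-site
#' indices -> sliding windows -> null band -> candidate regions. All
#' randomness lives in the null-band simulation and is governed by the seed
#' inside `ci_config`; a rerun with identical inputs and config reproduces
#' every table bit for bit.
#'
#' @param variants a `pooled_variants` table, or `NULL` if `vcf` is given.
#' @param vcf optional path to a two-sample VCF (parsed with
#'   [parse_pooled_vcf()]).
#' @param high_sample,low_sample sample names when reading from `vcf`.
#' @param thresholds a [filter_thresholds()].
#' @param window_cfg a [window_config()].
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param ci_table a prebuilt [build_ci_table()] result (e.g. reloaded from
#'   cache); when `NULL` one is built from `ci_config`.
#' @param ci_config a [null_sim_config()] used when `ci_table` is `NULL`.
#' @param level band coverage level for region calling (default 0.99, the
#'   P < 0.01 threshold).
#' @param out_dir optional directory; when given, the window table, region
#'   table (TSV and BED) and filter log are written there.
#' @param quiet suppress log lines.
#' @return a list with `indices`, `windows`, `regions`, `ci_table`, and
#'   `filter_tally`.
#' @export
run_scan <- function(variants = NULL, vcf = NULL,
                     high_sample = "SL", low_sample = "QL",
                     thresholds = filter_thresholds(),
                     window_cfg = window_config(),
                     chrom_lengths,
                     ci_table = NULL, ci_config = null_sim_config(),
                     level = 0.99, out_dir = NULL, quiet = FALSE) {
  if (is.null(variants)) {
    if (is.null(vcf)) stop("provide either `variants` or `vcf`")
    variants <- parse_pooled_vcf(vcf, high_sample, low_sample, quiet = quiet)
  }
  kept <- filter_snps(variants, thresholds, quiet = quiet)
  tally <- filter_tally(kept)
  if (is.null(ci_table)) ci_table <- build_ci_table(ci_config)
  if (!nrow(kept)) warning("no variants pass the quality filter; empty scan")
  indices <- compute_indices(kept)
  windows <- sliding_window(indices, window_cfg, chrom_lengths)
  regions <- call_candidate_regions(windows, ci_table, level)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_windows(windows, file.path(out_dir, "windows.tsv"))
    utils::write.table(regions, file.path(out_dir, "regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_regions_bed(regions, file.path(out_dir, "regions.bed"))
    writeLines(sprintf("%s=%d", names(tally), tally),
               file.path(out_dir, "filter_log.txt"))
  }
  list(indices = indices, windows = windows, regions = regions,
       ci_table = ci_table, filter_tally = tally)
}

#' Simulate an experiment and write its fixture bundle
#'
#' Runs [simulate_bsa_experiment()] and writes the two-sample VCF, a truth
#' TSV (QTL location and bulk membership), and phenotype/genotype TSVs for
#' the single-marker scan.
#'
#' @param params an [f2_sim_params()] object.
#' @param out_dir output directory (created if needed).
#' @param marker_stride keep every `marker_stride`-th marker in the genotype
#'   TSV (the causal marker is always kept); default 50 keeps the file small.
#' @return the [simulate_bsa_experiment()] result, invisibly.
#' @export
run_simulate <- function(params = f2_sim_params(), out_dir,
                         marker_stride = 50L) {
  if (params$n_f2 < 2L * params$pool_size) {
    stop("n_f2 must be at least 2 * pool_size")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  expt <- simulate_bsa_experiment(params, keep_genotypes = TRUE)
  write_fixture_vcf(expt$variants, file.path(out_dir, "pools.vcf"))
  truth_df <- data.frame(
    key = c("qtl_chrom", "qtl_pos", "qtl_marker",
            "high_bulk", "low_bulk"),
    value = c(expt$truth$qtl_chrom, expt$truth$qtl_pos,
              expt$truth$qtl_marker,
              paste(expt$truth$high_bulk, collapse = ","),
              paste(expt$truth$low_bulk, collapse = ",")),
    stringsAsFactors = FALSE
  )
  utils::write.table(truth_df, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  keep <- sort(unique(c(seq(1L, nrow(expt$map), by = marker_stride),
                        expt$truth$qtl_marker)))
  geno <- as.data.frame(expt$genotypes[, keep, drop = FALSE])
  names(geno) <- paste0(expt$map$chrom[keep], "_", expt$map$pos[keep])
  pheno_geno <- cbind(data.frame(individual = seq_along(expt$phenotypes),
                                 phenotype = expt$phenotypes), geno)
  utils::write.table(pheno_geno, file.path(out_dir, "pheno_geno.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(expt)
}

#' Plot the windowed delta(SNP-index) scan with its null band
#'
#' One panel per chromosome: the windowed mean delta(SNP-index) against the
#' window midpoint, with the two-sided null band (looked up per window from
#' its mean depth) drawn as dashed lines.
#'
#' @param windows a `window_stats` table.
#' @param ci_table a `null_ci_table`.
#' @param level band coverage level to draw.
#' @return a ggplot object.
#' @export
plot_scan <- function(windows, ci_table, level = 0.99) {
  band <- lookup_ci(ci_table, windows$mean_depth, level)
  if (is.null(dim(band))) band <- matrix(band, nrow = 1,
                                         dimnames = list(NULL, c("lower", "upper")))
  df <- cbind(windows, lower = band[, "lower"], upper = band[, "upper"])
  ggplot2::ggplot(df, ggplot2::aes(x = midpoint / 1e6)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = mean_delta), colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = upper), colour = "red",
                       linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = lower), colour = "red",
                       linetype = "dashed") +
    ggplot2::facet_wrap(~chrom, nrow = 1, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "Δ(SNP-index)") +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_bw()
}
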