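#!/usr/bin/env Rscript
# Stage 3: single-marker LOD / PVE scan of the F2 population.
#
# Uses the thinned genotype/phenotype table written by stage 1 (all 278
# individuals, every 50th marker plus the causal one) and fits genotype-class
# means per marker: LOD = (n/2) log10(RSS_null/RSS_full),
# PVE = 1 - RSS_full/RSS_null.

suppressPackageStartupMessages(library(bsascan))

pg_path <- file.path("results", "simulated", "pheno_geno.tsv")
if (!file.exists(pg_path)) stop("run analysis/01_simulate.R first")
pg <- utils::read.table(pg_path, header = TRUE, sep = "\t",
                        check.names = FALSE)
geno <- as.matrix(pg[, -(1:2)])
scan <- single_marker_scan(geno, pg$phenotype)

utils::write.table(scan, file.path("results", "qtl_scan.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

peak <- scan[which.max(scan$lod), ]
message("scanned ", nrow(scan), " markers in ", nrow(pg), " individuals")
message(sprintf("peak marker %s: LOD = %.1f, PVE = %.1f%%",
                peak$marker, peak$lod, 100 * peak$pve))
truth <- utils::read.table(file.path("results", "simulated", "truth.tsv"),
                           header = TRUE, sep = "\t")
causal <- paste0(truth$value[truth$key == "qtl_chrom"], "_",
                 truth$value[truth$key == "qtl_pos"])
at_causal <- scan[scan$marker == causal, ]
message(sprintf("causal marker %s: LOD = %.1f, PVE = %.1f%%",
                causal, at_causal$lod, 100 * at_causal$pve))
message("table -> results/qtl_scan.tsv")
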