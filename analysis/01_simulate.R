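#!/usr/bin/env Rscript
# Stage 1: forward-simulate the bulked-segregant experiment.
#
# Generates the default design — 278 F2 plants from two inbred parents, an
# incompletely dominant pericarp-color locus on chr3 at 20 Mb, extreme bulks
# of 20 light and 20 dark individuals, pooled sequencing at ~20x — and
# writes the pipeline-ready fixture bundle (two-sample VCF, truth table,
# phenotype/genotype table) under results/simulated/.

suppressPackageStartupMessages(library(bsascan))

params <- f2_sim_params(seed = 1L)
out_dir <- file.path("results", "simulated")
expt <- run_simulate(params, out_dir, marker_stride = 50L)

message("wrote ", out_dir, ": ",
        nrow(expt$variants), " pooled SNPs across ",
        length(params$chrom_lengths), " chromosomes")
message("planted QTL: ", expt$truth$qtl_chrom, ":",
        format(expt$truth$qtl_pos, scientific = FALSE),
        " (marker #", expt$truth$qtl_marker, ")")
message("bulk phenotype ranges: dark [",
        round(min(expt$phenotypes[expt$truth$high_bulk]), 2), ", ",
        round(max(expt$phenotypes[expt$truth$high_bulk]), 2), "], light [",
        round(min(expt$phenotypes[expt$truth$low_bulk]), 2), ", ",
        round(max(expt$phenotypes[expt$truth$low_bulk]), 2), "]")
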