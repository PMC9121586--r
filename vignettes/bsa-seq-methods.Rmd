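---
title: "Methods: the bulked-segregant scan and its simulated validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the bulked-segregant scan and its simulated validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The statistic

At a biallelic SNP distinguishing two inbred parents, a pool of reads from a
DNA bulk estimates the bulk's allele frequency. With the reference genome
identified with one parent, the SNP-index of a bulk is the fraction of its
reads carrying the other parent's ("mutant") allele, and the scan statistic
is

$$\Delta(\text{SNP-index}) \;=\; \frac{a_H}{a_H + r_H} - \frac{a_L}{a_L + r_L},$$

where $a$ and $r$ are alternate and reference read counts in the high ($H$)
and low ($L$) phenotype bulks. Under extreme-tail selection on a trait
controlled by a major locus, the bulks become enriched for opposite alleles
around that locus, so $\Delta$ approaches $\pm 1$ there and stays near 0 at
unlinked loci. The sign convention — high bulk minus low bulk, with the
alternate allele belonging to the high-phenotype parent — makes the expected
signal positive.

Assumptions: sites are fully informative (the parents are fixed for
alternate alleles; the simulator guarantees this by construction, and for
real data a parental filter should be applied upstream), reads are sampled
independently given the pool allele frequency, and the two bulks are
sequenced independently.

## Quality filtering

Sites are kept when base quality $\ge 30$, mapping quality $\ge 30$, and
read depth $\ge 2$. Two reading choices were genuinely open and are fixed as
follows:

* **Per-bulk depth.** The depth rule is applied to each bulk separately
  rather than to the summed depth, because the SNP-index of a zero-depth
  bulk is undefined; requiring both bulks to reach the threshold guarantees
  downstream definedness.
* **Inclusive keep.** "Below 30 excluded" is implemented as "at least 30
  kept", i.e. the boundary value passes.

`filter_snps()` reports how many sites each rule excluded (a site failing
several rules is counted under each), which makes filter audits cheap.

## Sliding windows

The per-site indices are smoothed with a 1-Mb window advanced in 10-kb
steps. Conventions that the windowed statistic needs but that are not
implied by "window size and increment" alone:

* Windows are anchored at coordinate 1 on every chromosome and use 1-based
  closed intervals, matching VCF coordinates; with `step = window_size` the
  windows tile the chromosome exactly, which is one of the tested
  invariants.
* Window means are plain, unweighted arithmetic means over member sites —
  the literal reading of "average SNP-index". Depth weighting is deliberately
  not offered.
* Windows with no member SNPs are omitted rather than emitted as missing:
  scan plots then interpolate across SNP deserts instead of dropping to an
  arbitrary value.
* Each window's plotting coordinate is its midpoint (start + half the
  window size, clipped to the chromosome end), and its representative depth
  for band lookup is the mean over member sites of the per-site average of
  the two bulk depths: one band per window needs one depth.

Window means are computed with per-chromosome cumulative sums
($O(\text{sites} + \text{windows})$) and are tested against a quadratic
brute-force oracle to $10^{-12}$.

## The null band

The significance threshold is a depth-conditional empirical band of
$\Delta$ under the hypothesis of **no QTL anywhere linked to the marker**:
each Monte-Carlo replicate draws two bulks of `pool_size` *unselected*
progeny from the cross's segregation (F2 dosages 0/1/2 with probabilities
¼, ½, ¼; RIL 0/2 equiprobable; BC1 0/1 equiprobable), forms each pool's
allele frequency, samples each bulk's alternate read count
$\mathrm{Binomial}(\text{depth}, p)$, and records $\Delta$. Phenotypic
selection is absent from the null by design: at an unlinked marker the
extreme bulks are exchangeable random samples. The two-stage draw
(genotypes, then reads) is kept explicitly rather than collapsed into a
beta-binomial so that the pool-size and depth components of variance remain
separate; the genotype stage uses the exact distribution of the dosage
*sum* (for F2, Binomial(2·pool, ½)), which is algebraically identical to
summing individual draws but vectorises.

Numerical choices:

* 10,000 iterations per depth over the grid 1–100×; both bulks share one
  simulated depth per replicate.
* Quantiles are nearest-rank order statistics (`quantile(type = 1)`), the
  simplest reproducible convention at this replicate count; the band at
  level $L$ spans the $(1-L)/2$ and $1-(1-L)/2$ quantiles.
* Band lookup for a (possibly fractional) window depth takes the nearest
  tabulated depth, breaking ties toward the smaller depth — the wider,
  more conservative band — and clamping queries outside the grid.
* Each depth's replicate stream is derived from the run seed by a fixed
  counter scheme, so the table is independent of evaluation order.
* The simulator is validated against exact enumeration of the full
  $\Delta$ distribution for pools of 1–2 at depths up to 3, against the
  analytic 3×3 genotype-pair law for pool size 1 at large depth, and
  against symmetry/centering checks at the default design.

## Region calling

A window is significant when its mean $\Delta$ leaves its band at the
chosen level (0.99 for the conventional P &lt; 0.01 threshold). Maximal
runs of overlapping-or-adjacent significant windows of the same sign merge
into one candidate region; sign consistency prevents fusing
opposite-effect artifacts. A single isolated significant window qualifies
as a region by default (`min_windows = 1`, configurable). Fine-mapping
spans are quoted marker-to-marker as the simple coordinate difference with
nearest-integer kilobase rounding (39,531,980–39,626,163 → 94,183 bp →
94 kb); no end-inclusive +1 is added, since only the simple difference
reproduces that printed arithmetic.

The single-marker scan fits genotype-class means by least squares per
marker: $\mathrm{LOD} = (n/2)\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)$ and
$\mathrm{PVE} = 1 - \mathrm{RSS}_1/\mathrm{RSS}_0$. It is a stand-in for
map-based multiple-QTL mapping, intended for synthetic-data validation
only; a constant phenotype returns LOD 0 and PVE 0, and a perfect fit
returns PVE 1 with infinite LOD.

## What the simulator emulates — and what it does not

`simulate_bsa_experiment()` forward-simulates the full design: two inbred
parents, an F2 of 278 plants, meiosis as a Poisson crossover process
(uniform breakpoints, no interference, no sex differences) at a constant
3.3 cM/Mb on seven 30-Mb chromosomes, parent-informative SNPs as a Poisson
process with 2-kb mean spacing, an incompletely dominant QTL with
phenotype $a(g-1) + d\,[g=1] + \mathcal N(0,\sigma)$, rank selection of the
20 highest and 20 lowest phenotypes into bulks, and pooled reads with
Poisson(20) per-site depth (truncated at 1) and a $10^{-3}$ per-read allele
error. Default choices that were genuinely open:

* $a = 1$, $d = 0.6a$: the heterozygote leans toward the dark-phenotype
  parent, mirroring an F1 that is visually closer to the dark parent.
* $\sigma = 0.5$: the trait is scored as a near-categorical visual scale.
  With these effects the light homozygote class (phenotype $-1$) is
  separated from the heterozygote ($0.6$) by $3.2\sigma$ — essentially
  fully classifiable — while heterozygote and dark homozygote ($1.0$)
  partially overlap. Consequently the low bulk is nearly fixed and the QTL
  region's windowed $\Delta$ reaches ≈ 0.85–0.95, the "close to 1" regime
  a major pericarp-color locus shows.
* The QTL sits at chr3:20 Mb — on the chromosome where such a locus is
  expected but placed interior to the (stylized, equal-length) chromosome
  so that recovery statistics are not confounded by telomere-edge window
  truncation.
* The reference genome is identified with the light parent, so the
  expected QTL-region $\Delta$ is $+1$; real designs where the reference
  is a third line can flip polarity site by site upstream.
* Phenotype is a continuous liability; ordinal color classes are
  reproducible by binning but are unnecessary for rank bulking. Ties in
  rank selection break by index order (low bulk takes earlier indices), a
  documented, deterministic rule.

Not modelled: read-level sequence simulation (FASTQ), mapping bias,
indels and structural variation, crossover interference, non-uniform
recombination maps, segregation distortion, and categorical phenotype
scoring error beyond the Gaussian residual. Passing recovery tests
therefore demonstrate the *pipeline logic* — that the statistic, band and
region caller recover a planted locus under the stated design — not
robustness to alignment artifacts or map heterogeneity in real data.

## Problem sizes and runtime choices

Unit tests run reduced designs (3 × 10-Mb chromosomes, 120 F2, 10-kb SNP
spacing, 2,000–5,000 null iterations) chosen so that the full suite
completes in about two minutes; the end-to-end recovery check runs 20
seeded full-design experiments against a shared 10,000-iteration band
table (the band depends only on pool size, cross and depth grid, so it is
built once and cached — the analysis scripts cache it as
`results/ci_table.tsv`). The analysis scripts and the acceptance script
use the full default design (~105,000 SNPs, 278 F2, depth 20).

## Known limitations

* The band compares a *windowed mean* against a *per-site* null quantile,
  as is conventional for this scan; windows averaging many sites are
  therefore conservative at high SNP density, and candidate regions are
  correspondingly wide. Fine localisation is the job of the marker scan
  and fine-mapping arithmetic, not the window scan.
* The parent-informed site filter (dropping sites heterozygous or missing
  in either parent) is assumed to have been applied upstream; the
  simulator emits only informative sites.
* `single_marker_scan()` ignores linkage between markers and fits each
  marker independently; its PVE at the causal marker exceeds what a
  multiple-QTL model would attribute in the presence of linked background
  variation.
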