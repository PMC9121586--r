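#' Configuration for the no-QTL null simulation
#'
#' The null band of delta(SNP-index) is built by Monte-Carlo: for each read
#' depth, two bulks of random (unselected) progeny are drawn from the cross's
#' segregation, reads are sampled binomially from each bulk's allele
#' frequency, and the per-replicate delta is recorded. Extreme-phenotype
#' selection is deliberately absent — at a marker unlinked to any QTL the
#' bulks are exchangeable random samples, which is exactly the null
#' hypothesis the band encodes.
#'
#' @param pool_size individuals per bulk (default 20).
#' @param population cross type: `"F2"` (dosages 0/1/2 with probability
#'   1/4, 1/2, 1/4), `"RIL"` (0/2 equiprobable) or `"BC1"` (0/1 equiprobable).
#' @param n_iterations Monte-Carlo replicates per depth (default 10,000).
#' @param depths integer grid of read depths to tabulate (default 1:100).
#' @param ci_levels two-sided coverage levels (default 0.95 and 0.99).
#' @param seed integer RNG seed; per-depth streams are derived from it by a
#'   fixed counter scheme so the table does not depend on evaluation order.
#' @return a list of class `null_sim_config`.
#' @export
null_sim_config <- function(pool_size = 20, population = c("F2", "RIL", "BC1"),
                            n_iterations = 10000, depths = 1:100,
                            ci_levels = c(0.95, 0.99), seed = 1L) {
  population <- match.arg(population)
  stopifnot(pool_size >= 1, n_iterations >= 1, length(depths) >= 1,
            all(depths >= 1), all(ci_levels > 0 & ci_levels < 1))
  structure(
    list(pool_size = as.integer(pool_size), population = population,
         n_iterations = as.integer(n_iterations),
         depths = as.integer(depths), ci_levels = sort(ci_levels),
         seed = as.integer(seed)),
    class = "null_sim_config"
  )
}

# Dosage-sum sampler: the sum of pool_size iid cross dosages, drawn from its
# exact distribution (F2 dosage is Binomial(2, 1/2) per individual, so the
# pool sum is Binomial(2*pool, 1/2); RIL and BC1 reduce likewise).
.pool_dosage_sum <- function(n, pool_size, population) {
  switch(population,
    F2 = stats::rbinom(n, 2L * pool_size, 0.5),
    RIL = 2L * stats::rbinom(n, pool_size, 0.5),
    BC1 = stats::rbinom(n, pool_size, 0.5)
  )
}


#' Simulate the null distribution of delta(SNP-index) at one depth
#'
#' One replicate: (i) draw `pool_size` unselected progeny genotypes per bulk
#' from the cross's unlinked-marker segregation; (ii) form each bulk's alt
#' allele frequency p = (sum of dosages) / (2 * pool_size); (iii) draw the
#' bulk's alt read count ~ Binomial(depth, p); (iv) SNP-index = alt reads /
#' depth; (v) delta = high minus low. Deterministic given the config seed
#' and depth.
#'
#' @param cfg a [null_sim_config()].
#' @param depth read depth shared by both bulks.
#' @return numeric vector of `cfg$n_iterations` delta values.
#' @export
simulate_null_delta <- function(cfg, depth) {
  stopifnot(inherits(cfg, "null_sim_config"), depth >= 1)
  depth <- as.integer(depth)
  set.seed((cfg$seed + depth * 131071L) %% .Machine$integer.max)
  n <- cfg$n_iterations
  denom <- 2L * cfg$pool_size  # diploid pool: 2 alleles per individual
  p_high <- .pool_dosage_sum(n, cfg$pool_size, cfg$population) / denom
  p_low <- .pool_dosage_sum(n, cfg$pool_size, cfg$population) / denom
  idx_high <- stats::rbinom(n, depth, p_high) / depth
  idx_low <- stats::rbinom(n, depth, p_low) / depth
  idx_high - idx_low
}

#' Tabulate null confidence bands over a depth grid
#'
#' For every depth in the config grid, simulates the null delta(SNP-index)
#' sample and records its empirical two-sided quantiles (nearest-rank order
#' statistics, `quantile(type = 1)`) at each coverage level: the band at
#' level L spans the (1-L)/2 and 1-(1-L)/2 quantiles.
#'
#' @param cfg a [null_sim_config()].
#' @return a `data.frame` of class `null_ci_table` with columns
#'   `depth, level, lower, upper` and the config stored in attribute
#'   `config`.
#' @export
build_ci_table <- function(cfg = null_sim_config()) {
  stopifnot(inherits(cfg, "null_sim_config"))
  rows <- lapply(cfg$depths, function(d) {
    delta <- simulate_null_delta(cfg, d)
    do.call(rbind, lapply(cfg$ci_levels, function(lev) {
      a <- (1 - lev) / 2
      q <- unname(stats::quantile(delta, probs = c(a, 1 - a), type = 1))
      data.frame(depth = d, level = lev, lower = q[1], upper = q[2])
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- cfg
  class(out) <- c("null_ci_table", class(out))
  out
}

#' Look up the null band for a depth
#'
#' Returns the band tabulated at the grid depth nearest to the query; ties
#' are broken toward the smaller depth (the wider, more conservative band),
#' and queries beyond either end of the grid clamp to the nearest end.
#'
#' @param table a [build_ci_table()] result.
#' @param depth query depth (may be fractional, e.g. a window mean depth);
#'   vectorised.
#' @param level coverage level; must be tabulated.
#' @return for scalar `depth`, a named vector `c(lower=, upper=)`; for
#'   vector `depth`, a two-column matrix.
#' @export
lookup_ci <- function(table, depth, level) {
  stopifnot(inherits(table, "null_ci_table"), nrow(table) > 0)
  sub <- table[table$level == level, , drop = FALSE]
  if (!nrow(sub)) {
    stop("level ", level, " not tabulated; available: ",
         paste(unique(table$level), collapse = ", "))
  }
  sub <- sub[order(sub$depth), , drop = FALSE]
  grid <- sub$depth
  pick <- vapply(depth, function(d) {
    dist <- abs(grid - d)
    cand <- which(dist == min(dist))
    cand[1]  # grid sorted ascending: first candidate is the smaller depth
  }, integer(1))
  out <- cbind(lower = sub$lower[pick], upper = sub$upper[pick])
  if (length(depth) == 1L) {
    out <- c(lower = unname(out[1, 1]), upper = unname(out[1, 2]))
  }
  out
}

#' Serialise / reload a null band table
#'
#' The TSV carries `depth level lower upper` plus `#`-prefixed header lines
#' recording the simulation config and seed; quantiles are written with 17
#' significant digits so the round trip is lossless.
#'
#' @param table a `null_ci_table`.
#' @param path file path.
#' @return `write_ci_table` the path, invisibly; `read_ci_table` the
#'   reloaded `null_ci_table`.
#' @export
write_ci_table <- function(table, path) {
  cfg <- attr(table, "config")
  hdr <- character()
  if (!is.null(cfg)) {
    hdr <- sprintf("# %s=%s",
                   c("pool_size", "population", "n_iterations", "seed"),
                   c(cfg$pool_size, cfg$population, cfg$n_iterations, cfg$seed))
  }
  body <- sprintf("%d\t%.17g\t%.17g\t%.17g",
                  table$depth, table$level, table$lower, table$upper)
  writeLines(c(hdr, "depth\tlevel\tlower\tupper", body), path)
  invisible(path)
}

#' @rdname write_ci_table
#' @export
read_ci_table <- function(path) {
  if (!file.exists(path)) stop("CI table not found: ", path)
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  class(out) <- c("null_ci_table", class(out))
  out
}
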