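#' Comparative-Ct (2^-ddCt) relative expression
#'
#' Per biological replicate: dCt = Ct_target - Ct_reference; ddCt = dCt
#' minus the mean dCt of the calibrator group; fold change = 2^(-ddCt).
#' Technical triplicates are averaged upstream — rows here are biological
#' replicates. By construction the calibrator group's fold changes have
#' geometric mean exactly 1, and all folds are invariant to adding a common
#' constant to every Ct value.
#'
#' @param assay data.frame with columns `group`, `ct_target`,
#'   `ct_reference` (one row per biological replicate; an optional
#'   `replicate` column is carried through).
#' @param calibrator name of the calibrator group (must be present).
#' @return the assay with columns `dct`, `ddct` and `fold` appended.
#' @export
relative_expression <- function(assay, calibrator) {
  stopifnot(all(c("group", "ct_target", "ct_reference") %in% names(assay)))
  if (any(!is.finite(assay$ct_target)) || any(!is.finite(assay$ct_reference))) {
    stop("Ct values must be finite")
  }
  cal <- assay$group == calibrator
  if (!any(cal)) stop("calibrator group '", calibrator, "' has no replicates")
  dct <- assay$ct_target - assay$ct_reference
  ddct <- dct - mean(dct[cal])
  out <- assay
  out$dct <- dct
  out$ddct <- ddct
  out$fold <- 2^(-ddct)
  out
}

#' Two-sample Student's t comparison
#'
#' Classical two-sided pooled-variance Student's t-test of two groups of
#' relative-expression values (Welch's unequal-variance form is available
#' behind `welch = TRUE`). Degenerate input — essentially zero variance in
#' both groups with equal means is allowed only when the groups differ; a
#' fully constant comparison errors.
#'
#' @param group_a,group_b numeric vectors (each length >= 2).
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @param welch use Welch's t instead of the pooled-variance form.
#' @return a list with `t`, `df`, `p`, and `significant` (p < alpha).
#' @export
two_sample_t <- function(group_a, group_b, alpha = 0.05, welch = FALSE) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  fit <- tryCatch(
    stats::t.test(group_a, group_b, var.equal = !welch),
    error = function(e) stop("t-test failed (degenerate variance?): ",
                             conditionMessage(e))
  )
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value, significant = fit$p.value < alpha)
}
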