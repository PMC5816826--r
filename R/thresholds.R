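#' Analysis thresholds
#'
#' Bundles every numeric cutoff used across the pipeline, with the study's
#' published defaults: the 300-aa SSP size limit (strict `<`), the 2.5-fold
#' (linear) MiSSP induction cutoff, the FPKM > 1 expression rule, the
#' |log2FC| > 1 and FDR < 0.05 regulation rule, the 5-fold host-preference
#' rule, the 6,495-bp flanking-intergenic-region cutoff separating the
#' gene-dense (GDR) from the gene-sparse (GSR) genome compartment, the
#' >90\%-of-gene deletion rule for absence calls, and the number of
#' unrestricted permutations used by PERMANOVA.
#'
#' @param ssp_max_len Maximum SSP length in amino acids (exclusive).
#' @param missp_fold Linear fold-change a MiSSP candidate must exceed.
#' @param expressed_fpkm FPKM a gene must exceed to count as expressed.
#' @param reg_lfc Absolute log2 fold-change a regulated gene must exceed.
#' @param reg_fdr FDR below which a regulated call is accepted.
#' @param host_fold Linear fold difference beyond which expression is
#'   considered host-preferential.
#' @param gsr_cutoff_bp Flanking intergenic length (bp) above which a flank
#'   is considered repeat-rich.
#' @param absence_deletion_frac Fraction of a gene that must be deleted
#'   (uncovered by hits) for an absence call.
#' @param n_permutations Default PERMANOVA permutation count.
#'
#' @return A validated list of class `"missp_thresholds"`.
#' @export
#' @examples
#' th <- missp_thresholds()
#' th$gsr_cutoff_bp
missp_thresholds <- function(ssp_max_len = 300,
                             missp_fold = 2.5,
                             expressed_fpkm = 1.0,
                             reg_lfc = 1.0,
                             reg_fdr = 0.05,
                             host_fold = 5.0,
                             gsr_cutoff_bp = 6495,
                             absence_deletion_frac = 0.90,
                             n_permutations = 9999) {
  th <- list(
    ssp_max_len = ssp_max_len,
    missp_fold = missp_fold,
    expressed_fpkm = expressed_fpkm,
    reg_lfc = reg_lfc,
    reg_fdr = reg_fdr,
    host_fold = host_fold,
    gsr_cutoff_bp = gsr_cutoff_bp,
    absence_deletion_frac = absence_deletion_frac,
    n_permutations = n_permutations
  )
  for (nm in names(th)) {
    v <- th[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("threshold '", nm, "' must be a single positive finite number")
  }
  if (th$absence_deletion_frac >= 1)
    stop("threshold 'absence_deletion_frac' must lie in (0, 1)")
  if (th$reg_fdr >= 1)
    stop("threshold 'reg_fdr' must lie in (0, 1)")
  th$n_permutations <- as.integer(th$n_permutations)
  class(th) <- "missp_thresholds"
  th
}

.as_thresholds <- function(thresholds) {
  if (is.null(thresholds)) return(missp_thresholds())
  if (!inherits(thresholds, "missp_thresholds"))
    stop("'thresholds' must be created by missp_thresholds()")
  thresholds
}
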