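# Expression-level utilities: RPKM and the delta-delta-Ct relative
# expression calculation for qRT-PCR.

#' Reads per kilobase per million (RPKM)
#'
#' `count / (gene_length_bp / 1000) / (library_total / 1e6)`.  Vectorised
#' over all arguments.
#'
#' @param count Raw read count(s).
#' @param gene_length_bp Gene length(s) in bp; > 0.
#' @param library_total Library total(s); > 0.
#' @return RPKM value(s).
#' @export
rpkm <- function(count, gene_length_bp, library_total) {
  if (any(gene_length_bp <= 0)) stop("gene_length_bp must be > 0")
  if (any(library_total <= 0)) stop("library_total must be > 0")
  count / (gene_length_bp / 1000) / (library_total / 1e6)
}

#' Relative expression by the delta-delta-Ct method
#'
#' For each sample, `dCt = ct_target - ct_reference` normalises the target
#' gene to the reference gene; `ddCt = dCt - mean(dCt over wild-type
#' samples)` anchors the scale to the wild-type mean, and relative
#' expression is `2^(-ddCt)`.  By construction the geometric mean of the
#' wild-type relative expressions is exactly 1; a sample with ddCt = 1 has
#' half the wild-type expression.
#'
#' @param records Data frame with columns `sample_id`, `genotype`,
#'   `ct_target`, `ct_reference` (finite, positive Ct values).
#' @param wildtype_label Genotype value identifying wild-type samples.
#' @return The input with added columns `d_ct`, `dd_ct` and
#'   `relative_expression`.
#' @export
delta_delta_ct <- function(records, wildtype_label = "WT") {
  need <- c("sample_id", "genotype", "ct_target", "ct_reference")
  missing <- setdiff(need, colnames(records))
  if (length(missing) > 0L) {
    stop("records are missing columns: ", paste(missing, collapse = ", "))
  }
  ct <- c(records$ct_target, records$ct_reference)
  if (any(!is.finite(ct)) || any(ct <= 0)) {
    stop("Ct values must be finite and > 0")
  }
  wt <- records$genotype == wildtype_label
  if (!any(wt)) stop("no wild-type records with genotype ", wildtype_label)
  d_ct <- records$ct_target - records$ct_reference
  dd_ct <- d_ct - mean(d_ct[wt])
  records$d_ct <- d_ct
  records$dd_ct <- dd_ct
  records$relative_expression <- 2^(-dd_ct)
  records
}
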