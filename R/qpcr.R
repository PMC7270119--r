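#' Relative expression by the 2^-ddCt method
#'
#' Computes qPCR relative quantification for one gene: technical-replicate Ct
#' values are averaged on the Ct scale, the reference gene (e.g. actin) is
#' subtracted within each genotype (dCt = Ct_target - Ct_reference), the
#' calibrator genotype's dCt is subtracted (ddCt), and the fold change is
#' `2^(-ddCt)`. Amplification efficiency is fixed at 2, the standard 2^-ddCt
#' assumption.
#'
#' @param records Data frame of Ct measurements with columns `gene_id`,
#'   `genotype_id`, `ct_target`, `ct_reference` and optionally `replicate`
#'   (see [read_qpcr_table()]).
#' @param gene_id Gene to quantify.
#' @param sample_id Genotype whose expression is reported.
#' @param calibrator_id Genotype used as the calibrator (fold 1 by
#'   definition when `sample_id == calibrator_id`).
#' @return A one-row data frame: `gene_id`, `sample_id`, `calibrator_id`,
#'   `delta_ct_sample`, `delta_ct_calibrator`, `ddct`, `fold`.
#' @examples
#' recs <- data.frame(gene_id = "g", genotype_id = c("F1", "P1"),
#'                    ct_target = c(20, 23), ct_reference = c(18, 19))
#' relative_expression(recs, "g", sample_id = "F1", calibrator_id = "P1")
#' # ddCt = (20-18) - (23-19) = -2, fold = 4
#' @export
relative_expression <- function(records, gene_id, sample_id, calibrator_id) {
  needed <- c("gene_id", "genotype_id", "ct_target", "ct_reference")
  missing <- setdiff(needed, names(records))
  if (length(missing))
    stop("records missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  delta_ct <- function(genotype) {
    rows <- records$gene_id == gene_id & records$genotype_id == genotype
    if (!any(rows))
      stop("no Ct record for gene '", gene_id, "', genotype '", genotype, "'",
           call. = FALSE)
    ct_t <- records$ct_target[rows]
    ct_r <- records$ct_reference[rows]
    if (any(!is.finite(ct_t)) || any(!is.finite(ct_r)))
      stop("non-finite Ct for gene '", gene_id, "', genotype '", genotype, "'",
           call. = FALSE)
    mean(ct_t) - mean(ct_r)  # technical replicates averaged on the Ct scale
  }
  dct_s <- delta_ct(sample_id)
  dct_c <- delta_ct(calibrator_id)
  ddct <- dct_s - dct_c
  data.frame(gene_id = gene_id, sample_id = sample_id,
             calibrator_id = calibrator_id,
             delta_ct_sample = dct_s, delta_ct_calibrator = dct_c,
             ddct = ddct, fold = 2^(-ddct), stringsAsFactors = FALSE)
}

#' Direction concordance between qPCR folds and RNA-Seq DEG calls
#'
#' For each gene present in both inputs, checks that the qPCR fold change
#' points in the same direction as the RNA-Seq call: `up` agrees with
#' fold > 1, `down` with fold < 1, and `ns` with a fold inside the band
#' `[1/ns_band, ns_band]`.
#'
#' @param qpcr_folds Data frame with columns `gene_id` and `fold` (one row
#'   per gene for the comparison of interest).
#' @param rnaseq_calls Data frame with columns `gene_id` and `call`
#'   (`up`/`down`/`ns`), e.g. one comparison's rows from [call_degs()].
#' @param ns_band Fold band treated as "no change" when the RNA-Seq call is
#'   `ns` (default 1.5).
#' @return List with `table` (per-gene `gene_id`, `fold`, `call`, `agree`)
#'   and `agreement` (fraction of overlapping genes that agree).
#' @export
qpcr_concordance <- function(qpcr_folds, rnaseq_calls, ns_band = 1.5) {
  stopifnot(all(c("gene_id", "fold") %in% names(qpcr_folds)),
            all(c("gene_id", "call") %in% names(rnaseq_calls)))
  merged <- merge(qpcr_folds[, c("gene_id", "fold")],
                  rnaseq_calls[, c("gene_id", "call")], by = "gene_id")
  if (nrow(merged) == 0L)
    stop("no overlapping genes between qPCR folds and RNA-Seq calls",
         call. = FALSE)
  merged$agree <- ifelse(
    merged$call == "up", merged$fold > 1,
    ifelse(merged$call == "down", merged$fold < 1,
           merged$fold >= 1 / ns_band & merged$fold <= ns_band))
  merged <- merged[order(merged$gene_id), , drop = FALSE]
  rownames(merged) <- NULL
  list(table = merged, agreement = mean(merged$agree))
}
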