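#' Inheritance-mode classification of hybrid expression
#'
#' Each gene's expression pattern across the maternal parent, the F1 hybrid
#' and the paternal parent is placed in one of twelve classes, grouped as:
#'
#' * additive (classes 1, 12): the hybrid sits at the mid-parent value while
#'   the parents differ;
#' * expression-level dominance (ELD; classes 2, 11 paternal, 4, 9 maternal):
#'   the hybrid matches one parent while differing from the other;
#' * overdominance (classes 5, 6, 8 transgressive up-regulation; 3, 7, 10
#'   transgressive down-regulation): the hybrid lies above or below both
#'   parents.
#'
#' "Differs" and the "approximately equal" of each rule are both
#' operationalized through the same signed fold-change threshold used for DEG
#' calling (default 2): two levels differ when their signed fold change
#' reaches the threshold in magnitude, and are "approximately equal"
#' otherwise. There is one expression value per genotype, so no
#' replicate-based test is available.
#'
#' Class assignment precedence: transgressive patterns are identified first
#' (hybrid beyond both parents); then additivity (parents differ, the hybrid
#' is within the threshold of the arithmetic mid-parent value and lies
#' strictly between the parents); then ELD (parents differ, the hybrid is
#' within the threshold of exactly one parent and beyond it from the other).
#' Anything residual -- including genes with no differential expression at
#' all -- is class `"none"`. Additivity is tested before ELD because a hybrid
#' at the mid-parent value of two well-separated parents is necessarily
#' within a 2-fold band of the higher parent as well; mid-parent agreement is
#' the stronger, more specific claim and takes priority.
#'
#' Within each transgressive triple the subclass records the parent relation
#' in the order maternal > paternal / parents equal / maternal < paternal:
#' up-regulation 5/6/8, down-regulation 3/7/10.
#'
#' @param maternal,hybrid,paternal Non-negative abundance vectors, one entry
#'   per gene.
#' @param threshold Signed fold-change magnitude at/above which two levels
#'   are considered different (default 2, must be >= 1).
#' @param pseudocount Positive pseudocount for ratio formation.
#' @return For `pairwise_states()`: data frame of states
#'   (`"higher"`/`"lower"`/`"equal"`) for F1 vs maternal, F1 vs paternal and
#'   maternal vs paternal, plus the underlying signed fold changes and the F1
#'   vs mid-parent fold change. For `classify_12bin()`: the same columns plus
#'   `class` (`"1"`..`"12"` or `"none"`) and `coarse_mode`.
#' @examples
#' classify_12bin(maternal = 400, hybrid = 200, paternal = 100)  # class 1
#' classify_12bin(maternal = 100, hybrid = 400, paternal = 150)  # class 5..8
#' @export
pairwise_states <- function(maternal, hybrid, paternal, threshold = 2,
                            pseudocount = 0.01) {
  if (threshold < 1) stop("threshold must be >= 1", call. = FALSE)
  n <- max(length(maternal), length(hybrid), length(paternal))
  maternal <- rep_len(maternal, n)
  hybrid <- rep_len(hybrid, n)
  paternal <- rep_len(paternal, n)
  fc_fm <- signed_fold_change(hybrid, maternal, pseudocount)
  fc_fp <- signed_fold_change(hybrid, paternal, pseudocount)
  fc_mp <- signed_fold_change(maternal, paternal, pseudocount)
  fc_fmid <- signed_fold_change(hybrid, (maternal + paternal) / 2, pseudocount)
  data.frame(
    f1_vs_maternal = fc_state(fc_fm, threshold),
    f1_vs_paternal = fc_state(fc_fp, threshold),
    maternal_vs_paternal = fc_state(fc_mp, threshold),
    f1_vs_midparent = fc_state(fc_fmid, threshold),
    fc_f1_maternal = fc_fm, fc_f1_paternal = fc_fp,
    fc_maternal_paternal = fc_mp, fc_f1_midparent = fc_fmid,
    stringsAsFactors = FALSE)
}

#' @rdname pairwise_states
#' @export
classify_12bin <- function(maternal, hybrid, paternal, threshold = 2,
                           pseudocount = 0.01) {
  st <- pairwise_states(maternal, hybrid, paternal, threshold, pseudocount)
  n <- nrow(st)
  maternal <- rep_len(maternal, n)
  hybrid <- rep_len(hybrid, n)
  paternal <- rep_len(paternal, n)
  cls <- rep("none", n)

  up <- st$f1_vs_maternal == "higher" & st$f1_vs_paternal == "higher"
  dn <- st$f1_vs_maternal == "lower" & st$f1_vs_paternal == "lower"
  cls[up] <- c(higher = "5", equal = "6", lower = "8")[
    st$maternal_vs_paternal[up]]
  cls[dn] <- c(higher = "3", equal = "7", lower = "10")[
    st$maternal_vs_paternal[dn]]

  parents_differ <- st$maternal_vs_paternal != "equal"
  between <- hybrid > pmin(maternal, paternal) &
             hybrid < pmax(maternal, paternal)
  additive <- !up & !dn & parents_differ & between &
              st$f1_vs_midparent == "equal"
  cls[additive] <- ifelse(st$maternal_vs_paternal[additive] == "higher",
                          "1", "12")

  rest <- !up & !dn & !additive & parents_differ
  eld_m <- rest & st$f1_vs_maternal == "equal" & st$f1_vs_paternal != "equal"
  eld_p <- rest & st$f1_vs_paternal == "equal" & st$f1_vs_maternal != "equal"
  cls[eld_m] <- ifelse(st$maternal_vs_paternal[eld_m] == "higher", "4", "9")
  cls[eld_p] <- ifelse(st$maternal_vs_paternal[eld_p] == "lower", "2", "11")

  st$class <- cls
  st$coarse_mode <- coarse_mode_of_class(cls)
  st
}

#' Map the twelve class numbers to coarse inheritance modes
#'
#' @param class Character vector of class labels (`"1"`..`"12"` or `"none"`).
#' @return Character vector: `"additive"`, `"ELD_paternal"`,
#'   `"ELD_maternal"`, `"transgressive_up"`, `"transgressive_down"` or
#'   `"none"`.
#' @export
coarse_mode_of_class <- function(class) {
  map <- c(`1` = "additive", `12` = "additive",
           `2` = "ELD_paternal", `11` = "ELD_paternal",
           `4` = "ELD_maternal", `9` = "ELD_maternal",
           `5` = "transgressive_up", `6` = "transgressive_up",
           `8` = "transgressive_up",
           `3` = "transgressive_down", `7` = "transgressive_down",
           `10` = "transgressive_down",
           none = "none")
  out <- map[as.character(class)]
  if (anyNA(out)) stop("unknown class label", call. = FALSE)
  unname(out)
}

#' Classify every gene of a trio in an expression matrix
#'
#' Runs [classify_12bin()] on the three genotype columns of one cross.
#'
#' @param expr An [expression_matrix()].
#' @param trio A [trio_design()].
#' @param genes Optional character vector restricting classification to a
#'   gene subset (e.g. the common DEGs of the cross).
#' @param threshold,pseudocount See [classify_12bin()]; `pseudocount` defaults
#'   to the matrix's own.
#' @return Data frame with `gene_id`, `cross_id`, `class`, `coarse_mode`, the
#'   three pairwise signed fold changes and the F1-vs-mid-parent fold change,
#'   ordered by gene id.
#' @export
classify_modes <- function(expr, trio, genes = NULL, threshold = 2,
                           pseudocount = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  check_trio_in_matrix(trio, expr)
  if (is.null(pseudocount)) pseudocount <- expr$pseudocount
  v <- expr$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing))
      stop("unknown gene id(s): ", paste(utils::head(missing, 5),
                                         collapse = ", "), call. = FALSE)
    v <- v[genes, , drop = FALSE]
  }
  res <- classify_12bin(v[, trio$maternal_id], v[, trio$hybrid_id],
                        v[, trio$paternal_id], threshold, pseudocount)
  out <- cbind(data.frame(gene_id = rownames(v), cross_id = trio$cross_id,
                          stringsAsFactors = FALSE),
               res[, c("class", "coarse_mode", "fc_f1_maternal",
                       "fc_f1_paternal", "fc_maternal_paternal",
                       "fc_f1_midparent")])
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coarse per-hybrid mode from two hybrid-vs-parent fold changes
#'
#' The three-level rule used when only the hybrid's two parent comparisons
#' are available (no parent-vs-parent information): a gene significantly
#' changed (|FC| at/above threshold) in the same direction versus both
#' parents is `overdominance`; versus exactly one parent, `dominance`;
#' versus neither, `additive`. Significant changes of opposite sign get the
#' label `discordant`.
#'
#' @param fc_vs_maternal,fc_vs_paternal Signed fold changes of the hybrid
#'   against each parent (vectors recycled).
#' @param threshold Significance threshold on |FC| (default 2).
#' @return Character vector of labels.
#' @examples
#' classify_per_hybrid_coarse(2.75, 2.69)  # overdominance
#' classify_per_hybrid_coarse(2.15, 1.60)  # dominance
#' classify_per_hybrid_coarse(1.23, 1.35)  # additive
#' @export
classify_per_hybrid_coarse <- function(fc_vs_maternal, fc_vs_paternal,
                                       threshold = 2) {
  n <- max(length(fc_vs_maternal), length(fc_vs_paternal))
  f1 <- rep_len(fc_vs_maternal, n)
  f2 <- rep_len(fc_vs_paternal, n)
  sig1 <- abs(f1) >= threshold
  sig2 <- abs(f2) >= threshold
  out <- rep("additive", n)
  out[xor(sig1, sig2)] <- "dominance"
  both <- sig1 & sig2
  out[both & sign(f1) == sign(f2)] <- "overdominance"
  out[both & sign(f1) != sign(f2)] <- "discordant"
  out
}

#' Summarize inheritance-mode proportions
#'
#' Counts and percentages of the coarse modes per cross and pooled over all
#' crosses. Percentages are computed over classified genes (class not
#' `"none"`); dominance is the sum of maternal and paternal ELD, and
#' overdominance the sum of transgressive up- and down-regulation. When
#' nothing is classified all percentages are zero and `n_classified` is 0.
#'
#' @param classifications Data frame from [classify_modes()] (rows from
#'   several crosses may be concatenated).
#' @return Data frame with one row per cross plus a `"pooled"` row: counts
#'   (`n_*`) and percentages (`pct_*`).
#' @export
mode_summary <- function(classifications) {
  stopifnot(is.data.frame(classifications),
            all(c("cross_id", "coarse_mode") %in% names(classifications)))
  if (nrow(classifications) == 0L)
    stop("no classifications to summarize", call. = FALSE)
  one <- function(d, label) {
    n <- function(mode) sum(d$coarse_mode == mode)
    counts <- c(additive = n("additive"),
                ELD_maternal = n("ELD_maternal"),
                ELD_paternal = n("ELD_paternal"),
                transgressive_up = n("transgressive_up"),
                transgressive_down = n("transgressive_down"),
                none = n("none"))
    n_classified <- sum(counts[names(counts) != "none"])
    pct <- if (n_classified > 0) 100 * counts / n_classified else counts * 0
    data.frame(
      cross_id = label, n_genes = nrow(d), n_classified = n_classified,
      n_additive = counts[["additive"]],
      n_eld_maternal = counts[["ELD_maternal"]],
      n_eld_paternal = counts[["ELD_paternal"]],
      n_transgressive_up = counts[["transgressive_up"]],
      n_transgressive_down = counts[["transgressive_down"]],
      n_none = counts[["none"]],
      pct_additive = pct[["additive"]],
      pct_eld_maternal = pct[["ELD_maternal"]],
      pct_eld_paternal = pct[["ELD_paternal"]],
      pct_dominance = pct[["ELD_maternal"]] + pct[["ELD_paternal"]],
      pct_transgressive_up = pct[["transgressive_up"]],
      pct_transgressive_down = pct[["transgressive_down"]],
      pct_overdominance = pct[["transgressive_up"]] +
        pct[["transgressive_down"]],
      stringsAsFactors = FALSE)
  }
  crosses <- sort(unique(classifications$cross_id))
  rows <- lapply(crosses, function(cr)
    one(classifications[classifications$cross_id == cr, , drop = FALSE], cr))
  rows <- c(rows, list(one(classifications, "pooled")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Label universal DEGs per hybrid from a fold-change table
#'
#' Applies [classify_per_hybrid_coarse()] to each hybrid of a table of genes
#' carrying four signed fold changes (hybrid 1 vs its two parents, hybrid 2
#' vs its two parents), and tallies how many genes are overdominant in both
#' hybrids and how many change consistently up or down across all four
#' comparisons.
#'
#' @param fc_table Data frame with columns `gene_id`, `fc_h1_p1`, `fc_h1_p2`,
#'   `fc_h2_p1`, `fc_h2_p2`.
#' @param threshold Significance threshold on |FC| (default 2).
#' @return List with `labels` (data frame `gene_id`, `mode_hybrid1`,
#'   `mode_hybrid2`), `n_overdominant_both`, `n_up_both` (all four fold
#'   changes positive) and `n_down_both`.
#' @export
label_universal_degs <- function(fc_table, threshold = 2) {
  needed <- c("gene_id", "fc_h1_p1", "fc_h1_p2", "fc_h2_p1", "fc_h2_p2")
  missing <- setdiff(needed, names(fc_table))
  if (length(missing))
    stop("fc_table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  m1 <- classify_per_hybrid_coarse(fc_table$fc_h1_p1, fc_table$fc_h1_p2,
                                   threshold)
  m2 <- classify_per_hybrid_coarse(fc_table$fc_h2_p1, fc_table$fc_h2_p2,
                                   threshold)
  labels <- data.frame(gene_id = as.character(fc_table$gene_id),
                       mode_hybrid1 = m1, mode_hybrid2 = m2,
                       stringsAsFactors = FALSE)
  fcs <- as.matrix(fc_table[, needed[-1]])
  list(labels = labels,
       n_overdominant_both = sum(m1 == "overdominance" &
                                   m2 == "overdominance"),
       n_up_both = sum(apply(fcs > 0, 1L, all)),
       n_down_both = sum(apply(fcs < 0, 1L, all)))
}
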