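#' Configuration for a full pipeline run
#'
#' Collects input paths (or in-memory objects), thresholds and the output
#' directory for [run_pipeline()]. Every parameter is recorded in the run's
#' metadata file, so a run can be reproduced from its own outputs.
#'
#' @param expression Path to an expression table, or an
#'   [expression_matrix()]; `NULL` skips all expression stages.
#' @param traits Path to a trait table, or a data frame; `NULL` skips the
#'   heterosis stage.
#' @param qpcr Path to a qPCR Ct table, or a data frame; `NULL` skips the
#'   qPCR stage.
#' @param trios List of one or two [trio_design()] objects (required for
#'   expression stages).
#' @param qpcr_calibrators Named character vector mapping each trio's
#'   cross_id to the calibrator genotype for qPCR fold computation; defaults
#'   to each trio's maternal parent.
#' @param up_threshold,down_threshold DEG thresholds (defaults 2 / -2).
#' @param mode_threshold Threshold for inheritance-mode "approximately
#'   equal"/"different" judgements (default 2).
#' @param qpcr_band No-change fold band for qPCR concordance (default 1.5).
#' @param pseudocount Pseudocount for all ratios (default 0.01).
#' @param min_fpkm Optional expression floor for DEG calling (default 0).
#' @param seed Integer recorded in metadata (the pipeline itself is
#'   deterministic; the seed matters when the inputs were simulated).
#' @param outdir Output directory, created if absent.
#' @return A `run_config` list.
#' @export
run_config <- function(expression = NULL, traits = NULL, qpcr = NULL,
                       trios = NULL, qpcr_calibrators = NULL,
                       up_threshold = 2, down_threshold = -2,
                       mode_threshold = 2, qpcr_band = 1.5,
                       pseudocount = 0.01, min_fpkm = 0, seed = NULL,
                       outdir = "hetexpress_run") {
  cfg <- list(expression = expression, traits = traits, qpcr = qpcr,
              trios = trios, qpcr_calibrators = qpcr_calibrators,
              up_threshold = up_threshold, down_threshold = down_threshold,
              mode_threshold = mode_threshold, qpcr_band = qpcr_band,
              pseudocount = pseudocount, min_fpkm = min_fpkm, seed = seed,
              outdir = outdir)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full heterosis / expression-mode pipeline
#'
#' Executes every stage whose input is present and writes deterministic TSV
#' artifacts to the configured output directory: a heterosis table, DEG calls
#' per comparison, DEG set counts and memberships, per-gene inheritance-mode
#' classifications, a mode summary, a universal-DEG table with per-hybrid
#' coarse labels, a log2-transformed matrix export for external heat-map
#' tools, the library correlation matrix, qPCR folds and concordance (when Ct
#' data are given), a plain-text log and a JSON metadata file recording every
#' threshold, the pseudocount and the seed. Stages without input are skipped
#' with a logged notice. Rerunning with the same config and inputs produces
#' byte-identical artifacts.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of the in-memory stage results plus
#'   `artifact_paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  results <- list()
  paths <- character(0)
  emit <- function(x, name) {
    p <- file.path(config$outdir, name)
    write_report(x, p)
    paths <<- c(paths, p)
    p
  }

  # -- heterosis stage ------------------------------------------------------
  if (!is.null(config$traits)) {
    traits <- if (is.character(config$traits)) read_trait_table(config$traits)
              else config$traits
    het <- heterosis_table(traits)
    het_out <- as.data.frame(het)
    het_out$mph_percent <- round_half_away(het_out$mph_percent, 2)
    het_out$hph_percent <- round_half_away(het_out$hph_percent, 2)
    emit(het_out, "heterosis.tsv")
    results$heterosis <- het
    note("heterosis: ", nrow(het), " trait x cross rows")
  } else note("heterosis: skipped (no trait input)")

  # -- expression stages ----------------------------------------------------
  if (!is.null(config$expression)) {
    if (is.null(config$trios) || !length(config$trios))
      stop("expression stages require at least one trio_design", call. = FALSE)
    expr <- if (is.character(config$expression))
      read_expression_table(config$expression, pseudocount = config$pseudocount)
    else config$expression
    trios <- config$trios

    corr <- library_correlation(expr)
    corr_df <- data.frame(genotype_id = rownames(corr),
                          as.data.frame(corr, check.names = FALSE),
                          check.names = FALSE, stringsAsFactors = FALSE)
    emit(corr_df, "library_correlation.tsv")
    results$correlation <- corr

    log2_df <- data.frame(gene_id = gene_ids(expr),
                          as.data.frame(log2(expr$values + expr$pseudocount),
                                        check.names = FALSE),
                          check.names = FALSE, stringsAsFactors = FALSE)
    emit(log2_df, "log2_matrix.tsv")

    calls <- lapply(trios, function(tr)
      call_degs(expr, tr, config$up_threshold, config$down_threshold,
                config$min_fpkm))
    all_calls <- do.call(rbind, calls)
    rownames(all_calls) <- NULL
    emit(all_calls, "deg_calls.tsv")
    results$deg_calls <- all_calls

    commons <- mapply(common_degs_per_cross, calls, trios, SIMPLIFY = FALSE)
    count_rows <- lapply(seq_along(trios), function(i) {
      tr <- trios[[i]]; cm <- commons[[i]]
      pc <- cm$per_comparison
      data.frame(cross_id = tr$cross_id,
                 up_vs_maternal = length(pc$F1_vs_maternal$up),
                 down_vs_maternal = length(pc$F1_vs_maternal$down),
                 up_vs_paternal = length(pc$F1_vs_paternal$up),
                 down_vs_paternal = length(pc$F1_vs_paternal$down),
                 common_up = length(cm$common_up),
                 common_down = length(cm$common_down),
                 stringsAsFactors = FALSE)
    })
    counts <- do.call(rbind, count_rows)
    results$common_degs <- commons
    note("deg: ", paste(sprintf("%s: %d common up, %d common down",
                                counts$cross_id, counts$common_up,
                                counts$common_down), collapse = "; "))

    mode_genes <- lapply(seq_along(trios), function(i)
      sort(c(commons[[i]]$common_up, commons[[i]]$common_down)))
    classifications <- do.call(rbind, lapply(seq_along(trios), function(i) {
      g <- mode_genes[[i]]
      if (!length(g)) return(NULL)
      classify_modes(expr, trios[[i]], genes = g,
                     threshold = config$mode_threshold,
                     pseudocount = config$pseudocount)
    }))
    if (!is.null(classifications) && nrow(classifications)) {
      emit(classifications, "mode_classifications.tsv")
      emit(mode_summary(classifications), "mode_summary.tsv")
      results$classifications <- classifications
    } else note("modes: no common DEGs to classify")

    if (length(trios) == 2L) {
      sets <- universal_degs(commons[[1L]], commons[[2L]])
      counts$universal_up <- length(sets$universal_up)
      counts$universal_down <- length(sets$universal_down)
      counts$discordant <- length(sets$discordant)
      counts$unique_union <- sets$n_unique_union
      emit(sets, "deg_set_members.tsv")
      results$deg_sets <- sets
      note("universal: ", length(sets$universal_up), " up, ",
           length(sets$universal_down), " down, ",
           length(sets$discordant), " discordant; union ",
           sets$n_unique_union)

      universal <- sort(c(sets$universal_up, sets$universal_down))
      if (length(universal)) {
        tr1 <- trios[[1L]]; tr2 <- trios[[2L]]
        v <- expr$values[universal, , drop = FALSE]
        fc_tab <- data.frame(
          gene_id = universal,
          fc_h1_p1 = signed_fold_change(v[, tr1$hybrid_id],
                                        v[, tr1$maternal_id],
                                        config$pseudocount),
          fc_h1_p2 = signed_fold_change(v[, tr1$hybrid_id],
                                        v[, tr1$paternal_id],
                                        config$pseudocount),
          fc_h2_p1 = signed_fold_change(v[, tr2$hybrid_id],
                                        v[, tr2$maternal_id],
                                        config$pseudocount),
          fc_h2_p2 = signed_fold_change(v[, tr2$hybrid_id],
                                        v[, tr2$paternal_id],
                                        config$pseudocount),
          stringsAsFactors = FALSE)
        lab <- label_universal_degs(fc_tab, threshold = config$mode_threshold)
        fc_tab$mode_hybrid1 <- lab$labels$mode_hybrid1
        fc_tab$mode_hybrid2 <- lab$labels$mode_hybrid2
        emit(fc_tab, "universal_degs.tsv")
        results$universal_labels <- lab
      }
    }
    emit(counts, "deg_set_counts.tsv")
    results$deg_set_counts <- counts
  } else note("expression stages: skipped (no expression input)")

  # -- qPCR stage -----------------------------------------------------------
  if (!is.null(config$qpcr)) {
    if (is.null(config$trios) || !length(config$trios))
      stop("qPCR stage requires trio_design(s) to define comparisons",
           call. = FALSE)
    qp <- if (is.character(config$qpcr)) read_qpcr_table(config$qpcr)
          else config$qpcr
    fold_rows <- list()
    for (tr in config$trios) {
      calib <- config$qpcr_calibrators[[tr$cross_id]]
      if (is.null(calib)) calib <- tr$maternal_id
      for (g in sort(unique(qp$gene_id[qp$genotype_id == tr$hybrid_id]))) {
        re <- relative_expression(qp, g, sample_id = tr$hybrid_id,
                                  calibrator_id = calib)
        re$cross_id <- tr$cross_id
        fold_rows[[length(fold_rows) + 1L]] <- re
      }
    }
    folds <- do.call(rbind, fold_rows)
    emit(folds, "qpcr_folds.tsv")
    results$qpcr_folds <- folds
    if (!is.null(results$deg_calls)) {
      conc_rows <- lapply(config$trios, function(tr) {
        calib <- config$qpcr_calibrators[[tr$cross_id]]
        if (is.null(calib)) calib <- tr$maternal_id
        f <- folds[folds$cross_id == tr$cross_id, , drop = FALSE]
        cmp <- if (calib == tr$maternal_id) "F1_vs_maternal"
               else "F1_vs_paternal"
        calls <- results$deg_calls[
          results$deg_calls$cross_id == tr$cross_id &
          results$deg_calls$comparison == cmp, , drop = FALSE]
        if (!nrow(f) || !length(intersect(f$gene_id, calls$gene_id)))
          return(NULL)
        cc <- qpcr_concordance(f, calls, ns_band = config$qpcr_band)
        cc$table$cross_id <- tr$cross_id
        cc$table
      })
      conc <- do.call(rbind, conc_rows)
      if (!is.null(conc) && nrow(conc)) {
        emit(conc, "qpcr_concordance.tsv")
        results$qpcr_concordance <- conc
        note("qpcr: agreement ", round(mean(conc$agree), 4), " over ",
             nrow(conc), " gene comparisons")
      }
    }
  } else note("qpcr: skipped (no Ct input)")

  meta <- list(
    up_threshold = config$up_threshold,
    down_threshold = config$down_threshold,
    mode_threshold = config$mode_threshold,
    qpcr_band = config$qpcr_band,
    pseudocount = config$pseudocount,
    min_fpkm = config$min_fpkm,
    seed = config$seed,
    fold_change_convention = "signed symmetric ratio; |FC| >= 1; negative = lower",
    trios = lapply(config$trios, unclass))
  write_run_metadata(meta, file.path(config$outdir, "run_metadata.json"))
  writeLines(log_lines, file.path(config$outdir, "log.txt"))
  results$artifact_paths <- c(paths,
                              file.path(config$outdir, "run_metadata.json"),
                              file.path(config$outdir, "log.txt"))
  results$log <- log_lines
  invisible(results)
}
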