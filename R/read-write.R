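# Delimiter chosen from the file extension unless given explicitly.
detect_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  ext <- tolower(tools::file_ext(path))
  switch(ext, tsv = "\t", tab = "\t", txt = "\t", csv = ",",
         stop("cannot infer delimiter from extension '.", ext,
              "'; pass sep= explicitly", call. = FALSE))
}

#' Read a gene-by-genotype expression table
#'
#' Reads a delimited text file (TSV or CSV, auto-detected from the extension)
#' whose header row holds genotype ids and whose first column holds gene ids,
#' and returns a validated [expression_matrix()]. Duplicated gene ids,
#' negative, missing or non-numeric cells are errors.
#'
#' @param path Path to the table.
#' @param pseudocount Positive pseudocount stored with the matrix; see
#'   [expression_matrix()].
#' @param sep Optional delimiter overriding extension-based detection.
#' @return An `expression_matrix`.
#' @export
read_expression_table <- function(path, pseudocount = 0.01, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- detect_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("empty table: ", path, call. = FALSE)
  genes <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  bad <- !vapply(vals, is.numeric, TRUE)
  if (any(bad))
    stop("non-numeric abundance column(s): ",
         paste(names(vals)[bad], collapse = ", "), call. = FALSE)
  m <- as.matrix(vals)
  rownames(m) <- genes
  expression_matrix(m, pseudocount = pseudocount)
}

#' Read a trait table of parent-hybrid means
#'
#' Expects delimited text with columns `cross_id`, `trait_name`,
#' `maternal_mean`, `paternal_mean`, `hybrid_mean` (an optional `unit` column
#' is carried through). One row per (cross, trait). Non-numeric means are
#' rejected with the offending row and column named; a zero parental mean is
#' accepted here and only rejected when heterosis is computed.
#'
#' @param path Path to the table (TSV or CSV by extension).
#' @param sep Optional delimiter override.
#' @return A data frame of class `trait_table`, one row per (cross, trait).
#' @seealso [heterosis_table()]
#' @export
read_trait_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- detect_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no records in trait table: ", path, call. = FALSE)
  needed <- c("cross_id", "trait_name", "maternal_mean", "paternal_mean",
              "hybrid_mean")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("trait table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (col in c("maternal_mean", "paternal_mean", "hybrid_mean")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stop("non-numeric value in column '", col, "', row ", bad[1L],
             " (", v[bad[1L]], ")", call. = FALSE)
      df[[col]] <- num
    }
    if (anyNA(df[[col]]))
      stop("missing value in column '", col, "', row ",
           which(is.na(df[[col]]))[1L], call. = FALSE)
  }
  df$cross_id <- as.character(df$cross_id)
  df$trait_name <- as.character(df$trait_name)
  if (!"unit" %in% names(df)) df$unit <- NA_character_
  df <- df[, c("cross_id", "trait_name", "unit", "maternal_mean",
               "paternal_mean", "hybrid_mean")]
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Read a qPCR Ct table
#'
#' Expects columns `gene_id`, `genotype_id`, `ct_target`, `ct_reference` and
#' optionally `replicate`. Ct values must be finite and positive (cycles).
#'
#' @param path Path to the table (TSV or CSV by extension).
#' @param sep Optional delimiter override.
#' @return A data frame with one row per well (technical replicate).
#' @seealso [relative_expression()]
#' @export
read_qpcr_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- detect_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no records in qPCR table: ", path, call. = FALSE)
  needed <- c("gene_id", "genotype_id", "ct_target", "ct_reference")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("qPCR table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (col in c("ct_target", "ct_reference")) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)) || any(v <= 0))
      stop("Ct values in '", col, "' must be finite positive numbers",
           call. = FALSE)
  }
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  df
}

#' Write a pipeline result as deterministic delimited text
#'
#' Writes a tab-separated file with a fixed column order and fully specified
#' row order (gene id, then cross id, where present), so the same input always
#' produces byte-identical output. Methods exist for the data-frame results of
#' every stage and for [universal_degs()] set objects (written long, one
#' membership row per gene).
#'
#' @param x A stage result.
#' @param path Output file path.
#' @param ... Unused.
#' @return Invisibly, the path written.
#' @export
write_report <- function(x, path, ...) UseMethod("write_report")

#' @rdname write_report
#' @export
write_report.data.frame <- function(x, path, ...) {
  ord_cols <- intersect(c("gene_id", "cross_id", "comparison", "trait_name"),
                        names(x))
  if (length(ord_cols))
    x <- x[do.call(order, lapply(ord_cols, function(cn) x[[cn]])), ,
           drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(format_report_df(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_report
#' @export
write_report.deg_sets <- function(x, path, ...) {
  long <- data.frame(
    gene_id = c(x$universal_up, x$universal_down, x$discordant),
    set = rep(c("universal_up", "universal_down", "discordant"),
              c(length(x$universal_up), length(x$universal_down),
                length(x$discordant))),
    stringsAsFactors = FALSE)
  long <- long[order(long$gene_id, long$set), , drop = FALSE]
  write_report.data.frame(long, path)
}

# Numbers rendered with stable full precision, independent of options().
format_report_df <- function(df) {
  df[] <- lapply(df, function(col) {
    if (is.double(col)) format(col, digits = 15, trim = TRUE, scientific = FALSE)
    else col
  })
  df
}

#' Write run metadata as JSON
#'
#' Records every threshold, the pseudocount and the seed used by a run so the
#' run can be reproduced exactly from its own outputs.
#'
#' @param meta Named list of parameters.
#' @param path Output path (JSON).
#' @return Invisibly, the path.
#' @export
write_run_metadata <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
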