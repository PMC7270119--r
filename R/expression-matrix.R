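#' Construct a validated gene-by-genotype expression matrix
#'
#' Wraps a non-negative numeric matrix of FPKM-like abundances (one row per
#' gene, one column per genotype) together with the pseudocount used whenever
#' a ratio is formed from its values. Validation is strict: negative entries,
#' missing entries and duplicated identifiers are errors, never silently
#' repaired -- an FPKM of 0 and an absent value are different claims.
#'
#' @param values Numeric matrix with unique rownames (gene ids) and unique
#'   colnames (genotype ids); all entries finite and `>= 0`.
#' @param pseudocount Positive value added to both operands of every ratio
#'   formed from this matrix (default 0.01 FPKM), so fold changes are defined
#'   for zero-expression genes.
#'
#' @return An object of class `expression_matrix`.
#' @seealso [read_expression_table()], [signed_fold_change()]
#' @export
expression_matrix <- function(values, pseudocount = 0.01) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix", call. = FALSE)
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("empty table: no genes or no genotypes", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry gene ids as rownames and genotype ids as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate genotype id: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("missing or non-finite abundance values are not allowed", call. = FALSE)
  if (any(values < 0))
    stop("negative abundance values are not allowed", call. = FALSE)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      !is.finite(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be a single positive number", call. = FALSE)
  structure(list(values = values, pseudocount = pseudocount),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d genotypes (pseudocount %g)\n",
              nrow(x$values), ncol(x$values), x$pseudocount))
  cat("genotypes:", paste(colnames(x$values), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Gene and genotype identifiers of an expression matrix
#' @param x An `expression_matrix`.
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
genotype_ids <- function(x) colnames(x$values)
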