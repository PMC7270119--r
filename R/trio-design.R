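#' Define a parent-hybrid trio
#'
#' A trio ties together the three genotypes of one cross: the maternal inbred
#' parent, the paternal inbred parent, and their F1 hybrid. All downstream
#' fold-change and classification operations take a trio to know which columns
#' of an expression matrix to compare.
#'
#' @param cross_id Short label for the cross (e.g. `"A"`).
#' @param maternal_id Genotype label of the maternal parent.
#' @param paternal_id Genotype label of the paternal parent.
#' @param hybrid_id Genotype label of the F1 hybrid.
#'
#' @return An object of class `trio_design`: a list with the four label
#'   fields.
#' @examples
#' trio_design("A", maternal_id = "L2-4", paternal_id = "L2-28",
#'             hybrid_id = "L4-7")
#' @export
trio_design <- function(cross_id, maternal_id, paternal_id, hybrid_id) {
  ids <- c(cross_id = cross_id, maternal_id = maternal_id,
           paternal_id = paternal_id, hybrid_id = hybrid_id)
  if (!all(vapply(ids, function(x) is.character(x) && length(x) == 1L, TRUE)))
    stop("all trio_design fields must be single character strings", call. = FALSE)
  if (any(!nzchar(ids)))
    stop("trio_design labels must be non-empty", call. = FALSE)
  geno <- ids[c("maternal_id", "paternal_id", "hybrid_id")]
  if (anyDuplicated(geno))
    stop("maternal, paternal and hybrid genotype labels must be distinct",
         call. = FALSE)
  structure(as.list(ids), class = "trio_design")
}

#' @export
print.trio_design <- function(x, ...) {
  cat(sprintf("Trio %s: %s (maternal) x %s (paternal) -> %s (F1)\n",
              x$cross_id, x$maternal_id, x$paternal_id, x$hybrid_id))
  invisible(x)
}

# Check that a trio's genotypes exist as matrix columns.
check_trio_in_matrix <- function(trio, expr) {
  stopifnot(inherits(trio, "trio_design"))
  ids <- c(trio$maternal_id, trio$paternal_id, trio$hybrid_id)
  missing <- setdiff(ids, genotype_ids(expr))
  if (length(missing))
    stop("unknown genotype id(s) for trio ", trio$cross_id, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
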