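#' Paths to bundled example tables
#'
#' The package ships two small plain-text tables for Easter lily
#' parent-hybrid crosses: `"trait_means.csv"` (per-genotype trait means for
#' two crosses: plant height, leaf length, days to flowering, number of
#' flowers, flower diameter) and `"universal_deg_fc.csv"` (28 universal DEGs
#' with the four hybrid-vs-parent signed fold changes and the published
#' per-hybrid coarse mode labels).
#'
#' @param file File name, or `NULL` to list available files.
#' @return A file path (or a character vector of file names).
#' @examples
#' hetexpress_example()
#' read_trait_table(hetexpress_example("trait_means.csv"))
#' @export
hetexpress_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "hetexpress")))
  path <- system.file("extdata", file, package = "hetexpress")
  if (!nzchar(path)) stop("no such example file: ", file, call. = FALSE)
  path
}
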