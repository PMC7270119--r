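#' Signed (symmetric) fold change
#'
#' The fold-change convention used throughout: with `x = a + pseudocount` and
#' `y = b + pseudocount`, the value is `x/y` when `x >= y` and `-y/x` when
#' `x < y`. The result is never inside the open interval (-1, 1); equal
#' abundances give exactly 1, and `signed_fold_change(a, b) ==
#' -signed_fold_change(b, a)` whenever `a != b`. A value of -3 reads
#' "3-fold lower". This is the natural-scale counterpart of a symmetric log2
#' ratio, not a log2 fold change.
#'
#' @param a,b Non-negative abundances (FPKM); vectors recycled.
#' @param pseudocount Positive value added to both operands, so the ratio is
#'   defined for zero abundances.
#' @return Numeric vector of signed fold changes.
#' @examples
#' signed_fold_change(8, 2)   #  3.985... (pseudocount 0.01)
#' signed_fold_change(2, 8)   # -3.985...
#' signed_fold_change(10, 10) #  1
#' @export
signed_fold_change <- function(a, b, pseudocount = 0.01) {
  if (any(a < 0) || any(b < 0))
    stop("abundances must be non-negative", call. = FALSE)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0)
    stop("pseudocount must be a single positive number", call. = FALSE)
  x <- a + pseudocount
  y <- b + pseudocount
  ifelse(x >= y, x / y, -y / x)
}

# State of a signed fold change at a threshold: "higher" / "lower" / "equal".
fc_state <- function(fc, threshold) {
  ifelse(fc >= threshold, "higher", ifelse(fc <= -threshold, "lower", "equal"))
}

#' Call differentially expressed genes for one trio
#'
#' Computes the signed fold change of the hybrid against each parent for every
#' gene and calls each comparison `up` (fold change at or above
#' `up_threshold`), `down` (at or below `down_threshold`) or `ns`. Thresholds
#' are inclusive, matching the convention FC >= 2 / FC <= -2.
#'
#' @param expr An [expression_matrix()].
#' @param trio A [trio_design()]; its genotypes must be matrix columns.
#' @param up_threshold Fold change at/above which a gene is up (default 2,
#'   must be >= 1).
#' @param down_threshold Fold change at/below which a gene is down (default
#'   -2, must be <= -1).
#' @param min_fpkm Optional expression floor: genes whose hybrid AND parent
#'   abundances are all below this value are dropped before calling (default
#'   0, no floor).
#' @return Data frame with two rows per gene (one per parent comparison):
#'   `gene_id`, `cross_id`, `comparison` (e.g. `"F1_vs_maternal"`),
#'   `parent_id`, `signed_fc`, `call`.
#' @export
call_degs <- function(expr, trio, up_threshold = 2, down_threshold = -2,
                      min_fpkm = 0) {
  stopifnot(inherits(expr, "expression_matrix"))
  check_trio_in_matrix(trio, expr)
  if (up_threshold < 1) stop("up_threshold must be >= 1", call. = FALSE)
  if (down_threshold > -1) stop("down_threshold must be <= -1", call. = FALSE)
  v <- expr$values
  h <- v[, trio$hybrid_id]
  m <- v[, trio$maternal_id]
  p <- v[, trio$paternal_id]
  keep <- (h >= min_fpkm) | (m >= min_fpkm) | (p >= min_fpkm)
  g <- gene_ids(expr)[keep]
  h <- h[keep]; m <- m[keep]; p <- p[keep]
  fc_m <- signed_fold_change(h, m, expr$pseudocount)
  fc_p <- signed_fold_change(h, p, expr$pseudocount)
  out <- data.frame(
    gene_id = rep(g, 2L),
    cross_id = trio$cross_id,
    comparison = rep(c("F1_vs_maternal", "F1_vs_paternal"), each = length(g)),
    parent_id = rep(c(trio$maternal_id, trio$paternal_id), each = length(g)),
    signed_fc = c(fc_m, fc_p),
    stringsAsFactors = FALSE)
  out$call <- ifelse(out$signed_fc >= up_threshold, "up",
                     ifelse(out$signed_fc <= down_threshold, "down", "ns"))
  out <- out[order(out$gene_id, out$comparison), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes differentially expressed against both parents of one cross
#'
#' A gene belongs to the common-up set when it is called `up` against both
#' parents, and to the common-down set when called `down` against both. A gene
#' up versus one parent and down versus the other belongs to neither set.
#'
#' @param calls Output of [call_degs()] for one trio (both comparisons).
#' @param trio The [trio_design()] the calls belong to.
#' @return List with sorted character vectors `common_up` and `common_down`,
#'   plus per-comparison `up` / `down` sets under `per_comparison`.
#' @export
common_degs_per_cross <- function(calls, trio) {
  stopifnot(is.data.frame(calls),
            all(c("gene_id", "comparison", "call") %in% names(calls)))
  cmp <- unique(calls$comparison)
  if (!all(c("F1_vs_maternal", "F1_vs_paternal") %in% cmp))
    stop("calls must cover both parent comparisons of trio ", trio$cross_id,
         call. = FALSE)
  split_calls <- split(calls, calls$comparison)
  sets <- lapply(split_calls, function(d)
    list(up = sort(d$gene_id[d$call == "up"]),
         down = sort(d$gene_id[d$call == "down"])))
  list(
    common_up = sort(intersect(sets$F1_vs_maternal$up,
                               sets$F1_vs_paternal$up)),
    common_down = sort(intersect(sets$F1_vs_maternal$down,
                                 sets$F1_vs_paternal$down)),
    per_comparison = sets)
}

#' Universal and discordant DEG sets across two crosses
#'
#' Intersects the common-up / common-down gene sets of two independent
#' crosses. Universal DEGs change in the same direction in both hybrids;
#' discordant genes are common DEGs with opposite direction between the two
#' crosses. The unique-union count applies inclusion-exclusion over all four
#' input sets.
#'
#' @param cross_a,cross_b Lists with elements `common_up` and `common_down`
#'   (as returned by [common_degs_per_cross()]), or `up` / `down`.
#' @return Object of class `deg_sets`: sorted vectors `universal_up`,
#'   `universal_down`, `discordant`, the per-input counts, and
#'   `n_unique_union` (distinct genes across all four sets).
#' @export
universal_degs <- function(cross_a, cross_b) {
  get_set <- function(x, dir) {
    s <- x[[paste0("common_", dir)]]
    if (is.null(s)) s <- x[[dir]]
    if (is.null(s)) stop("input sets must have common_up/common_down (or up/down)",
                         call. = FALSE)
    unique(as.character(s))
  }
  a_up <- get_set(cross_a, "up"); a_down <- get_set(cross_a, "down")
  b_up <- get_set(cross_b, "up"); b_down <- get_set(cross_b, "down")
  if (length(intersect(a_up, a_down)))
    stop("integrity error: gene(s) in both up and down of the same cross: ",
         paste(utils::head(intersect(a_up, a_down), 5), collapse = ", "),
         call. = FALSE)
  if (length(intersect(b_up, b_down)))
    stop("integrity error: gene(s) in both up and down of the same cross: ",
         paste(utils::head(intersect(b_up, b_down), 5), collapse = ", "),
         call. = FALSE)
  structure(list(
    universal_up = sort(intersect(a_up, b_up)),
    universal_down = sort(intersect(a_down, b_down)),
    discordant = sort(union(intersect(a_up, b_down), intersect(a_down, b_up))),
    n_a_up = length(a_up), n_a_down = length(a_down),
    n_b_up = length(b_up), n_b_down = length(b_down),
    n_unique_union = length(unique(c(a_up, a_down, b_up, b_down)))),
    class = "deg_sets")
}

#' @export
print.deg_sets <- function(x, ...) {
  cat("DEG sets across two crosses\n")
  cat(sprintf("  cross A: %d up, %d down; cross B: %d up, %d down\n",
              x$n_a_up, x$n_a_down, x$n_b_up, x$n_b_down))
  cat(sprintf("  universal: %d up, %d down; discordant: %d\n",
              length(x$universal_up), length(x$universal_down),
              length(x$discordant)))
  cat(sprintf("  distinct genes over all four sets: %d\n", x$n_unique_union))
  invisible(x)
}

#' Pearson correlation between genotype libraries
#'
#' Quality-control correlation of expression profiles, computed on
#' `log2(value + pseudocount)`. Returns a symmetric genotype-by-genotype
#' matrix with unit diagonal. A zero-variance column yields `NA` entries and a
#' warning rather than a silent 0.
#'
#' @param expr An [expression_matrix()] with at least 2 genes.
#' @return Symmetric numeric matrix of Pearson r in `[-1, 1]` (or `NA`).
#' @export
library_correlation <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (nrow(expr$values) < 2L)
    stop("need at least 2 genes for library correlation", call. = FALSE)
  lv <- log2(expr$values + expr$pseudocount)
  sds <- apply(lv, 2L, stats::sd)
  if (any(sds == 0))
    warning("zero-variance genotype column(s): ",
            paste(colnames(lv)[sds == 0], collapse = ", "),
            "; correlation undefined (NA)", call. = FALSE)
  r <- suppressWarnings(stats::cor(lv, method = "pearson"))
  diag(r) <- 1
  r
}
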