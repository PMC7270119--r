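#' Inheritance-mode class proportions for simulation
#'
#' Named proportion vector over the twelve classes plus `"none"`, used by
#' [simulate_trios()]. The `"overdominant"` preset mirrors a strongly
#' overdominant hybrid leaf transcriptome -- 19.35% additive, 2.56% paternal
#' ELD, 2.20% maternal ELD, 41.68% transgressive up-regulation and 34.21%
#' transgressive down-regulation of classified genes -- with each group's
#' share split evenly over its member classes. The `"uniform"` preset puts
#' equal mass on all twelve classes.
#'
#' @param preset `"overdominant"` (default) or `"uniform"`.
#' @param none Proportion of genes with no differential expression at all
#'   (default 0); the class proportions are rescaled to `1 - none`.
#' @return Named numeric vector over `c("1", ..., "12", "none")` summing
#'   to 1.
#' @export
mode_class_proportions <- function(preset = c("overdominant", "uniform"),
                                   none = 0) {
  preset <- match.arg(preset)
  stopifnot(none >= 0, none < 1)
  p <- switch(preset,
    overdominant = c(`1` = 19.35 / 2, `12` = 19.35 / 2,
                     `2` = 2.56 / 2, `11` = 2.56 / 2,
                     `4` = 2.20 / 2, `9` = 2.20 / 2,
                     `5` = 41.68 / 3, `6` = 41.68 / 3, `8` = 41.68 / 3,
                     `3` = 34.21 / 3, `7` = 34.21 / 3, `10` = 34.21 / 3) / 100,
    uniform = stats::setNames(rep(1 / 12, 12), as.character(1:12)))
  p <- p / sum(p) * (1 - none)
  c(p, none = none)
}

# Noise-free expression levels (maternal, hybrid, paternal) for one class.
# L is the low baseline level, E the effect-size ratio. Levels tied by "~" in
# the class definition are exactly equal; differing levels are separated by a
# factor E, except that additive classes place the hybrid exactly at the
# arithmetic mid-parent of two parents separated by E^2 (a hybrid at the
# mid-parent value of parents only E apart would be within the default 2-fold
# band of both parents and carry no recoverable additive signal).
class_levels <- function(class, L, E) {
  switch(class,
    `1`  = c(E^2 * L, (E^2 + 1) * L / 2, L),
    `12` = c(L, (E^2 + 1) * L / 2, E^2 * L),
    `2`  = c(L, E * L, E * L),
    `11` = c(E * L, L, L),
    `4`  = c(E * L, E * L, L),
    `9`  = c(L, L, E * L),
    `5`  = c(E * L, E^2 * L, L),
    `6`  = c(L, E * L, L),
    `8`  = c(L, E^2 * L, E * L),
    `3`  = c(E^2 * L, L, E * L),
    `7`  = c(E * L, L, E * L),
    `10` = c(E * L, L, E^2 * L),
    none = c(L, L, L),
    stop("unknown class: ", class, call. = FALSE))
}

#' Simulate parent-hybrid expression trios with known ground truth
#'
#' Generates a gene-by-genotype FPKM-like matrix for one or two crosses in
#' which every gene follows a known inheritance-mode class. Each gene draws a
#' baseline level `L = 2^N(baseline_log2_mean, baseline_log2_sd)` and a class
#' from `class_proportions`; the three noise-free genotype levels are then
#' fixed by the class geometry (levels declared equal by the class are
#' exactly equal; differing levels are separated by `effect_size`, except the
#' additive classes, whose hybrid sits exactly at the mid-parent of parents
#' `effect_size^2` apart). Finally every cell is multiplied by independent
#' log-normal noise `2^N(0, noise_sd)`.
#'
#' With two crosses each gene's class is drawn independently per cross; the
#' `n_universal_up`, `n_universal_down`, `n_discordant_ab` and
#' `n_discordant_ba` arguments override the first genes' classes so that a
#' chosen number of genes is transgressively regulated in both crosses with
#' concordant or discordant direction, exercising universal-DEG detection.
#'
#' @param n_genes Number of genes.
#' @param class_proportions Named proportions over the 12 classes and
#'   `"none"`; see [mode_class_proportions()] (default: the `"overdominant"`
#'   preset).
#' @param effect_size True ratio separating "different" levels (default 4;
#'   must exceed 1).
#' @param baseline_log2_mean,baseline_log2_sd Log2-scale mean and sd of the
#'   baseline expression level (defaults 4 and 1.5, i.e. a median of 16 FPKM
#'   spanning roughly 1-250 FPKM over 2 sd).
#' @param noise_sd Standard deviation of multiplicative log2-normal noise per
#'   cell (default 0.1; 0 gives noise-free data).
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @param n_crosses 1 or 2 (default 2).
#' @param n_universal_up,n_universal_down Number of genes forced
#'   transgressive up (resp. down) in both crosses.
#' @param n_discordant_ab,n_discordant_ba Number of genes forced up in cross
#'   A and down in cross B (and vice versa).
#' @return Object of class `trio_simulation`: `expression` (an
#'   [expression_matrix()] with genotypes `P1_<cross>`, `F1_<cross>`,
#'   `P2_<cross>`), `truth` (data frame `gene_id`, `cross_id`, `class`,
#'   `coarse_mode`), `trios` (list of [trio_design()]) and `config`.
#' @export
simulate_trios <- function(n_genes = 1000,
                           class_proportions = mode_class_proportions(),
                           effect_size = 4,
                           baseline_log2_mean = 4, baseline_log2_sd = 1.5,
                           noise_sd = 0.1, seed = NULL, n_crosses = 2,
                           n_universal_up = 0, n_universal_down = 0,
                           n_discordant_ab = 0, n_discordant_ba = 0) {
  valid <- c(as.character(1:12), "none")
  if (is.null(names(class_proportions)) ||
      !all(names(class_proportions) %in% valid))
    stop("class_proportions must be named with classes 1..12 and 'none'",
         call. = FALSE)
  if (any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must be non-negative and sum to 1", call. = FALSE)
  if (effect_size <= 1) stop("effect_size must be > 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!n_crosses %in% 1:2) stop("n_crosses must be 1 or 2", call. = FALSE)
  n_forced <- n_universal_up + n_universal_down + n_discordant_ab +
    n_discordant_ba
  if (n_forced > 0 && n_crosses != 2)
    stop("cross-overlap injection requires n_crosses = 2", call. = FALSE)
  if (n_forced > n_genes)
    stop("overlap injection exceeds n_genes", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  crosses <- c("A", "B")[seq_len(n_crosses)]
  genes <- sprintf("g%05d", seq_len(n_genes))
  L <- 2^stats::rnorm(n_genes, baseline_log2_mean, baseline_log2_sd)

  cls <- vapply(crosses, function(cr)
    sample(names(class_proportions), n_genes, replace = TRUE,
           prob = class_proportions), character(n_genes))
  cls <- matrix(cls, nrow = n_genes,
                dimnames = list(genes, crosses))
  if (n_forced > 0) {
    forced_a <- rep(c("6", "7", "6", "7"),
                    c(n_universal_up, n_universal_down, n_discordant_ab,
                      n_discordant_ba))
    forced_b <- rep(c("6", "7", "7", "6"),
                    c(n_universal_up, n_universal_down, n_discordant_ab,
                      n_discordant_ba))
    cls[seq_len(n_forced), "A"] <- forced_a
    cls[seq_len(n_forced), "B"] <- forced_b
  }

  cols <- as.vector(vapply(crosses, function(cr)
    paste0(c("P1_", "F1_", "P2_"), cr), character(3L)))
  values <- matrix(NA_real_, n_genes, length(cols),
                   dimnames = list(genes, cols))
  for (ci in seq_along(crosses)) {
    lev <- t(vapply(seq_len(n_genes), function(i)
      class_levels(cls[i, ci], L[i], effect_size), numeric(3L)))
    values[, (ci - 1L) * 3L + 1:3] <- lev  # maternal, hybrid, paternal
  }
  if (noise_sd > 0)
    values <- values * 2^stats::rnorm(length(values), 0, noise_sd)

  truth <- data.frame(
    gene_id = rep(genes, n_crosses),
    cross_id = rep(crosses, each = n_genes),
    class = as.vector(cls),
    coarse_mode = coarse_mode_of_class(as.vector(cls)),
    stringsAsFactors = FALSE)
  trios <- lapply(crosses, function(cr)
    trio_design(cr, maternal_id = paste0("P1_", cr),
                paternal_id = paste0("P2_", cr),
                hybrid_id = paste0("F1_", cr)))
  names(trios) <- crosses
  structure(list(
    expression = expression_matrix(values),
    truth = truth,
    trios = trios,
    config = list(n_genes = n_genes, class_proportions = class_proportions,
                  effect_size = effect_size,
                  baseline_log2_mean = baseline_log2_mean,
                  baseline_log2_sd = baseline_log2_sd, noise_sd = noise_sd,
                  seed = seed, n_crosses = n_crosses,
                  n_universal_up = n_universal_up,
                  n_universal_down = n_universal_down,
                  n_discordant_ab = n_discordant_ab,
                  n_discordant_ba = n_discordant_ba)),
    class = "trio_simulation")
}

#' @export
print.trio_simulation <- function(x, ...) {
  cat(sprintf("trio_simulation: %d genes, %d cross(es), effect %g, noise_sd %g\n",
              x$config$n_genes, x$config$n_crosses, x$config$effect_size,
              x$config$noise_sd))
  invisible(x)
}

#' Simulate trait trios with known heterosis
#'
#' Draws parental trait means uniformly and constructs the hybrid mean from a
#' target mid-parent heterosis, `F1 = MP * (1 + MPH/100)`, so the true MPH
#' (and the implied HPH) are known exactly.
#'
#' @param n_traits Number of trait rows.
#' @param parent_range Range (min, max) for the two parental means.
#' @param mph_range Range (min, max) of the target MPH in percent.
#' @param seed Optional integer seed.
#' @param cross_id Cross label attached to all rows.
#' @return Data frame usable by [heterosis_table()] with the extra truth
#'   columns `true_mph` and `true_hph`.
#' @export
simulate_trait_trios <- function(n_traits = 5, parent_range = c(3, 200),
                                 mph_range = c(-10, 100), seed = NULL,
                                 cross_id = "S") {
  stopifnot(length(parent_range) == 2L, parent_range[1] > 0,
            diff(parent_range) >= 0, length(mph_range) == 2L,
            diff(mph_range) >= 0)
  if (!is.null(seed)) set.seed(seed)
  m <- stats::runif(n_traits, parent_range[1], parent_range[2])
  p <- stats::runif(n_traits, parent_range[1], parent_range[2])
  mph <- stats::runif(n_traits, mph_range[1], mph_range[2])
  mp <- (m + p) / 2
  h <- mp * (1 + mph / 100)
  hp <- pmax(m, p)
  data.frame(
    cross_id = cross_id,
    trait_name = sprintf("trait_%02d", seq_len(n_traits)),
    unit = NA_character_,
    maternal_mean = m, paternal_mean = p, hybrid_mean = h,
    true_mph = mph, true_hph = 100 * (h - hp) / hp,
    stringsAsFactors = FALSE)
}
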