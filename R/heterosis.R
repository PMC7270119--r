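#' Mid-parent and high-parent heterosis
#'
#' Heterosis (hybrid vigor) measures the superiority of an F1 hybrid over its
#' inbred parents for a quantitative trait. Mid-parent heterosis is
#' `MPH = 100 * (F1 - MP) / MP` with `MP = (maternal + paternal) / 2`;
#' high-parent (better-parent) heterosis is `HPH = 100 * (F1 - HP) / HP` with
#' `HP = max(maternal, paternal)`. The "better" parent is always the parent
#' with the larger trait mean: whether a large value is desirable (plant
#' height) or not (days to flowering) is interpretation, not arithmetic.
#'
#' Values are computed in full precision; rounding (2 decimals, half away
#' from zero) happens only in reports.
#'
#' @param maternal_mean,paternal_mean,hybrid_mean Trait means (same units);
#'   vectors are recycled to a common length.
#' @return Numeric vector of heterosis percentages.
#' @examples
#' mid_parent_heterosis(37.2, 34.7, 47.1)   # 31.01...
#' high_parent_heterosis(37.2, 34.7, 47.1)  # 26.61...
#' @export
mid_parent_heterosis <- function(maternal_mean, paternal_mean, hybrid_mean) {
  check_trait_means(maternal_mean, paternal_mean, hybrid_mean)
  mp <- (maternal_mean + paternal_mean) / 2
  if (any(mp == 0))
    stop("undefined heterosis: mid-parent value is zero", call. = FALSE)
  100 * (hybrid_mean - mp) / mp
}

#' @rdname mid_parent_heterosis
#' @export
high_parent_heterosis <- function(maternal_mean, paternal_mean, hybrid_mean) {
  check_trait_means(maternal_mean, paternal_mean, hybrid_mean)
  hp <- pmax(maternal_mean, paternal_mean)
  if (any(hp == 0))
    stop("undefined heterosis: high-parent value is zero", call. = FALSE)
  100 * (hybrid_mean - hp) / hp
}

check_trait_means <- function(m, p, h) {
  if (!all(is.finite(m), is.finite(p), is.finite(h)))
    stop("trait means must be finite numbers", call. = FALSE)
  invisible(TRUE)
}

#' Heterosis table for a set of trait trios
#'
#' Applies [mid_parent_heterosis()] and [high_parent_heterosis()] to every
#' (cross, trait) row of a trait table and returns one result row per input
#' row, ordered by trait name then cross id. A zero parental mean in any row
#' aborts with the row's identity.
#'
#' @param traits A `trait_table` from [read_trait_table()], or any data frame
#'   with columns `cross_id`, `trait_name`, `maternal_mean`, `paternal_mean`,
#'   `hybrid_mean`.
#' @return Data frame with columns `cross_id`, `trait_name`, `unit`,
#'   `maternal_mean`, `paternal_mean`, `hybrid_mean`, `mid_parent`,
#'   `high_parent`, `mph_percent`, `hph_percent` (full precision).
#' @export
heterosis_table <- function(traits) {
  if (!is.data.frame(traits) || nrow(traits) == 0L)
    stop("no trait records", call. = FALSE)
  needed <- c("cross_id", "trait_name", "maternal_mean", "paternal_mean",
              "hybrid_mean")
  missing <- setdiff(needed, names(traits))
  if (length(missing))
    stop("trait table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- data.frame(
    cross_id = as.character(traits$cross_id),
    trait_name = as.character(traits$trait_name),
    unit = if ("unit" %in% names(traits)) as.character(traits$unit)
           else NA_character_,
    maternal_mean = traits$maternal_mean,
    paternal_mean = traits$paternal_mean,
    hybrid_mean = traits$hybrid_mean,
    stringsAsFactors = FALSE)
  out$mid_parent <- (out$maternal_mean + out$paternal_mean) / 2
  out$high_parent <- pmax(out$maternal_mean, out$paternal_mean)
  bad <- which(out$mid_parent == 0 | out$high_parent == 0)
  if (length(bad))
    stop("undefined heterosis (zero parental value) for trait '",
         out$trait_name[bad[1L]], "', cross '", out$cross_id[bad[1L]], "'",
         call. = FALSE)
  out$mph_percent <- 100 * (out$hybrid_mean - out$mid_parent) / out$mid_parent
  out$hph_percent <- 100 * (out$hybrid_mean - out$high_parent) / out$high_parent
  out <- out[order(out$trait_name, out$cross_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("heterosis_table", "data.frame")
  out
}

#' @export
print.heterosis_table <- function(x, ...) {
  shown <- as.data.frame(x)
  shown$mph_percent <- round_half_away(shown$mph_percent, 2)
  shown$hph_percent <- round_half_away(shown$hph_percent, 2)
  print(shown, row.names = FALSE)
  invisible(x)
}

#' Round half away from zero
#'
#' Report-time rounding rule used throughout: exact halves round away from
#' zero (31.015 -> 31.02, -31.015 -> -31.02), unlike [round()]'s
#' round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}
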