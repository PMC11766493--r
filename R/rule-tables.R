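#' Vesicle type specifications (V1-V6)
#'
#' The six admissible vesicle types, each defined by an inclusive range of
#' peptide counts, RNA counts, and codon-assigned amino-acid counts, together
#' with the fitness-score range the corner counts imply.  V6 vesicles are the
#' FUCAs (first universal cellular ancestors): large protocells that still
#' lack a complete genetic code.
#'
#' The printed fitness range is informational: the governing relation is
#' always `FS = NA x NP` (see [fitness_score()]).
#'
#' @return A tibble with one row per type and columns `type`, `np_min`,
#'   `np_max`, `nr_min`, `nr_max`, `na_min`, `na_max`, `fs_min`, `fs_max`.
#' @seealso [classify_vesicle()], [make_vesicle()]
#' @export
#' @examples
#' vesicle_type_specs()
vesicle_type_specs <- function() {
  tibble::tibble(
    type   = paste0("V", 1:6),
    np_min = c(2L, 5L, 11L, 21L, 31L, 41L),
    np_max = c(4L, 10L, 20L, 30L, 40L, 50L),
    nr_min = c(5L, 10L, 25L, 50L, 75L, 120L),
    nr_max = c(10L, 30L, 70L, 100L, 140L, 160L),
    na_min = c(5L, 6L, 8L, 10L, 12L, 14L),
    na_max = c(6L, 8L, 10L, 12L, 14L, 16L),
    fs_min = c(10L, 30L, 88L, 210L, 272L, 576L),
    fs_max = c(24L, 80L, 200L, 360L, 560L, 800L)
  )
}

# peptide-count lower bounds of V1..V6; NP < 2 is below the vesicle threshold
.np_breaks <- c(2L, 5L, 11L, 21L, 31L, 41L)
.type_labels <- c("below_threshold", paste0("V", 1:6))

#' Merge/acquisition probability matrix
#'
#' Pairwise encounter-resolution probabilities: entry `[i, j]` is the
#' probability that a vesicle of type `Vi` absorbs an encountered vesicle of
#' type `Vj` (its complement is the probability of being absorbed).  The
#' matrix is antisymmetric (`m[i, j] + m[j, i] == 1`) with 0.5 on the
#' diagonal; larger vesicles dominate smaller ones, and V1 never absorbs a
#' larger vesicle.  At resolution time the looked-up probability is perturbed
#' by a multiplicative jitter of 5-10% (see [resolve_encounter()]); exact 0
#' and 1 entries stay exact.
#'
#' @return A 6x6 numeric matrix with dimnames `V1`..`V6`.
#' @export
#' @examples
#' merge_matrix()["V6", "V2"]  # 0.9: a FUCA usually absorbs a V2
merge_matrix <- function() {
  m <- matrix(c(
    0.5, 0.0, 0.0, 0.0, 0.0, 0.0,
    1.0, 0.5, 0.4, 0.3, 0.2, 0.1,
    1.0, 0.6, 0.5, 0.4, 0.3, 0.2,
    1.0, 0.7, 0.6, 0.5, 0.4, 0.3,
    1.0, 0.8, 0.7, 0.6, 0.5, 0.4,
    1.0, 0.9, 0.8, 0.7, 0.6, 0.5
  ), nrow = 6, byrow = TRUE)
  dimnames(m) <- list(paste0("V", 1:6), paste0("V", 1:6))
  m
}

#' Biopolymer joining rules
#'
#' Per-cycle probability that two molecules inside the same vesicle join into
#' one longer molecule, as a function of the two molecules' length classes.
#' Peptides use the length classes 3-10, 11-25, 26-50, >=51 amino acids; RNAs
#' use 6-30, 31-60, 61-120, >120 nucleotide bases.  Probabilities are
#' symmetric in the two classes and fall off with length, from 1e-5 for two
#' short molecules to 1e-7 for two long ones.
#'
#' @param kind `"peptide"` or `"rna"`.
#' @return A list with `breaks` (lower bounds of the four length classes,
#'   suitable for `findInterval()`), `labels`, and `prob`, the symmetric 4x4
#'   joining-probability matrix.
#' @export
#' @examples
#' join_rules("peptide")$prob[1, 1]  # 1e-5 for two short peptides
join_rules <- function(kind = c("peptide", "rna")) {
  kind <- match.arg(kind)
  prob <- matrix(c(
    1.00, 0.60, 0.30, 0.10,
    0.60, 0.30, 0.10, 0.05,
    0.30, 0.10, 0.05, 0.02,
    0.10, 0.05, 0.02, 0.01
  ), nrow = 4, byrow = TRUE) * 1e-5
  if (kind == "peptide") {
    breaks <- c(3L, 11L, 26L, 51L)
    labels <- c("3-10", "11-25", "26-50", ">=51")
  } else {
    breaks <- c(6L, 31L, 61L, 121L)
    labels <- c("6-30", "31-60", "61-120", ">120")
  }
  dimnames(prob) <- list(labels, labels)
  list(kind = kind, breaks = breaks, labels = labels, prob = prob)
}

# length -> class index 1..4 (lengths below the first break are clamped into
# class 1; they cannot arise from the default generator but joins must stay
# total)
.length_class <- function(len, breaks) {
  pmax(findInterval(len, breaks), 1L)
}
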