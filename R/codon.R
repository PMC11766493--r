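#' Size of the codon-combination pool
#'
#' With `b` nucleotides available before the code froze (4 to 6), the pool
#' of possible combinations of the 20 amino acids with triplet codons is
#' `20 * b^3`: 1280, 2500, or 4320.  Each run draws one pool size and
#' records it in the run summary; the pool does not modulate assignment
#' probability (the assignment dynamics are governed by
#' [assignment_probability()]).
#'
#' @param b Integer number of available nucleotides, in 4..6.
#' @return Integer pool size.
#' @export
#' @examples
#' combination_pool_size(4)  # 1280
#' combination_pool_size(6)  # 4320
combination_pool_size <- function(b) {
  b <- as.integer(b)
  if (any(is.na(b)) || any(b < 4L | b > 6L)) {
    stop("number of available nucleotides must be an integer in 4..6")
  }
  20L * b * b * b
}

#' Per-attempt codon-assignment probability
#'
#' In `"fixed"` mode every attempt succeeds with probability
#' `p_synchronize` (default 0.999) regardless of how many amino acids are
#' already assigned.  In `"feedback"` mode the probability grows with the
#' number `n` already assigned — each assignment shrinks the pool left for
#' the rest, accelerating the next one:
#' `P = base_p * (20 / (20 - n))^2`, i.e. `1e-3` for the first amino acid
#' and 0.4 for the twentieth.
#'
#' @param n_assigned Integer vector, number of amino acids already assigned
#'   (0..19).
#' @param mode `"fixed"` or `"feedback"`.
#' @param base_p Feedback-mode base probability (default `1e-3`).
#' @param p_synchronize Fixed-mode success probability (default 0.999).
#' @return Numeric vector of probabilities.
#' @export
#' @examples
#' assignment_probability(0, mode = "feedback")   # 0.001
#' assignment_probability(10, mode = "feedback")  # 0.004
#' assignment_probability(7, mode = "fixed")      # 0.999
assignment_probability <- function(n_assigned, mode = c("fixed", "feedback"),
                                   base_p = 1e-3, p_synchronize = 0.999) {
  mode <- match.arg(mode)
  if (any(n_assigned < 0 | n_assigned > 19)) {
    stop("n_assigned must lie in 0..19 (a full code admits no further ",
         "assignment)")
  }
  if (mode == "fixed") {
    rep_len(p_synchronize, length(n_assigned))
  } else {
    base_p * (20 / (20 - n_assigned))^2
  }
}

#' Attempt one codon assignment for a vesicle
#'
#' At most one amino acid can be assigned per whole wet-and-dry cycle (two
#' simulator cycles); attempts therefore only fire on even cycle indices,
#' the end of each wet-dry pair.  While fewer than ten amino acids are
#' assigned the candidate is the lowest unassigned early amino acid (any
#' vesicle type may attempt it); once the ten early ones are complete, the
#' candidate is the lowest unassigned late amino acid, but only a V6 vesicle
#' (FUCA) may attempt it, and only when late assignment is enabled for the
#' experiment.  The attempt succeeds with [assignment_probability()].
#'
#' With `config$candidate_rule = "random"` the candidate is instead drawn
#' uniformly from the unassigned amino acids of the admissible block; amino
#' acid identities never affect the dynamics, only the early/late split.
#'
#' @param v A [vesicle()].
#' @param config A [sim_config()].
#' @param cycle_index Integer simulator cycle (1-based); attempts fire when
#'   it is even.
#' @return The (possibly updated) vesicle.
#' @export
#' @examples
#' set.seed(1)
#' v <- vesicle(rep(5, 45), rep(15, 130), assigned_aas = 1:19)
#' v2 <- attempt_assignment(v, sim_config(experiment = "stage2"), 2)
#' length(v2$assigned_aas)
attempt_assignment <- function(v, config = sim_config(), cycle_index = 2L) {
  if (cycle_index %% 2L != 0L) return(v)
  n <- length(v$assigned_aas)
  if (n >= 20L) return(v)
  if (n < 10L) {
    pool <- setdiff(1:10, v$assigned_aas)
  } else {
    if (!isTRUE(config$late_assignment) || classify_vesicle(v) != "V6") {
      return(v)
    }
    pool <- setdiff(11:20, v$assigned_aas)
  }
  candidate <- if (identical(config$candidate_rule, "random")) {
    pool[sample.int(length(pool), 1L)]
  } else {
    min(pool)
  }
  p <- assignment_probability(n, mode = config$assignment_mode,
                              base_p = config$base_assign_p,
                              p_synchronize = config$p_synchronize)
  if (stats::runif(1) < p) {
    v$assigned_aas <- sort(c(v$assigned_aas, candidate))
  }
  v
}

#' Union of two codon-assignment sets
#'
#' When two vesicles merge, the merged vesicle obtains all codon
#' assignments of both ancestors (horizontal biomolecule transfer of the
#' code itself).  The union of two sets that each respect early-before-late
#' again respects it: late indices only occur in sets that already contain
#' all ten early indices.
#'
#' @param a_set,b_set Integer vectors of assigned amino-acid indices.
#' @return Sorted integer vector, the set union.
#' @export
#' @examples
#' union_assignments(1:5, c(1:4, 6))  # 1..6
union_assignments <- function(a_set, b_set) {
  sort(unique(c(as.integer(a_set), as.integer(b_set))))
}
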