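#' Draw the pond volume for a phase
#'
#' The pond starts at 100 units; each dry phase draws a volume uniformly
#' from \[50, 80\] and each wet phase from \[80, 100\].  Shrinking volume
#' concentrates the vesicles and raises their contact probability
#' quadratically (see [contact_probability()]).
#'
#' @param phase `"wet"` or `"dry"`.
#' @return Volume in units.
#' @export
#' @examples
#' set.seed(1)
#' update_volume("dry")
update_volume <- function(phase = c("wet", "dry")) {
  phase <- match.arg(phase)
  if (phase == "dry") stats::runif(1, 50, 80) else stats::runif(1, 80, 100)
}

#' Pairwise contact probability
#'
#' `PC = base * (100 / X)^2` with `X` the current pond volume: halving the
#' volume quadruples the chance that any given pair of vesicles meets during
#' a cycle.  The base probability lies in \[1e-6, 1e-5\] and is drawn once
#' per run (see [sim_config()]).
#'
#' @param base Base contact probability.
#' @param volume Current pond volume in units (> 0).
#' @return Probability of contact for one vesicle pair.
#' @export
#' @examples
#' contact_probability(1e-5, 50)  # 4e-5
contact_probability <- function(base, volume) {
  if (any(volume <= 0)) stop("pond volume must be positive")
  base * (100 / volume)^2
}

#' Sample the contact events of one cycle
#'
#' Draws the number of contacts as a binomial over all `n (n - 1) / 2`
#' vesicle pairs with per-pair probability `p_contact`, then samples that
#' many disjoint pairs (a vesicle takes part in at most one encounter per
#' cycle, so the event count is capped at `floor(n / 2)`).  Event-count
#' sampling is statistically equivalent to sweeping a Bernoulli draw over
#' every pair but costs O(events) instead of O(n^2).
#'
#' @param n Number of living vesicles.
#' @param p_contact Per-pair contact probability for this cycle.
#' @return An integer matrix with two columns (`a`, `b`), one row per
#'   contact event; zero rows when no contact occurs.
#' @export
#' @examples
#' set.seed(1)
#' sample_contacts(5000, 4e-5)
sample_contacts <- function(n, p_contact) {
  if (n < 2L || p_contact <= 0) {
    return(matrix(integer(), ncol = 2, dimnames = list(NULL, c("a", "b"))))
  }
  n_pairs <- as.numeric(n) * (n - 1) / 2
  m <- stats::rbinom(1L, n_pairs, min(p_contact, 1))
  m <- min(m, n %/% 2L)
  if (m == 0L) {
    return(matrix(integer(), ncol = 2, dimnames = list(NULL, c("a", "b"))))
  }
  idx <- sample.int(n, 2L * m)
  matrix(idx, ncol = 2, dimnames = list(NULL, c("a", "b")))
}

# multiplicative jitter of an absorb probability: relative factor uniform in
# +/- [margin]; exact 0 and 1 entries stay exact (jittering an impossibility
# must not make it possible)
.jitter_prob <- function(p, margin = c(0.05, 0.10)) {
  out <- p
  inner <- p > 0 & p < 1
  k <- sum(inner)
  if (k) {
    f <- stats::runif(k, margin[1], margin[2]) *
      sample(c(-1, 1), k, replace = TRUE)
    out[inner] <- pmin(pmax(p[inner] * (1 + f), 0), 1)
  }
  out
}

#' Resolve an encounter between two vesicles
#'
#' Looks up the absorb probability for the pair of types in
#' [merge_matrix()], perturbs it by a uniform relative jitter of 5-10%
#' (complement renormalized; exact 0/1 entries untouched), draws the
#' absorber, and merges the loser's contents into the winner via
#' [merge_vesicles()].  With merging disabled in the configuration the
#' encounter has no effect.  Vesicles below the V1 threshold behave as V1 in
#' the lookup.
#'
#' @param a,b Two distinct [vesicle()]s.
#' @param config A [sim_config()].
#' @return A list with `outcome` (`"merge"` or `"no_merge"`) and, for a
#'   merge, `winner` (the merged vesicle) and `absorbed` (the removed one),
#'   both flagged `merged_this_cycle`.
#' @export
#' @examples
#' set.seed(1)
#' a <- make_vesicle("V1"); b <- make_vesicle("V2")
#' resolve_encounter(a, b, sim_config())$winner  # V2 always absorbs V1
resolve_encounter <- function(a, b, config = sim_config()) {
  if (!isTRUE(config$merge_enabled)) {
    return(list(outcome = "no_merge"))
  }
  ia <- max(findInterval(length(a$peptides), .np_breaks), 1L)
  ib <- max(findInterval(length(b$peptides), .np_breaks), 1L)
  p_a <- .jitter_prob(merge_matrix()[ia, ib], config$merge_jitter)
  a_wins <- stats::runif(1) < p_a
  winner <- if (a_wins) a else b
  absorbed <- if (a_wins) b else a
  absorbed$merged_this_cycle <- TRUE
  list(outcome = "merge",
       winner = merge_vesicles(winner, absorbed),
       absorbed = absorbed)
}

#' Merge two vesicles
#'
#' The winner gains every peptide and RNA of the absorbed vesicle (counts
#' are conserved: `NP` and `NR` add) and the union of both codon-assignment
#' sets ([union_assignments()]).  The merged vesicle is flagged as having
#' merged this cycle, which exempts it from the survival lottery.
#'
#' @param winner,absorbed Two [vesicle()]s.
#' @return The merged [vesicle()] (the winner's identity).
#' @export
#' @examples
#' w <- vesicle(rep(5, 5), rep(15, 15), 1:5)
#' l <- vesicle(rep(5, 10), rep(15, 30), c(1:4, 6))
#' merge_vesicles(w, l)
merge_vesicles <- function(winner, absorbed) {
  winner$peptides <- c(winner$peptides, absorbed$peptides)
  winner$rnas <- c(winner$rnas, absorbed$rnas)
  winner$assigned_aas <- union_assignments(winner$assigned_aas,
                                           absorbed$assigned_aas)
  winner$merged_this_cycle <- TRUE
  winner
}

# draw and execute joins for one molecule-length vector under one rule
# table; each molecule participates in at most one join per cycle, and the
# number of joining pairs per class combination is binomial over the pair
# count (equivalent to per-pair Bernoulli sweeps at these probabilities).
.sample_joins <- function(len, rules) {
  n <- length(len)
  if (n < 2L) return(len)
  cls <- .length_class(len, rules$breaks)
  cnt <- tabulate(cls, 4L)
  kmat <- matrix(0L, 4, 4)
  for (i in 1:4) {
    for (j in i:4) {
      n_pairs <- if (i == j) cnt[i] * (cnt[i] - 1) / 2 else cnt[i] * cnt[j]
      if (n_pairs < 1) next
      kmat[i, j] <- stats::rbinom(1L, n_pairs, rules$prob[i, j])
    }
  }
  if (!sum(kmat)) return(len)
  .exec_joins(len, rules$breaks, kmat)
}

# execute `kmat[i, j]` joins between molecules of length classes i and j
# (upper-triangular counts); joined molecules are consumed and the product
# is not eligible for a further join this cycle
.exec_joins <- function(len, breaks, kmat) {
  cls <- .length_class(len, breaks)
  used <- rep(FALSE, length(len))
  new_len <- integer()
  for (i in 1:4) {
    for (j in i:4) {
      k <- kmat[i, j]
      while (k > 0L) {
        avail_i <- which(!used & cls == i)
        avail_j <- which(!used & cls == j)
        if (i == j) {
          if (length(avail_i) < 2L) break
          pick <- avail_i[sample.int(length(avail_i), 2L)]
        } else {
          if (!length(avail_i) || !length(avail_j)) break
          pick <- c(avail_i[sample.int(length(avail_i), 1L)],
                    avail_j[sample.int(length(avail_j), 1L)])
        }
        used[pick] <- TRUE
        new_len <- c(new_len, sum(len[pick]))
        k <- k - 1L
      }
    }
  }
  if (length(new_len)) c(len[!used], new_len) else len
}

#' Join biopolymers within a vesicle
#'
#' Every unordered pair of peptides (and, independently, of RNAs) inside a
#' vesicle may join into one molecule of summed length, with the
#' length-class probability of [join_rules()]; each molecule joins at most
#' once per cycle.  Joining conserves total residue length while reducing
#' molecule counts, so it trades peptide number (and hence fitness) for
#' molecule length.
#'
#' @param v A [vesicle()].
#' @param peptide_rules,rna_rules Rule tables, defaulting to
#'   [join_rules()].
#' @return The (possibly updated) vesicle.
#' @export
#' @examples
#' set.seed(1)
#' v <- make_vesicle("V2")
#' v2 <- join_biopolymers(v)
join_biopolymers <- function(v, peptide_rules = join_rules("peptide"),
                             rna_rules = join_rules("rna")) {
  v$peptides <- .sample_joins(v$peptides, peptide_rules)
  v$rnas <- .sample_joins(v$rnas, rna_rules)
  v
}

#' Absorb monomers from the pond
#'
#' Amino acids, nucleotides and short oligomers are in unlimited supply in
#' the pond.  Each cycle a vesicle absorbs peptide material with
#' probability `p_abs` and, independently, RNA material with probability
#' `p_abs`.  In the default `"elongate"` mode the absorbed material extends
#' one randomly chosen existing molecule (peptides grow by a draw from the
#' short-peptide length range, RNAs by three times such a draw), so
#' molecule counts never change without a merger.  In `"add"` mode the
#' vesicle instead gains a whole new short molecule.
#'
#' @param v A [vesicle()].
#' @param config A [sim_config()]; supplies `p_abs`, `absorb_mode` and the
#'   length range.
#' @return The (possibly updated) vesicle.
#' @export
#' @examples
#' set.seed(1)
#' v <- make_vesicle("V1")
#' absorb_monomers(v, sim_config(p_abs = 1))
absorb_monomers <- function(v, config = sim_config()) {
  lmin <- config$init_peptide_len[1]
  lmax <- config$init_peptide_len[2]
  if (stats::runif(1) < config$p_abs) {
    gain <- sample(lmin:lmax, 1L)
    if (config$absorb_mode == "elongate" && length(v$peptides)) {
      k <- sample.int(length(v$peptides), 1L)
      v$peptides[k] <- v$peptides[k] + gain
    } else {
      v$peptides <- c(v$peptides, gain)
    }
  }
  if (stats::runif(1) < config$p_abs) {
    gain <- 3L * sample(lmin:lmax, 1L)
    if (config$absorb_mode == "elongate" && length(v$rnas)) {
      k <- sample.int(length(v$rnas), 1L)
      v$rnas[k] <- v$rnas[k] + gain
    } else {
      v$rnas <- c(v$rnas, gain)
    }
  }
  v
}
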