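#' Construct a vesicle
#'
#' A vesicle is one protocell agent: a bag of peptides and RNAs (only their
#' lengths are modelled, not their sequences) plus the set of amino acids
#' that have been assigned a codon set.  Amino-acid indices 1-10 are the ten
#' "early" amino acids (Gly, Ala, Ser, Asp, Glu, Val, Leu, Ile, Pro, Thr);
#' 11-20 are the ten "late" ones (Phe, Tyr, Arg, His, Trp, Asn, Gln, Lys,
#' Cys, Met).  A vesicle may only hold late assignments once all ten early
#' amino acids are assigned (the early-before-late invariant).
#'
#' @param peptides Integer vector of peptide lengths (amino acids, each >= 1).
#' @param rnas Integer vector of RNA lengths (nucleotide bases, each >= 1).
#' @param assigned_aas Integer vector of assigned amino-acid indices in 1..20.
#' @param id Optional integer identifier.
#' @param merged_this_cycle Logical; whether the vesicle took part in a
#'   merger during the current cycle (exempts it from the survival lottery).
#' @return An object of class `"vesicle"`.
#' @export
#' @examples
#' v <- vesicle(peptides = c(4, 7, 9), rnas = rep(12, 8), assigned_aas = 1:5)
#' classify_vesicle(v)
vesicle <- function(peptides, rnas, assigned_aas = integer(),
                    id = NA_integer_, merged_this_cycle = FALSE) {
  peptides <- as.integer(peptides)
  rnas <- as.integer(rnas)
  assigned_aas <- sort(unique(as.integer(assigned_aas)))
  if (any(peptides < 1L)) stop("peptide lengths must be >= 1")
  if (any(rnas < 1L)) stop("RNA lengths must be >= 1")
  if (length(assigned_aas) &&
      (min(assigned_aas) < 1L || max(assigned_aas) > 20L)) {
    stop("assigned amino-acid indices must lie in 1..20")
  }
  if (any(assigned_aas > 10L) && !all(1:10 %in% assigned_aas)) {
    stop("early-before-late violated: late amino acids (11..20) require all ",
         "ten early amino acids (1..10) to be assigned")
  }
  structure(
    list(id = as.integer(id), peptides = peptides, rnas = rnas,
         assigned_aas = assigned_aas,
         merged_this_cycle = isTRUE(merged_this_cycle)),
    class = "vesicle"
  )
}

#' @export
print.vesicle <- function(x, ...) {
  cat(sprintf("<vesicle%s> %s: NP=%d NR=%d NA=%d FS=%d\n",
              if (is.na(x$id)) "" else paste0(" ", x$id),
              classify_vesicle(x),
              length(x$peptides), length(x$rnas), length(x$assigned_aas),
              fitness_score(x)))
  invisible(x)
}

#' Classify a peptide count into a vesicle type
#'
#' Classification keys on the peptide count NP alone: 2-4 -> V1, 5-10 -> V2,
#' 11-20 -> V3, 21-30 -> V4, 31-40 -> V5, and NP >= 41 -> V6 (open-ended,
#' since mergers can push NP past any printed upper bound).  NP < 2 falls
#' below the threshold of being a vesicle.  NP is the only monotone,
#' non-overlapping axis of the type table, which keeps classification total
#' after arbitrary mergers; RNA and assigned-amino-acid counts are not
#' re-checked after creation.
#'
#' @param np Integer vector of peptide counts (>= 0).
#' @return Character vector of labels in
#'   `c("below_threshold", "V1", ..., "V6")`.
#' @export
#' @examples
#' classify_np(c(1, 3, 45))
classify_np <- function(np) {
  stopifnot(all(np >= 0))
  .type_labels[findInterval(np, .np_breaks) + 1L]
}

#' @describeIn classify_np Classify a `vesicle` object.
#' @param v A [vesicle()].
#' @export
classify_vesicle <- function(v) {
  classify_np(length(v$peptides))
}

#' Fitness score of a vesicle
#'
#' `FS = NA x NP`: the product of the number of codon-assigned amino acids
#' and the number of peptides.  A vesicle with no assignments (or no
#' peptides) has fitness 0.
#'
#' @param v A [vesicle()].
#' @return A non-negative integer.
#' @export
#' @examples
#' v <- vesicle(peptides = rep(5, 21), rnas = rep(15, 60), assigned_aas = 1:10)
#' fitness_score(v)  # 10 * 21 = 210
fitness_score <- function(v) {
  length(v$assigned_aas) * length(v$peptides)
}

#' Survival probability from a fitness score
#'
#' `PS = ln(FS) / 10`, clamped into \[0, 1\]: scores of 1 or less map to 0
#' (the raw logarithm would be non-positive) and scores above `e^10` map
#' to 1.  Vesicles that merged during the current cycle bypass this lottery
#' entirely (see [survival_lottery()]).
#'
#' @param fs Numeric vector of non-negative fitness scores.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
#' @examples
#' survival_probability(c(1, 800, 30000))
survival_probability <- function(fs) {
  stopifnot(all(fs >= 0))
  ifelse(fs <= 1, 0, pmin(1, log(fs) / 10))
}

#' Is this vesicle a FUCA?  A LUCA?
#'
#' A FUCA (first universal cellular ancestor) is any type-V6 vesicle: a
#' large protocell that has not yet completed the genetic code.  A LUCA
#' (last universal common/cellular ancestor) is a vesicle with all twenty
#' amino acids codon-assigned, at least 100 peptides, and at least 300 RNAs;
#' the first LUCA ends a simulation.  Every LUCA is necessarily a FUCA under
#' the classification rule, since NP >= 100 implies type V6.
#'
#' @param v A [vesicle()].
#' @param na_required,np_min,nr_min The LUCA thresholds (defaults 20, 100,
#'   300).
#' @return Logical scalar.
#' @export
#' @examples
#' v <- vesicle(rep(8, 100), rep(24, 300), assigned_aas = 1:20)
#' is_luca(v)
is_fuca <- function(v) {
  classify_vesicle(v) == "V6"
}

#' @rdname is_fuca
#' @export
is_luca <- function(v, na_required = 20L, np_min = 100L, nr_min = 300L) {
  length(v$assigned_aas) >= na_required &&
    length(v$peptides) >= np_min &&
    length(v$rnas) >= nr_min
}

#' Sample a new vesicle of a given type
#'
#' Draws a fresh vesicle from the type-specification table: NP uniform over
#' the type's peptide range; NR uniform over the intersection of the type's
#' RNA range with the admissible ratio band `NR/NP` in \[2.5, 3.5\] (the
#' ratio band takes precedence when the intersection is empty); per-peptide
#' lengths uniform over `config$init_peptide_len` (default 3-10 amino
#' acids); per-RNA lengths 3x an independent draw from the same range; and
#' the assigned set equal to the first `k` amino acids with `k` uniform over
#' the type's assigned range (so V6 seeds carry all ten early plus some late
#' amino acids).
#'
#' @param type_label One of `"V1"`..`"V6"`.
#' @param config A [sim_config()]; supplies the peptide-length range and
#'   ratio band.
#' @return A [vesicle()].
#' @export
#' @examples
#' set.seed(1)
#' make_vesicle("V1")
make_vesicle <- function(type_label, config = sim_config()) {
  specs <- vesicle_type_specs()
  ti <- match(type_label, specs$type)
  if (is.na(ti)) {
    stop("unknown vesicle type label: ", type_label,
         " (expected one of ", paste(specs$type, collapse = ", "), ")")
  }
  b <- .make_batch(rep(ti, 1L), config)
  vesicle(peptides = b$pep[[1]], rnas = b$rna[[1]],
          assigned_aas = seq_len(b$na[1]))
}

# ---- internal vectorized batch construction ---------------------------------

# types: integer vector of type indices 1..6.  Returns parallel vectors
# np, nr, na and list columns pep, rna.  When np_override is given (stage-2
# style custom inventories) NP is taken as given and NR follows the ratio
# band alone; na_range overrides the per-type assigned range.
.make_batch <- function(types, config = sim_config(), np_override = NULL,
                        na_range = NULL) {
  specs <- vesicle_type_specs()
  n <- length(types)
  if (n == 0L) {
    return(list(np = integer(), nr = integer(), na = integer(),
                pep = list(), rna = list()))
  }
  rlo <- config$ratio_range[1]
  rhi <- config$ratio_range[2]
  if (is.null(np_override)) {
    np <- .runif_int(specs$np_min[types], specs$np_max[types])
    nr_lo <- pmax(as.integer(ceiling(rlo * np)), specs$nr_min[types])
    nr_hi <- pmin(as.integer(floor(rhi * np)), specs$nr_max[types])
  } else {
    np <- as.integer(np_override)
    nr_lo <- as.integer(ceiling(rlo * np))
    nr_hi <- as.integer(floor(rhi * np))
  }
  # ratio band takes precedence when it misses the type's RNA range
  bad <- nr_lo > nr_hi
  if (any(bad)) {
    nr_lo[bad] <- as.integer(ceiling(rlo * np[bad]))
    nr_hi[bad] <- pmax(as.integer(floor(rhi * np[bad])), nr_lo[bad])
  }
  nr <- .runif_int(nr_lo, nr_hi)
  if (is.null(na_range)) {
    na <- .runif_int(specs$na_min[types], specs$na_max[types])
  } else {
    na <- .runif_int(rep(as.integer(na_range[1]), n),
                     rep(as.integer(na_range[2]), n))
  }
  lmin <- config$init_peptide_len[1]
  lmax <- config$init_peptide_len[2]
  pep_all <- sample(lmin:lmax, sum(np), replace = TRUE)
  rna_all <- 3L * sample(lmin:lmax, sum(nr), replace = TRUE)
  pep <- unname(split(pep_all, rep.int(seq_len(n), np)))
  rna <- unname(split(rna_all, rep.int(seq_len(n), nr)))
  list(np = np, nr = nr, na = na, pep = pep, rna = rna)
}

# vectorized uniform integer draw on [lo, hi] (inclusive), lo/hi vectors
.runif_int <- function(lo, hi) {
  as.integer(pmin(lo + floor(stats::runif(length(lo)) * (hi - lo + 1L)), hi))
}
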