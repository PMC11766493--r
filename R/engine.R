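# The population engine.
#
# A pond_state is an environment holding the whole system as parallel
# vectors (np, nr, na, merged, been_v6, id) plus two ragged list columns of
# molecule lengths (pep, rna).  All per-cycle processes are vectorized over
# the population; only rare events (mergers, joins, absorptions) touch the
# list columns, so ~1500-cycle runs with ~5000 living agents stay cheap.
#
# The assigned-amino-acid set of every vesicle is represented by its count
# `na` alone: under the deterministic lowest-index candidate rule the set is
# always the prefix {1..na}, and the union taken at a merger is the prefix
# {1..max(na_a, na_b)}.  Population runs therefore always use the
# deterministic candidate rule; the alternative random-candidate rule is
# available on single vesicle objects (see attempt_assignment()).

#' Create a pond state
#'
#' Seeds the RNG from the configuration, draws the per-run base contact
#' probability and codon-pool size, and builds the initial population:
#' `v1_init` V1 plus `v2_init` V2 vesicles for the stage-1, combined and
#' control experiments, or `stage2_fuca_count` seeded FUCAs (type V6 with
#' peptide counts in `stage2_np_range`, RNA counts tied to the NR/NP ratio
#' band, and 14-16 assigned amino acids) for stage 2.  The pond starts at
#' 100 volume units in cycle 0; cycle 1 is a dry phase and phases alternate
#' strictly thereafter.
#'
#' @param config A [sim_config()].
#' @return An environment of class `"pond_state"`.
#' @export
#' @examples
#' st <- new_pond_state(sim_config(seed = 1))
#' pond_census(st)
new_pond_state <- function(config = sim_config()) {
  validate_config(config)
  set.seed(config$seed)
  st <- new.env(parent = emptyenv())
  st$cfg <- config
  st$cycle <- 0L
  st$phase <- "init"
  st$volume <- 100
  st$contact_base <- if (is.na(config$contact_base)) {
    stats::runif(1, config$contact_base_range[1], config$contact_base_range[2])
  } else {
    config$contact_base
  }
  st$pool_b <- if (is.null(config$pool_b)) sample(4:6, 1L) else config$pool_b
  st$pool_size <- combination_pool_size(st$pool_b)

  st$np <- integer(); st$nr <- integer(); st$na <- integer()
  st$pep <- list(); st$rna <- list()
  st$merged <- logical(); st$been_v6 <- logical(); st$id <- integer()
  st$next_id <- 1L
  st$dead_cum <- 0
  st$fuca_cum <- 0L
  st$first_fuca_cycle <- NA_integer_
  st$lucas <- list()
  st$first_luca_cycle <- NA_integer_
  st$halted <- FALSE

  if (config$experiment == "stage2") {
    n <- config$stage2_fuca_count
    if (n > 0L) {
      np0 <- .runif_int(rep(config$stage2_np_range[1], n),
                        rep(config$stage2_np_range[2], n))
      batch <- .make_batch(rep(6L, n), config, np_override = np0,
                           na_range = config$stage2_na_range)
      .pop_append(st, batch, been_v6 = TRUE)
    }
  } else {
    types <- c(rep(1L, config$v1_init), rep(2L, config$v2_init))
    .pop_append(st, .make_batch(types, config))
  }

  ncol_census <- 14L
  st$census <- matrix(NA_real_, nrow = config$max_cycles + 1L,
                      ncol = ncol_census)
  colnames(st$census) <- c("cycle", "volume", "n_below", "n_V1", "n_V2",
                           "n_V3", "n_V4", "n_V5", "n_V6", "n_total",
                           "n_dead_cum", "n_fuca_cum", "n_luca",
                           "mean_fs")
  st$census_phase <- character(config$max_cycles + 1L)
  st$census_max_na <- integer(config$max_cycles + 1L)
  st$census_rows <- 0L
  .census_row(st)
  st
}

#' @export
print.pond_state <- function(x, ...) {
  cat(sprintf(
    "<pond_state> cycle %d (%s), volume %.1f, %d vesicles alive, %d FUCAs produced, %d LUCAs\n",
    x$cycle, x$phase, x$volume, length(x$np), x$fuca_cum, length(x$lucas)))
  invisible(x)
}

# append a batch (list np/nr/na/pep/rna) to the population
.pop_append <- function(st, batch, been_v6 = FALSE) {
  n <- length(batch$np)
  if (n == 0L) return(invisible(st))
  st$np <- c(st$np, batch$np)
  st$nr <- c(st$nr, batch$nr)
  st$na <- c(st$na, batch$na)
  st$pep <- c(st$pep, batch$pep)
  st$rna <- c(st$rna, batch$rna)
  st$merged <- c(st$merged, rep(FALSE, n))
  st$been_v6 <- c(st$been_v6, rep(been_v6, n) | batch$np >= 41L)
  st$id <- c(st$id, seq.int(st$next_id, length.out = n))
  st$next_id <- st$next_id + n
  invisible(st)
}

# keep only the vesicles flagged TRUE
.pop_keep <- function(st, keep) {
  if (all(keep)) return(invisible(st))
  st$np <- st$np[keep]
  st$nr <- st$nr[keep]
  st$na <- st$na[keep]
  st$pep <- st$pep[keep]
  st$rna <- st$rna[keep]
  st$merged <- st$merged[keep]
  st$been_v6 <- st$been_v6[keep]
  st$id <- st$id[keep]
  invisible(st)
}

#' Vesicle influx
#'
#' Adds `k` new vesicles to the pond, with `k` drawn uniformly from the
#' phase's configured range (2000-3000 in a dry phase, 4000-5000 in a wet
#' phase by default); each new vesicle is independently V1 or V2 with equal
#' probability, built like [make_vesicle()].
#'
#' @param state A [new_pond_state()].
#' @param phase `"wet"` or `"dry"`.
#' @param config Configuration (defaults to the state's own).
#' @return The state, invisibly.
#' @export
influx <- function(state, phase = state$phase, config = state$cfg) {
  rng <- if (phase == "dry") config$influx_dry else config$influx_wet
  k <- .runif_int(rng[1], rng[2])
  if (k > 0L) {
    types <- sample(1:2, k, replace = TRUE)
    .pop_append(state, .make_batch(types, config))
  }
  invisible(state)
}

#' Dry-phase breakage
#'
#' Each living vesicle is destroyed with probability `p_break`; destroyed
#' contents are lost to the pond (whose monomer supply is unlimited
#' anyway).  Applied during dry phases only in the cycle loop.
#'
#' @param state A [new_pond_state()].
#' @param p_break Breakage probability (defaults to the configured value).
#' @return The state, invisibly.
#' @export
apply_breakage <- function(state, p_break = state$cfg$p_break) {
  n <- length(state$np)
  if (n == 0L || p_break <= 0) return(invisible(state))
  keep <- stats::runif(n) >= p_break
  state$dead_cum <- state$dead_cum + (n - sum(keep))
  .pop_keep(state, keep)
}

#' Survival lottery
#'
#' Every vesicle that did not merge this cycle survives with probability
#' [survival_probability()] of its [fitness_score()]; vesicles that took
#' part in a merger are exempt.  Merge flags are reset afterwards and
#' deaths accumulate in the state's perished counter.
#'
#' @param state A [new_pond_state()].
#' @return The state, invisibly.
#' @export
survival_lottery <- function(state) {
  n <- length(state$np)
  if (n == 0L) return(invisible(state))
  fs <- state$na * state$np
  ps <- survival_probability(fs)
  keep <- state$merged | (stats::runif(n) < ps)
  state$dead_cum <- state$dead_cum + (n - sum(keep))
  .pop_keep(state, keep)
  state$merged <- rep(FALSE, length(state$np))
  invisible(state)
}

# vectorized encounter resolution over the sampled disjoint pairs
.resolve_encounters <- function(st, pairs) {
  a <- pairs[, 1L]; b <- pairs[, 2L]
  m <- merge_matrix()
  ia <- pmax(findInterval(st$np[a], .np_breaks), 1L)
  ib <- pmax(findInterval(st$np[b], .np_breaks), 1L)
  p_a <- .jitter_prob(m[cbind(ia, ib)], st$cfg$merge_jitter)
  a_wins <- stats::runif(length(a)) < p_a
  w <- ifelse(a_wins, a, b)
  l <- ifelse(a_wins, b, a)

  np <- st$np; nr <- st$nr; na <- st$na
  pep <- st$pep; rna <- st$rna
  for (k in seq_along(w)) {
    wi <- w[k]; li <- l[k]
    pep[[wi]] <- c(pep[[wi]], pep[[li]])
    rna[[wi]] <- c(rna[[wi]], rna[[li]])
    np[wi] <- np[wi] + np[li]
    nr[wi] <- nr[wi] + nr[li]
    na[wi] <- max(na[wi], na[li])
  }
  st$np <- np; st$nr <- nr; st$na <- na
  st$pep <- pep; st$rna <- rna
  st$merged[w] <- TRUE
  st$dead_cum <- st$dead_cum + length(l)
  keep <- rep(TRUE, length(st$np))
  keep[l] <- FALSE
  .pop_keep(st, keep)
}

# population-wide biopolymer joining: tabulate per-vesicle length-class
# counts, draw binomial join counts per class combination, and execute the
# (rare) joins vesicle by vesicle
.join_step_one <- function(st, which_mol, rules) {
  n <- length(st$np)
  if (n == 0L) return(invisible(st))
  mols <- if (which_mol == "pep") st$pep else st$rna
  cnt_col <- if (which_mol == "pep") st$np else st$nr
  all_len <- unlist(mols, use.names = FALSE)
  if (length(all_len) < 2L) return(invisible(st))
  ves <- rep.int(seq_len(n), cnt_col)
  cls <- .length_class(all_len, rules$breaks)
  cmat <- matrix(tabulate((ves - 1L) * 4L + cls, 4L * n),
                 nrow = n, byrow = TRUE)
  total <- integer(n)
  kdraw <- vector("list", 10L)
  combo <- 0L
  combos <- which(upper.tri(diag(4), diag = TRUE), arr.ind = TRUE)
  for (r in seq_len(nrow(combos))) {
    i <- combos[r, 1L]; j <- combos[r, 2L]
    size <- if (i == j) cmat[, i] * (cmat[, i] - 1) / 2
            else as.numeric(cmat[, i]) * cmat[, j]
    k <- stats::rbinom(n, size, rules$prob[i, j])
    combo <- combo + 1L
    kdraw[[combo]] <- k
    total <- total + k
  }
  touched <- which(total > 0L)
  if (!length(touched)) return(invisible(st))
  for (v in touched) {
    kmat <- matrix(0L, 4, 4)
    for (r in seq_len(nrow(combos))) {
      kmat[combos[r, 1L], combos[r, 2L]] <- kdraw[[r]][v]
    }
    mols[[v]] <- .exec_joins(mols[[v]], rules$breaks, kmat)
  }
  if (which_mol == "pep") {
    st$pep <- mols
    st$np[touched] <- lengths(mols[touched])
  } else {
    st$rna <- mols
    st$nr[touched] <- lengths(mols[touched])
  }
  invisible(st)
}

.join_step <- function(st) {
  .join_step_one(st, "pep", join_rules("peptide"))
  .join_step_one(st, "rna", join_rules("rna"))
  invisible(st)
}

# monomer absorption across the population (see absorb_monomers())
.absorb_step <- function(st) {
  n <- length(st$np)
  if (n == 0L || st$cfg$p_abs <= 0) return(invisible(st))
  cfg <- st$cfg
  lmin <- cfg$init_peptide_len[1]; lmax <- cfg$init_peptide_len[2]
  ev_p <- which(stats::runif(n) < cfg$p_abs)
  ev_r <- which(stats::runif(n) < cfg$p_abs)
  if (length(ev_p)) {
    gains <- sample(lmin:lmax, length(ev_p), replace = TRUE)
    if (cfg$absorb_mode == "elongate") {
      for (t in seq_along(ev_p)) {
        v <- ev_p[t]
        if (st$np[v] == 0L) next
        k <- sample.int(st$np[v], 1L)
        st$pep[[v]][k] <- st$pep[[v]][k] + gains[t]
      }
    } else {
      for (t in seq_along(ev_p)) {
        v <- ev_p[t]
        st$pep[[v]] <- c(st$pep[[v]], gains[t])
      }
      st$np[ev_p] <- st$np[ev_p] + 1L
    }
  }
  if (length(ev_r)) {
    gains <- 3L * sample(lmin:lmax, length(ev_r), replace = TRUE)
    if (cfg$absorb_mode == "elongate") {
      for (t in seq_along(ev_r)) {
        v <- ev_r[t]
        if (st$nr[v] == 0L) next
        k <- sample.int(st$nr[v], 1L)
        st$rna[[v]][k] <- st$rna[[v]][k] + gains[t]
      }
    } else {
      for (t in seq_along(ev_r)) {
        v <- ev_r[t]
        st$rna[[v]] <- c(st$rna[[v]], gains[t])
      }
      st$nr[ev_r] <- st$nr[ev_r] + 1L
    }
  }
  invisible(st)
}

# codon-assignment attempts, fired at the end of each wet-dry pair (even
# cycle index): early amino acids for every vesicle below ten assignments,
# late ones for V6 vesicles when the experiment enables them
.assign_step <- function(st) {
  n <- length(st$np)
  if (n == 0L) return(invisible(st))
  cfg <- st$cfg
  elig <- st$na < 10L
  if (cfg$late_assignment) {
    elig <- elig | (st$na >= 10L & st$na < 20L & st$np >= 41L)
  }
  idx <- which(elig)
  if (!length(idx)) return(invisible(st))
  p <- assignment_probability(st$na[idx], mode = cfg$assignment_mode,
                              base_p = cfg$base_assign_p,
                              p_synchronize = cfg$p_synchronize)
  succ <- idx[stats::runif(length(idx)) < p]
  st$na[succ] <- st$na[succ] + 1L
  invisible(st)
}

.flag_new_fucas <- function(st) {
  new <- st$np >= 41L & !st$been_v6
  k <- sum(new)
  if (k > 0L) {
    st$fuca_cum <- st$fuca_cum + k
    st$been_v6[new] <- TRUE
    if (is.na(st$first_fuca_cycle)) st$first_fuca_cycle <- st$cycle
  }
  invisible(st)
}

.check_luca <- function(st) {
  cfg <- st$cfg
  cand <- which(st$na >= cfg$luca_na & st$np >= cfg$luca_np &
                  st$nr >= cfg$luca_nr)
  if (length(cand)) {
    if (is.na(st$first_luca_cycle)) st$first_luca_cycle <- st$cycle
    for (v in cand) {
      st$lucas[[length(st$lucas) + 1L]] <- vesicle(
        peptides = st$pep[[v]], rnas = st$rna[[v]],
        assigned_aas = seq_len(st$na[v]), id = st$id[v])
    }
    if (cfg$halt_on_luca) st$halted <- TRUE
  }
  invisible(st)
}

.census_row <- function(st) {
  cls <- findInterval(st$np, .np_breaks)  # 0 = below threshold
  counts <- tabulate(cls + 1L, 7L)
  r <- st$census_rows + 1L
  st$census[r, ] <- c(st$cycle, st$volume, counts, length(st$np),
                      st$dead_cum, st$fuca_cum, length(st$lucas),
                      if (length(st$np)) mean(st$na * st$np) else NA_real_)
  st$census_phase[r] <- st$phase
  st$census_max_na[r] <- if (length(st$na)) max(st$na) else 0L
  st$census_rows <- r
  invisible(st)
}

#' Advance the pond by one cycle
#'
#' One cycle is one phase (dry on odd cycle indices, wet on even ones).
#' The fixed order of operations is: phase flip, volume draw, vesicle
#' influx, contact sampling, encounter resolution (merger and codon-set
#' union), biopolymer joining, monomer absorption, codon-assignment attempt
#' (end of each wet-dry pair), dry-phase breakage, survival lottery, LUCA
#' check, and census.
#'
#' @param state A [new_pond_state()].
#' @return The state, invisibly; `state$halted` turns `TRUE` when the first
#'   LUCA has emerged and the experiment halts on it.
#' @export
step_cycle <- function(state) {
  cfg <- state$cfg
  state$cycle <- state$cycle + 1L
  state$phase <- if (state$cycle %% 2L == 1L) "dry" else "wet"
  state$volume <- update_volume(state$phase)
  if (cfg$influx_enabled) influx(state)
  n <- length(state$np)
  if (cfg$merge_enabled && n >= 2L) {
    pc <- contact_probability(state$contact_base, state$volume)
    pairs <- sample_contacts(n, pc)
    if (nrow(pairs)) .resolve_encounters(state, pairs)
  }
  .join_step(state)
  .absorb_step(state)
  if (state$cycle %% 2L == 0L) .assign_step(state)
  .flag_new_fucas(state)
  if (state$phase == "dry") apply_breakage(state)
  if (cfg$lottery_every == "cycle" || state$cycle %% 2L == 0L) {
    survival_lottery(state)
  }
  .check_luca(state)
  .census_row(state)
  invisible(state)
}

#' Per-cycle census of a pond state
#'
#' @param state A [new_pond_state()].
#' @return A tibble with one row per recorded cycle (cycle 0 is the
#'   initiation row): cycle, phase, volume, counts per type (including
#'   below-threshold remnants), totals, cumulative deaths, cumulative FUCA
#'   emergences, LUCA count, mean fitness score and maximum assigned-AA
#'   count.
#' @export
pond_census <- function(state) {
  r <- seq_len(state$census_rows)
  out <- tibble::as_tibble(as.data.frame(state$census[r, , drop = FALSE]))
  out$phase <- state$census_phase[r]
  out$max_na <- state$census_max_na[r]
  out[, c("cycle", "phase", "volume", "n_below", "n_V1", "n_V2", "n_V3",
          "n_V4", "n_V5", "n_V6", "n_total", "n_dead_cum", "n_fuca_cum",
          "n_luca", "mean_fs", "max_na")]
}
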