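#' Run a full simulation
#'
#' Builds the initial pond for the configured experiment and advances it
#' cycle by cycle ([step_cycle()]) until `max_cycles` or until the first
#' LUCA emerges (for experiments that halt on it).  All randomness flows
#' from `config$seed`, so identical configurations reproduce identical
#' results bit for bit.
#'
#' @param config A [sim_config()].
#' @return A `"pond_run"`: a list with `summary` (a `"run_summary"`),
#'   `census` (per-cycle tibble, see [pond_census()]), `lucas` (tibble of
#'   LUCA compositions, zero rows if none emerged), `state` (the final
#'   [new_pond_state()]) and `config`.
#' @export
#' @examples
#' run <- run_simulation(sim_config(experiment = "stage1", seed = 1,
#'                                  max_cycles = 4))
#' run$summary$cycles_run
run_simulation <- function(config = sim_config()) {
  st <- new_pond_state(config)
  while (st$cycle < config$max_cycles && !st$halted) {
    step_cycle(st)
    if (config$verbose && st$cycle %% 100L == 0L) {
      cat(sprintf("cycle %4d (%s): %d alive, %d FUCAs, %d LUCAs\n",
                  st$cycle, st$phase, length(st$np), st$fuca_cum,
                  length(st$lucas)))
    }
  }
  .build_run(st)
}

.luca_table <- function(st) {
  cfg <- st$cfg
  if (!length(st$lucas)) {
    return(tibble::tibble(id = integer(), np = integer(), nr = integer(),
                          na = integer(), pct_pep_long = numeric(),
                          pct_rna_long = numeric()))
  }
  tibble::tibble(
    id = vapply(st$lucas, function(v) v$id, integer(1)),
    np = vapply(st$lucas, function(v) length(v$peptides), integer(1)),
    nr = vapply(st$lucas, function(v) length(v$rnas), integer(1)),
    na = vapply(st$lucas, function(v) length(v$assigned_aas), integer(1)),
    pct_pep_long = vapply(st$lucas, function(v) {
      100 * mean(v$peptides > cfg$pep_len_threshold)
    }, numeric(1)),
    pct_rna_long = vapply(st$lucas, function(v) {
      100 * mean(v$rnas > cfg$rna_len_threshold)
    }, numeric(1))
  )
}

.build_run <- function(st) {
  cfg <- st$cfg
  lucas <- .luca_table(st)
  cls <- findInterval(st$np, .np_breaks)
  counts <- tabulate(cls + 1L, 7L)
  # the reported LUCA composition is the fittest LUCA's
  li <- if (nrow(lucas)) which.max(lucas$na * lucas$np) else NA_integer_
  summary <- structure(list(
    experiment = cfg$experiment,
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    contact_base = st$contact_base,
    pool_b = st$pool_b,
    pool_size = st$pool_size,
    cycles_run = st$cycle,
    volume_at_halt = st$volume,
    n_alive = length(st$np),
    n_below = counts[1], n_V1 = counts[2], n_V2 = counts[3],
    n_V3 = counts[4], n_V4 = counts[5], n_V5 = counts[6], n_V6 = counts[7],
    total_dead = st$dead_cum,
    first_fuca_cycle = st$first_fuca_cycle,
    fucas_produced = st$fuca_cum,
    first_luca_cycle = st$first_luca_cycle,
    n_lucas = nrow(lucas),
    luca_np = if (is.na(li)) NA_integer_ else lucas$np[li],
    luca_nr = if (is.na(li)) NA_integer_ else lucas$nr[li],
    luca_na = if (is.na(li)) NA_integer_ else lucas$na[li],
    pct_pep_long = if (is.na(li)) NA_real_ else lucas$pct_pep_long[li],
    pct_rna_long = if (is.na(li)) NA_real_ else lucas$pct_rna_long[li]
  ), class = "run_summary")
  structure(list(summary = summary, census = pond_census(st),
                 lucas = lucas, state = st, config = cfg),
            class = "pond_run")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("<run_summary> %s (seed %d): %d cycles, %d alive, %s dead\n",
              x$experiment, x$seed, x$cycles_run, x$n_alive,
              format(x$total_dead, big.mark = ",")))
  cat(sprintf("  first FUCA: %s   FUCAs produced: %d\n",
              ifelse(is.na(x$first_fuca_cycle), "never",
                     paste("cycle", x$first_fuca_cycle)),
              x$fucas_produced))
  cat(sprintf("  first LUCA: %s   LUCAs: %d\n",
              ifelse(is.na(x$first_luca_cycle), "never",
                     paste("cycle", x$first_luca_cycle)), x$n_lucas))
  if (!is.na(x$luca_np)) {
    cat(sprintf(
      "  LUCA composition: NP=%d NR=%d NA=%d (%.0f%% long peptides, %.0f%% long RNAs)\n",
      x$luca_np, x$luca_nr, x$luca_na, x$pct_pep_long, x$pct_rna_long))
  }
  invisible(x)
}

#' @export
print.pond_run <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' One row of summary statistics for a run
#'
#' @param run A `"pond_run"` (or its `"run_summary"`).
#' @return A one-row tibble.
#' @export
summary_row <- function(run) {
  s <- if (inherits(run, "pond_run")) run$summary else run
  tibble::as_tibble(lapply(unclass(s), function(x) {
    if (is.null(x)) NA else x
  }))
}

#' Run the four experiment designs
#'
#' `run_stage1()` starts from simple V1/V2 vesicles only and watches FUCAs
#' (type V6) emerge through mergers; `run_stage2()` starts from 300 seeded
#' FUCAs and watches a LUCA emerge through late-amino-acid codon
#' assignment; `run_combined()` runs both stages together from a V1/V2
#' start and halts at the first LUCA; `run_control()` is the combined
#' design with merging disabled — the negative control in which no FUCA or
#' LUCA ever arises and the census stays V1/V2 only.
#'
#' @param config A [sim_config()] whose `experiment` matches, or `NULL` to
#'   build one from `...`.
#' @param ... Passed to [sim_config()] when `config` is `NULL`.
#' @return A `"pond_run"`; see [run_simulation()].
#' @export
#' @examples
#' run <- run_stage1(seed = 1, max_cycles = 4)
#' run$summary$n_alive
run_stage1 <- function(config = NULL, ...) {
  .run_experiment("stage1", config, ...)
}

#' @rdname run_stage1
#' @export
run_stage2 <- function(config = NULL, ...) {
  .run_experiment("stage2", config, ...)
}

#' @rdname run_stage1
#' @export
run_combined <- function(config = NULL, ...) {
  .run_experiment("combined", config, ...)
}

#' @rdname run_stage1
#' @export
run_control <- function(config = NULL, ...) {
  .run_experiment("control", config, ...)
}

.run_experiment <- function(experiment, config, ...) {
  if (is.null(config)) {
    config <- sim_config(experiment = experiment, ...)
  } else if (!identical(config$experiment, experiment)) {
    stop("configuration is for experiment \"", config$experiment,
         "\", expected \"", experiment, "\"")
  }
  run_simulation(config)
}

#' Replicate batches
#'
#' Runs the configured experiment once per seed and aggregates the run
#' summaries into one table with a row per replicate plus `min`, `median`
#' and `max` summary rows.  Replicate seeds are derived from the master
#' seed (`config$seed`) by one `sample.int()` draw, so a batch is fully
#' reproducible from the configuration alone; an explicit `seed_list`
#' overrides the derivation.
#'
#' @param config A [sim_config()].
#' @param n_reps Number of replicates (>= 1).
#' @param seed_list Optional integer vector of seeds, length `n_reps`.
#' @return A `"pond_replicates"`: list with `runs` (the individual
#'   `"pond_run"`s) and `table` (the aggregated tibble).
#' @export
#' @examples
#' reps <- run_replicates(sim_config("stage1", max_cycles = 2), n_reps = 2)
#' reps$table$replicate
run_replicates <- function(config, n_reps, seed_list = NULL) {
  stopifnot(n_reps >= 1L)
  if (is.null(seed_list)) {
    set.seed(config$seed)
    seed_list <- sample.int(.Machine$integer.max - 1L, n_reps)
  }
  if (length(seed_list) != n_reps) {
    stop("`seed_list` must have length `n_reps`")
  }
  if (anyDuplicated(seed_list)) {
    warning("duplicate seeds in `seed_list`; replicates will coincide")
  }
  runs <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    cfg_i <- config
    cfg_i$seed <- as.integer(seed_list[i])
    runs[[i]] <- run_simulation(cfg_i)
  }
  rows <- do.call(rbind, lapply(runs, summary_row))
  num <- vapply(rows, is.numeric, logical(1))
  stat_row <- function(f, label) {
    out <- rows[1, ]
    out[1, ] <- NA
    for (cn in names(rows)[num]) {
      v <- rows[[cn]]
      out[[cn]] <- if (all(is.na(v))) NA else f(v, na.rm = TRUE)
    }
    out$experiment <- label
    out
  }
  table <- rbind(
    cbind(tibble::tibble(replicate = as.character(seq_len(n_reps))), rows),
    cbind(tibble::tibble(replicate = c("min", "median", "max")),
          rbind(stat_row(min, "min"), stat_row(stats::median, "median"),
                stat_row(max, "max")))
  )
  structure(list(runs = runs, table = tibble::as_tibble(table),
                 config = config, seed_list = as.integer(seed_list)),
            class = "pond_replicates")
}

#' @export
print.pond_replicates <- function(x, ...) {
  cat(sprintf("<pond_replicates> %s x %d seeds\n", x$config$experiment,
              length(x$runs)))
  print(x$table[, intersect(c("replicate", "seed", "cycles_run",
                              "first_fuca_cycle", "fucas_produced",
                              "first_luca_cycle", "n_lucas", "n_alive"),
                            names(x$table))])
  invisible(x)
}
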