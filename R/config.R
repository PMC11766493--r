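#' Simulation configuration
#'
#' Collects every tunable parameter of the simulator, with defaults equal to
#' the model's standard parameter set.  An empty call yields a runnable
#' configuration for the chosen experiment.
#'
#' Experiment-dependent defaults: `max_cycles` is 200 for `stage1` and
#' `stage2` and 1500 for `combined` and `control`; late-amino-acid
#' assignment is off in `stage1` and on otherwise; merging is forced off in
#' the `control` experiment; simulations halt at the first LUCA except in
#' `stage1`.
#'
#' @param experiment One of `"stage1"`, `"stage2"`, `"combined"`,
#'   `"control"`: start from simple vesicles and watch FUCAs emerge; start
#'   from 300 FUCAs and watch a LUCA emerge; run both stages together; or
#'   run the combined design with vesicle merging disabled (the negative
#'   control).
#' @param seed Integer RNG seed; every source of randomness in a run flows
#'   from it.
#' @param max_cycles Maximum number of simulator cycles (one cycle = one wet
#'   or one dry phase); `NULL` for the experiment default.
#' @param v1_init,v2_init Initial numbers of V1 and V2 vesicles (3000 and
#'   2000).
#' @param influx_dry,influx_wet Ranges (length 2) for the number of new
#'   V1/V2 vesicles added per dry (2000-3000) and wet (4000-5000) cycle.
#' @param influx_enabled Logical; set `FALSE` to disable the external vesicle
#'   supply entirely.
#' @param contact_base Base contact probability (default `1e-5`, the
#'   leading constant of the contact formula); set `NA` to instead draw one
#'   value per run uniformly from `contact_base_range`.
#' @param contact_base_range Admissible range for the base contact
#'   probability when it is drawn, default `c(1e-6, 1e-5)`.
#' @param merge_enabled Logical or `NA` for the experiment default
#'   (`FALSE` only for `control`).
#' @param merge_jitter Relative jitter band applied to the looked-up
#'   absorb probability at each encounter, default `c(0.05, 0.10)`.
#' @param p_abs Per-cycle probability of absorbing monomers from the pond
#'   (default `5e-3`).
#' @param absorb_mode `"elongate"` (absorbed monomers extend one existing
#'   molecule; the default) or `"add"` (absorption adds a whole new short
#'   molecule).
#' @param p_break Per-vesicle breakage probability in each dry phase
#'   (default 0.01).
#' @param p_synchronize Fixed-mode codon-assignment success probability per
#'   wet-dry cycle (default 0.999).
#' @param assignment_mode `"fixed"` or `"feedback"`; see
#'   [assignment_probability()].
#' @param base_assign_p Feedback-mode base probability (default `1e-3`).
#' @param late_assignment Logical or `NA` for the experiment default;
#'   whether V6 vesicles may assign the ten late amino acids.
#' @param lottery_every `"pair"` (survival lottery once per complete
#'   wet-dry cycle, i.e. every second phase; the default, matching the
#'   cadence of codon assignment) or `"cycle"` (every phase).
#' @param init_peptide_len Range of per-peptide lengths at creation
#'   (default 3-10 amino acids); RNA lengths are 3x draws from the same
#'   range.
#' @param ratio_range Admissible `NR/NP` band at creation, default
#'   `c(2.5, 3.5)`.
#' @param luca_na,luca_np,luca_nr LUCA criteria: all 20 amino acids
#'   assigned, at least 100 peptides, at least 300 RNAs.
#' @param stage2_fuca_count Number of FUCAs seeding a stage-2 run (300).
#' @param stage2_np_range Peptide-count range of the seeded FUCAs
#'   (default `c(100, 416)`).
#' @param stage2_na_range Assigned-amino-acid range of the seeded FUCAs
#'   (default `c(14, 16)`).
#' @param pep_len_threshold,rna_len_threshold Reporting thresholds for the
#'   fraction of long molecules in a LUCA (peptides over 50 amino acids,
#'   RNAs over 150 nucleotides).  Reporting metrics only, not LUCA criteria.
#' @param candidate_rule `"lowest"` (deterministic lowest-index candidate,
#'   the default) or `"random"`; see [attempt_assignment()].
#' @param pool_b Number of nucleotides available for codon combinations
#'   (4..6), or `NULL` to draw one per run; see [combination_pool_size()].
#' @param verbose Logical; print a one-line summary every 100 cycles.
#' @return A validated object of class `"sim_config"` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(experiment = "control", seed = 7)
#' cfg$merge_enabled  # FALSE: the control disables merging
sim_config <- function(experiment = c("stage1", "stage2", "combined",
                                      "control"),
                       seed = 1L,
                       max_cycles = NULL,
                       v1_init = 3000L,
                       v2_init = 2000L,
                       influx_dry = c(2000L, 3000L),
                       influx_wet = c(4000L, 5000L),
                       influx_enabled = TRUE,
                       contact_base = 1e-5,
                       contact_base_range = c(1e-6, 1e-5),
                       merge_enabled = NA,
                       merge_jitter = c(0.05, 0.10),
                       p_abs = 5e-3,
                       absorb_mode = c("elongate", "add"),
                       p_break = 0.01,
                       p_synchronize = 0.999,
                       assignment_mode = c("fixed", "feedback"),
                       base_assign_p = 1e-3,
                       late_assignment = NA,
                       lottery_every = c("pair", "cycle"),
                       init_peptide_len = c(3L, 10L),
                       ratio_range = c(2.5, 3.5),
                       luca_na = 20L,
                       luca_np = 100L,
                       luca_nr = 300L,
                       stage2_fuca_count = 300L,
                       stage2_np_range = c(100L, 416L),
                       stage2_na_range = c(14L, 16L),
                       pep_len_threshold = 50L,
                       rna_len_threshold = 150L,
                       candidate_rule = c("lowest", "random"),
                       pool_b = NULL,
                       verbose = FALSE) {
  experiment <- match.arg(experiment)
  absorb_mode <- match.arg(absorb_mode)
  assignment_mode <- match.arg(assignment_mode)
  lottery_every <- match.arg(lottery_every)
  candidate_rule <- match.arg(candidate_rule)

  if (is.null(max_cycles)) {
    max_cycles <- switch(experiment, stage1 = 200L, stage2 = 200L,
                         combined = 1500L, control = 1500L)
  }
  if (is.na(late_assignment)) late_assignment <- experiment != "stage1"
  if (experiment == "control") {
    if (isTRUE(merge_enabled)) {
      warning("experiment = \"control\" forces merge_enabled = FALSE")
    }
    merge_enabled <- FALSE
  } else if (is.na(merge_enabled)) {
    merge_enabled <- TRUE
  }
  halt_on_luca <- experiment != "stage1"

  cfg <- list(
    experiment = experiment,
    seed = as.integer(seed),
    max_cycles = as.integer(max_cycles),
    v1_init = as.integer(v1_init),
    v2_init = as.integer(v2_init),
    influx_dry = as.integer(influx_dry),
    influx_wet = as.integer(influx_wet),
    influx_enabled = isTRUE(influx_enabled),
    contact_base = as.numeric(contact_base),
    contact_base_range = as.numeric(contact_base_range),
    merge_enabled = isTRUE(merge_enabled),
    merge_jitter = as.numeric(merge_jitter),
    p_abs = as.numeric(p_abs),
    absorb_mode = absorb_mode,
    p_break = as.numeric(p_break),
    p_synchronize = as.numeric(p_synchronize),
    assignment_mode = assignment_mode,
    base_assign_p = as.numeric(base_assign_p),
    late_assignment = isTRUE(late_assignment),
    lottery_every = lottery_every,
    init_peptide_len = as.integer(init_peptide_len),
    ratio_range = as.numeric(ratio_range),
    luca_na = as.integer(luca_na),
    luca_np = as.integer(luca_np),
    luca_nr = as.integer(luca_nr),
    stage2_fuca_count = as.integer(stage2_fuca_count),
    stage2_np_range = as.integer(stage2_np_range),
    stage2_na_range = as.integer(stage2_na_range),
    pep_len_threshold = as.integer(pep_len_threshold),
    rna_len_threshold = as.integer(rna_len_threshold),
    candidate_rule = candidate_rule,
    pool_b = if (is.null(pool_b)) NULL else as.integer(pool_b),
    halt_on_luca = halt_on_luca,
    verbose = isTRUE(verbose)
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks every probability lies in \[0, 1\], every range is non-empty and
#' ordered, and counts are admissible.  Called by [sim_config()] and
#' [load_config()]; errors name the offending key.
#'
#' @param cfg A `"sim_config"` object.
#' @return `cfg`, invisibly, if valid.
#' @export
validate_config <- function(cfg) {
  chk_prob <- function(x, key) {
    if (any(is.na(x)) || any(x < 0 | x > 1)) {
      stop(sprintf("`%s` must be a probability in [0, 1], got %s",
                   key, paste(format(x), collapse = ", ")), call. = FALSE)
    }
  }
  chk_range <- function(x, key, lo = -Inf) {
    if (length(x) != 2L || any(is.na(x)) || x[1] > x[2] || x[1] < lo) {
      stop(sprintf("`%s` must be an ordered length-2 range (lower >= %s)",
                   key, format(lo)), call. = FALSE)
    }
  }
  chk_prob(cfg$p_abs, "p_abs")
  chk_prob(cfg$p_break, "p_break")
  chk_prob(cfg$p_synchronize, "p_synchronize")
  chk_prob(cfg$base_assign_p, "base_assign_p")
  if (!is.na(cfg$contact_base)) chk_prob(cfg$contact_base, "contact_base")
  chk_range(cfg$contact_base_range, "contact_base_range", lo = 0)
  chk_prob(cfg$contact_base_range, "contact_base_range")
  chk_range(cfg$influx_dry, "influx_dry", lo = 0)
  chk_range(cfg$influx_wet, "influx_wet", lo = 0)
  chk_range(cfg$merge_jitter, "merge_jitter", lo = 0)
  chk_range(cfg$init_peptide_len, "init_peptide_len", lo = 1)
  chk_range(cfg$ratio_range, "ratio_range", lo = 0)
  chk_range(cfg$stage2_np_range, "stage2_np_range", lo = 2)
  chk_range(cfg$stage2_na_range, "stage2_na_range", lo = 0)
  if (cfg$stage2_na_range[2] > 20L) {
    stop("`stage2_na_range` cannot exceed 20", call. = FALSE)
  }
  if (cfg$max_cycles < 0L) stop("`max_cycles` must be >= 0", call. = FALSE)
  if (cfg$v1_init < 0L || cfg$v2_init < 0L) {
    stop("initial vesicle counts must be >= 0", call. = FALSE)
  }
  if (cfg$stage2_fuca_count < 0L) {
    stop("`stage2_fuca_count` must be >= 0", call. = FALSE)
  }
  if (!is.null(cfg$pool_b) && (cfg$pool_b < 4L || cfg$pool_b > 6L)) {
    stop("`pool_b` must lie in 4..6", call. = FALSE)
  }
  invisible(cfg)
}

#' Load a configuration from a YAML document
#'
#' Reads a key-value configuration file, rejects unknown keys, applies the
#' defaults of [sim_config()] for everything absent, and validates.  An
#' empty document yields the full default configuration.  `load_config()`
#' and [write_config()] round-trip losslessly.
#'
#' @param path Path to a YAML file, or a named list already in memory.
#' @return A validated `"sim_config"`.
#' @export
#' @examples
#' path <- tempfile(fileext = ".yaml")
#' writeLines("experiment: control\nseed: 7", path)
#' load_config(path)$merge_enabled
load_config <- function(path) {
  doc <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(doc)) doc <- list()
  if (!is.list(doc)) stop("configuration document must be a key-value map")
  known <- names(formals(sim_config))
  unknown <- setdiff(names(doc), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  doc <- lapply(doc, function(x) if (is.list(x)) unlist(x) else x)
  do.call(sim_config, doc)
}

#' Write a configuration to YAML
#'
#' @param cfg A `"sim_config"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$halt_on_luca <- NULL  # derived, not a sim_config() argument
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' A short platform-stable hash of the full configuration (including the
#' seed), echoed into every run summary and output file for provenance.
#'
#' @param cfg A `"sim_config"`.
#' @return A character scalar.
#' @export
config_hash <- function(cfg) {
  x <- unclass(cfg)
  rlang::hash(x[order(names(x))])
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> experiment=%s seed=%d max_cycles=%d merge=%s\n",
              x$experiment, x$seed, x$max_cycles,
              if (x$merge_enabled) "on" else "off"))
  invisible(x)
}
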