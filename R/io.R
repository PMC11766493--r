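#' Write the output file set of a run
#'
#' Emits, into `out_dir`: `census.tsv` (per-cycle census), `summary.tsv`
#' (one-row run summary), `summary.json` (the same summary as structured
#' JSON with a config echo), `config_echo.yaml` (the exact configuration),
#' `type_specs.tsv` (the six vesicle type specifications, for provenance),
#' and `log.txt`.  All tabular files are UTF-8, tab-separated, with a
#' header row and LF line endings; given the same configuration and seed
#' the files are byte-identical across runs.
#'
#' @param run A `"pond_run"` from [run_simulation()].
#' @param out_dir Output directory (created if absent; must be writable).
#' @return Named character vector of the written paths, invisibly.
#' @export
#' @examples
#' run <- run_stage1(seed = 1, max_cycles = 2)
#' paths <- write_run_outputs(run, tempfile("pondlife-out-"))
#' basename(paths)
write_run_outputs <- function(run, out_dir) {
  stopifnot(inherits(run, "pond_run"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  probe <- file.path(out_dir, ".write-test")
  ok <- tryCatch({
    writeLines("", probe)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("output directory is not writable: ", out_dir)
  unlink(probe)

  paths <- c(
    census = file.path(out_dir, "census.tsv"),
    summary_tsv = file.path(out_dir, "summary.tsv"),
    summary_json = file.path(out_dir, "summary.json"),
    config = file.path(out_dir, "config_echo.yaml"),
    type_specs = file.path(out_dir, "type_specs.tsv"),
    log = file.path(out_dir, "log.txt")
  )
  write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  }
  write_tsv(run$census, paths[["census"]])
  srow <- summary_row(run)
  names(srow)[names(srow) == "first_fuca_cycle"] <- "cycles_to_first_fuca"
  names(srow)[names(srow) == "first_luca_cycle"] <- "cycles_to_first_luca"
  write_tsv(srow, paths[["summary_tsv"]])
  jsonlite::write_json(
    list(summary = unclass(run$summary),
         lucas = run$lucas,
         config = Filter(Negate(is.null), unclass(run$config))),
    paths[["summary_json"]],
    auto_unbox = TRUE, digits = NA, na = "null", null = "null", pretty = TRUE)
  write_config(run$config, paths[["config"]])
  write_tsv(vesicle_type_specs(), paths[["type_specs"]])
  s <- run$summary
  writeLines(c(
    sprintf("experiment: %s", s$experiment),
    sprintf("seed: %d", s$seed),
    sprintf("config_hash: %s", s$config_hash),
    sprintf("contact_base: %.6g", s$contact_base),
    sprintf("codon_pool_size: %d (b = %d)", s$pool_size, s$pool_b),
    sprintf("cycles_run: %d", s$cycles_run),
    sprintf("vesicles_alive: %d", s$n_alive),
    sprintf("total_dead: %.0f", s$total_dead),
    sprintf("first_fuca_cycle: %s", format(s$first_fuca_cycle)),
    sprintf("fucas_produced: %d", s$fucas_produced),
    sprintf("first_luca_cycle: %s", format(s$first_luca_cycle)),
    sprintf("n_lucas: %d", s$n_lucas)
  ), paths[["log"]])
  invisible(paths)
}
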