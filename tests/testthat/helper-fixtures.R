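# small deterministic builders used across the suite

# a vesicle with prescribed counts: np peptides of length plen, nr RNAs of
# length rlen, and the first `na` amino acids assigned
fixture_vesicle <- function(np, nr, na = 0L, plen = 5L, rlen = 15L) {
  vesicle(peptides = rep(plen, np), rnas = rep(rlen, nr),
          assigned_aas = seq_len(na))
}

# a tiny, fast configuration: small initial population, no influx, short runs
fixture_config <- function(experiment = "stage1", max_cycles = 10L,
                           influx_enabled = FALSE, ...) {
  sim_config(experiment = experiment, v1_init = 30L, v2_init = 20L,
             influx_enabled = influx_enabled, max_cycles = max_cycles, ...)
}
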