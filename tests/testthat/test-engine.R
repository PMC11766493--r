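test_that("a fresh pond starts full, at volume 100, with the configured census", {
  st <- new_pond_state(fixture_config())
  expect_identical(st$cycle, 0L)
  expect_identical(st$volume, 100)
  cen <- pond_census(st)
  expect_identical(nrow(cen), 1L)
  expect_identical(cen$volume, 100)
  expect_identical(cen$n_V1, 30)
  expect_identical(cen$n_V2, 20)
  expect_identical(cen$n_total, 50)
  # a stage-2 pond seeds FUCAs instead
  st2 <- new_pond_state(sim_config(experiment = "stage2",
                                   stage2_fuca_count = 40L,
                                   influx_enabled = FALSE))
  expect_identical(length(st2$np), 40L)
  expect_true(all(st2$np >= 100 & st2$np <= 416))
  expect_true(all(st2$na >= 14 & st2$na <= 16))
  expect_true(all(st2$been_v6))
  rat <- st2$nr / st2$np
  expect_true(all(rat >= 2.4 & rat <= 3.6))
})

test_that("phases alternate strictly and volumes stay inside the phase bands", {
  st <- new_pond_state(fixture_config(max_cycles = 12L))
  for (i in 1:12) step_cycle(st)
  cen <- pond_census(st)
  expect_identical(cen$phase, c("init", rep(c("dry", "wet"), 6)))
  dry <- cen$volume[cen$phase == "dry"]
  wet <- cen$volume[cen$phase == "wet"]
  expect_true(all(dry >= 50 & dry <= 80))
  expect_true(all(wet >= 80 & wet <= 100))
})

test_that("influx adds the configured number of V1/V2 vesicles", {
  set.seed(4)
  cfg <- fixture_config(influx_dry = c(100L, 120L), influx_wet = c(200L, 250L))
  st <- new_pond_state(cfg)
  n0 <- length(st$np)
  st$phase <- "dry"
  influx(st)
  added_dry <- length(st$np) - n0
  expect_gte(added_dry, 100L); expect_lte(added_dry, 120L)
  st$phase <- "wet"
  n1 <- length(st$np)
  influx(st)
  added_wet <- length(st$np) - n1
  expect_gte(added_wet, 200L); expect_lte(added_wet, 250L)
  # all newcomers are V1 or V2
  expect_true(all(st$np[(n0 + 1):length(st$np)] <= 10L))
})

test_that("dry-phase breakage and the survival lottery remove the right vesicles", {
  set.seed(6)
  st <- new_pond_state(fixture_config())
  n0 <- length(st$np)
  apply_breakage(st, p_break = 0)
  expect_identical(length(st$np), n0)
  apply_breakage(st, p_break = 1)
  expect_identical(length(st$np), 0L)
  expect_identical(st$dead_cum, as.numeric(n0))

  # merged vesicles are exempt from the lottery even at fitness zero
  st <- new_pond_state(fixture_config())
  st$na <- rep(0L, length(st$np))          # FS = 0 -> certain death ...
  st$merged <- rep(TRUE, length(st$np))    # ... unless merged this cycle
  n0 <- length(st$np)
  survival_lottery(st)
  expect_identical(length(st$np), n0)
  expect_false(any(st$merged))             # flags reset afterwards
  survival_lottery(st)                     # now nobody is exempt
  expect_identical(length(st$np), 0L)
})

test_that("encounter resolution conserves peptide and RNA totals", {
  set.seed(12)
  for (trial in 1:10) {
    st <- new_pond_state(fixture_config(seed = trial))
    tot_pep <- sum(st$np); tot_rna <- sum(st$nr)
    len_pep <- sum(unlist(st$pep)); len_rna <- sum(unlist(st$rna))
    n <- length(st$np)
    pairs <- sample_contacts(n, 0.2)
    dead0 <- st$dead_cum
    pondlife:::.resolve_encounters(st, pairs)
    expect_identical(sum(st$np), tot_pep)
    expect_identical(sum(st$nr), tot_rna)
    expect_identical(sum(unlist(st$pep)), len_pep)
    expect_identical(sum(unlist(st$rna)), len_rna)
    expect_identical(length(st$np), n - nrow(pairs))
    expect_identical(st$dead_cum, dead0 + nrow(pairs))
    # winners carry the union of the parents' assignment prefixes
    expect_true(all(st$na <= 20L))
  }
})

test_that("the vectorized joining step matches the per-vesicle sampler's contract", {
  set.seed(13)
  st <- new_pond_state(fixture_config())
  rules <- join_rules("peptide")
  rules$prob[] <- 0.5  # inflate so joins actually occur
  tot_len <- sum(unlist(st$pep))
  np0 <- st$np
  pondlife:::.join_step_one(st, "pep", rules)
  expect_identical(sum(unlist(st$pep)), tot_len)   # residues conserved
  expect_true(all(st$np <= np0))                   # joining only shrinks NP
  expect_true(all(st$np >= ceiling(np0 / 2)))      # one join per molecule
  expect_identical(st$np, lengths(st$pep))         # counts stay in sync
})

test_that("identical seed and configuration reproduce a run bit for bit", {
  cfg <- fixture_config(max_cycles = 8L, influx_enabled = TRUE,
                        influx_dry = c(20L, 30L), influx_wet = c(40L, 50L))
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$summary, b$summary)
  expect_identical(a$census, b$census)
  c2 <- run_simulation(fixture_config(max_cycles = 8L, seed = 2L,
                                      influx_enabled = TRUE,
                                      influx_dry = c(20L, 30L),
                                      influx_wet = c(40L, 50L)))
  expect_false(identical(a$census, c2$census))
})

test_that("lowering pond volume raises expected merge activity", {
  # quadratic contact scaling: at fixed N the expected number of encounter
  # events at volume 50 is 4x that at volume 100
  set.seed(21)
  n <- 400L
  m50 <- mean(replicate(400, nrow(sample_contacts(n, contact_probability(1e-5, 50)))))
  m100 <- mean(replicate(400, nrow(sample_contacts(n, contact_probability(1e-5, 100)))))
  expect_gt(m50 / m100, 3.2)
  expect_lt(m50 / m100, 4.8)
})

test_that("a merging-disabled pond never grows beyond V2", {
  cfg <- sim_config(experiment = "control", seed = 3, max_cycles = 60L,
                    v1_init = 300L, v2_init = 200L,
                    influx_dry = c(100L, 150L), influx_wet = c(200L, 250L))
  run <- run_simulation(cfg)
  cen <- run$census
  expect_true(all(cen$n_V3 == 0 & cen$n_V4 == 0 & cen$n_V5 == 0 &
                    cen$n_V6 == 0))
  expect_identical(run$summary$fucas_produced, 0L)
  expect_identical(run$summary$n_lucas, 0L)
})
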