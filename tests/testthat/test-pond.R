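test_that("pond volume stays inside the phase bands", {
  set.seed(1)
  dry <- replicate(200, update_volume("dry"))
  wet <- replicate(200, update_volume("wet"))
  expect_true(all(dry >= 50 & dry <= 80))
  expect_true(all(wet >= 80 & wet <= 100))
})

test_that("contact probability scales with the inverse square of volume", {
  expect_equal(contact_probability(1e-5, 100), 1e-5)
  expect_equal(contact_probability(1e-5, 50), 4e-5)
  expect_equal(contact_probability(1e-6, 80), 1.5625e-6)
  expect_error(contact_probability(1e-5, 0), "positive")
})

test_that("merge matrix is antisymmetric with a fair diagonal", {
  m <- merge_matrix()
  expect_identical(dim(m), c(6L, 6L))
  expect_equal(m + t(m), matrix(1, 6, 6), ignore_attr = TRUE)
  expect_equal(unname(diag(m)), rep(0.5, 6))
  # V1 never absorbs anything larger; larger types dominate
  expect_equal(unname(m[1, 2:6]), rep(0, 5))
  expect_equal(unname(m[6, ]), c(1, 0.9, 0.8, 0.7, 0.6, 0.5))
})

test_that("encounter jitter stays within 5-10% and leaves 0/1 exact", {
  set.seed(3)
  p <- replicate(500, pondlife:::.jitter_prob(0.4))
  rel <- abs(p / 0.4 - 1)
  expect_true(all(rel >= 0.05 - 1e-12 & rel <= 0.10 + 1e-12))
  expect_identical(unique(replicate(50, pondlife:::.jitter_prob(0))), 0)
  expect_identical(unique(replicate(50, pondlife:::.jitter_prob(1))), 1)
})

test_that("encounter resolution follows the matrix and conserves contents", {
  set.seed(11)
  cfg <- sim_config()
  # V1 meets V2: the V2 always absorbs (matrix entry 0 jitters to 0)
  for (r in 1:20) {
    a <- fixture_vesicle(3, 8, na = 5)   # V1
    b <- fixture_vesicle(7, 21, na = 6)  # V2
    res <- resolve_encounter(a, b, cfg)
    expect_identical(res$outcome, "merge")
    expect_identical(length(res$winner$peptides), 10L)  # 3 + 7
    expect_identical(length(res$winner$rnas), 29L)      # 8 + 21
    expect_true(res$winner$merged_this_cycle)
    expect_true(res$absorbed$merged_this_cycle)
    expect_identical(length(res$absorbed$peptides), 3L) # the V1 lost
  }
  # merging is disabled in control mode
  cfg0 <- sim_config(experiment = "control")
  expect_identical(resolve_encounter(a, b, cfg0)$outcome, "no_merge")
  # a V6 absorbs a V2 with probability about 0.9
  wins <- replicate(3000, {
    res <- resolve_encounter(fixture_vesicle(45, 140, na = 15),
                             fixture_vesicle(7, 21, na = 6), cfg)
    length(res$absorbed$peptides) == 7L  # the V2 was the one absorbed
  })
  expect_gt(mean(wins), 0.85)
  expect_lt(mean(wins), 0.95)
})

test_that("merging vesicles concatenates inventories and unions the code", {
  w <- vesicle(rep(4, 5), rep(12, 15), assigned_aas = 1:5)
  l <- vesicle(rep(6, 10), rep(18, 30), assigned_aas = c(1:4, 6))
  m <- merge_vesicles(w, l)
  expect_identical(length(m$peptides), 15L)
  expect_identical(length(m$rnas), 45L)
  expect_identical(m$assigned_aas, 1:6)
  expect_true(m$merged_this_cycle)
  # total residue material is conserved
  expect_identical(sum(m$peptides), sum(w$peptides) + sum(l$peptides))
  # identical assignment sets add no new amino acid
  m2 <- merge_vesicles(vesicle(rep(4, 5), rep(12, 15), 1:5),
                       vesicle(rep(4, 5), rep(12, 15), 1:5))
  expect_identical(m2$assigned_aas, 1:5)
})

test_that("joining rule tables carry the canonical probabilities", {
  pep <- join_rules("peptide")
  rna <- join_rules("rna")
  expect_equal(pep$prob[1, 1], 1e-5)
  expect_equal(pep$prob[4, 4], 0.01e-5)
  expect_equal(pep$prob[1, 4], 0.1e-5)
  expect_equal(pep$prob, t(pep$prob))  # symmetric in the two classes
  expect_equal(unname(rna$prob), unname(pep$prob))  # same surface
  expect_true(all(pep$prob > 0 & pep$prob <= 1e-5))
  # length classes: peptides by amino acids, RNAs by bases
  expect_identical(pondlife:::.length_class(c(5, 13, 30, 60), pep$breaks),
                   1:4)
  expect_identical(pondlife:::.length_class(c(9, 45, 100, 200), rna$breaks),
                   1:4)
})

test_that("biopolymer joining conserves residues and respects one-join-per-molecule", {
  set.seed(5)
  rules <- join_rules("peptide")
  rules$prob[] <- 1  # force every admissible pair to try to join
  for (r in 1:20) {
    len <- sample(3:60, 9, replace = TRUE)
    out <- pondlife:::.sample_joins(len, rules)
    expect_identical(sum(out), sum(len))       # residues conserved
    expect_gte(length(out), ceiling(9 / 2))    # each molecule joins <= once
    expect_lt(length(out), 9)                  # something joined
  }
  # no pair, no join
  expect_identical(pondlife:::.sample_joins(7L, rules), 7L)
  # at the default probabilities a small vesicle essentially never joins
  v <- fixture_vesicle(4, 10)
  out <- replicate(200, length(join_biopolymers(v)$peptides))
  expect_true(all(out == 4L))
})

test_that("monomer absorption elongates by default and adds when asked", {
  set.seed(8)
  cfg_el <- sim_config(p_abs = 1)
  v <- fixture_vesicle(4, 10)
  v2 <- absorb_monomers(v, cfg_el)
  expect_identical(length(v2$peptides), 4L)          # counts unchanged
  expect_identical(sum(v2$peptides) - sum(v$peptides) >= 3, TRUE)
  expect_true(sum(v2$rnas) > sum(v$rnas))
  cfg_add <- sim_config(p_abs = 1, absorb_mode = "add")
  v3 <- absorb_monomers(v, cfg_add)
  expect_identical(length(v3$peptides), 5L)          # one new short peptide
  expect_true(v3$peptides[5] >= 3 && v3$peptides[5] <= 10)
  expect_identical(length(v3$rnas), 11L)
  cfg_off <- sim_config(p_abs = 0)
  expect_identical(absorb_monomers(v, cfg_off)$peptides, v$peptides)
})

test_that("contact sampling matches a brute-force per-pair Bernoulli oracle", {
  # small-N oracle: sweep an independent Bernoulli draw over all pairs,
  # then discard conflicting events so each vesicle meets at most one
  # partner; the event-count-first sampler must agree on the mean number
  # of encounters within Monte-Carlo error
  n <- 6L; pc <- 0.01; reps <- 1e5
  pairs <- t(utils::combn(n, 2))
  set.seed(123)
  hits <- matrix(stats::runif(reps * nrow(pairs)) < pc, nrow = reps)
  cnt <- rowSums(hits)
  multi <- which(cnt >= 2L)
  for (r in multi) {
    idx <- sample(which(hits[r, ]))  # random resolution order
    seen <- logical(n); kept <- 0L
    for (k in idx) {
      if (!seen[pairs[k, 1]] && !seen[pairs[k, 2]]) {
        seen[pairs[k, ]] <- TRUE
        kept <- kept + 1L
      }
    }
    cnt[r] <- kept
  }
  oracle_mean <- mean(cnt)
  impl_mean <- mean(replicate(reps, nrow(sample_contacts(n, pc))))
  expect_equal(impl_mean, oracle_mean, tolerance = 0.05)  # relative
  # and both sit near the binomial expectation 15 * pc
  expect_equal(oracle_mean, nrow(pairs) * pc, tolerance = 0.05)
})

test_that("contact sampling respects its edge cases", {
  expect_identical(nrow(sample_contacts(1, 0.5)), 0L)
  expect_identical(nrow(sample_contacts(100, 0)), 0L)
  set.seed(2)
  p <- sample_contacts(2, 1)
  expect_identical(nrow(p), 1L)
  expect_setequal(as.vector(p), 1:2)
  # pairs are disjoint: no vesicle appears twice
  big <- sample_contacts(1000, 0.01)
  expect_false(any(duplicated(as.vector(big))))
})
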