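---
title: "The protocell merger model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The protocell merger model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pondlife)
```

## The model

`pondlife` simulates a "warm little pond" in which protocell vesicles
evolve by absorbing, acquiring and merging with one another under
alternating wet and dry phases.  The hypothesis being exercised is that the
last universal common ancestor (LUCA) did not evolve from a single lineage
in isolation but by pooling "global inventions" — peptides, RNAs, and
fragments of the genetic code — through repeated vesicle mergers
(horizontal biomolecule transfer).  The simulator therefore deliberately
excludes the chemistry around that mechanism: polymer synthesis, RNA
self-replication, membrane physics and metabolism are all out of scope, and
molecules are modelled as lengths only, with no sequence content.

A **vesicle** is a bag of peptide lengths (amino acids), RNA lengths
(nucleotide bases), and a set of amino acids that have been assigned a
codon set (the growing standard genetic code, SGC).  Vesicles fall into six
types, V1 through V6, by their peptide count NP: 2–4, 5–10, 11–20, 21–30,
31–40, and 41 and above.  V6 vesicles are **FUCAs** — first universal
cellular ancestors, large protocells whose code is still incomplete.  A
vesicle with all twenty amino acids assigned, at least 100 peptides, and at
least 300 RNAs is a **LUCA**; the first LUCA ends a simulation.

Each cycle is one phase.  Dry phases shrink the pond to 50–80 volume
units, wet phases refill it to 80–100; the pond starts at 100.  The
probability that a given pair of vesicles meets in a cycle is

$$P_C = p_0 \left( \frac{100}{X} \right)^2,$$

with $X$ the current volume, so drying concentrates the population and
drives encounters.  When two vesicles meet, one absorbs the other with a
type-pair probability (larger types dominate; two equal types are a coin
flip), perturbed multiplicatively by 5–10% at each encounter; the winner
gains all peptides, all RNAs, and the union of both codon-assignment sets.
Within a vesicle, pairs of peptides (or RNAs) join into longer molecules
with probabilities of at most $10^{-5}$ per pair per cycle, falling with
length; vesicles also absorb monomers from the pond's unlimited supply at
$5 \times 10^{-3}$ per cycle.

The fitness of a vesicle is $FS = N_A \times N_P$, the product of its
assigned-amino-acid and peptide counts, and a vesicle that did **not**
merge during a cycle survives its selection step with probability
$PS = \ln(FS)/10$ (clamped into $[0,1]$; $FS \le 1$ maps to 0).  Merging is
thus doubly favoured: it grows both factors of the fitness product and
exempts the participants from the current lottery.

Codon assignment proceeds strictly early-before-late: the ten early amino
acids (Gly, Ala, Ser, Asp, Glu, Val, Leu, Ile, Pro, Thr) must all be
assigned before any of the ten late ones (Phe … Met), and only FUCAs may
assign late amino acids.  One amino acid at most is assigned per complete
wet–dry cycle, with fixed probability 0.999 per attempt; an alternative
positive-feedback mode uses $P = 10^{-3}\,(20/(20-n))^2$, which grows from
$10^{-3}$ at $n = 0$ to $0.4$ at $n = 19$ as each assignment shrinks the
remaining codon pool.  The codon-combination pool itself is
$20\,b^3 \in \{1280, 2500, 4320\}$ for $b \in \{4,5,6\}$ available
nucleotides; it is drawn once per run and recorded, but does not modulate
the assignment probability.

## Experiments

Four designs are provided, differing only in initial population and which
assignment rules are active:

* **stage1** — 3000 V1 + 2000 V2; merging on; early assignment only;
  200 cycles.  Measures FUCA emergence.
* **stage2** — 300 seeded FUCAs (NP uniform in 100–416, NR tied to the
  NR/NP ratio band 2.5–3.5, 14–16 amino acids assigned); late assignment
  on; halts at the first LUCA.
* **combined** — stage-1 start with both assignment phases active; halts
  at the first LUCA or 1500 cycles.
* **control** — identical to combined but with merging disabled.  This is
  the negative control: without mergers NP can never grow (see below), so
  no vesicle ever leaves V1/V2 and no FUCA or LUCA can emerge.

In every phase the pond gains 2000–3000 (dry) or 4000–5000 (wet) fresh
V1/V2 vesicles; this influx replaces the de-novo vesicle formation that is
outside the model's scope and keeps populations at a quasi-steady
~4000–5000 living vesicles.

The per-cycle order of operations is fixed: phase flip, volume draw,
influx, contact sampling, encounter resolution, biopolymer joining,
monomer absorption, codon assignment (end of each wet–dry pair), dry-phase
breakage, survival lottery, LUCA check, census.

## What the generator emulates — and what it does not

The initial populations and influx **are** the study conditions: all
defaults in `sim_config()` are the model's standard parameter set, and the
stage-2 seeded-FUCA ranges are the model's canonical initial inventories.
New vesicles draw NP from their type's range, NR from the intersection of
the type range with the ratio band NR/NP ∈ [2.5, 3.5] (ratio wins if the
intersection is empty), per-peptide lengths uniform in 3–10 amino acids,
and per-RNA lengths three times such a draw — so every molecule starts in
the shortest joining-rule length class, and long molecules can only arise
by joining or elongation.

What passing tests show is that the *mechanism* behaves as intended:
merging (and only merging) moves vesicles up the type ladder, codes
complete only through FUCA-stage late assignment, and removing mergers
removes emergence entirely.  They do not show that the real prebiotic
parameters were these, and exact emergence *times* are not a stable
quantity of the model — they are single stochastic realizations that shift
with every under-specified mechanical choice.  One-sided envelopes
(emergence no later than a bound, production no smaller than a bound,
control exactly null) are the reproducible surface, and those are what the
test suite asserts.

## Numerical and design choices

Several mechanics are genuinely open in the model's verbal description;
the choices below were fixed once, during model selection against the
model's intended census and emergence behaviour, and are all configurable.

* **Classification keys on NP only, V6 open-ended.**  After arbitrary
  mergers the per-type RNA and assigned-amino-acid ranges overlap; NP is
  the only monotone non-overlapping axis, and keying on it keeps
  classification total.  RNA counts are checked at creation only.
* **Contact base probability fixed at $10^{-5}$.**  The contact formula
  admits a base anywhere in $[10^{-6}, 10^{-5}]$.  The combined experiment
  turns out to be supercritical in this parameter: below roughly
  $6 \times 10^{-6}$ merger cascades are too sparse for any FUCA lineage
  to finish its code within a desk-scale horizon, whereas the combined
  design is meant to produce its LUCA reliably and stage-1 runs their
  FUCAs in a consistent window — behaviour of one effective contact rate,
  not of a fresh order-of-magnitude draw per run.  We therefore default to
  the formula's leading constant $10^{-5}$; setting `contact_base = NA`
  restores a per-run uniform draw from `contact_base_range`.
* **Survival lottery once per wet–dry pair.**  Fitness selection is
  described over wet-and-dry cycles, the same cadence as codon assignment.
  A per-phase lottery doubles the death pressure, collapses the standing
  population to roughly half its intended quasi-steady size (~5000), and
  leaves the upper types essentially unpopulated; the per-pair default
  keeps every type represented at the magnitudes the model is built
  around.  `lottery_every = "cycle"` restores the per-phase variant.
* **Absorption elongates by default.**  Absorbed monomers extend one
  existing molecule rather than adding a new one, consistent with
  integrating material "into existing" molecules and — decisively — with
  the control observation that without mergers nothing ever grows past V2:
  if absorption added molecules, lone vesicles would drift across type
  boundaries.  `absorb_mode = "add"` restores the additive variant.
* **Breakage probability 0.01 per dry phase.**  No value is given for dry
  breakage; 1% per dry phase is small against the fitness lottery and its
  contents are discarded (the monomer supply is unlimited anyway).
* **Jitter on encounter probabilities** is multiplicative, uniform in
  ±[5%, 10%], applied to the row-absorbs entry with the complement
  renormalized; exact 0 and 1 entries stay exact, so an impossible
  acquisition stays impossible.
* **Event-count contact sampling.**  Contacts are drawn as a binomial
  count over all pairs, then that many disjoint pairs are selected, one
  encounter per vesicle per cycle — O(events) instead of an O(N²) pair
  sweep, and verified against the brute-force per-pair Bernoulli oracle at
  small N.
* **Deterministic lowest-index candidate** for codon assignment: amino
  acid identities never affect the dynamics, only the early/late split, so
  the assigned set is always the prefix {1..NA}.  This is what lets the
  population engine carry a count rather than a set; population runs always
  use this rule, and the random-candidate alternative is available on
  single vesicle objects.
* **Clamping** of $\ln(FS)/10$ into $[0,1]$, with $FS \le 1 \mapsto 0$:
  the formula is negative below $FS = 1$ and exceeds 1 above $e^{10}$, and
  neither case is addressed by the source.
* **FUCA counting** is cumulative over first entries into V6: a vesicle
  that reaches V6 and is later absorbed still counted, which is why
  cumulative FUCA production can exceed the living V6 census many-fold.
* **Pool size is drawn as $20 b^3$** with $b$ uniform in {4, 5, 6}, the
  generative form behind the stated 1280–4320 interval, rather than as an
  arbitrary integer in that interval.

## Problem sizes

The test suite runs the four designs at their full default populations
(3000 + 2000 initial vesicles, thousands more per cycle): the control for
1330 cycles on two seeds, stage 1 for 200 cycles on eight seeds, stage 2 on
twenty-five seeds, and the combined design on two seeds; property suites
use ponds of ~50 vesicles and 10^5-replicate Monte-Carlo comparisons.  The
vectorized engine covers roughly a thousand cycles of a ~5000-agent pond
per half minute, which keeps the whole suite and the acceptance script
desk-scale.

## Known limitations

* Emergence times are sensitive to the contact rate and to every
  under-specified mechanical choice; treat them as order-of-magnitude
  quantities and compare only envelope bounds across configurations.
* The pond is well-mixed: no spatial structure, no lipid accounting, no
  vesicle division.
* Molecules are lengths; sequence, function and chemistry are out of
  scope, as are stop codons and the actual contents of the codon table.
* Long-molecule fractions inside a LUCA depend mostly on elongation and
  joining, both rare at the default rates, so they stay near zero at the
  halt of a successful combined run; they are reported as metrics, not
  enforced as LUCA criteria.
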