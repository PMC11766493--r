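# pondlife

An agent-based simulator of protocell evolution in a "warm little pond"
under wet–dry cycling, built to exercise a specific origin-of-life
hypothesis: that the last universal common ancestor (**LUCA**) evolved not
from one lineage in isolation but by *pooling global inventions* — vesicles
repeatedly absorbing, acquiring and merging with one another, exchanging
peptides, RNAs, and fragments of the genetic code (horizontal biomolecule
transfer).

The simulator tracks a population of vesicles, each a bag of peptide
lengths, RNA lengths, and a set of codon-assigned amino acids.  Vesicle
types V1–V6 are keyed on peptide count NP (2–4, 5–10, 11–20, 21–30, 31–40,
≥41); a V6 vesicle is a **FUCA** (a large protocell with an incomplete
code), and a vesicle with all 20 amino acids assigned, NP ≥ 100 and
NR ≥ 300 is a **LUCA**, which ends the run.  The core relations are

* contact probability `PC = p0 · (100 / X)²` with pond volume `X` (50–80
  units in a dry phase, 80–100 wet) — drying concentrates the pond and
  drives encounters;
* fitness `FS = NA × NP` and survival `PS = ln(FS) / 10` for vesicles that
  did not merge this cycle (merging exempts both participants);
* encounter resolution by a type-pair acquisition matrix (larger types
  dominate, equal types are a coin flip, each probability jittered ±5–10%),
  with the winner taking all contents and the union of both codon sets;
* codon assignment strictly early-before-late (ten early amino acids
  before any of the ten late ones; late assignment is FUCA-only), one
  amino acid per wet–dry cycle with probability 0.999, or the
  positive-feedback law `P = 10⁻³ (20 / (20 − n))²`.

Four experiment designs are provided: `stage1` (FUCA emergence from simple
V1/V2 vesicles), `stage2` (LUCA emergence from 300 seeded FUCAs),
`combined` (both stages together), and `control` (identical to combined
but with merging disabled — the negative control, in which nothing ever
grows past V2).  See the methods vignette
(`vignettes/protocell-merger-model.Rmd`) for the model's assumptions,
parameter defaults and design decisions.

## A worked example

A combined two-stage run from a cold start, halting at the first LUCA:

```r
library(pondlife)
run <- run_combined(seed = 42)
print(run)
#> <run_summary> combined (seed 42): 40 cycles, 4537 alive, 136,786 dead
#>   first FUCA: cycle 6   FUCAs produced: 309
#>   first LUCA: cycle 40   LUCAs: 1
#>   LUCA composition: NP=121 NR=343 NA=20 (0% long peptides, 0% long RNAs)
```

The pond reached its first FUCA (a vesicle crossing 41 peptides, built
purely by mergers) in cycle 6, produced 309 distinct FUCAs, and in cycle
40 one FUCA lineage completed all twenty codon assignments while holding
121 peptides and 343 RNAs — a LUCA — at which point the run halts.  The
per-cycle census shows the standing type distribution:

```r
tail(run$census[, c("cycle", "phase", "volume", "n_V1", "n_V2", "n_V3",
                    "n_V4", "n_V5", "n_V6", "n_total", "n_fuca_cum")], 3)
#> # A tibble: 3 × 11
#>   cycle phase volume  n_V1  n_V2  n_V3  n_V4  n_V5  n_V6 n_total n_fuca_cum
#>   <dbl> <chr>  <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>   <dbl>      <dbl>
#> 1    38 wet     98.0  1143  2226   819   238    79    75    4580        285
#> 2    39 dry     59.8  1860  2748  1017   284    90    84    6083        296
#> 3    40 wet     95.4  1122  2112   918   234    73    78    4537        309
```

Roughly 4500–6000 vesicles are alive at any time (influx feeds V1/V2 every
phase; dry phases add fewer but concentrate the pond), with the type
pyramid thinning toward V6.  The same run with `run_control()` — merging
disabled, everything else identical — produces zero FUCAs, zero LUCAs, and
a census containing nothing beyond V2, which is the model's central
contrast.

Batches, result files and the command line:

```r
reps <- run_replicates(sim_config(experiment = "stage2"), n_reps = 25)
write_run_outputs(run, "runs/combined-42")   # census.tsv, summary.json, ...
```

```sh
Rscript inst/cli/pondlife.R control --seed 7 --max-cycles 1400 --out runs/ctrl
```

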