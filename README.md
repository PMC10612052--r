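# virdup

Discovery and characterization of large internal tandem duplications in
small viral genomes from long sequencing reads.

Short-read assemblies collapse long near-identical repeats: a read that
falls inside a repeat copy maps equally well to every copy, so the assembly
sees the segment once. The motivating case is the Sf-rhabdovirus of
*Spodoptera frugiperda* Sf9 cells, whose short-read genome (X+, GenBank
KF947078) was later shown by long-read sequencing to carry a 3.7 kb internal
duplication — the corrected genome X+3.7 (GenBank OQ158798) repeats the
interval between reference positions 4767 and 8523, separated by an inserted
`GA` dinucleotide. `virdup` implements that inference chain as tested,
reusable components, for anyone who works with small genomes (viruses,
organelles, plasmids) and suspects a repeat their assembly cannot see.

## What it does

* **Junction calling from long reads.** Reads are aligned to the
  *unduplicated* reference by k-mer seed-and-chain (`align_reads()`). A read
  crossing a duplication junction aligns as two colinear blocks whose
  reference coordinates jump *backward* — from the donor base `d` to the
  acceptor base `a ≤ d` — with any inserted bases left in the gap
  (`detect_backjumps()`). Candidates are refined by breakpoint re-alignment,
  canonicalized against microhomology ambiguity (`canonicalize_junction()`),
  clustered, and reported as consensus junctions `d^insert^a` with read
  support (`cluster_junctions()`, `call_junctions()`).
* **Reconstruction and exact liftover.** A duplication model
  (`dup_model()`) — reference, junction, optional terminal extension,
  per-copy edit list — defines the derived genome
  (`reconstruct()`) and exact coordinate maps among the reference, the
  first ("primary") copy and the second ("duplication") copy
  (`lift_ref_to_new()`, `lift_new_to_ref()`). `tidy()` renders the edit
  table in all three coordinate systems; `glance()` summarizes lengths,
  boundaries and copy identity.
* **Paralog-aware variant assignment.** `call_copy_variants()` maps long
  reads to the naive (edit-free) reconstruction and genotypes each repeat
  position separately per copy, using only reads anchored across the
  junction or in unique flanking sequence — the automated form of manually
  reviewing junction-spanning reads.
* **In-silico PCR.** `find_primer_sites()` (mismatch counting with an exact
  3' clamp) and `enumerate_amplicons()` reproduce duplication-diagnostic
  assays: primer pairs that only form a product across the junction, and
  pairs whose product length differs between copies.
* **Short-read mappability.** `map_short_reads()` contrasts the two
  standard multi-mapper policies — discard ("ignore") vs uniform random
  placement — and `compare_policies()` shows the coverage holes confined to
  the repeat copies that make short reads blind to the duplication.
* **Annotation.** `find_orfs()` and `scan_motif()` recover gene structure,
  junction-fusion ORFs, and the conserved intergenic signal
  (`GACACAAAAT`-like) whose absence between duplication-derived ORFs argues
  against their independent transcription.
* **Synthetic data.** `make_reference()` generates rhabdovirus-like genomes
  (genes N, P, M, G, X, L with intergenic motifs; the default layout matches
  the published X+ coordinates); `simulate_long_reads()` /
  `simulate_short_reads()` add configurable substitution/insertion/deletion
  errors with full ground truth; `sfrhabdo_model()` builds a surrogate X+3.7
  fixture carrying every published landmark at its published coordinate.

## Worked example

```r
library(virdup)
library(dplyr)

# the surrogate Sf-rhabdovirus X+3.7 duplication model
model <- sfrhabdo_model(seed = 1)
model
#> <dup_model> sfrhabdo_Xplus_surrogate: junction 8523^GA^4767 (segment 3757 nt), ext5 72, 26 edit(s)

glance(model) |> select(segment_length, primary_length, duplication_length,
                        primary_start, duplication_start, copy_identity_pct)
#> # A tibble: 1 × 6
#>   segment_length primary_length duplication_length primary_start
#>            <int>          <int>              <int>         <int>
#> 1           3757           3762               3757          4839
#> # ℹ 2 more variables: duplication_start <int>, copy_identity_pct <dbl>

# simulate nanopore-like reads from the duplicated genome and rediscover
# the junction against the unduplicated reference
genome_x37 <- reconstruct(model)
reads <- simulate_long_reads(genome_x37, n_reads = 120,
                             sub_rate = 0.03, ins_rate = 0.04, del_rate = 0.03,
                             seed = 42)
calls <- call_junctions(reads, model$reference)
calls |> select(donor, acceptor, insert, support)
#> # A tibble: 1 × 4
#>   donor acceptor insert support
#>   <int>    <int> <chr>    <int>
#> 1  8523     4767 GA          13

# in-silico PCR with the published duplication-spanning primer pair
primers <- sfrhabdo_primers()
enumerate_amplicons(genome_x37,
                    primers[primers$name == "F9", ],
                    primers[primers$name == "R6", ],
                    max_mismatch = 1, model = model) |>
  select(length, fwd_region, rev_region, spans_junction)
#> # A tibble: 1 × 4
#>   length fwd_region rev_region  spans_junction
#>    <int> <chr>      <chr>       <lgl>
#> 1   1935 primary    duplication TRUE
```

The junction call recovers the published breakpoint `8523^GA^4767` from 13
junction-spanning simulated reads at ~10% read error, the repeat copies have
the published lengths (3762 / 3757 nt, ~99% identity, primary copy starting
at derived position 4839), and the duplication-diagnostic primer pair yields
the published 1935 bp product — which cannot form on the unduplicated
reference at all.

A thin command-line wrapper ships in `inst/scripts/virdup`
(`simulate`, `reconstruct`, `call-junctions`, `ispcr`, `assign-variants`,
`mappability`, `annotate`, `demo`). The methods vignette
(`vignettes/duplication-discovery.Rmd`) documents the model, the parameter
defaults and the numerical design choices.

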