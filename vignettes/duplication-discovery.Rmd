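---
title: "Discovering internal duplications in small viral genomes from long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering internal duplications in small viral genomes from long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Short-read assemblies of small genomes silently collapse long, near-identical
repeats: every read that falls inside a repeat copy maps equally well to all
copies, so a reference-guided or de novo assembly sees no reason to believe
the segment exists twice. The Sf-rhabdovirus of *Spodoptera frugiperda* Sf9
cells is the motivating case: its X+ genome (GenBank KF947078), assembled from
short reads, later turned out to carry a 3.7 kb internal tandem duplication —
the interval between two breakpoints appears twice, separated by a two-base
insertion, and the corrected genome (X+3.7, GenBank OQ158798) is ~3.8 kb
longer. Only long reads spanning the duplication junction, plus targeted
RT-PCR, could establish this.

`virdup` packages that inference chain as reusable, tested components:

1. **Junction discovery** (`align_reads()`, `detect_backjumps()`,
   `cluster_junctions()`, `call_junctions()`): noisy long reads are aligned to
   the *unduplicated* reference by k-mer seed-and-chain; a read crossing the
   junction aligns as two colinear blocks whose reference coordinates jump
   *backward* (donor → acceptor), with the inserted bases left in the gap.
2. **Reconstruction and liftover** (`dup_model()`, `reconstruct()`,
   `lift_ref_to_new()`, `lift_new_to_ref()`): a duplication model — junction,
   optional terminal extension, per-copy edit list — defines the derived
   genome and exact coordinate maps among the reference, the first ("primary")
   copy and the second ("duplication") copy.
3. **Paralog-aware variant assignment** (`call_copy_variants()`): the two
   copies are not identical; assigning each difference to its copy requires
   reads anchored in unique sequence or across the junction. This automates
   what was originally a manual review of junction-spanning reads.
4. **In-silico PCR** (`find_primer_sites()`, `enumerate_amplicons()`): the
   published RT-PCR verification scheme — a primer pair that can only form a
   product across the junction, and a pair whose product lengths differ
   between copies — is reproduced by coordinate arithmetic.
5. **Short-read mappability** (`map_short_reads()`, `compare_policies()`):
   the two standard treatments of multi-mapping reads ("ignore" vs "random
   placement") are contrasted to show *why* short reads miss the repeat.
6. **Annotation** (`find_orfs()`, `scan_motif()`): duplications that cut
   genes mid-frame create fusion ORFs across the junction, and the conserved
   intergenic transcription signal is absent between duplication-derived
   ORFs — both structural signatures are recomputed rather than asserted.

## The duplication model

A model is the tuple (reference, donor, acceptor, insert, terminal
extension, edits). Coordinates are 1-based inclusive throughout, matching
how positions are reported in the virology literature. The derived sequence
is

```
pad(ext5) + edited(ref[1..donor]) + insert + edited(ref[acceptor..L])
```

so the interval `[acceptor, donor]` appears twice. Edits are expressed in
*reference* coordinates plus a copy label (`primary`, `duplication`,
`unique`); insertions anchor "after base p" and render as `p^p+1`, the
convention used in the published variant table. Applying edits never moves
the junction: donor and acceptor always refer to the unedited reference.
Indels that would span the acceptor or donor boundary are rejected rather
than truncated — no biological case required them, and truncation would make
liftover ambiguous. The terminal extension models extra bases found at the
genome end in the deposited sequence; only its *length* matters for
coordinates, so it defaults to seeded random bases. Whether those bases
belong at the 5' or 3' end of the deposited orientation is ambiguous in the
source material; the model exposes them as a 5' pad because that choice
reproduces the published coordinate table exactly. The deposited genome's
absolute length is *not* a model output: it differs from reference length +
insertion arithmetic by unexplained terminal trimming, which is why the
fixtures validate coordinates and interval lengths, never total deposited
length.

Liftover is computed from explicit per-base maps built during edit
application, so it is exact by construction and testable by brute force: the
round trip derived → reference → derived is the identity on every base that
exists in the reference (pad, junction insert and edit-inserted bases map to
their anchoring reference position and are flagged). Bases deleted in a copy
map to the image of the last retained base, which matches how the published
table renders a deletion site (`7777^7778`).

## Junction calling: parameters and numerical choices

* `k = 13` (anchor k-mer): at ≤ 10% read error an exact 13-mer survives about
  every 3–4 read bases, enough to anchor blocks densely, while random 13-mer
  collisions in a ~13.5 kb genome are rare.
* `max_chain_gap = 200`: anchors further apart than this open a new block.
* `min_jump = 50`: only backward reference jumps of at least 50 nt count as
  duplication evidence; smaller jumps are indistinguishable from noisy
  deletions.
* `max_read_gap = 20`: at most 20 unaligned read bases are tolerated at the
  junction.
* `min_support = 2`, clustering tolerance `tol = 20` nt.

Two numerical choices deserve explanation because naive versions fail at
realistic error rates. First, **per-candidate breakpoint refinement**: exact
k-mer anchors stop at the last clean 13-mer, so with ~10% error the raw block
ends underestimate the donor and overestimate the acceptor whenever an error
falls near the junction — which is the common case, since an error *anywhere*
in the 13 bases flanking the junction displaces the anchor. The unaligned gap
bases are therefore re-aligned against both reference flanks by a small
dynamic program (match +1, mismatch and gap −3, unexplained insert base
−0.6). The penalties are chosen so that a genuine short insert is never
absorbed into a flank on the strength of a single coincidental base match
(absorbing a 2 nt insert with one mismatch scores −1, keeping it as insert
scores −0.2), while a true sequencing error inside a flank is still absorbed
as a mismatch. Second, **consensus by plurality of refined triples** rather
than coordinate-wise medians: after refinement, reads without errors at the
junction all produce the *identical* (donor, acceptor, insert) triple,
whereas error-bearing candidates are idiosyncratic; a plurality vote with
ties broken toward the shortest insert and then the largest donor is
therefore much more robust than a median, which error-displaced candidates
bias systematically in one direction.

Microhomology makes breakpoint representation non-unique: when sequence
flanking the breakpoint is repeated, several triples describe the same
molecule. The package's canonical representative — shortest insert, ties to
the largest donor — is a convention of this implementation, not something
the source data can decide; `canonicalize_junction()` applies it everywhere
so that equivalent representations always collapse before comparison.

## Copy-aware variant calling

`call_copy_variants()` deliberately ignores any edits already present in the
supplied model: reads are mapped against the *naive* (edit-free)
reconstruction, so every reported difference is read evidence, not a baked-in
assumption. Reads are informative for a repeat position only if anchored:
junction-spanning reads (≥ `min_anchor` = 100 nt on both sides of the insert)
attribute their left-of-insert bases to the primary copy and right-of-insert
bases to the duplication; reads reaching ≥ 100 nt into unique sequence
upstream (downstream) anchor the primary (duplication) copy; everything else
inside the repeat is unassignable and contributes to neither pileup — never
resolved randomly, because random resolution is precisely what destroys copy
assignment.

Consensus thresholds are `min_depth = 3` informative reads and `min_af = 0.7`
majority. Three further choices matter at realistic error rates:

* Pileup alignments use gap penalties well above the mismatch penalty
  (match 2, mismatch −2, gap −6). With gap ≈ mismatch costs, an optimal
  alignment converts a true substitution into "insertion + reference match"
  whenever a sequencing indel lands nearby, silently erasing the variant from
  the pileup.
* Indels are treated as *events*, not per-position gap votes: each read's
  deletion runs and insertion strings are left-normalized (VCF convention)
  against the mapping target, then clustered around recurrent anchors (±3 nt,
  requiring at least two reads), with support counted as distinct reads.
  Per-position gap voting instead concentrates homopolymer sequencing noise
  at run left-edges and dilutes true indels whose placement jitters.
* Substitutions are genotyped in a second pass against the indel-corrected
  reconstruction (the long-established indel-realignment idea): once the
  called indels are part of the mapping target, substitutions adjacent to
  them become clean mismatch columns.

Called edits are re-expressed through the model's liftover in all three
coordinate systems — reference, primary copy, duplication copy — the exact
layout of the published comparison table, via `tidy()` on the fitted model.

## The synthetic-data generator

`make_reference()` emulates a rhabdovirus-like genome: genes N, P, M, G, X, L
in canonical order on one strand, each a stop-free ORF, separated by spacers
each carrying one copy of the conserved intergenic motif `GACACAAAAT`.
Default gene and spacer lengths reproduce the published X+ layout
coordinate-for-coordinate (13,534 nt total), so planted landmarks (primer
sites, variant positions) fall at their published coordinates. Each spacer
ends with an in-frame TAA guard immediately before the next gene's ATG so
that maximal-ORF discovery recovers planted boundaries deterministically,
and candidate genomes with stray motif occurrences are rejected and
regenerated under derived seeds.

Read simulation places substitution, insertion and deletion errors i.i.d.
per base (defaults 3%/4%/3%, calibrated so that alignment identity falls in
the 88–94% band observed for direct-RNA nanopore reads of this virus);
long-read lengths are log-normal with mean 2500 nt, near the reported
averages of ~2.5–2.9 kb; short reads are 99 bp innie pairs. Quality is a
constant per-read Phred score drawn from N(12, 4) for long reads — only
mean-quality filtering (`filter_reads_by_quality()`, default Q7, mirroring
basecaller trimming) is modelled, not per-base quality. Half the reads are
reverse-strand by default; the observed strand ratio in the real data is
based on too few reads to estimate. What the generator does *not* emulate:
homopolymer-context errors, basecalling artifacts, poly(A) tails,
transcript-level (mRNA) structure, or coverage biases. Passing tests
therefore demonstrate correctness of the inference machinery under a clean
error model, not robustness to every artifact of real nanopore data.

The surrogate X+3.7 fixture (`sfrhabdo_model()`) plants, on a generated
reference: the four published primer sites at their published coordinates
(plus a synthetic downstream mispriming site explaining the published
read-through product), the published reference allele at every curated
variant site, and deterministic guard bases adjacent to the junction and the
indel anchors so the published representations are the canonical ones. All
published coordinate-derived quantities — copy lengths 3762/3757 nt, the
~99% copy identity, amplicon sizes 1935, 1122/1115, 795, 4879 and 8059 bp,
and the full gene-coordinate liftover table — are reproduced exactly on this
surrogate; only the unconstrained sequence content is random. The
duplication-dependent F9×R6 assay is run with one tolerated primer mismatch
because a curated copy variant sits inside the primary-copy F9 site (as it
does on the real genome); the 3'-terminal five bases stay exact, which is
the package's polymerase-clamp annealing model. Primer thermodynamics are
deliberately out of scope — on these genomes product sets are fully
determined by coordinates.

The X− variant's 320 nt deletion has no published boundaries; the fixture
places it at reference 6400–6719, inside the X gene extending into the X–L
spacer, which reproduces the published 795 bp product.

The three published differences *outside* the repeat are printed in
deposited-genome coordinates in the source material; the fixture stores them
converted to reference coordinates (2709, 9624, 13,360).

## Mappability

`map_short_reads()` enumerates each read's best-scoring placements subject
to the two CLC-style thresholds (aligned length fraction ≥ 0.5, identity ≥
0.8); ties are either discarded ("ignore") or placed uniformly at random
(seeded). Mates are mapped independently — pairing-aware rescue is out of
scope. The contract is the *policy semantics*, not score parity with any
particular commercial mapper. On a reconstructed duplication, the ignore
policy leaves coverage holes exactly where no read can reach a
copy-distinguishing position, i.e. confined to the repeat copies, while
random placement covers everything at the cost of arbitrary assignment —
the qualitative contrast the package's comparison reproduces at desk scale.

## Problem sizes used by the test suite

The property tests run at deliberately small scale: junction parameter
recovery uses 20 seeded replicates of 120 simulated long reads each (the
junction-spanning subset is then ~15 reads — orders of magnitude below the
thousands of junction reads in the real data); noisy variant recovery uses
10 replicates of 170 reads (~24× raw coverage, versus several-hundred-fold
real-data depths); mappability analyses tile 99-mers every few bases rather
than sampling hundreds of millions of reads. These sizes are the package's
choice of a desk-scale experiment that still exercises every code path;
real-data read counts and depth statistics are properties of the deposited
sequencing runs, not of this implementation, and are not reproduction
targets.

## Known limitations

* Exactly one duplication junction per model: no nesting, inversions or
  translocations.
* Consensus-level variants only; no quasispecies frequency modelling.
* Linear genomes only.
* The ORF-calling rules of the original annotation (start-codon choice,
  length threshold) are unstated in the source material; `find_orfs()` uses
  maximal ATG-to-stop frames with a 60-codon default, so ORF *counts* are
  threshold-dependent and the fixtures validate ORF structure (positions,
  fusion across the junction) rather than bare counts.
* The N gene's deposited coordinate offset is inconsistent with the other
  genes (+9 vs +72) and cannot be reproduced by liftover; it is excluded
  from the gene-coordinate fixtures.
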