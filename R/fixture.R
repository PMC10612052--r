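# The Sf-rhabdovirus X+3.7 surrogate fixture.
#
# The deposited Sf-rhabdovirus sequences (KF947078 reference, OQ158798
# derived genome) are not shipped; instead a synthetic surrogate reference
# with the same published layout is generated: same gene/spacer coordinates,
# the four published RT-PCR primer binding sites planted at their published
# positions, the published reference alleles planted at every curated
# variant site, and deterministic guard bases around the junction and the
# indel sites so that canonical representations are unambiguous. On this
# surrogate, every published coordinate-derived quantity (liftovers, copy
# lengths, amplicon sizes) is reproduced exactly; only the unconstrained
# sequence content is random.

replace_at <- function(seq, start, replacement) {
  paste0(substring(seq, 1L, start - 1L), replacement,
         substring(seq, start + nchar(replacement), nchar(seq)))
}

# base guards: pick a fixed base different from the disallowed ones
guard_base <- function(not) setdiff(c("T", "C", "A", "G"), not)[1]

sfrhabdo_patches <- function() {
  primers <- sfrhabdo_primers()
  p <- function(nm) primers$seq[primers$name == nm]
  list(
    # primer binding sites at their published reference coordinates
    list(start = 6209L, seq = p("F7")),
    list(start = 6313L, seq = revcomp(p("R6"))),
    list(start = 7304L, seq = revcomp(p("R7"))),
    list(start = 8157L, seq = p("F9")),
    # synthetic downstream mispriming site for R7: the published 8059 bp
    # long-range product ends at reference nt 10,503
    list(start = 10484L, seq = revcomp(p("R7"))),
    # junction guards: keep 8523^GA^4767 the canonical representation
    list(start = 8524L, seq = guard_base(c("G"))),
    list(start = 4766L, seq = guard_base(c("A"))),
    # indel guards: keep the curated indels left-normalized at their
    # published anchors
    list(start = 7016L, seq = guard_base(c("C"))),
    list(start = 7050L, seq = guard_base(c("G"))),
    list(start = 7698L, seq = guard_base(c("G"))),
    list(start = 7699L, seq = "AG"))
}

#' Surrogate Sf-rhabdovirus X+ reference genome
#'
#' A synthetic 13,534 nt reference with the published Sf-rhabdovirus X+
#' (KF947078) layout: genes N, P, M, G, X, L at the published coordinates,
#' the GACACAAAAT intergenic motif in each spacer, the four published
#' RT-PCR primer sites (F7, R7, F9, R6) planted at their published
#' positions (plus a synthetic downstream R7 mispriming site ending at nt
#' 10,503), and the published reference alleles planted at every curated
#' variant site. Unconstrained positions are random under `seed`. The
#' construction asserts that every primer has exactly its intended binding
#' sites (within one mismatch) and retries deterministically otherwise.
#'
#' @param seed seed for the unconstrained sequence content.
#' @return a [genome()].
#' @export
sfrhabdo_reference <- function(seed = 1L) {
  edits <- sfrhabdo_edits()
  primers <- sfrhabdo_primers()
  patches <- sfrhabdo_patches()
  for (attempt in 0:24) {
    g <- make_reference(genome_architecture(), seed = derive_seed(seed, 500L + attempt),
                        name = "sfrhabdo_Xplus_surrogate")
    s <- g$seq
    for (pt in patches) s <- replace_at(s, pt$start, pt$seq)
    # plant the published reference allele at each curated substitution /
    # deletion site (insertion anchors have no reference allele)
    for (i in seq_len(nrow(edits))) {
      if (edits$kind[i] == "substitution") {
        s <- replace_at(s, edits$ref_pos[i], edits$ref_allele[i])
      }
    }
    stopifnot(substring(s, 8164, 8164) == "C")  # inside the F9 site
    g$seq <- s
    if (sfrhabdo_sites_ok(g, primers)) return(g)
  }
  stop("failed to build a clean surrogate reference")
}

# each primer must bind exactly where planted, with no stray near-matches
sfrhabdo_sites_ok <- function(g, primers) {
  expect <- list(F7 = c("+6209"), R6 = c("-6313"),
                 R7 = c("-7304", "-10484"), F9 = c("+8157"))
  for (nm in names(expect)) {
    st <- find_primer_sites(g, primers[primers$name == nm, ],
                            max_mismatch = 1L)
    got <- paste0(st$strand, st$start)
    if (!setequal(got, expect[[nm]])) return(FALSE)
  }
  can <- canonicalize_junction(g, 8523L, 4767L, "GA")
  identical(can, list(donor = 8523L, acceptor = 4767L, insert = "GA"))
}

#' Curated per-copy variant table of the X+3.7 genome
#'
#' The published differences between the X+3.7 primary and duplication
#' copies and the X+ reference, as a [copy_edits()] table in reference
#' coordinates: 10 duplication-copy substitutions, 10 primary-copy
#' substitutions, three primary-copy indels (+6 nt after 7016, +1 nt after
#' 7050, deletion of 7699-7700), and the three substitutions outside the
#' repeat (converted to reference coordinates).
#'
#' @return a `copy_edits` tibble.
#' @export
sfrhabdo_edits <- function() {
  read_edits(system.file("extdata", "sfrhabdo_edits.tsv", package = "virdup",
                         mustWork = TRUE))
}

#' Published Sf-rhabdovirus RT-PCR primers
#' @return primer tibble (F7, R7, F9, R6 with published sequences and
#'   binding coordinates on KF947078).
#' @export
sfrhabdo_primers <- function() {
  read_primers(system.file("extdata", "sfrhabdo_primers.tsv", package = "virdup",
                           mustWork = TRUE))
}

#' Published gene coordinates in both genomes
#'
#' Gene coordinate pairs for the X+ reference (KF947078) and the X+3.7
#' genome (OQ158798), with the repeat copy each X+3.7 annotation lies in.
#' (The N gene is omitted: its deposited offset is inconsistent with the
#' other genes and is not reproducible by coordinate liftover.)
#'
#' @return tibble `gene`, `ref_start`, `ref_end`, `new_start`, `new_end`,
#'   `copy`.
#' @export
sfrhabdo_gene_coords <- function() {
  tibble::as_tibble(read.delim(system.file("extdata", "sfrhabdo_genes.tsv",
                                           package = "virdup", mustWork = TRUE),
                               stringsAsFactors = FALSE))
}

#' Surrogate X+3.7 duplication model
#'
#' The [dup_model()] tying together the surrogate reference, the published
#' junction (donor 8523, acceptor 4767, insert "GA"), the published 72 nt
#' terminal extension, and the curated edit list. Its reconstruction is the
#' surrogate X+3.7 genome (17,370 nt: the deposited genome's absolute
#' length differs by unexplained terminal trimming and is not a model
#' output).
#'
#' @param seed seed for the unconstrained sequence content.
#' @return a [dup_model()].
#' @export
sfrhabdo_model <- function(seed = 1L) {
  dup_model(sfrhabdo_reference(seed), donor = 8523L, acceptor = 4767L,
            insert = "GA", terminal_ext5 = 72L, edits = sfrhabdo_edits(),
            ext5_seed = derive_seed(seed, 907L))
}

#' Surrogate X-minus variant genome
#'
#' The X- variant carries a 320 nt deletion extending from the X gene into
#' the X-L intergenic region; its published boundaries are not printed, so
#' the surrogate places it at reference 6400-6719 (inside the F7-R7
#' interval, starting in the X gene), which reproduces the published 795 bp
#' F7xR7 product.
#'
#' @param seed seed passed to [sfrhabdo_reference()].
#' @return a [genome()].
#' @export
sfrhabdo_xminus <- function(seed = 1L) {
  delete_interval(sfrhabdo_reference(seed), 6400L, 6719L)
}
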