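#' Describe a rhabdovirus-like genome architecture
#'
#' Template for [make_reference()]: six genes in the canonical order
#' N, P, M, G, X, L on one strand, each an open reading frame (ATG to stop),
#' separated by intergenic spacers that each carry one copy of a conserved
#' intergenic motif. Default gene and spacer lengths reproduce the layout of
#' the Sf-rhabdovirus X+ reference (KF947078), so genes land at the same
#' coordinates (N 81-1646, P 1726-2871, M 3088-4014, G 4140-5972,
#' X 6161-6490, L 6833-13255; total 13,534 nt).
#'
#' @param gene_lengths named integer vector of ORF lengths in nt (multiples
#'   of 3, including the stop codon) for genes N, P, M, G, X, L.
#' @param spacer_lengths named integer vector of intergenic spacer lengths
#'   for gaps N-P, P-M, M-G, G-X, X-L.
#' @param intergenic_motif conserved intergenic motif planted once per
#'   spacer (IUPAC letters allowed).
#' @param leader_len,trailer_len untranslated leader/trailer lengths.
#' @param seed default generation seed used by [make_reference()].
#' @return a `genome_architecture` list.
#' @export
genome_architecture <- function(gene_lengths = c(N = 1566L, P = 1146L, M = 927L,
                                                 G = 1833L, X = 330L, L = 6423L),
                                spacer_lengths = c(79L, 216L, 125L, 188L, 342L),
                                intergenic_motif = "GACACAAAAT",
                                leader_len = 80L, trailer_len = 279L,
                                seed = 1L) {
  if (!nchar(intergenic_motif)) stop("config error: motif must be non-empty")
  intergenic_motif <- clean_seq(intergenic_motif)
  gene_lengths <- as.integer(gene_lengths)
  names(gene_lengths) <- c("N", "P", "M", "G", "X", "L")
  if (any(gene_lengths < 6L) || any(gene_lengths %% 3L != 0L))
    stop("config error: gene lengths must be multiples of 3 and >= 6")
  spacer_lengths <- as.integer(spacer_lengths)
  if (length(spacer_lengths) != 5L ||
      any(spacer_lengths < nchar(intergenic_motif) + 3L))
    stop("config error: five spacers, each long enough for motif + stop guard")
  structure(list(gene_lengths = gene_lengths,
                 spacer_lengths = spacer_lengths,
                 intergenic_motif = intergenic_motif,
                 leader_len = as.integer(leader_len),
                 trailer_len = as.integer(trailer_len),
                 seed = as.integer(seed)),
            class = "genome_architecture")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  setdiff(apply(expand.grid(b, b, b), 1, paste, collapse = ""), STOP_CODONS)
}

random_orf <- function(len_nt) {
  n_codons <- len_nt %/% 3L
  body <- sample(sense_codons(), n_codons - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), sample(STOP_CODONS, 1L))
}

# spacer = random prefix + motif + random suffix ending in an in-frame TAA
# guard, so the maximal ORF of the following gene starts at its own ATG
random_spacer <- function(len, motif) {
  k <- nchar(motif)
  pre <- (len - k - 3L) %/% 2L
  post <- len - k - 3L - pre
  paste0(if (pre) random_dna(pre) else "", motif,
         if (post) random_dna(post) else "", "TAA")
}

#' Generate a synthetic rhabdovirus-like reference genome
#'
#' Builds a random genome under a [genome_architecture()]: genes N, P, M, G,
#' X, L in order on the plus strand, each a stop-free ORF, separated by
#' spacers carrying exactly one intergenic motif each. Each spacer (and the
#' leader) ends with an in-frame TAA guard immediately before the next
#' gene's ATG so that maximal-ORF discovery recovers the planted gene
#' boundaries. Candidate genomes with stray motif occurrences are rejected
#' and regenerated deterministically, so the returned genome contains the
#' motif exactly five times (once per intergenic spacer).
#'
#' @param arch a [genome_architecture()].
#' @param seed generation seed (defaults to the architecture's seed).
#' @param name genome name.
#' @return a [genome()] with the six gene annotations populated.
#' @export
#' @examples
#' g <- make_reference(genome_architecture(seed = 1))
#' g$annotations
make_reference <- function(arch = genome_architecture(), seed = arch$seed,
                           name = "synthetic_ref") {
  genes <- names(arch$gene_lengths)
  motif_dna <- gsub("[^ACGT]", "", arch$intergenic_motif)
  strict_motif <- identical(motif_dna, arch$intergenic_motif)
  for (attempt in 0:49) {
    g <- withr::with_seed(derive_seed(seed, attempt), {
      leader <- if (arch$leader_len >= 3L) {
        paste0(random_dna(arch$leader_len - 3L), "TAA")
      } else if (arch$leader_len > 0L) random_dna(arch$leader_len) else ""
      parts <- character(0)
      ann <- list()
      pos <- nchar(leader)
      parts <- c(parts, leader)
      for (i in seq_along(genes)) {
        orf <- random_orf(arch$gene_lengths[i])
        ann[[i]] <- tibble::tibble(gene = genes[i], start = pos + 1L,
                                   end = pos + nchar(orf), strand = "+")
        parts <- c(parts, orf)
        pos <- pos + nchar(orf)
        if (i < length(genes)) {
          sp <- random_spacer(arch$spacer_lengths[i], arch$intergenic_motif)
          parts <- c(parts, sp)
          pos <- pos + nchar(sp)
        }
      }
      parts <- c(parts, if (arch$trailer_len > 0L) random_dna(arch$trailer_len) else "")
      genome(paste(parts, collapse = ""), name = name,
             annotations = dplyr::bind_rows(ann))
    })
    # reject genomes with stray motif copies outside the five spacers
    if (strict_motif) {
      n_hits <- length(Biostrings::matchPattern(arch$intergenic_motif,
                                                Biostrings::DNAString(g$seq)))
      if (n_hits == 5L) return(g)
    } else {
      return(g)
    }
  }
  stop("failed to generate a motif-clean genome; adjust architecture")
}
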