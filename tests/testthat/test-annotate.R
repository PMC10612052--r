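test_that("ORF discovery recovers the planted genes exactly", {
  g <- make_reference(genome_architecture(seed = 1))
  orfs <- find_orfs(g, min_codons = 60, strand = "+")
  ann <- g$annotations
  planted <- paste(ann$start, ann$end)
  found <- paste(orfs$start, orfs$end)
  expect_true(all(planted %in% found))
  # anything extra must still be a genuine maximal ORF of the sequence
  extra <- orfs[!found %in% planted, ]
  for (i in seq_len(nrow(extra))) {
    s <- substring(g$seq, extra$start[i], extra$end[i])
    n <- nchar(s)
    expect_equal(n %% 3, 0)
    expect_equal(substring(s, 1, 3), "ATG")
    codons <- substring(s, seq(1, n - 2, 3), seq(3, n, 3))
    expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
    expect_gte(length(codons), 60)
  }
})

test_that("a stop-saturated sequence has no ORFs", {
  g <- genome(strrep("TAA", 100), "stops")
  expect_equal(nrow(find_orfs(g, min_codons = 2)), 0L)
})

test_that("minus-strand ORFs are reported in plus-strand coordinates", {
  fwd <- make_reference(genome_architecture(seed = 5))
  g <- genome(revcomp(fwd$seq), "flipped")
  orfs <- find_orfs(g, min_codons = 60, strand = "-")
  L <- genome_length(g)
  ann <- fwd$annotations
  expected <- paste(L - ann$end + 1L, L - ann$start + 1L)
  expect_true(all(expected %in% paste(orfs$start, orfs$end)))
})

test_that("a duplication junction inside genes creates a fusion ORF", {
  # gene1 then gene2; the derived genome jumps back from a codon boundary in
  # gene2 to a codon boundary in gene1, with a frame-preserving insert, so a
  # fusion ORF runs from gene2's start codon to gene1's stop
  withr::with_seed(91, {
    codon_pool <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                            c("A","C","G","T")), 1, paste, collapse = ""),
                          c("TAA", "TAG", "TGA"))
    gene1 <- paste0("ATG", paste(sample(codon_pool, 60, TRUE), collapse = ""), "TAA")
    gene2 <- paste0("ATG", paste(sample(codon_pool, 80, TRUE), collapse = ""), "TAA")
    seq <- paste0(rand_seq(57), "TAA", gene1, rand_seq(27), "TAA", gene2, rand_seq(60))
  })
  g1_start <- 61L; g1_end <- g1_start + nchar(gene1) - 1L
  g2_start <- g1_end + 31L; g2_end <- g2_start + nchar(gene2) - 1L
  ref <- genome(seq, "fusion_toy")
  acceptor <- g1_start + 3L * 20L          # start of gene1 codon 21
  # donor at a gene2 codon start whose base is not T, so the codon completed
  # by the insert ([base, G, A]) cannot be a stop
  donor_candidates <- g2_start + 3L * (25:40)
  donor <- donor_candidates[substring(seq, donor_candidates, donor_candidates) != "T"][1]
  m <- dup_model(ref, donor = donor, acceptor = acceptor, insert = "GA")
  recon <- reconstruct(m)
  orfs <- find_orfs(recon, min_codons = 60, strand = "+")
  fusion_end <- lift_ref_to_new(m, g1_end, "duplication")
  hit <- orfs[orfs$end == fusion_end & orfs$start <= donor, ]
  expect_equal(nrow(hit), 1L)
  expect_lte(hit$start, g2_start)  # starts at (or upstream of) gene2's ATG
})

test_that("motif scanning respects strand, mismatches and IUPAC validation", {
  g <- make_reference(genome_architecture(seed = 1))
  hits <- scan_motif(g, "GACACAAAAT")
  expect_equal(nrow(hits), 5L)
  # one mismatch tolerance can only add occurrences
  expect_gte(nrow(scan_motif(g, "GACACAAAAT", max_mismatch = 1)), 5L)
  # reverse-strand occurrences of the reverse complement
  rc <- scan_motif(g, revcomp("GACACAAAAT"), strand = "-")
  expect_equal(nrow(rc), 5L)
  expect_equal(rc$start, hits$start)
  expect_error(scan_motif(g, ""), "config")
  expect_error(scan_motif(g, "GAC!T"))
})

test_that("no intergenic motif lies between the duplication-derived extra ORFs", {
  m <- sfx_model()
  recon <- sfx_recon()
  hits <- scan_motif(recon, "GACACAAAAT")
  # derived-coordinate gaps between the published extra ORFs L1, L2, L3/G1
  between <- function(a, b) any(hits$start > a & hits$end < b)
  expect_false(between(7153, 7290))   # L1 .. L2
  expect_false(between(7817, 8582))   # L2 .. L3/G1
})

test_that("duplicate-copy ORF images equal liftover of the primary images", {
  ref <- make_reference(genome_architecture(seed = 2))
  # X gene lies inside the repeat interval used by the fixture junction
  m <- dup_model(ref, donor = 8523, acceptor = 4767, insert = "GA")
  recon <- reconstruct(m)
  orfs <- find_orfs(recon, min_codons = 60, strand = "+")
  x <- ref$annotations[ref$annotations$gene == "X", ]
  img_p <- c(lift_ref_to_new(m, x$start, "primary"), lift_ref_to_new(m, x$end, "primary"))
  img_d <- c(lift_ref_to_new(m, x$start, "duplication"), lift_ref_to_new(m, x$end, "duplication"))
  expect_true(paste(img_p[1], img_p[2]) %in% paste(orfs$start, orfs$end))
  expect_true(paste(img_d[1], img_d[2]) %in% paste(orfs$start, orfs$end))
})

test_that("ORFs export as GFF3", {
  g <- make_reference(genome_architecture(seed = 1))
  orfs <- find_orfs(g, min_codons = 60, strand = "+")
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(orfs, path, seqid = g$name)
  lines <- readLines(path)
  expect_equal(lines[1], "##gff-version 3")
  expect_equal(length(lines) - 1L, nrow(orfs))
})
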