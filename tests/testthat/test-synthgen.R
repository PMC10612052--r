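test_that("generated references have the planted architecture", {
  g <- make_reference(genome_architecture(seed = 1))
  expect_equal(genome_length(g), 13534L)
  ann <- g$annotations
  expect_equal(ann$gene, c("N", "P", "M", "G", "X", "L"))
  expect_equal(ann$start, c(81L, 1726L, 3088L, 4140L, 6161L, 6833L))
  expect_equal(ann$end, c(1646L, 2871L, 4014L, 5972L, 6490L, 13255L))
  # exactly one intergenic motif per spacer, five in total
  hits <- scan_motif(g, "GACACAAAAT")
  expect_equal(nrow(hits), 5L)
  spacers <- cbind(ann$end[-6] + 1L, ann$start[-1] - 1L)
  expect_true(all(hits$start >= spacers[, 1] & hits$end <= spacers[, 2]))
  # determinism
  expect_identical(make_reference(genome_architecture(seed = 1))$seq, g$seq)
  expect_false(identical(make_reference(genome_architecture(seed = 2))$seq, g$seq))
})

test_that("degenerate architectures and bad configs are handled", {
  arch <- genome_architecture(gene_lengths = setNames(rep(6L, 6), c("N","P","M","G","X","L")),
                              spacer_lengths = rep(13L, 5),
                              leader_len = 10L, trailer_len = 10L, seed = 3)
  g <- make_reference(arch)
  orfs <- find_orfs(g, min_codons = 2, strand = "+")
  expect_true(all(g$annotations$start %in% orfs$start))
  expect_error(genome_architecture(intergenic_motif = ""), "config")
  expect_error(genome_architecture(intergenic_motif = "GAC!T"))
})

test_that("zero-error long reads are exact oriented substrings with correct truth", {
  g <- toy_genome(2000, seed = 4)
  reads <- simulate_long_reads(g, n_reads = 30, mean_len = 300, sub_rate = 0,
                               ins_rate = 0, del_rate = 0, seed = 21)
  expect_equal(nrow(reads), 30L)
  for (i in seq_len(nrow(reads))) {
    tmpl <- substring(g$seq, reads$truth_start[i], reads$truth_end[i])
    if (reads$strand[i] == "-") tmpl <- revcomp(tmpl)
    expect_identical(reads$seq[i], tmpl)
  }
  expect_identical(reads,
                   simulate_long_reads(g, n_reads = 30, mean_len = 300, sub_rate = 0,
                                       ins_rate = 0, del_rate = 0, seed = 21))
})

test_that("realized error rates converge to the configured rates", {
  g <- toy_genome(4000, seed = 8)
  reads <- simulate_long_reads(g, n_reads = 40, mean_len = 2800,
                               sub_rate = 0.03, ins_rate = 0.04, del_rate = 0.03,
                               seed = 7)
  n <- sum(reads$truth_end - reads$truth_start + 1)
  expect_gt(n, 1e5)
  for (rate in list(c("n_sub", 0.03), c("n_ins", 0.04), c("n_del", 0.03))) {
    p <- as.numeric(rate[2])
    phat <- sum(reads[[rate[1]]]) / n
    expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / n))
  }
  expect_error(simulate_long_reads(g, 5, sub_rate = 0.5, ins_rate = 0.4,
                                   del_rate = 0.2, seed = 1), "config")
})

test_that("simulated noisy reads align in the observed nanopore identity band", {
  g <- sfx_ref()
  reads <- simulate_long_reads(g, n_reads = 12, sub_rate = 0.03, ins_rate = 0.04,
                               del_rate = 0.03, seed = 31)
  chains <- align_reads(reads, g)
  ids <- unique(chains[, c("read_id", "identity_pct")])$identity_pct
  expect_gte(mean(ids), 88)
  expect_lte(mean(ids), 94)
})

test_that("paired short reads are exact innies at the drawn fragment size", {
  g <- toy_genome(10000, seed = 12)
  reads <- simulate_short_reads(g, n_pairs = 50, seed = 3)
  expect_equal(nrow(reads), 100L)
  for (p in unique(reads$pair_id)[1:10]) {
    mates <- reads[reads$pair_id == p, ]
    expect_setequal(mates$strand, c("+", "-"))
    for (i in 1:2) {
      tmpl <- substring(g$seq, mates$truth_start[i], mates$truth_end[i])
      if (mates$strand[i] == "-") tmpl <- revcomp(tmpl)
      expect_identical(mates$seq[i], tmpl)
    }
  }
  expect_identical(reads, simulate_short_reads(g, n_pairs = 50, seed = 3))
})

test_that("short-read coverage matches the Lander-Waterman expectation", {
  g <- toy_genome(10000, seed = 13)
  reads <- simulate_short_reads(g, n_pairs = 2000, seed = 9)
  depth <- integer(genome_length(g))
  bump <- integer(genome_length(g) + 1)
  for (i in seq_len(nrow(reads))) {
    bump[reads$truth_start[i]] <- bump[reads$truth_start[i]] + 1L
    bump[reads$truth_end[i] + 1L] <- bump[reads$truth_end[i] + 1L] - 1L
  }
  depth <- cumsum(bump[seq_len(genome_length(g))])
  expected <- 2000 * 2 * 99 / 10000
  expect_lt(abs(mean(depth) - expected) / expected, 0.05)
})

test_that("quality filtering matches a brute-force per-read mean", {
  reads <- tibble::tibble(
    id = paste0("r", 1:4),
    seq = c("ACGT", "ACGT", "ACGTA", "AC"),
    qual = c(strrep(intToUtf8(20 + 33), 4),   # Q20
             strrep(intToUtf8(2 + 33), 4),    # Q2
             paste0(strrep(intToUtf8(5 + 33), 3), strrep(intToUtf8(20 + 33), 2)),  # mean 11
             strrep(intToUtf8(10 + 33), 2)))
  manual <- vapply(reads$qual, function(q) mean(utf8ToInt(q) - 33), numeric(1))
  kept <- filter_reads_by_quality(reads, min_mean_q = 7)
  expect_identical(kept$id, reads$id[manual >= 7])
  expect_equal(nrow(filter_reads_by_quality(reads, min_mean_q = 0)), 4L)
  expect_equal(nrow(filter_reads_by_quality(reads, min_mean_q = 25)), 0L)
  expect_equal(filter_reads_by_quality(reads, min_mean_q = 0, min_len = 5)$id, "r3")
})

test_that("fastq round-trips through files", {
  g <- toy_genome(500, seed = 2)
  reads <- simulate_long_reads(g, n_reads = 5, mean_len = 120, seed = 1)
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  back <- read_fastq(path)
  expect_equal(back$seq, reads$seq)
  expect_equal(back$qual, reads$qual)
})
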