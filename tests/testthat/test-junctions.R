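# all (donor, acceptor, insert) triples equivalent to a given junction on a
# toy sequence, by brute-force molecule comparison
equivalent_triples <- function(seq, donor, acceptor, insert, max_ins = 4L) {
  L <- nchar(seq)
  mol <- paste0(substring(seq, 1, donor), insert, substring(seq, acceptor, L))
  out <- list()
  for (d in max(1, donor - max_ins):min(L, donor + max_ins)) {
    for (a in max(2, acceptor - max_ins):min(L, acceptor + max_ins)) {
      ilen <- nchar(mol) - d - (L - a + 1)
      if (ilen < 0 || ilen > max_ins || a > d) next
      cand <- paste0(substring(seq, 1, d),
                     substring(mol, d + 1, d + ilen),
                     substring(seq, a, L))
      if (cand == mol) {
        out[[length(out) + 1L]] <- list(donor = d, acceptor = a,
                                        insert = substring(mol, d + 1, d + ilen))
      }
    }
  }
  out
}

test_that("equivalent junction representations collapse to one canonical triple", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      seq <- rand_seq(80)
      donor <- sample(30:60, 1)
      acceptor <- sample(10:donor, 1)
      insert <- if (runif(1) < 0.4) "" else rand_seq(sample(1:3, 1))
      triples <- equivalent_triples(seq, donor, acceptor, insert)
      canon <- lapply(triples, function(t)
        canonicalize_junction(seq, t$donor, t$acceptor, t$insert))
      expect_gte(length(canon), 1)
      expect_length(unique(canon), 1L)
      ref_can <- canon[[1]]
      # canonical form: shortest insert, then largest donor, among equivalents
      lens <- vapply(triples, function(t) nchar(t$insert), integer(1))
      expect_equal(nchar(ref_can$insert), min(lens))
      donors <- vapply(triples, function(t) t$donor, integer(1))
      expect_equal(ref_can$donor, max(donors[lens == min(lens)]))
    }
  })
})

test_that("back-jump detection finds the published junction structure", {
  g <- sfx_ref()
  # a read crossing the junction with clean flanks
  read <- paste0(substring(g$seq, 8157, 8523), "GA", substring(g$seq, 4767, 5200))
  reads <- tibble::tibble(id = "jread", seq = read)
  chains <- align_reads(reads, g)
  cand <- detect_backjumps(chains, reads, g)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$donor, 8523L)
  expect_equal(cand$acceptor, 4767L)
  expect_equal(cand$insert, "GA")

  # a plain reference read yields no candidate
  plain <- tibble::tibble(id = "p", seq = substring(g$seq, 2000, 2600))
  expect_equal(nrow(detect_backjumps(align_reads(plain, g), plain, g)), 0L)
})

test_that("error-free tiling reads give candidates exactly for junction-spanning reads", {
  ref <- toy_genome(2600, seed = 19)
  # guard flanks so the planted junction is its own canonical representation
  s <- ref$seq
  s <- set_base(s, 1501, setdiff(c("A","C","G","T"), c("G", substring(s, 700, 700)))[1])
  s <- set_base(s, 699, setdiff(c("A","C","G","T"), "A")[1])
  ref <- genome(s, "toyjunc")
  m <- dup_model(ref, donor = 1500, acceptor = 700, insert = "GA")
  recon <- reconstruct(m)
  reads <- tile_reads(recon, width = 400, step = 75)
  chains <- align_reads(reads, ref)
  cand <- detect_backjumps(chains, reads, ref)
  # truth: the insert occupies reconstructed positions 1501-1502
  spans <- reads$truth_start <= 1501 - 13 & reads$truth_end >= 1502 + 13
  expect_setequal(cand$read_id, reads$id[spans])
  expect_true(all(cand$donor == 1500 & cand$acceptor == 700 & cand$insert == "GA"))
  calls <- cluster_junctions(cand, ref)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$support, sum(spans))
})

test_that("unanimous candidates cluster into a single consensus call", {
  g <- toy_genome(2000, seed = 23)
  cand <- tibble::tibble(read_id = paste0("r", 1:5), donor = 1500L,
                         acceptor = 700L, insert = "GA", read_gap = 2L)
  calls <- cluster_junctions(cand, g)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$support, 5L)
  expect_equal(calls$donor, canonicalize_junction(g, 1500L, 700L, "GA")$donor)
  # below min_support nothing is reported
  expect_equal(nrow(cluster_junctions(cand[1, ], g, min_support = 2)), 0L)
  expect_equal(nrow(cluster_junctions(cand[0, ], g)), 0L)
})

test_that("no junctions are called from an unduplicated genome", {
  g <- sfx_ref()
  reads <- simulate_long_reads(g, n_reads = 25, sub_rate = 0, ins_rate = 0,
                               del_rate = 0, seed = 29)
  calls <- call_junctions(reads, g, min_support = 1)
  expect_equal(nrow(calls), 0L)
})

test_that("noisy reads recover the published junction within tolerance", {
  model <- sfx_model()
  gtrue <- sfx_recon()
  reads <- simulate_long_reads(gtrue, n_reads = 120, sub_rate = 0.03,
                               ins_rate = 0.04, del_rate = 0.03, seed = 1003)
  calls <- call_junctions(reads, sfx_ref(), compute_identity = FALSE)
  expect_gte(nrow(calls), 1)
  expect_lte(abs(calls$donor[1] - 8523), 2)
  expect_lte(abs(calls$acceptor[1] - 4767), 2)
  expect_equal(calls$insert[1], "GA")
})

test_that("the per-read report renders junction-spanning alignments", {
  g <- sfx_ref()
  reads <- tibble::tibble(
    id = c("span", "plain"),
    seq = c(paste0(substring(g$seq, 8157, 8523), "GA", substring(g$seq, 4767, 5200)),
            substring(g$seq, 1000, 1500)))
  chains <- align_reads(reads, g)
  cand <- detect_backjumps(chains, reads, g)
  rep <- junction_read_report(chains, cand)
  expect_equal(rep$aligned_region[rep$read_id == "span"], "8157-8523^GA^4767-5200")
  expect_equal(rep$aligned_region[rep$read_id == "plain"], "1000-1500")
})
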