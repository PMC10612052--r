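test_that("reconstruction concatenates pad, edited prefix, insert and resumed suffix", {
  ref <- genome("ACGTACGTAA", "toy")
  m <- dup_model(ref, donor = 6, acceptor = 3, insert = "GA")
  g <- reconstruct(m)
  expect_equal(g$seq, paste0("ACGTAC", "GA", "GTACGTAA"))
  expect_equal(genome_length(g), 16L)

  # single-base duplication: donor == acceptor, empty insert
  m1 <- dup_model(ref, donor = 5, acceptor = 5)
  expect_equal(genome_length(reconstruct(m1)), 11L)

  # junction segment length matches the published duplication size
  mx <- sfx_model()
  expect_equal(mx$donor - mx$acceptor + 1L, 3757L)
})

test_that("model construction rejects invalid junctions and boundary-spanning edits", {
  ref <- toy_genome(100)
  expect_error(dup_model(ref, donor = 120, acceptor = 10), "coordinate")
  expect_error(dup_model(ref, donor = 20, acceptor = 50), "acceptor")
  # deletion spanning the acceptor boundary is rejected, not truncated
  ed <- copy_edits(39, "deletion", substring(ref$seq, 39, 42), "", "primary")
  expect_error(dup_model(ref, donor = 80, acceptor = 40, edits = ed), "model error")
  # unique edit inside the repeat is inconsistent
  ed2 <- copy_edits(50, "substitution", substring(ref$seq, 50, 50), "N", "unique")
  expect_error(dup_model(ref, donor = 80, acceptor = 40, edits = ed2))
})

test_that("edit tables are validated field-by-field", {
  expect_error(copy_edits(5, "insertion", "A", "TT", "primary"), "insertion")
  expect_error(copy_edits(5, "deletion", "", "T", "primary"), "deletion")
  expect_error(copy_edits(5, "substitution", "AC", "T", "primary"), "substitution")
  expect_error(copy_edits(5, "substitution", "A", "T", "middle"), "copy")
  ok <- copy_edits(5, "substitution", "A", "T", "unique")
  expect_s3_class(ok, "copy_edits")
})

test_that("liftover reproduces the published gene coordinate pairs", {
  m <- sfx_model()
  gc <- sfrhabdo_gene_coords()
  expect_equal(lift_ref_to_new(m, gc$ref_start, gc$copy), gc$new_start)
  expect_equal(lift_ref_to_new(m, gc$ref_end, gc$copy), gc$new_end)
  # the junction-fusion ORF endpoints and the repeat boundary
  expect_equal(lift_ref_to_new(m, 8505, "primary"), 8582L)
  expect_equal(lift_ref_to_new(m, 5972, "duplication"), 9808L)
  expect_equal(lift_ref_to_new(m, 4767, "primary"), 4839L)
  expect_equal(lift_ref_to_new(m, 6833, "primary"), 6905L)
  expect_equal(lift_ref_to_new(m, 6833, "duplication"), 10669L)
  expect_equal(lift_ref_to_new(m, 6161, "duplication"), 9997L)
  expect_equal(lift_ref_to_new(m, 13255, "primary"), 17091L)
  expect_equal(lift_ref_to_new(m, 13255, "duplication"), 17091L)
  expect_error(lift_ref_to_new(m, 20000), "coordinate")
})

test_that("liftover is the identity for a bare model", {
  ref <- toy_genome(150)
  m <- dup_model(ref, donor = 100, acceptor = 60)
  expect_equal(lift_ref_to_new(m, 1:59, "primary"), 1:59)
})

test_that("derived-to-reference liftover labels regions and inverts the forward map", {
  m <- sfx_model()
  expect_equal(lift_new_to_ref(m, 4839)$pos_ref, 4767L)
  expect_equal(lift_new_to_ref(m, 4839)$region, "primary")
  expect_equal(lift_new_to_ref(m, 8603)$pos_ref, 4767L)
  expect_equal(lift_new_to_ref(m, 8603)$region, "duplication")
  ins <- lift_new_to_ref(m, 8601)
  expect_equal(ins$region, "insert")
  expect_equal(ins$pos_ref, 8523L)
  expect_true(ins$from_insertion)

  # exhaustive round trip over every base of a small edited model
  m2 <- random_small_model(401)
  g2 <- reconstruct(m2)
  rt <- lift_new_to_ref(m2, seq_len(genome_length(g2)))
  ok <- !rt$from_insertion
  prim <- ok & rt$region %in% c("upstream", "primary")
  dup <- ok & rt$region %in% c("duplication", "downstream")
  expect_equal(lift_ref_to_new(m2, rt$pos_ref[prim], "primary"), rt$pos_new[prim])
  expect_equal(lift_ref_to_new(m2, rt$pos_ref[dup], "duplication"), rt$pos_new[dup])
})

test_that("copy sequences have the published lengths and expose planted differences", {
  cs <- copy_sequences(sfx_model())
  expect_equal(nchar(cs$primary), 3762L)
  expect_equal(nchar(cs$duplication), 3757L)

  # no edits: both copies identical and the segment occurs twice verbatim
  ref <- toy_genome(400, seed = 5)
  m0 <- dup_model(ref, donor = 300, acceptor = 101)
  cs0 <- copy_sequences(m0)
  expect_identical(cs0$primary, cs0$duplication)
  seg <- substring(ref$seq, 101, 300)
  hits <- gregexpr(seg, reconstruct(m0)$seq, fixed = TRUE)[[1]]
  expect_length(hits, 2L)

  # one planted substitution per copy -> Hamming distance 2 at known columns
  ref50 <- toy_genome(50, seed = 9)
  ed <- validate_edits(dplyr::bind_rows(
    copy_edits(20, "substitution", substring(ref50$seq, 20, 20),
               setdiff(c("A", "C", "G", "T"), substring(ref50$seq, 20, 20))[1], "primary"),
    copy_edits(30, "substitution", substring(ref50$seq, 30, 30),
               setdiff(c("A", "C", "G", "T"), substring(ref50$seq, 30, 30))[1], "duplication")))
  m2 <- dup_model(ref50, donor = 45, acceptor = 11, edits = ed)
  cs2 <- copy_sequences(m2)
  diff_cols <- which(strsplit(cs2$primary, "")[[1]] != strsplit(cs2$duplication, "")[[1]])
  expect_equal(diff_cols, c(20L, 30L) - 11L + 1L)
})

test_that("length conservation and liftover bijectivity hold for random models", {
  for (s in 1:300) {
    m <- random_small_model(s)
    g <- reconstruct(m)
    expect_equal(genome_length(g),
                 genome_length(m$reference) + m$terminal_ext5 +
                   (m$donor - m$acceptor + 1L) + nchar(m$insert) +
                   virdup:::net_indel(m$edits))
    rt <- lift_new_to_ref(m, seq_len(genome_length(g)))
    ok <- !rt$from_insertion
    prim <- ok & rt$region %in% c("upstream", "primary")
    dup <- ok & rt$region %in% c("duplication", "downstream")
    expect_identical(lift_ref_to_new(m, rt$pos_ref[prim], "primary"), rt$pos_new[prim])
    expect_identical(lift_ref_to_new(m, rt$pos_ref[dup], "duplication"), rt$pos_new[dup])
  }
})

test_that("tidy renders edits in all three coordinate systems", {
  td <- tidy(sfx_model())
  ins6 <- td[td$ref_pos == "7016^7017", ]
  expect_equal(ins6$primary_pos, "7089-7094")
  expect_equal(ins6$primary_allele, "AAAACC")
  expect_equal(ins6$duplication_pos, "10852^10853")
  expect_equal(ins6$duplication_allele, "-")
  sub <- td[td$ref_pos == "4878", ]
  expect_equal(sub$primary_pos, "4950")
  expect_equal(sub$primary_allele, "T")
  expect_equal(sub$duplication_pos, "8714")
  expect_equal(sub$duplication_allele, "C")
  del <- td[td$ref_pos == "7699-7700", ]
  expect_equal(del$primary_pos, "7777^7778")
  expect_equal(del$duplication_pos, "11535-11536")
  expect_equal(del$duplication_allele, "AG")
})

test_that("glance summarizes the fixture model with the published quantities", {
  gl <- glance(sfx_model())
  expect_equal(gl$segment_length, 3757L)
  expect_equal(gl$primary_length, 3762L)
  expect_equal(gl$duplication_length, 3757L)
  expect_equal(gl$primary_start, 4839L)
  expect_equal(gl$duplication_start, 8603L)
  expect_equal(gl$duplication_end, 12359L)
  expect_equal(round(gl$copy_identity_pct), 99)
})

test_that("copy identity matches the closed-form expectation from the edit list", {
  # 3757 shared columns + 7 inserted + 2 deleted = 3764 columns;
  # 20 substitution columns mismatch; 9 gap columns
  expect_equal(copy_identity(sfx_model()), 100 * 3735 / 3764, tolerance = 1e-10)
})

test_that("indel left-normalization follows the VCF convention", {
  seq <- "AACCCGTT"
  # deletion of one C anywhere in the CCC run normalizes to the run start
  expect_equal(virdup:::normalize_indel_left(seq, 5, "C", "deletion")$pos, 3L)
  # insertion of C after any C in the run normalizes to before the run
  norm <- virdup:::normalize_indel_left(seq, 5, "C", "insertion")
  expect_equal(norm$pos, 2L)
  expect_equal(norm$allele, "C")
  # non-repetitive context does not shift
  expect_equal(virdup:::normalize_indel_left(seq, 6, "G", "deletion")$pos, 6L)
})
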