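# a perfect tandem duplication: duplicated genome A(600) S S B(600) with
# S = 500 nt, plus the matching single-copy genome A S B
perfect_dup_pair <- function(seed = 55) {
  withr::with_seed(seed, {
    A <- rand_seq(600); S <- rand_seq(500); B <- rand_seq(600)
    list(dup = genome(paste0(A, S, S, B), "perfectdup"),
         single = genome(paste0(A, S, B), "perfectdup"))
  })
}

test_that("repeat-free genomes give identical profiles under both policies", {
  g <- toy_genome(3000, seed = 57)
  reads <- tile_reads(g, width = 60, step = 9)
  pi <- map_short_reads(reads, g, "ignore")
  pr <- map_short_reads(reads, g, "random", seed = 5)
  expect_identical(pi$depth, pr$depth)
  expect_equal(pi$covered_fraction, 1)
  cmp <- compare_policies(pi, pr)
  expect_equal(cmp$covered_fraction_ignore, cmp$covered_fraction_random)
  expect_error(map_short_reads(reads, g, "sometimes"))
  expect_error(map_short_reads(reads, g, "random"), "seed")
})

test_that("ignore policy blanks exact-tie positions deep inside a perfect repeat", {
  g <- perfect_dup_pair()$dup
  reads <- tile_reads(g, width = 50, step = 1)
  pi <- map_short_reads(reads, g, "ignore")
  # reads fully inside either copy are exact ties; only boundary-crossing
  # reads are placed, so uncovered bases are exactly those farther than 49
  # from a copy-distinguishing position
  ui <- uncovered_intervals(pi)
  expect_equal(nrow(ui), 2L)
  expect_equal(ui$start, c(650L, 1150L))
  expect_equal(ui$end, c(1051L, 1551L))
  # conservation: total depth equals summed span length of placed reads
  expect_equal(sum(pi$depth), pi$n_mapped * 50L)

  pr <- map_short_reads(reads, g, "random", seed = 11)
  expect_equal(pr$covered_fraction, 1)
  expect_equal(sum(pr$depth), pr$n_mapped * 50L)
})

test_that("random placement halves repeat depth for single-copy-derived reads", {
  # reads tiling the unduplicated genome, mapped onto the duplicated one:
  # each repeat-interior read is an exact tie between the two copies, so
  # random placement gives each copy about half the unique-region depth
  pair <- perfect_dup_pair()
  reads <- tile_reads(pair$single, width = 50, step = 1)
  pr <- map_short_reads(reads, pair$dup, "random", seed = 11)
  expect_equal(pr$covered_fraction, 1)
  interior1 <- 650:1051
  interior2 <- 1150:1551
  unique_depth <- mean(pr$depth[100:500])
  for (interior in list(interior1, interior2)) {
    ratio <- mean(pr$depth[interior]) / unique_depth
    expect_gt(ratio, 0.4)
    expect_lt(ratio, 0.6)
  }
})

test_that("coverage under ignore grows with copy divergence and read length", {
  base <- toy_genome(2600, seed = 63)
  m0 <- dup_model(base, donor = 1500, acceptor = 601)  # identical copies
  seg_pos <- seq(610, 1490, by = 20)                    # 5% divergence
  ed <- validate_edits(dplyr::bind_rows(lapply(seg_pos, function(p) {
    refa <- substring(base$seq, p, p)
    copy_edits(p, "substitution", refa,
               setdiff(c("A", "C", "G", "T"), refa)[1], "duplication")
  })))
  m5 <- dup_model(base, donor = 1500, acceptor = 601, edits = ed)
  cf <- function(m, width) {
    g <- reconstruct(m)
    reads <- tile_reads(g, width = width, step = 3)
    map_short_reads(reads, g, "ignore")$covered_fraction
  }
  expect_gte(cf(m5, 50), cf(m0, 50))
  expect_gt(cf(m5, 50), cf(m0, 50))  # strictly better at 5% divergence
  expect_gte(cf(m0, 90), cf(m0, 50)) # longer reads bridge more of the repeat
})

test_that("policy comparison summarizes per-region depth against the model", {
  m <- sfx_model()
  g <- sfx_recon()
  reads <- tile_reads(g, width = 99, step = 11)
  pi <- map_short_reads(reads, g, "ignore")
  pr <- map_short_reads(reads, g, "random", seed = 3)
  cmp <- compare_policies(pi, pr, m)
  expect_setequal(cmp$region, c("upstream", "primary", "insert", "duplication",
                                "downstream", "total"))
  tot <- cmp[cmp$region == "total", ]
  expect_lte(tot$covered_fraction_ignore, tot$covered_fraction_random)
  # ignore-policy holes are confined to the repeat copies
  ui <- uncovered_intervals(pi)
  rm_ <- region_map(m)
  prim <- rm_[rm_$region == "primary", ]
  dup <- rm_[rm_$region == "duplication", ]
  expect_true(all(ui$start >= prim$start & ui$end <= dup$end))
  expect_equal(cmp$uncovered_ignore[cmp$region %in% c("upstream", "downstream")],
               c(0L, 0L))
  # mismatched genomes are refused
  expect_error(compare_policies(pi, map_short_reads(tile_reads(sfx_ref(), 99, 301),
                                                    sfx_ref(), "ignore")),
               "different genomes")
})

test_that("profiles export as bedGraph and tidy/glance views", {
  g <- toy_genome(800, seed = 71)
  reads <- tile_reads(g, width = 50, step = 13)
  p <- map_short_reads(reads, g, "ignore")
  td <- tidy(p)
  expect_equal(nrow(td), 800L)
  expect_equal(td$depth, p$depth)
  gl <- glance(p)
  expect_equal(gl$n_mapped, p$n_mapped)
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(p, path)
  bg <- read.delim(path, header = FALSE)
  expect_equal(sum((bg$V3 - bg$V2) * bg$V4), sum(p$depth))
})
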