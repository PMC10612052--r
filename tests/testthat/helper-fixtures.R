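# Shared fixtures, cached per test run (building the surrogate model takes
# a couple of seconds; several files reuse it).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

sfx_model <- function() cached("model", function() sfrhabdo_model(1))
sfx_ref <- function() sfx_model()$reference
sfx_recon <- function() cached("recon", function() reconstruct(sfx_model()))
sfx_primer <- function(nm) {
  pr <- cached("primers", sfrhabdo_primers)
  pr[pr$name == nm, ]
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

toy_genome <- function(len = 300, seed = 11, name = "toy") {
  withr::with_seed(seed, genome(rand_seq(len), name))
}

set_base <- function(seq, pos, value) {
  paste0(substring(seq, 1, pos - 1), value,
         substring(seq, pos + nchar(value), nchar(seq)))
}

# a random small duplication model, optionally with random per-copy edits;
# used by the liftover/length property tests
random_small_model <- function(seed) {
  withr::with_seed(seed, {
    L <- sample(80:250, 1)
    ref <- genome(rand_seq(L), "rand")
    acceptor <- sample(10:(L - 30), 1)
    donor <- sample(acceptor:(L - 10), 1)
    insert <- if (runif(1) < 0.5) "" else rand_seq(sample(1:4, 1))
    ext5 <- sample(0:12, 1)
    edits <- copy_edits()
    seg <- donor - acceptor + 1
    if (seg >= 20 && runif(1) < 0.7) {
      pos <- sample(seq(acceptor + 3, donor - 5, by = 6),
                    min(3, max(1, seg %/% 12)))
      rows <- lapply(pos, function(p) {
        kind <- sample(c("substitution", "insertion", "deletion"), 1)
        if (kind == "substitution") {
          refa <- substring(ref$seq, p, p)
          copy_edits(p, "substitution", refa,
                     sample(setdiff(c("A", "C", "G", "T"), refa), 1),
                     sample(c("primary", "duplication"), 1))
        } else if (kind == "insertion") {
          copy_edits(p, "insertion", "", rand_seq(sample(1:3, 1)),
                     sample(c("primary", "duplication"), 1))
        } else {
          copy_edits(p, "deletion", substring(ref$seq, p, p + 1), "",
                     sample(c("primary", "duplication"), 1))
        }
      })
      edits <- validate_edits(dplyr::bind_rows(rows))
    }
    dup_model(ref, donor, acceptor, insert, terminal_ext5 = ext5,
              edits = edits, ext5_seed = seed)
  })
}
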