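# Alignment scoring used for chain re-alignment, pileups and short-read
# placement. Gaps cost clearly more than mismatches so that a true
# substitution next to a sequencing indel is still aligned as a mismatch
# column instead of being absorbed into the gap (which would erase the
# variant evidence from the pileup).
ALN_MATCH <- 2L
ALN_MISMATCH <- -2L
ALN_GAP <- -6L

# banded global alignment wrapper; band grows with the length difference
band_align <- function(a, b, band = 64L) {
  band_align_cpp(a, b, band = max(band, abs(nchar(a) - nchar(b)) + 16L),
                 match = ALN_MATCH, mismatch = ALN_MISMATCH, gap = ALN_GAP)
}

# chain one oriented read against an indexed reference: anchor, partition
# into colinear blocks, then DP-chain blocks along the read (reference
# jumps between consecutive blocks are allowed -- they are the structural
# signal). Returns NULL when no anchors.
chain_one_strand <- function(idx, read, k, max_chain_gap, max_hits,
                             overlap_tol = 5L, switch_penalty = 4,
                             gap_penalty = 0.2) {
  anc <- kmer_anchors_cpp(idx, read, max_hits)
  if (nrow(anc) == 0) return(NULL)
  ord <- order(anc[, 1], anc[, 2])
  rp <- anc[ord, 1]; fp <- anc[ord, 2]
  bid <- partition_blocks_cpp(rp, fp, max_gap = max_chain_gap, diag_tol = 50L)
  blocks <- tibble::tibble(read_pos = rp, ref_pos = fp, block = bid) %>%
    dplyr::group_by(.data$block) %>%
    dplyr::summarise(read_start = min(.data$read_pos),
                     read_end = max(.data$read_pos) + k - 1L,
                     ref_start = min(.data$ref_pos),
                     ref_end = max(.data$ref_pos) + k - 1L,
                     n_anchors = dplyr::n(), .groups = "drop") %>%
    dplyr::arrange(.data$read_start, .data$ref_start)
  B <- nrow(blocks)
  span <- blocks$read_end - blocks$read_start + 1L
  score <- as.numeric(span)
  prev <- rep(NA_integer_, B)
  if (B > 1) {
    for (i in 2:B) {
      for (j in 1:(i - 1)) {
        if (blocks$read_start[i] <= blocks$read_end[j] - overlap_tol) next
        gap <- max(0L, blocks$read_start[i] - blocks$read_end[j] - 1L)
        cand <- score[j] + span[i] - gap_penalty * gap - switch_penalty
        if (cand > score[i]) { score[i] <- cand; prev[i] <- j }
      }
    }
  }
  end <- which.max(score)
  chain <- integer(0)
  while (!is.na(end)) { chain <- c(end, chain); end <- prev[end] }
  list(blocks = blocks[chain, , drop = FALSE], score = max(score))
}

# base-level re-alignment of each chain block; returns summed alignment
# stats and (optionally) per-base read<->reference coordinate pairs
block_alignments <- function(read, ref_seq, blocks, keep_pairs = FALSE) {
  stats <- list(n_match = 0L, n_mismatch = 0L, n_gap = 0L, n_cols = 0L)
  pairs <- if (keep_pairs) vector("list", nrow(blocks)) else NULL
  for (i in seq_len(nrow(blocks))) {
    a <- substring(read, blocks$read_start[i], blocks$read_end[i])
    b <- substring(ref_seq, blocks$ref_start[i], blocks$ref_end[i])
    al <- band_align(a, b)
    stats$n_match <- stats$n_match + al$n_match
    stats$n_mismatch <- stats$n_mismatch + al$n_mismatch
    stats$n_gap <- stats$n_gap + al$n_gap
    stats$n_cols <- stats$n_cols + al$n_cols
    if (keep_pairs) {
      rp <- ifelse(al$a_pos > 0L, al$a_pos + blocks$read_start[i] - 1L, 0L)
      fp <- ifelse(al$b_pos > 0L, al$b_pos + blocks$ref_start[i] - 1L, 0L)
      pairs[[i]] <- cbind(read_pos = rp, ref_pos = fp)
    }
  }
  list(stats = stats, pairs = if (keep_pairs) do.call(rbind, pairs) else NULL)
}

#' Align reads to a reference by k-mer seed-and-chain
#'
#' Finds exact k-mer anchors of each read (both strands) against the
#' reference, groups them into colinear blocks, and chains blocks along the
#' read by dynamic programming. Reference-coordinate jumps between
#' consecutive blocks are allowed and preserved: a backward jump is the
#' signature of an internal duplication (see [detect_backjumps()]). Reads
#' aligning better on the minus strand are reverse-complemented before
#' chaining, so reported coordinates always refer to the working
#' (reference-forward) orientation of the read. Identity and gap
#' percentages come from a base-level banded re-alignment of the chained
#' blocks.
#'
#' @param reads read tibble (columns `id`, `seq`) or a single character
#'   sequence.
#' @param g reference [genome()].
#' @param k anchor k-mer size (default 13).
#' @param max_chain_gap largest within-block anchor gap, in bases.
#' @param max_hits k-mers occurring more often than this in the reference
#'   are skipped as repetitive.
#' @param compute_identity skip the base-level re-alignment (identity and
#'   gap percentages come back `NA`) when `FALSE`; junction detection does
#'   not need it and large batches run severalfold faster.
#' @return tibble of chain blocks: `read_id`, `strand`, `block`,
#'   `read_start`, `read_end`, `ref_start`, `ref_end`, `n_anchors`,
#'   `chain_score`, `identity_pct`, `gaps_pct` (chain-level values repeated
#'   per block). Reads without anchors yield no rows.
#' @export
align_reads <- function(reads, g, k = 13L, max_chain_gap = 200L, max_hits = 8L,
                        compute_identity = TRUE) {
  if (is.character(reads)) {
    reads <- tibble::tibble(id = sprintf("read_%03d", seq_along(reads)), seq = reads)
  }
  idx <- kmer_index_cpp(g$seq, k)
  out <- purrr::map(seq_len(nrow(reads)), function(i) {
    seq_f <- reads$seq[i]
    if (nchar(seq_f) < k) return(NULL)
    fwd <- chain_one_strand(idx, seq_f, k, max_chain_gap, max_hits)
    seq_r <- revcomp(seq_f)
    rev <- chain_one_strand(idx, seq_r, k, max_chain_gap, max_hits)
    if (is.null(fwd) && is.null(rev)) return(NULL)
    use_rev <- !is.null(rev) && (is.null(fwd) || rev$score > fwd$score)
    ch <- if (use_rev) rev else fwd
    working <- if (use_rev) seq_r else seq_f
    st <- if (compute_identity) {
      block_alignments(working, g$seq, ch$blocks)$stats
    } else {
      list(n_cols = 0L)
    }
    dplyr::mutate(ch$blocks,
                  read_id = reads$id[i],
                  strand = if (use_rev) "-" else "+",
                  chain_score = ch$score,
                  identity_pct = if (st$n_cols) 100 * st$n_match / st$n_cols else NA_real_,
                  gaps_pct = if (st$n_cols) 100 * st$n_gap / st$n_cols else NA_real_,
                  .before = 1)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(read_id = character(), strand = character(),
                          chain_score = numeric(), identity_pct = numeric(),
                          gaps_pct = numeric(), block = integer(),
                          read_start = integer(), read_end = integer(),
                          ref_start = integer(), ref_end = integer(),
                          n_anchors = integer()))
  }
  res
}
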