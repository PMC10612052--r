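#' Canonicalize a duplication junction representation
#'
#' When the sequence flanking a breakpoint is repeated on both sides,
#' several (donor, acceptor, insert) triples describe the same molecule
#' (microhomology ambiguity). The canonical representative used throughout
#' the package is the one with the shortest insert, ties broken by the
#' largest donor: insert bases matching the reference immediately after the
#' donor are absorbed rightward (donor grows), then bases matching the
#' reference immediately before the acceptor are absorbed leftward
#' (acceptor shrinks); an empty insert is shifted right while the base
#' after the donor equals the acceptor base.
#'
#' @param g reference [genome()] or plain sequence string.
#' @param donor,acceptor junction coordinates on the reference.
#' @param insert inserted bases (possibly empty).
#' @return list with canonical `donor`, `acceptor`, `insert`.
#' @export
canonicalize_junction <- function(g, donor, acceptor, insert = "") {
  seq <- if (inherits(g, "genome")) g$seq else g
  L <- nchar(seq)
  ins <- if (nchar(insert)) seq_chars(insert) else character(0)
  repeat {
    if (length(ins) && donor < L &&
        substring(seq, donor + 1L, donor + 1L) == ins[1]) {
      donor <- donor + 1L
      ins <- ins[-1]
    } else if (length(ins) && acceptor > 1L &&
               substring(seq, acceptor - 1L, acceptor - 1L) == ins[length(ins)]) {
      acceptor <- acceptor - 1L
      ins <- ins[-length(ins)]
    } else break
  }
  if (!length(ins)) {
    while (donor < L &&
           substring(seq, donor + 1L, donor + 1L) ==
           substring(seq, acceptor, acceptor)) {
      donor <- donor + 1L
      acceptor <- acceptor + 1L
    }
  }
  list(donor = donor, acceptor = acceptor, insert = paste(ins, collapse = ""))
}

# Per-candidate breakpoint refinement. Anchoring stops at the last exact
# k-mer, so with noisy reads the raw block ends underestimate the donor and
# overestimate the acceptor whenever an error falls near the junction, and
# the unaligned gap bases then contain flank sequence plus errors. This
# small DP re-aligns the gap against both reference flanks (mismatches and
# 1-base indels allowed), choosing the split donor-extension / insert /
# acceptor-extension that maximizes the alignment score with a per-base
# insert penalty; ties prefer the shortest insert, then the largest donor.
refine_breakpoint <- function(gap_seq, ref_seq, e1, s2,
                              match = 1, mismatch = -3, gapp = -3,
                              ins_pen = 0.6) {
  g <- nchar(gap_seq)
  if (g == 0) return(list(donor = e1, acceptor = s2, insert = ""))
  L <- nchar(ref_seq)
  gb <- seq_chars(gap_seq)
  wl <- min(g + 6L, L - e1)
  wr <- min(g + 6L, s2 - 1L)
  refL <- if (wl > 0) seq_chars(substring(ref_seq, e1 + 1L, e1 + wl)) else character(0)
  refR <- if (wr > 0) seq_chars(substring(ref_seq, s2 - wr, s2 - 1L)) else character(0)

  # Lmat[i+1, p+1]: best score aligning gap prefix of length i to donor-side
  # flank prefix of length p
  flank_dp <- function(gchars, fchars) {
    n <- length(gchars); m <- length(fchars)
    M <- matrix(-Inf, n + 1L, m + 1L)
    M[1, ] <- gapp * (0:m)
    M[, 1] <- gapp * (0:n)
    M[1, 1] <- 0
    for (i in seq_len(n)) {
      for (p in seq_len(m)) {
        M[i + 1L, p + 1L] <- max(
          M[i, p] + if (gchars[i] == fchars[p]) match else mismatch,
          M[i, p + 1L] + gapp,
          M[i + 1L, p] + gapp)
      }
    }
    M
  }
  Lmat <- flank_dp(gb, refL)
  Rmat <- flank_dp(rev(gb), rev(refR))

  best <- list(score = -Inf, i = 0L, m = 0L, p = 0L, q = 0L)
  for (i in 0:g) {
    lrow <- Lmat[i + 1L, ]
    lp <- max(which(lrow == max(lrow))) - 1L  # largest donor extension on ties
    for (m in 0:(g - i)) {
      rrow <- Rmat[m + 1L, ]
      rq <- max(which(rrow == max(rrow))) - 1L
      ins_len <- g - i - m
      sc <- lrow[lp + 1L] + rrow[rq + 1L] - ins_pen * ins_len
      better <- sc > best$score + 1e-9 ||
        (abs(sc - best$score) < 1e-9 &&
           (ins_len < g - best$i - best$m ||
              (ins_len == g - best$i - best$m && lp > best$p)))
      if (better) best <- list(score = sc, i = i, m = m, p = lp, q = rq)
    }
  }
  list(donor = e1 + best$p,
       acceptor = s2 - best$q,
       insert = if (best$i + best$m < g)
         paste(gb[(best$i + 1L):(g - best$m)], collapse = "") else "")
}

#' Detect duplication back-jumps in alignment chains
#'
#' Scans each read's chain for consecutive blocks where the reference
#' coordinate jumps backward by at least `min_jump` while the read
#' continues with at most `max_read_gap` unaligned bases: the signature of
#' a read crossing an internal-duplication junction. The unaligned read
#' bases become the candidate insert; every candidate is canonicalized
#' against the reference (see [canonicalize_junction()]), which also
#' recovers breakpoint bases that noisy anchoring left in the gap.
#'
#' @param chains chain tibble from [align_reads()].
#' @param reads the read tibble that was aligned (for gap-base lookup).
#' @param g the reference [genome()].
#' @param min_jump minimum backward jump (default 50 nt) -- forward jumps
#'   and small backward jumps are deletion-like noise, not duplications.
#' @param max_read_gap largest tolerated unaligned read gap at the junction.
#' @return tibble of junction candidates: `read_id`, `donor`, `acceptor`,
#'   `insert`, `read_gap`.
#' @export
detect_backjumps <- function(chains, reads, g, min_jump = 50L,
                             max_read_gap = 20L) {
  empty <- tibble::tibble(read_id = character(), donor = integer(),
                          acceptor = integer(), insert = character(),
                          read_gap = integer())
  if (nrow(chains) == 0) return(empty)
  seqs <- setNames(reads$seq, reads$id)
  out <- chains %>%
    dplyr::group_by(.data$read_id) %>%
    dplyr::group_map(function(ch, key) {
      if (nrow(ch) < 2) return(NULL)
      ch <- dplyr::arrange(ch, .data$read_start)
      working <- seqs[[key$read_id]]
      if (ch$strand[1] == "-") working <- revcomp(working)
      rows <- list()
      for (i in seq_len(nrow(ch) - 1)) {
        jump <- ch$ref_start[i + 1] - ch$ref_end[i] - 1L
        if (jump > -min_jump) next
        gap <- ch$read_start[i + 1] - ch$read_end[i] - 1L
        if (gap > max_read_gap) next
        donor <- ch$ref_end[i]
        acceptor <- ch$ref_start[i + 1]
        if (gap < 0) {  # anchor overlap from repeated k-mers; trim acceptor side
          acceptor <- acceptor - gap
          insert <- ""
        } else if (gap == 0) {
          insert <- ""
        } else {
          gap_seq <- substring(working, ch$read_end[i] + 1L, ch$read_start[i + 1] - 1L)
          ref_seq <- if (inherits(g, "genome")) g$seq else g
          refined <- refine_breakpoint(gap_seq, ref_seq, donor, acceptor)
          donor <- refined$donor
          acceptor <- refined$acceptor
          insert <- refined$insert
        }
        if (acceptor > donor) next
        can <- canonicalize_junction(g, donor, acceptor, insert)
        rows[[length(rows) + 1L]] <-
          tibble::tibble(read_id = key$read_id, donor = can$donor,
                         acceptor = can$acceptor, insert = can$insert,
                         read_gap = max(gap, 0L))
      }
      dplyr::bind_rows(rows)
    }) %>%
    dplyr::bind_rows()
  if (nrow(out) == 0) empty else out
}

#' Cluster junction candidates and call consensus junctions
#'
#' Single-linkage clustering of candidates on (donor, acceptor) with a
#' per-axis tolerance. The consensus breakpoint of a cluster is the
#' coordinate-wise median over the members whose insert has the modal
#' length (noisy members whose breakpoints could not be canonicalized
#' cleanly carry longer, error-containing inserts and are down-weighted by
#' this rule); the consensus insert is a per-position majority vote over
#' those members, and the final triple is canonicalized. Clusters with
#' support below `min_support` are dropped.
#'
#' @param candidates tibble from [detect_backjumps()].
#' @param g reference [genome()].
#' @param tol per-axis clustering tolerance in nt.
#' @param min_support minimum reads per reported junction.
#' @return tibble of junction calls: `donor`, `acceptor`, `insert`,
#'   `support`, `read_ids` (list column).
#' @export
cluster_junctions <- function(candidates, g, tol = 20L, min_support = 2L) {
  empty <- tibble::tibble(donor = integer(), acceptor = integer(),
                          insert = character(), support = integer(),
                          read_ids = list())
  if (nrow(candidates) == 0) return(empty)
  n <- nrow(candidates)
  cl <- if (n == 1) 1L else {
    dd <- abs(outer(candidates$donor, candidates$donor, "-"))
    da <- abs(outer(candidates$acceptor, candidates$acceptor, "-"))
    stats::cutree(stats::hclust(stats::as.dist(pmax(dd, da)), method = "single"),
                  h = tol)
  }
  out <- purrr::map(unique(cl), function(k) {
    mem <- candidates[cl == k, , drop = FALSE]
    # plurality vote over refined candidate triples: exact candidates recur
    # across reads while error-bearing ones are idiosyncratic; ties prefer
    # the shortest insert, then the largest donor (the canonical order)
    key <- paste(mem$donor, mem$acceptor, mem$insert, sep = "|")
    tab <- table(key)
    top_keys <- names(tab)[tab == max(tab)]
    cand <- mem[match(top_keys, key), , drop = FALSE]
    cand <- cand[order(nchar(cand$insert), -cand$donor), , drop = FALSE]
    can <- canonicalize_junction(g, cand$donor[1], cand$acceptor[1],
                                 cand$insert[1])
    tibble::tibble(donor = can$donor, acceptor = can$acceptor,
                   insert = can$insert, support = nrow(mem),
                   read_ids = list(mem$read_id))
  }) %>% dplyr::bind_rows()
  out <- out[out$support >= min_support, , drop = FALSE]
  dplyr::arrange(out, dplyr::desc(.data$support))
}

#' Call duplication junctions from long reads
#'
#' One-stop wrapper: align reads by seed-and-chain, detect back-jump
#' candidates, cluster and canonicalize. The per-read candidate table is
#' attached as attribute `"candidates"`, the chain table as `"chains"`.
#'
#' @inheritParams align_reads
#' @inheritParams detect_backjumps
#' @inheritParams cluster_junctions
#' @return junction call tibble as [cluster_junctions()].
#' @export
call_junctions <- function(reads, g, k = 13L, max_chain_gap = 200L,
                           min_jump = 50L, max_read_gap = 20L, tol = 20L,
                           min_support = 2L, compute_identity = TRUE) {
  chains <- align_reads(reads, g, k = k, max_chain_gap = max_chain_gap,
                        compute_identity = compute_identity)
  cand <- detect_backjumps(chains, reads, g, min_jump = min_jump,
                           max_read_gap = max_read_gap)
  calls <- cluster_junctions(cand, g, tol = tol, min_support = min_support)
  attr(calls, "candidates") <- cand
  attr(calls, "chains") <- chains
  calls
}

#' Per-read junction report
#'
#' Mirrors the per-read summary used for junction-spanning long reads: the
#' aligned region rendered as `start-donor^insert^acceptor-end` (or
#' `start-end` for reads without a junction), with chain identity and gap
#' percentages.
#'
#' @param chains chain tibble from [align_reads()].
#' @param candidates candidate tibble from [detect_backjumps()].
#' @return tibble with `read_id`, `aligned_region`, `strand`,
#'   `identity_pct`, `gaps_pct`.
#' @export
junction_read_report <- function(chains, candidates) {
  if (nrow(chains) == 0) {
    return(tibble::tibble(read_id = character(), aligned_region = character(),
                          strand = character(), identity_pct = numeric(),
                          gaps_pct = numeric()))
  }
  chains %>%
    dplyr::group_by(.data$read_id) %>%
    dplyr::group_map(function(ch, key) {
      ch <- dplyr::arrange(ch, .data$read_start)
      cand <- candidates[candidates$read_id == key$read_id, , drop = FALSE]
      region <- if (nrow(cand)) {
        paste0(ch$ref_start[1], "-",
               paste(purrr::map_chr(seq_len(nrow(cand)), function(i) {
                 paste0(cand$donor[i], "^",
                        ifelse(nchar(cand$insert[i]), cand$insert[i], "-"),
                        "^", cand$acceptor[i])
               }), collapse = "-"),
               "-", ch$ref_end[nrow(ch)])
      } else {
        paste0(ch$ref_start[1], "-", ch$ref_end[nrow(ch)])
      }
      tibble::tibble(read_id = key$read_id, aligned_region = region,
                     strand = ch$strand[1],
                     identity_pct = ch$identity_pct[1],
                     gaps_pct = ch$gaps_pct[1])
    }) %>%
    dplyr::bind_rows()
}
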