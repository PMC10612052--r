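# Candidate placements of one oriented read: anchor diagonals are grouped
# and each group is scored by banded global alignment against the implied
# genome window. Returns a data.frame of candidates with exact scores.
candidate_placements <- function(idx, read, g_seq, k, max_hits) {
  anc <- kmer_anchors_cpp(idx, read, max_hits)
  if (nrow(anc) == 0) return(NULL)
  n <- nchar(read)
  L <- nchar(g_seq)
  diag <- anc[, 2] - anc[, 1]
  grp <- cumsum(c(1L, diff(sort(unique(diag))) > 10L))
  diag_rep <- setNames(grp, sort(unique(diag)))
  out <- vector("list", max(grp))
  for (gid in unique(grp)) {
    dvals <- as.integer(names(diag_rep)[diag_rep == gid])
    sel <- diag %in% dvals
    # window implied by the anchor diagonals: read-sized, widened only by
    # the observed diagonal drift, so a clean read aligns gap-free
    ws <- max(1L, min(anc[sel, 2] - anc[sel, 1] + 1L))
    we <- min(L, ws + n - 1L + (max(diag[sel]) - min(diag[sel])))
    al <- band_align(read, substring(g_seq, ws, we))
    aligned_read <- sum(al$a_pos > 0L & al$b_pos > 0L)
    bpos <- al$b_pos[al$b_pos > 0L & al$a_pos > 0L]
    if (length(bpos) == 0) next
    out[[gid]] <- data.frame(score = al$score,
                             aligned_len = aligned_read,
                             identity = if (al$n_cols) al$n_match /
                               (al$n_match + al$n_mismatch + al$n_gap) else 0,
                             start = ws + min(bpos) - 1L,
                             end = ws + max(bpos) - 1L)
  }
  if (all(vapply(out, is.null, logical(1)))) return(NULL)
  do.call(rbind, out)
}

#' Map short reads under a multi-mapping placement policy
#'
#' Each read's candidate placements are all genome positions achieving its
#' best alignment score, subject to an aligned-length fraction and an
#' identity fraction threshold (the two CLC-style mapping knobs). A read
#' with a unique best placement is placed there. A read whose best score is
#' tied across several positions (typical inside near-identical repeats) is
#' handled by `policy`: `"ignore"` discards it; `"random"` places it at one
#' tie chosen uniformly (seeded). Depth is accumulated over the reference
#' span of each placed read.
#'
#' @param reads read tibble (`id`, `seq`).
#' @param g a [genome()].
#' @param policy `"ignore"` or `"random"`.
#' @param length_fraction minimum aligned fraction of the read (default 0.5).
#' @param similarity_fraction minimum identity of the alignment (default 0.8).
#' @param k anchor k-mer size.
#' @param seed RNG seed; required for `policy = "random"`.
#' @param max_hits repetitive k-mer cutoff for candidate discovery.
#' @return a `coverage_profile`: per-base depth plus mapping counts.
#' @export
map_short_reads <- function(reads, g, policy = c("ignore", "random"),
                            length_fraction = 0.5, similarity_fraction = 0.8,
                            k = 13L, seed = NULL, max_hits = 64L) {
  policy <- match.arg(policy)
  if (policy == "random" && is.null(seed))
    stop("config error: policy 'random' needs a seed")
  L <- genome_length(g)
  idx <- kmer_index_cpp(g$seq, k)
  run <- function() {
    starts <- integer(0); ends <- integer(0)
    n_mapped <- 0L
    for (i in seq_len(nrow(reads))) {
      rd <- reads$seq[i]
      if (nchar(rd) < k) next
      cand <- rbind(candidate_placements(idx, rd, g$seq, k, max_hits),
                    candidate_placements(idx, revcomp(rd), g$seq, k, max_hits))
      if (is.null(cand) || nrow(cand) == 0) next
      cand <- cand[cand$aligned_len >= length_fraction * nchar(rd) &
                     cand$identity >= similarity_fraction, , drop = FALSE]
      if (nrow(cand) == 0) next
      best <- cand[cand$score == max(cand$score), , drop = FALSE]
      # the same placement can be reached from both strands of a palindromic
      # window; count distinct genome spans as the tie set
      best <- unique(best[, c("start", "end")])
      if (nrow(best) > 1L) {
        if (policy == "ignore") next
        best <- best[sample.int(nrow(best), 1L), , drop = FALSE]
      }
      n_mapped <- n_mapped + 1L
      starts <- c(starts, best$start)
      ends <- c(ends, best$end)
    }
    depth <- integer(L)
    if (length(starts)) {
      bump <- integer(L + 1L)
      for (j in seq_along(starts)) {
        bump[starts[j]] <- bump[starts[j]] + 1L
        bump[ends[j] + 1L] <- bump[ends[j] + 1L] - 1L
      }
      depth <- cumsum(bump[seq_len(L)])
    }
    list(depth = depth, n_mapped = n_mapped)
  }
  res <- if (policy == "random") withr::with_seed(seed, run()) else run()
  structure(list(depth = res$depth, policy = policy,
                 n_reads = nrow(reads), n_mapped = res$n_mapped,
                 covered_len = sum(res$depth >= 1L),
                 covered_fraction = sum(res$depth >= 1L) / L,
                 genome_name = g$name, genome_length = L,
                 length_fraction = length_fraction,
                 similarity_fraction = similarity_fraction),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("<coverage_profile> ", x$genome_name, " (", x$genome_length, " nt), policy ",
      x$policy, ": ", x$n_mapped, "/", x$n_reads, " reads placed, ",
      round(100 * x$covered_fraction, 1), "% covered\n", sep = "")
  invisible(x)
}

#' @rdname map_short_reads
#' @param x a `coverage_profile`.
#' @param ... unused.
#' @export
tidy.coverage_profile <- function(x, ...) {
  tibble::tibble(pos = seq_along(x$depth), depth = x$depth)
}

#' @rdname map_short_reads
#' @export
glance.coverage_profile <- function(x, ...) {
  tibble::tibble(policy = x$policy, n_reads = x$n_reads,
                 n_mapped = x$n_mapped, covered_len = x$covered_len,
                 covered_fraction = x$covered_fraction,
                 mean_depth = mean(x$depth), max_depth = max(x$depth))
}

#' Zero-coverage intervals of a coverage profile
#' @param profile a `coverage_profile`.
#' @return tibble with `start`, `end` of each uncovered run.
#' @export
uncovered_intervals <- function(profile) {
  r <- rle(profile$depth == 0L)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  tibble::tibble(start = starts[r$values], end = as.integer(ends[r$values]))
}

#' Contrast ignore- and random-placement coverage profiles
#'
#' Summarizes, per model region (or for the whole genome when no model is
#' given), mean depth and uncovered bases under the two multi-mapping
#' policies. With near-identical repeat copies the ignore policy leaves
#' coverage holes confined to the repeat, while random placement covers it
#' at the cost of arbitrary read assignment; `covered_fraction` under
#' ignore can never exceed random (checked, with a warning if violated by a
#' mismatched input pair).
#'
#' @param profile_ignore,profile_random `coverage_profile`s over the same
#'   genome and read set.
#' @param model optional [dup_model()] for per-region rows.
#' @return tibble with per-region and total rows: `region`, `start`, `end`,
#'   `mean_depth_ignore`, `mean_depth_random`, `uncovered_ignore`,
#'   `uncovered_random`, `covered_fraction_ignore`,
#'   `covered_fraction_random`.
#' @export
compare_policies <- function(profile_ignore, profile_random, model = NULL) {
  if (profile_ignore$genome_length != profile_random$genome_length ||
      profile_ignore$genome_name != profile_random$genome_name)
    stop("profiles come from different genomes")
  regions <- if (is.null(model)) {
    tibble::tibble(region = "genome", start = 1L,
                   end = profile_ignore$genome_length)
  } else {
    region_map(model)
  }
  rows <- purrr::pmap(regions, function(region, start, end) {
    di <- profile_ignore$depth[start:end]
    dr <- profile_random$depth[start:end]
    tibble::tibble(region = region, start = start, end = end,
                   mean_depth_ignore = mean(di), mean_depth_random = mean(dr),
                   uncovered_ignore = sum(di == 0L),
                   uncovered_random = sum(dr == 0L),
                   covered_fraction_ignore = mean(di > 0L),
                   covered_fraction_random = mean(dr > 0L))
  })
  out <- dplyr::bind_rows(rows)
  total <- tibble::tibble(region = "total", start = 1L,
                          end = profile_ignore$genome_length,
                          mean_depth_ignore = mean(profile_ignore$depth),
                          mean_depth_random = mean(profile_random$depth),
                          uncovered_ignore = sum(profile_ignore$depth == 0L),
                          uncovered_random = sum(profile_random$depth == 0L),
                          covered_fraction_ignore = profile_ignore$covered_fraction,
                          covered_fraction_random = profile_random$covered_fraction)
  if (profile_ignore$covered_fraction > profile_random$covered_fraction)
    warning("ignore-policy coverage exceeds random-policy coverage; ",
            "are the profiles from the same read set?")
  dplyr::bind_rows(out, total)
}

#' Write a coverage profile as bedGraph
#' @param profile a `coverage_profile`.
#' @param path output file.
#' @param name track name (defaults to the genome name).
#' @export
write_bedgraph <- function(profile, path, name = profile$genome_name) {
  r <- rle(profile$depth)
  ends <- cumsum(r$lengths)
  starts <- c(0L, head(ends, -1))  # bedGraph is 0-based half-open
  df <- data.frame(chrom = name, start = starts, end = ends, depth = r$values)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
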