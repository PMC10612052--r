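# Apply i.i.d. per-base sequencing errors to a template string.
# Per template base: deleted with del_rate; otherwise substituted with
# sub_rate (to a random different base); after each template base a random
# base is inserted with ins_rate. Returns the read plus event counts.
apply_seq_errors <- function(seq, sub_rate, ins_rate, del_rate) {
  n <- nchar(seq)
  if (sub_rate + ins_rate + del_rate >= 1)
    stop("config error: error rates must sum to < 1")
  if (n == 0) return(list(seq = "", n_sub = 0L, n_ins = 0L, n_del = 0L))
  if (sub_rate + ins_rate + del_rate == 0)
    return(list(seq = seq, n_sub = 0L, n_ins = 0L, n_del = 0L))
  base <- seq_chars(seq)
  del <- runif(n) < del_rate
  sub <- !del & (runif(n) < sub_rate)
  if (any(sub)) {
    # substitute with one of the three other bases, uniformly
    shift <- sample.int(3L, sum(sub), replace = TRUE)
    idx <- match(base[sub], DNA_BASES)
    base[sub] <- DNA_BASES[((idx - 1L + shift) %% 4L) + 1L]
  }
  ins <- runif(n) < ins_rate
  out <- ifelse(del, "", base)
  if (any(ins)) {
    out[ins] <- paste0(out[ins], sample(DNA_BASES, sum(ins), replace = TRUE))
  }
  list(seq = paste(out, collapse = ""),
       n_sub = sum(sub), n_ins = sum(ins), n_del = sum(del))
}

phred_string <- function(q, n) strrep(intToUtf8(q + 33L), n)

#' Simulate noisy long reads from a genome
#'
#' Read lengths are log-normal with the requested mean (truncated at the
#' genome length); start positions are uniform; a configurable fraction of
#' reads is reverse-complemented; substitution/insertion/deletion errors are
#' placed i.i.d. per base. Each read records its true origin interval
#' (genome coordinates of the template before errors), strand, a constant
#' per-read Phred quality drawn from a normal distribution, and the realized
#' error-event counts.
#'
#' @param g a [genome()].
#' @param n_reads number of reads.
#' @param mean_len target mean read length (default 2500 nt).
#' @param sdlog log-normal shape parameter.
#' @param sub_rate,ins_rate,del_rate per-base error probabilities.
#' @param reverse_frac fraction of reverse-strand reads.
#' @param q_mean,q_sd per-read mean Phred quality distribution.
#' @param min_len shortest template length drawn.
#' @param seed RNG seed (required: simulations are always reproducible).
#' @return tibble with `id`, `seq`, `qual`, `truth_start`, `truth_end`,
#'   `strand`, `n_sub`, `n_ins`, `n_del`.
#' @export
simulate_long_reads <- function(g, n_reads, mean_len = 2500, sdlog = 0.6,
                                sub_rate = 0.03, ins_rate = 0.04,
                                del_rate = 0.03, reverse_frac = 0.5,
                                q_mean = 12, q_sd = 4, min_len = 100L,
                                seed = 1L) {
  stopifnot(inherits(g, "genome"), n_reads >= 0)
  if (sub_rate + ins_rate + del_rate >= 1)
    stop("config error: error rates must sum to < 1")
  L <- genome_length(g)
  if (n_reads == 0) return(empty_reads())
  withr::with_seed(seed, {
    meanlog <- log(mean_len) - sdlog^2 / 2
    lens <- pmin(L, pmax(min_len, round(stats::rlnorm(n_reads, meanlog, sdlog))))
    starts <- floor(runif(n_reads, 1, L - lens + 1 + 1))
    rev <- runif(n_reads) < reverse_frac
    q <- pmin(40L, pmax(2L, round(rnorm(n_reads, q_mean, q_sd))))
    rows <- purrr::map(seq_len(n_reads), function(i) {
      tmpl <- substring(g$seq, starts[i], starts[i] + lens[i] - 1L)
      if (rev[i]) tmpl <- revcomp(tmpl)
      er <- apply_seq_errors(tmpl, sub_rate, ins_rate, del_rate)
      tibble::tibble(id = sprintf("lr_%05d", i), seq = er$seq,
                     qual = phred_string(q[i], nchar(er$seq)),
                     truth_start = starts[i],
                     truth_end = starts[i] + lens[i] - 1L,
                     strand = if (rev[i]) "-" else "+",
                     n_sub = er$n_sub, n_ins = er$n_ins, n_del = er$n_del)
    })
    dplyr::bind_rows(rows)
  })
}

#' Simulate paired-end short reads
#'
#' Fragments are drawn uniformly with normal insert sizes; the two
#' mates are read inward from the fragment ends ("innies"): mate 1 from the
#' fragment strand, mate 2 reverse-complemented from the other end. Fragment
#' orientation is random per pair.
#'
#' @inheritParams simulate_long_reads
#' @param n_pairs number of read pairs.
#' @param read_len fixed read length (default 99 bp).
#' @param insert_mean,insert_sd fragment (outer insert) size distribution.
#' @return tibble as [simulate_long_reads()] plus `mate` (1 or 2) and
#'   `pair_id`; truth coordinates are per mate in genome coordinates.
#' @export
simulate_short_reads <- function(g, n_pairs, read_len = 99L,
                                 insert_mean = 300, insert_sd = 50,
                                 sub_rate = 0, ins_rate = 0, del_rate = 0,
                                 reverse_frac = 0.5, q_mean = 35, q_sd = 3,
                                 seed = 1L) {
  stopifnot(inherits(g, "genome"), n_pairs >= 0)
  L <- genome_length(g)
  if (read_len > L) stop("config error: read length exceeds genome length")
  if (n_pairs == 0) return(empty_reads())
  withr::with_seed(seed, {
    flen <- pmin(L, pmax(read_len, round(rnorm(n_pairs, insert_mean, insert_sd))))
    starts <- floor(runif(n_pairs, 1, L - flen + 1 + 1))
    flip <- runif(n_pairs) < reverse_frac
    q <- pmin(40L, pmax(2L, round(rnorm(n_pairs, q_mean, q_sd))))
    rows <- purrr::map(seq_len(n_pairs), function(i) {
      s <- starts[i]; e <- starts[i] + flen[i] - 1L
      m1 <- c(s, s + read_len - 1L)         # left end of fragment
      m2 <- c(e - read_len + 1L, e)         # right end of fragment
      # mate 1 reads the fragment 5'->3'; on a flipped fragment that is the
      # right end on the minus strand
      if (!flip[i]) {
        coords <- list(m1, m2); strands <- c("+", "-")
      } else {
        coords <- list(m2, m1); strands <- c("-", "+")
      }
      purrr::map2(coords, seq_along(coords), function(co, mate) {
        tmpl <- substring(g$seq, co[1], co[2])
        if (strands[mate] == "-") tmpl <- revcomp(tmpl)
        er <- apply_seq_errors(tmpl, sub_rate, ins_rate, del_rate)
        tibble::tibble(id = sprintf("sr_%06d/%d", i, mate), seq = er$seq,
                       qual = phred_string(q[i], nchar(er$seq)),
                       truth_start = co[1], truth_end = co[2],
                       strand = strands[mate],
                       n_sub = er$n_sub, n_ins = er$n_ins, n_del = er$n_del,
                       pair_id = i, mate = mate)
      }) %>% dplyr::bind_rows()
    })
    dplyr::bind_rows(rows)
  })
}

#' Deterministic error-free reads tiling a genome
#'
#' One read every `step` bases plus a final window flush with the genome
#' end, so every base is covered when `width >= step`. Useful for exact
#' mappability analyses without sampling noise.
#'
#' @param g a [genome()].
#' @param width read width.
#' @param step distance between read starts.
#' @return read tibble as [simulate_long_reads()].
#' @export
tile_reads <- function(g, width = 99L, step = 1L) {
  L <- genome_length(g)
  stopifnot(width <= L, step >= 1)
  starts <- unique(c(seq.int(1L, L - width + 1L, by = step), L - width + 1L))
  tibble::tibble(id = sprintf("tile_%06d", starts),
                 seq = substring(g$seq, starts, starts + width - 1L),
                 qual = phred_string(35L, width),
                 truth_start = starts, truth_end = starts + width - 1L,
                 strand = "+", n_sub = 0L, n_ins = 0L, n_del = 0L)
}

empty_reads <- function() {
  tibble::tibble(id = character(), seq = character(), qual = character(),
                 truth_start = integer(), truth_end = integer(),
                 strand = character(), n_sub = integer(), n_ins = integer(),
                 n_del = integer())
}

#' Filter reads by mean base quality and length
#'
#' Keeps reads whose arithmetic mean Phred score is at least `min_mean_q`
#' and whose length is at least `min_len`; order is preserved. This mirrors
#' basecaller-style quality trimming (e.g. a Q7 cutoff) plus an optional
#' short-fragment removal.
#'
#' @param reads read tibble with `seq` and `qual` columns.
#' @param min_mean_q minimum mean Phred quality (default 7).
#' @param min_len minimum read length (default 0 = off).
#' @return filtered tibble.
#' @export
filter_reads_by_quality <- function(reads, min_mean_q = 7, min_len = 0L) {
  mq <- purrr::map_dbl(reads$qual, function(q) {
    if (!nchar(q)) return(-Inf)
    mean(utf8ToInt(q) - 33L)
  })
  reads[mq >= min_mean_q & nchar(reads$seq) >= min_len, , drop = FALSE]
}

#' Write/read reads as FASTQ (Phred+33)
#' @param reads read tibble (`id`, `seq`, `qual`).
#' @param path FASTQ file.
#' @return `path` invisibly / a read tibble.
#' @export
write_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(setNames(reads$seq, reads$id))
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble::tibble(id = names(ss), seq = unname(as.character(ss)),
                 qual = unname(as.character(S4Vectors::mcols(ss)$qualities)))
}

#' Write the read truth sidecar TSV
#' @param reads read tibble with truth columns.
#' @param path output TSV.
#' @export
write_truth <- function(reads, path) {
  write.table(reads[, c("id", "truth_start", "truth_end", "strand")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
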