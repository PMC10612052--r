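# strip the edit list from a model: variant calling always works against
# the naive (edit-free) reconstruction, so called differences are genuine
# read evidence rather than baked-in assumptions
naive_model <- function(model) {
  dup_model(model$reference, model$donor, model$acceptor, model$insert,
            terminal_ext5 = model$terminal_ext5,
            ext5_seq = model$ext5_seq)
}

#' Assign each aligned read to a repeat copy of origin
#'
#' Inside a near-identical repeat a read aligns equally well to both
#' copies, so copy attribution must come from anchors: a read is
#' informative if its alignment (a) covers the junction insert with at
#' least `min_anchor` bases on both sides (label `"both"`: its bases left
#' of the insert are primary-copy evidence, right of it duplication-copy
#' evidence), or (b) extends at least `min_anchor` bases into unique
#' sequence upstream of the primary copy (label `"primary"`) or downstream
#' of the duplication copy (label `"duplication"`). Reads with no anchor
#' that overlap the repeat are `"unassignable"`; reads entirely outside the
#' repeat are `"unique"`. This automates the manual review step used to
#' place variants into their respective copies.
#'
#' @param chains chain tibble from [align_reads()] against
#'   `reconstruct(model)`.
#' @param model the (naive) [dup_model()] describing the repeat geometry.
#' @param min_anchor minimum anchoring bases (default 100).
#' @return tibble: `read_id`, `label`, `span_start`, `span_end`, `strand`.
#' @export
assign_read_copy <- function(chains, model, min_anchor = 100L) {
  maps <- model_maps(model)
  pr <- maps$primary_range; dr <- maps$duplication_range
  ir <- maps$insert_range
  junc_left <- if (is.na(ir[1])) pr[2] else ir[1] - 1L
  junc_right <- if (is.na(ir[1])) dr[1] else ir[2] + 1L
  chains %>%
    dplyr::group_by(.data$read_id) %>%
    dplyr::summarise(span_start = min(.data$ref_start),
                     span_end = max(.data$ref_end),
                     strand = .data$strand[1], .groups = "drop") %>%
    dplyr::mutate(label = dplyr::case_when(
      span_end < pr[1] | span_start > dr[2] ~ "unique",
      span_start <= junc_left - min_anchor + 1L &
        span_end >= junc_right + min_anchor - 1L ~ "both",
      span_start <= pr[1] - min_anchor ~ "primary",
      span_end >= dr[2] + min_anchor ~ "duplication",
      TRUE ~ "unassignable"))
}

# pileup events of one read against the derived genome: aligned bases,
# deletions (allele "-") and insertions (collapsed per anchor position)
read_events <- function(working_read, g_seq, blocks) {
  pairs <- block_alignments(working_read, g_seq, blocks, keep_pairs = TRUE)$pairs
  if (is.null(pairs) || nrow(pairs) == 0) return(NULL)
  rp <- pairs[, "read_pos"]; gp <- pairs[, "ref_pos"]
  rbase <- seq_chars(working_read)
  aligned <- gp > 0L
  allele <- ifelse(rp > 0L, rbase[pmax(rp, 1L)], "-")
  base_tbl <- data.frame(pos = gp[aligned], allele = allele[aligned])
  base_tbl <- base_tbl[order(base_tbl$pos), , drop = FALSE]
  # left-normalize per-read deletion runs so equivalent gap placements from
  # different reads pile up at the same genome positions
  del <- base_tbl$allele == "-"
  if (any(del)) {
    runs <- rle(del)
    ends <- cumsum(runs$lengths)
    starts <- c(1L, head(ends, -1) + 1L)
    for (ri in which(runs$values)) {
      i0 <- starts[ri]; i1 <- ends[ri]
      p <- base_tbl$pos[i0]; m <- i1 - i0 + 1L
      q <- normalize_indel_left(g_seq, p, substring(g_seq, p, p + m - 1L),
                                "deletion")$pos
      if (q < p) {
        # the gap moves to [q, q+m-1]; read bases originally aligned at
        # [q..p-1] shift to [q+m..p+m-1], preserving the read's evidence
        rows <- match(q:(p + m - 1L), base_tbl$pos)
        if (!anyNA(rows)) {
          shifted <- base_tbl$allele[rows[seq_len(p - q)]]
          base_tbl$allele[rows] <- c(rep("-", m), shifted)
        }
      }
    }
  }
  # per-read deletion runs (normalized), reported as events
  dels <- NULL
  del <- base_tbl$allele == "-"
  if (any(del)) {
    runs <- rle(del)
    ends <- cumsum(runs$lengths)
    starts <- c(1L, head(ends, -1) + 1L)
    keep <- runs$values
    dels <- data.frame(pos = base_tbl$pos[starts[keep]],
                       len = runs$lengths[keep])
  }
  ins <- NULL
  if (any(gp == 0L)) {
    # inserted read bases anchor to the last aligned genome position
    anchor <- cummax_na(ifelse(gp > 0L, gp, NA_integer_), init = 0L)
    w <- which(gp == 0L & anchor > 0L)
    if (length(w)) {
      ins <- stats::aggregate(list(seq = rbase[rp[w]]),
                              by = list(pos = anchor[w]),
                              FUN = paste, collapse = "")
      for (ii in seq_len(nrow(ins))) {
        norm <- normalize_indel_left(g_seq, ins$pos[ii], ins$seq[ii], "insertion")
        ins$pos[ii] <- norm$pos
        ins$seq[ii] <- norm$allele
      }
    }
  }
  list(bases = base_tbl, ins = ins, dels = dels)
}

# One pileup pass: map reads against the reconstruction of `model_x`,
# assign copy labels, and accumulate per-side allele counts plus insertion
# and deletion events restricted to each read's credit windows.
collect_pileups <- function(reads, model_x, min_anchor, k) {
  gnew <- reconstruct(model_x)
  Lnew <- genome_length(gnew)
  maps <- model_maps(model_x)
  pr <- maps$primary_range; dr <- maps$duplication_range
  ir <- maps$insert_range
  junc_left <- if (is.na(ir[1])) pr[2] else ir[1] - 1L
  junc_right <- if (is.na(ir[1])) dr[1] else ir[2] + 1L
  chains <- align_reads(reads, gnew, k = k, compute_identity = FALSE)
  labels <- assign_read_copy(chains, model_x, min_anchor = min_anchor)
  seqs <- setNames(reads$seq, reads$id)
  alleles <- c("A", "C", "G", "T", "-")
  counts <- list(primary = matrix(0L, Lnew, 5L),
                 duplication = matrix(0L, Lnew, 5L))
  ins_events <- list()
  del_events <- list()
  credit_windows <- function(label) {
    switch(label,
           both = list(primary = c(1L, junc_left), duplication = c(junc_right, Lnew)),
           primary = list(primary = c(1L, junc_left)),
           duplication = list(duplication = c(junc_right, Lnew)),
           unique = list(primary = c(1L, pr[1] - 1L), duplication = c(dr[2] + 1L, Lnew)),
           NULL)
  }
  for (i in seq_len(nrow(labels))) {
    wins <- credit_windows(labels$label[i])
    if (is.null(wins)) next
    rid <- labels$read_id[i]
    rid_chr <- as.character(rid)
    ch <- chains[chains$read_id == rid, , drop = FALSE]
    working <- seqs[[rid]]
    if (ch$strand[1] == "-") working <- revcomp(working)
    ev <- read_events(working, gnew$seq, ch)
    if (is.null(ev)) next
    for (side in names(wins)) {
      w <- wins[[side]]
      sel <- ev$bases$pos >= w[1] & ev$bases$pos <= w[2] &
        ev$bases$allele %in% alleles
      if (any(sel)) {
        idx <- cbind(ev$bases$pos[sel], match(ev$bases$allele[sel], alleles))
        counts[[side]][idx] <- counts[[side]][idx] + 1L
      }
      if (!is.null(ev$ins)) {
        isel <- ev$ins$pos >= w[1] & ev$ins$pos <= w[2]
        if (any(isel)) {
          ins_events[[length(ins_events) + 1L]] <-
            data.frame(read = rid_chr, side = side,
                       pos = ev$ins$pos[isel], seq = ev$ins$seq[isel])
        }
      }
      if (!is.null(ev$dels)) {
        dsel <- ev$dels$pos >= w[1] & ev$dels$pos <= w[2]
        if (any(dsel)) {
          del_events[[length(del_events) + 1L]] <-
            data.frame(read = rid_chr, side = side,
                       pos = ev$dels$pos[dsel], len = ev$dels$len[dsel])
        }
      }
    }
  }
  list(gnew = gnew, counts = counts,
       ins = if (length(ins_events)) dplyr::bind_rows(ins_events) else NULL,
       dels = if (length(del_events)) dplyr::bind_rows(del_events) else NULL,
       labels = labels, chains = chains)
}

#' Call paralog variants between repeat copies from long reads
#'
#' Maps reads against the naive (edit-free) reconstruction of the
#' duplication model, restricts pileups to copy-informative reads (see
#' [assign_read_copy()]), computes a per-position consensus separately for
#' primary-assigned and duplication-assigned evidence, and reports every
#' position where a copy consensus differs from the reference (or where the
#' two copies differ from each other), rendered in reference, primary-copy
#' and duplication-copy coordinates. Indels are left-aligned within their
#' copy before reporting. Variants in unique (non-repeated) regions are
#' reported with `copy = "unique"`.
#'
#' @param reads read tibble.
#' @param model a [dup_model()]; only its junction, terminal extension and
#'   reference are used (its edit list, if any, is ignored so calling stays
#'   de novo).
#' @param min_depth minimum informative reads per position (default 3).
#' @param min_af minimum consensus allele fraction (default 0.7).
#' @param min_anchor see [assign_read_copy()].
#' @param k anchor k-mer size for mapping.
#' @return tibble with one row per variant site: rendered `ref_pos`,
#'   `ref_allele`, `primary_pos`, `primary_allele`, `duplication_pos`,
#'   `duplication_allele`, `copy`, plus support counts
#'   `n_primary_reads`/`n_duplication_reads`. Attribute `"called_model"`
#'   carries the fitted [dup_model()] with the called edit list; attribute
#'   `"coverage_gaps"` counts positions skipped for depth.
#' @export
call_copy_variants <- function(reads, model, min_depth = 3L, min_af = 0.7,
                               min_anchor = 100L, k = 13L) {
  nm <- naive_model(model)
  ref_seq <- nm$reference$seq

  # pass 1: pileups against the naive reconstruction; call indels from
  # run-level events (per-read normalized runs voted as whole events)
  p1 <- collect_pileups(reads, nm, min_anchor, k)
  indel_edits <- called_indel_edits(p1, nm, min_depth, min_af)

  # pass 2: substitution genotyping against the indel-corrected haplotype.
  # Re-aligning against a reconstruction that carries the called indels
  # removes the alignment ambiguity around them, so substitutions adjacent
  # to an indel are read as clean mismatch columns.
  if (nrow(indel_edits)) {
    sub_model <- dup_model(nm$reference, nm$donor, nm$acceptor, nm$insert,
                           terminal_ext5 = nm$terminal_ext5,
                           ext5_seq = nm$ext5_seq, edits = indel_edits)
    p2 <- collect_pileups(reads, sub_model, min_anchor, k)
  } else {
    sub_model <- nm
    p2 <- p1
  }

  sub_edits <- list()
  gchars2 <- seq_chars(p2$gnew$seq)
  gaps <- list()
  for (side in c("primary", "duplication")) {
    cm <- p2$counts[[side]]
    base_depth <- rowSums(cm[, 1:4, drop = FALSE])
    eligible <- which(base_depth >= min_depth)
    bm <- cm[eligible, 1:4, drop = FALSE]
    top <- max.col(bm, ties.method = "first")
    frac <- bm[cbind(seq_along(eligible), top)] / base_depth[eligible]
    conf <- eligible[frac >= min_af]
    cons <- c("A", "C", "G", "T")[top[frac >= min_af]]
    differs <- cons != gchars2[conf]
    gaps[[side]] <- sum(base_depth < min_depth)
    if (!any(differs)) next
    bk <- lift_new_to_ref(sub_model, conf[differs])
    keep <- !bk$from_insertion
    if (!any(keep)) next
    sub_edits[[side]] <- tibble::tibble(
      ref_pos = bk$pos_ref[keep], kind = "substitution",
      ref_allele = substring(ref_seq, bk$pos_ref[keep], bk$pos_ref[keep]),
      alt_allele = cons[differs][keep],
      copy = dplyr::case_when(bk$region[keep] == "primary" ~ "primary",
                              bk$region[keep] == "duplication" ~ "duplication",
                              TRUE ~ "unique"))
  }
  sub_edits <- dplyr::bind_rows(sub_edits)
  if (nrow(sub_edits)) {
    # a unique-region difference is seen by both pileup sides; keep one row
    sub_edits <- sub_edits[!duplicated(paste(sub_edits$ref_pos, sub_edits$copy)), ,
                           drop = FALSE]
  }

  edits <- dplyr::bind_rows(indel_edits, sub_edits)
  if (nrow(edits)) {
    edits <- validate_edits(dplyr::arrange(edits, .data$ref_pos))
  } else {
    edits <- copy_edits()
  }
  called_model <- dup_model(model$reference, model$donor, model$acceptor,
                            model$insert, terminal_ext5 = model$terminal_ext5,
                            ext5_seq = model$ext5_seq, edits = edits)
  out <- tidy(called_model)
  if (nrow(out)) {
    supp <- support_counts(edits, sub_model, p2$counts)
    out <- dplyr::bind_cols(out, supp)
  } else {
    out$n_primary_reads <- integer(0)
    out$n_duplication_reads <- integer(0)
  }
  attr(out, "called_model") <- called_model
  attr(out, "coverage_gaps") <- tibble::tibble(side = names(gaps),
                                               n_low_depth = unlist(gaps))
  attr(out, "read_labels") <- p2$labels
  out
}

# group indel events around recurrent anchor positions: positions seen in
# at least two reads seed clusters (strongest first) that absorb events
# within +/- tol; isolated one-read events (sequencing-error noise spread
# over the whole genome) never seed a cluster
peak_clusters <- function(ev, tol = 3L) {
  tab <- sort(table(ev$pos), decreasing = TRUE)
  peaks <- as.integer(names(tab))[tab >= 2L]
  taken <- rep(FALSE, nrow(ev))
  out <- list()
  for (p in peaks) {
    sel <- which(!taken & abs(ev$pos - p) <= tol)
    if (length(sel) < 2L || !any(ev$pos[sel] == p)) next
    out[[length(out) + 1L]] <- list(anchor = p, events = ev[sel, , drop = FALSE])
    taken[sel] <- TRUE
  }
  out
}

# call insertion and deletion edits (reference coordinates, copy-labeled)
# from run-level events of a pileup pass against the naive reconstruction.
# Events from different reads land on slightly different anchors when
# sequencing errors fall inside or next to the indel, so events are
# clustered within a few bases and support is counted as distinct reads.
called_indel_edits <- function(p1, nm, min_depth, min_af, tol = 3L) {
  ref_seq <- nm$reference$seq
  rows <- list()
  depth_at <- function(side, pos) sum(p1$counts[[side]][pos, ])
  copy_at <- function(pos) {
    bk <- lift_new_to_ref(nm, pos)
    list(ref_pos = bk$pos_ref,
         copy = dplyr::case_when(bk$region == "primary" ~ "primary",
                                 bk$region == "duplication" ~ "duplication",
                                 TRUE ~ "unique"))
  }
  modal_int <- function(x) min(as.integer(names(which(table(x) == max(table(x))))))
  if (!is.null(p1$ins)) {
    for (side in unique(p1$ins$side)) {
      ev <- p1$ins[p1$ins$side == side, , drop = FALSE]
      for (clu in peak_clusters(ev, tol)) {
        e <- clu$events
        n <- length(unique(e$read))
        anchor <- clu$anchor
        denom <- depth_at(side, anchor)
        if (n < min_depth || denom == 0 || n / denom < min_af) next
        core_e <- e[e$pos == anchor, , drop = FALSE]
        lens <- nchar(core_e$seq)
        modal <- modal_int(lens)
        core <- core_e$seq[lens == modal]
        cons <- paste(apply(do.call(rbind, strsplit(core, "", fixed = TRUE)), 2,
                            function(col) names(sort(table(col), decreasing = TRUE))[1]),
                      collapse = "")
        at <- copy_at(anchor)
        norm <- normalize_indel_left(ref_seq, at$ref_pos, cons, "insertion")
        rows[[length(rows) + 1L]] <- tibble::tibble(
          ref_pos = norm$pos, kind = "insertion", ref_allele = "",
          alt_allele = norm$allele, copy = at$copy)
      }
    }
  }
  if (!is.null(p1$dels)) {
    for (side in unique(p1$dels$side)) {
      ev <- p1$dels[p1$dels$side == side, , drop = FALSE]
      for (clu in peak_clusters(ev, tol)) {
        e <- clu$events
        n <- length(unique(e$read))
        anchor <- clu$anchor
        denom <- depth_at(side, anchor)
        if (n < min_depth || denom == 0 || n / denom < min_af) next
        m <- modal_int(e$len[e$pos == anchor])
        at <- copy_at(anchor)
        norm <- normalize_indel_left(ref_seq, at$ref_pos,
                                     substring(ref_seq, at$ref_pos,
                                               at$ref_pos + m - 1L), "deletion")
        rows[[length(rows) + 1L]] <- tibble::tibble(
          ref_pos = norm$pos, kind = "deletion", ref_allele = norm$allele,
          alt_allele = "", copy = at$copy)
      }
    }
  }
  if (!length(rows)) return(copy_edits())
  ed <- dplyr::bind_rows(rows)
  ed <- ed[!duplicated(paste(ed$ref_pos, ed$kind, ed$copy)), , drop = FALSE]
  validate_edits(dplyr::arrange(ed, .data$ref_pos))
}

# informative-read depth at each called site, per copy, for the report
support_counts <- function(edits, model_x, counts) {
  n_p <- integer(nrow(edits)); n_d <- integer(nrow(edits))
  for (i in seq_len(nrow(edits))) {
    p <- edits$ref_pos[i]
    if (edits$copy[i] == "unique") {
      img <- lift_ref_to_new(model_x, p)
      side <- if (p < model_x$acceptor) "primary" else "duplication"
      n <- sum(counts[[side]][img, ])
      n_p[i] <- n; n_d[i] <- n
    } else {
      n_p[i] <- sum(counts$primary[lift_ref_to_new(model_x, p, "primary"), ])
      n_d[i] <- sum(counts$duplication[lift_ref_to_new(model_x, p, "duplication"), ])
    }
  }
  tibble::tibble(n_primary_reads = n_p, n_duplication_reads = n_d)
}

#' Write called variants as a minimal VCF against the derived genome
#'
#' @param variants output of [call_copy_variants()] (uses its
#'   `"called_model"` attribute).
#' @param path output VCF file.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  cm <- attr(variants, "called_model")
  if (is.null(cm)) stop("variants must carry a 'called_model' attribute")
  nm <- naive_model(cm)
  gnew <- reconstruct(nm)
  ed <- cm$edits
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", gnew$name, genome_length(gnew)),
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  for (i in seq_len(nrow(ed))) {
    copy <- ed$copy[i]
    sel_copy <- if (copy == "duplication") "duplication" else "primary"
    p <- ed$ref_pos[i]
    if (ed$kind[i] == "substitution") {
      pos <- lift_ref_to_new(nm, p, sel_copy)
      ref <- ed$ref_allele[i]; alt <- ed$alt_allele[i]
    } else if (ed$kind[i] == "insertion") {
      pos <- lift_ref_to_new(nm, p, sel_copy)
      base <- substring(gnew$seq, pos, pos)
      ref <- base; alt <- paste0(base, ed$alt_allele[i])
    } else {
      pos <- lift_ref_to_new(nm, p - 1L, sel_copy)
      base <- substring(gnew$seq, pos, pos)
      ref <- paste0(base, ed$ref_allele[i]); alt <- base
    }
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tCOPY=%s",
                              gnew$name, pos, ref, alt, copy))
  }
  writeLines(lines, path)
  invisible(path)
}
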