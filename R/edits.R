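#' Construct a per-copy edit table
#'
#' Edits describe how the primary copy, the duplicated copy, or the unique
#' (non-repeated) regions of a derived genome differ from the reference.
#' Positions are always reference coordinates, 1-based inclusive; an
#' insertion is anchored "after base `ref_pos`" (rendered `p^p+1` in
#' reports); a deletion starts at `ref_pos` and removes
#' `nchar(ref_allele)` bases.
#'
#' @param ref_pos integer reference positions (insertion anchors for
#'   insertions).
#' @param kind one of "substitution", "insertion", "deletion" per edit.
#' @param ref_allele reference allele (empty string for insertions).
#' @param alt_allele alternate allele (empty string for deletions).
#' @param copy which copy carries the alternate allele: "primary",
#'   "duplication" or "unique".
#' @return a validated tibble of class `copy_edits`.
#' @export
#' @examples
#' copy_edits(ref_pos = 10, kind = "substitution",
#'            ref_allele = "A", alt_allele = "G", copy = "duplication")
copy_edits <- function(ref_pos = integer(), kind = character(),
                       ref_allele = character(), alt_allele = character(),
                       copy = character()) {
  ed <- tibble::tibble(ref_pos = as.integer(ref_pos),
                       kind = as.character(kind),
                       ref_allele = toupper(as.character(ref_allele)),
                       alt_allele = toupper(as.character(alt_allele)),
                       copy = as.character(copy))
  validate_edits(ed)
}

validate_edits <- function(ed) {
  ed <- tibble::as_tibble(ed)
  need <- c("ref_pos", "kind", "ref_allele", "alt_allele", "copy")
  stopifnot(all(need %in% names(ed)))
  ed$ref_pos <- as.integer(ed$ref_pos)
  ed$ref_allele[is.na(ed$ref_allele)] <- ""
  ed$alt_allele[is.na(ed$alt_allele)] <- ""
  if (!all(ed$kind %in% c("substitution", "insertion", "deletion")))
    stop("edit kind must be substitution, insertion or deletion")
  if (!all(ed$copy %in% c("primary", "duplication", "unique")))
    stop("edit copy must be primary, duplication or unique")
  ins <- ed$kind == "insertion"
  del <- ed$kind == "deletion"
  sub <- ed$kind == "substitution"
  if (any(nchar(ed$ref_allele[ins]) != 0) || any(nchar(ed$alt_allele[ins]) == 0))
    stop("insertion must have empty ref_allele and nonempty alt_allele")
  if (any(nchar(ed$alt_allele[del]) != 0) || any(nchar(ed$ref_allele[del]) == 0))
    stop("deletion must have empty alt_allele and nonempty ref_allele")
  if (any(nchar(ed$ref_allele[sub]) == 0) ||
      any(nchar(ed$ref_allele[sub]) != nchar(ed$alt_allele[sub])))
    stop("substitution must have equal-length nonempty alleles")
  class(ed) <- c("copy_edits", class(tibble::tibble()))
  ed
}

#' Read/write a per-copy edit table as TSV
#'
#' The TSV mirrors the [copy_edits()] columns `ref_pos`, `kind`,
#' `ref_allele`, `alt_allele`, `copy`; empty alleles may be encoded as "-"
#' or left blank.
#' @param path TSV file.
#' @return a `copy_edits` tibble.
#' @export
read_edits <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                   colClasses = "character", comment.char = "#")
  df$ref_allele[df$ref_allele %in% c("-", ".")] <- ""
  df$alt_allele[df$alt_allele %in% c("-", ".")] <- ""
  copy_edits(ref_pos = as.integer(df$ref_pos), kind = df$kind,
             ref_allele = df$ref_allele, alt_allele = df$alt_allele,
             copy = df$copy)
}

#' @rdname read_edits
#' @param edits a `copy_edits` tibble.
#' @export
write_edits <- function(edits, path) {
  out <- as.data.frame(edits)
  out$ref_allele[out$ref_allele == ""] <- "-"
  out$alt_allele[out$alt_allele == ""] <- "-"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# net length change (insertions minus deletions) of an edit subset
net_indel <- function(ed) {
  if (nrow(ed) == 0) return(0L)
  as.integer(sum(nchar(ed$alt_allele[ed$kind == "insertion"])) -
               sum(nchar(ed$ref_allele[ed$kind == "deletion"])))
}

# Apply edits (reference coordinates, sorted internally) to the reference
# segment [seg_start, seg_end]. Returns the edited sequence plus, per output
# base, the originating reference position (`map`, NA for inserted bases)
# and the anchoring reference position (`anchor`, = map where defined).
apply_edits <- function(ref_seq, seg_start, seg_end, edits) {
  if (nrow(edits) == 0) {
    n <- seg_end - seg_start + 1L
    return(list(seq = substring(ref_seq, seg_start, seg_end),
                map = seq.int(seg_start, seg_end),
                anchor = seq.int(seg_start, seg_end)))
  }
  ord <- order(edits$ref_pos, match(edits$kind, c("substitution", "deletion", "insertion")))
  edits <- edits[ord, ]
  chunks <- character(0)
  maps <- list()
  anchors <- list()
  cursor <- seg_start
  emit_ref <- function(from, to) {
    if (to < from) return(invisible(NULL))
    chunks[[length(chunks) + 1L]] <<- substring(ref_seq, from, to)
    maps[[length(maps) + 1L]] <<- seq.int(from, to)
    anchors[[length(anchors) + 1L]] <<- seq.int(from, to)
    invisible(NULL)
  }
  for (i in seq_len(nrow(edits))) {
    p <- edits$ref_pos[i]
    kind <- edits$kind[i]
    refa <- edits$ref_allele[i]
    alta <- edits$alt_allele[i]
    if (kind == "insertion") {
      if (p < seg_start - 1L || p > seg_end) stop("model error: insertion anchor outside segment")
      if (p < cursor - 1L) stop("model error: overlapping edits")
      emit_ref(cursor, p)
      chunks[[length(chunks) + 1L]] <- alta
      maps[[length(maps) + 1L]] <- rep(NA_integer_, nchar(alta))
      anchors[[length(anchors) + 1L]] <- rep(p, nchar(alta))
      cursor <- p + 1L
    } else {
      m <- nchar(refa)
      if (p < seg_start || p + m - 1L > seg_end) stop("model error: edit outside segment")
      if (p < cursor) stop("model error: overlapping edits")
      have <- substring(ref_seq, p, p + m - 1L)
      if (have != refa)
        stop(sprintf("model error: ref_allele mismatch at %d (expected %s, reference has %s)",
                     p, refa, have))
      emit_ref(cursor, p - 1L)
      if (kind == "substitution") {
        chunks[[length(chunks) + 1L]] <- alta
        maps[[length(maps) + 1L]] <- seq.int(p, p + m - 1L)
        anchors[[length(anchors) + 1L]] <- seq.int(p, p + m - 1L)
      }
      cursor <- p + m
    }
  }
  emit_ref(cursor, seg_end)
  list(seq = paste(chunks, collapse = ""),
       map = unlist(maps, use.names = FALSE),
       anchor = unlist(anchors, use.names = FALSE))
}

# Left-align an indel: shift a deletion/insertion left while the base before
# the event equals its last base (standard VCF-style normalization).
# `allele` is the deleted run (deletion) or inserted run (insertion);
# `pos` is the deletion start, or the insertion anchor (after `pos`).
normalize_indel_left <- function(ref_seq, pos, allele, kind) {
  allele <- seq_chars(allele)
  m <- length(allele)
  if (kind == "deletion") {
    # deleted window [pos, pos+m-1]; shift while ref[pos-1] == ref[pos+m-1]
    while (pos > 1 && substring(ref_seq, pos - 1, pos - 1) == substring(ref_seq, pos + m - 1, pos + m - 1)) {
      pos <- pos - 1L
    }
    list(pos = pos, allele = substring(ref_seq, pos, pos + m - 1L))
  } else {
    # insertion after pos; shift while ref[pos] == last inserted base
    while (pos > 0 && substring(ref_seq, pos, pos) == allele[m]) {
      allele <- c(substring(ref_seq, pos, pos), allele[-m])
      pos <- pos - 1L
    }
    list(pos = pos, allele = paste(allele, collapse = ""))
  }
}
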