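#' Build a duplication model
#'
#' A duplication model ties together a reference genome, a single back-jump
#' junction (`donor^insert^acceptor`: the derived genome runs along the
#' reference to base `donor`, emits `insert`, then resumes at base
#' `acceptor` <= `donor`, so the interval `[acceptor, donor]` appears twice),
#' an optional terminal extension (extra bases prepended in the deposited
#' orientation; only its length matters for coordinates), and a per-copy
#' edit list. It defines the reconstructed genome and all coordinate
#' liftovers between the reference and the derived genome.
#'
#' @param reference a [genome()].
#' @param donor last reference base before the jump.
#' @param acceptor reference base resumed after the jump (`<= donor`).
#' @param insert inserted sequence at the junction (possibly empty).
#' @param terminal_ext5 number of extra bases prepended (default 0).
#' @param edits a [copy_edits()] tibble (default none).
#' @param ext5_seq optional explicit pad sequence of length `terminal_ext5`;
#'   by default random bases generated deterministically from `ext5_seed`.
#' @param ext5_seed seed for the generated pad (default 1).
#' @return an object of class `dup_model`.
#' @export
#' @examples
#' ref <- genome("ACGTACGTAA", "toy")
#' m <- dup_model(ref, donor = 6, acceptor = 3, insert = "GA")
#' reconstruct(m)$seq
dup_model <- function(reference, donor, acceptor, insert = "",
                      terminal_ext5 = 0L, edits = copy_edits(),
                      ext5_seq = NULL, ext5_seed = 1L) {
  stopifnot(inherits(reference, "genome"))
  donor <- as.integer(donor)
  acceptor <- as.integer(acceptor)
  L <- genome_length(reference)
  if (donor < 1 || donor > L || acceptor < 1 || acceptor > L)
    stop("coordinate error: junction outside reference")
  if (acceptor > donor)
    stop("coordinate error: acceptor must be <= donor (back-jump duplication)")
  if (nchar(insert)) insert <- clean_seq(insert, strict = TRUE)
  terminal_ext5 <- as.integer(terminal_ext5)
  stopifnot(terminal_ext5 >= 0)
  edits <- validate_edits(edits)
  validate_model_edits(edits, acceptor, donor, L)
  if (is.null(ext5_seq)) {
    ext5_seq <- if (terminal_ext5 > 0) {
      withr::with_seed(ext5_seed, random_dna(terminal_ext5))
    } else ""
  } else {
    ext5_seq <- clean_seq(ext5_seq, strict = TRUE)
    if (nchar(ext5_seq) != terminal_ext5)
      stop("ext5_seq length must equal terminal_ext5")
  }
  structure(list(reference = reference, donor = donor, acceptor = acceptor,
                 insert = insert, terminal_ext5 = terminal_ext5,
                 edits = edits, ext5_seq = ext5_seq,
                 cache = new.env(parent = emptyenv())),
            class = "dup_model")
}

# Edits must respect the junction: repeat-copy edits live inside
# [acceptor, donor]; unique edits outside; nothing spans a boundary.
validate_model_edits <- function(edits, acceptor, donor, L) {
  if (nrow(edits) == 0) return(invisible(TRUE))
  lo <- edits$ref_pos
  hi <- ifelse(edits$kind == "insertion", edits$ref_pos,
               edits$ref_pos + nchar(edits$ref_allele) - 1L)
  if (any(lo < 1 | hi > L)) stop("coordinate error: edit outside reference")
  rep_edit <- edits$copy %in% c("primary", "duplication")
  if (any(rep_edit & (lo < acceptor | hi > donor)))
    stop("model error: primary/duplication edit outside [acceptor, donor]")
  inside <- lo >= acceptor & hi <= donor
  outside <- hi < acceptor | lo > donor
  if (any(!rep_edit & !outside))
    stop("model error: unique edit inside the repeat, or edit spanning a junction boundary")
  invisible(TRUE)
}

#' @export
print.dup_model <- function(x, ...) {
  cat("<dup_model> ", x$reference$name, ": junction ",
      x$donor, "^", if (nchar(x$insert)) x$insert else "-", "^", x$acceptor,
      " (segment ", x$donor - x$acceptor + 1L, " nt), ext5 ", x$terminal_ext5,
      ", ", nrow(x$edits), " edit(s)\n", sep = "")
  invisible(x)
}

# Internal: compute and memoize the derived sequence and coordinate maps.
# img1[p] (p in 1..donor) and img2[p - acceptor + 1] (p in acceptor..L) give
# the derived coordinate of reference base p in the first/second pass;
# deleted bases take the image of the last retained base before them.
model_maps <- function(model) {
  if (!is.null(model$cache$maps)) return(model$cache$maps)
  ref <- model$reference$seq
  L <- nchar(ref)
  acc <- model$acceptor; don <- model$donor
  ed <- model$edits
  ed1 <- ed[ed$copy == "primary" | (ed$copy == "unique" & ed$ref_pos < acc), ]
  ed2 <- ed[ed$copy == "duplication" | (ed$copy == "unique" & ed$ref_pos > don), ]
  part1 <- apply_edits(ref, 1L, don, ed1)
  part2 <- apply_edits(ref, acc, L, ed2)
  ext5 <- model$terminal_ext5
  ins <- model$insert
  len1 <- nchar(part1$seq)
  off2 <- ext5 + len1 + nchar(ins)

  img_from_map <- function(map, seg_start, seg_end, offset) {
    img <- integer(seg_end - seg_start + 1L)
    keep <- !is.na(map)
    img[map[keep] - seg_start + 1L] <- which(keep) + offset
    # deleted bases inherit the image of the previous retained base
    miss <- img == 0L
    if (any(miss)) {
      img[miss] <- NA_integer_
      filled <- cummax_na(img, init = offset)
      img <- filled
    }
    img
  }
  img1 <- img_from_map(part1$map, 1L, don, ext5)
  img2 <- img_from_map(part2$map, acc, L, off2)

  new_seq <- paste0(model$ext5_seq, part1$seq, ins, part2$seq)
  # per-base inverse map over the derived genome
  pad_n <- ext5
  ins_n <- nchar(ins)
  new2ref <- c(rep(NA_integer_, pad_n), part1$anchor,
               rep(don, ins_n), part2$anchor)
  from_insertion <- c(rep(TRUE, pad_n), is.na(part1$map),
                      rep(TRUE, ins_n), is.na(part2$map))
  region <- c(rep("upstream", pad_n),
              ifelse(part1$anchor < acc, "upstream", "primary"),
              rep("insert", ins_n),
              ifelse(part2$anchor > don, "downstream", "duplication"))
  maps <- list(seq = new_seq, img1 = img1, img2 = img2,
               len1 = len1, off2 = off2,
               new2ref = new2ref, region = region,
               from_insertion = from_insertion,
               part1 = part1, part2 = part2)
  # region boundaries in derived coordinates
  maps$primary_range <- range_of(region, "primary")
  maps$duplication_range <- range_of(region, "duplication")
  maps$insert_range <- range_of(region, "insert")
  model$cache$maps <- maps
  maps
}

# forward-fill NA with last non-NA (init before first value)
cummax_na <- function(x, init) {
  out <- x
  last <- init
  for (i in seq_along(out)) {
    if (is.na(out[i])) out[i] <- last else last <- out[i]
  }
  out
}

range_of <- function(region, lab) {
  w <- which(region == lab)
  if (length(w) == 0) return(c(NA_integer_, NA_integer_))
  c(min(w), max(w))
}

#' Reconstruct the derived (duplicated) genome
#'
#' Concatenates the optional terminal pad, the edited reference up to the
#' donor base, the junction insert, and the edited reference from the
#' acceptor base to the end, so the repeat interval appears twice.
#' Annotations not crossing a junction boundary are carried over (repeat
#' annotations get a second, `"_dup"`-suffixed image); annotations crossing
#' the acceptor or donor are dropped (re-derive them with [find_orfs()]).
#'
#' @param model a [dup_model()].
#' @return a [genome()] for the derived sequence.
#' @export
reconstruct <- function(model) {
  stopifnot(inherits(model, "dup_model"))
  maps <- model_maps(model)
  ann <- model$reference$annotations
  out_ann <- NULL
  if (nrow(ann)) {
    acc <- model$acceptor; don <- model$donor
    crosses <- (ann$start < acc & ann$end >= acc) | (ann$start <= don & ann$end > don)
    keep <- ann[!crosses, , drop = FALSE]
    if (nrow(keep)) {
      prim <- keep
      prim$start <- lift_ref_to_new(model, keep$start, copy = "primary")
      prim$end <- lift_ref_to_new(model, keep$end, copy = "primary")
      in_rep <- keep$start >= acc & keep$end <= don
      dup <- keep[in_rep, , drop = FALSE]
      if (nrow(dup)) {
        dup$gene <- paste0(dup$gene, "_dup")
        dup$start <- lift_ref_to_new(model, keep$start[in_rep], copy = "duplication")
        dup$end <- lift_ref_to_new(model, keep$end[in_rep], copy = "duplication")
      }
      out_ann <- dplyr::arrange(dplyr::bind_rows(prim, dup), .data$start)
    }
  }
  genome(maps$seq, name = paste0(model$reference$name, "_dup"),
         annotations = out_ann)
}

#' Region map of the derived genome
#'
#' @param model a [dup_model()].
#' @return tibble with one row per region (`upstream`, `primary`, `insert`,
#'   `duplication`, `downstream`) giving its derived-coordinate range.
#' @export
region_map <- function(model) {
  maps <- model_maps(model)
  r <- rle(maps$region)
  ends <- cumsum(r$lengths)
  tibble::tibble(region = r$values,
                 start = c(1L, head(ends, -1) + 1L),
                 end = as.integer(ends))
}

#' Lift reference coordinates to the derived genome
#'
#' Maps 1-based reference positions to their derived-genome coordinate.
#' Positions inside the repeat `[acceptor, donor]` have two images; `copy`
#' selects which one. Positions outside the repeat have a single image and
#' `copy` is ignored. Bases deleted in the derived genome map to the image
#' of the last retained base before them.
#'
#' @param model a [dup_model()].
#' @param pos integer vector of reference positions.
#' @param copy "primary" or "duplication" (recycled).
#' @return integer vector of derived coordinates.
#' @export
lift_ref_to_new <- function(model, pos, copy = "primary") {
  maps <- model_maps(model)
  pos <- as.integer(pos)
  L <- genome_length(model$reference)
  if (any(pos < 1 | pos > L)) stop("coordinate error: position outside reference")
  copy <- rep_len(match.arg(copy, c("primary", "duplication"), several.ok = TRUE),
                  length(pos))
  out <- integer(length(pos))
  first <- pos < model$acceptor | (pos <= model$donor & copy == "primary")
  out[first] <- maps$img1[pos[first]]
  out[!first] <- maps$img2[pos[!first] - model$acceptor + 1L]
  out
}

#' Lift derived-genome coordinates back to the reference
#'
#' Inverse of [lift_ref_to_new()]. Bases that do not exist in the reference
#' (terminal pad, junction insert, edit-inserted bases) report the anchoring
#' reference position (the junction insert anchors at the donor) and are
#' flagged `from_insertion`.
#'
#' @param model a [dup_model()].
#' @param pos integer vector of derived-genome positions.
#' @return tibble with `pos_new`, `pos_ref`, `region` (one of upstream,
#'   primary, insert, duplication, downstream) and `from_insertion`.
#' @export
lift_new_to_ref <- function(model, pos) {
  maps <- model_maps(model)
  pos <- as.integer(pos)
  if (any(pos < 1 | pos > nchar(maps$seq)))
    stop("coordinate error: position outside derived genome")
  tibble::tibble(pos_new = pos,
                 pos_ref = maps$new2ref[pos],
                 region = maps$region[pos],
                 from_insertion = maps$from_insertion[pos])
}

#' Extract the primary and duplication copy sequences
#'
#' @param model a [dup_model()].
#' @return named list with elements `primary` and `duplication` (character
#'   sequences of the two repeat copies after their per-copy edits).
#' @export
copy_sequences <- function(model) {
  maps <- model_maps(model)
  pr <- maps$primary_range
  dr <- maps$duplication_range
  list(primary = substring(maps$seq, pr[1], pr[2]),
       duplication = substring(maps$seq, dr[1], dr[2]))
}

#' Percent identity of the two repeat copies
#'
#' Globally aligns the primary and duplication copy sequences and reports
#' matches over alignment columns as a percentage.
#'
#' @param model a [dup_model()].
#' @return numeric percent identity (not rounded).
#' @export
copy_identity <- function(model) {
  cs <- copy_sequences(model)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(cs$primary), Biostrings::DNAString(cs$duplication),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(2, -3),
    gapOpening = 5, gapExtension = 2)
  cols <- nchar(as.character(Biostrings::alignedPattern(pa)))
  100 * Biostrings::nmatch(pa) / cols
}

# ---- broom-style methods ----------------------------------------------------

render_range <- function(a, b) {
  ifelse(a == b, as.character(a), paste0(a, "-", b))
}

#' Tidy a duplication model: the edit table in all three coordinate systems
#'
#' One row per edit with the reference rendering (`p`, `p^p+1` for
#' insertions, `a-b` for deletions) and the corresponding primary-copy and
#' duplication-copy coordinates and alleles in the derived genome, the
#' layout used for reporting paralog variants between near-identical
#' copies.
#'
#' @param x a [dup_model()].
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.dup_model <- function(x, ...) {
  ed <- x$edits
  if (nrow(ed) == 0) {
    return(tibble::tibble(ref_pos = character(), ref_allele = character(),
                          primary_pos = character(), primary_allele = character(),
                          duplication_pos = character(), duplication_allele = character(),
                          copy = character()))
  }
  rows <- purrr::pmap(ed, function(ref_pos, kind, ref_allele, alt_allele, copy) {
    p <- ref_pos
    if (kind == "substitution") {
      m <- nchar(ref_allele)
      ref_r <- render_range(p, p + m - 1L)
      if (copy == "unique") {
        img <- lift_ref_to_new(x, p)
        return(tibble::tibble(ref_pos = ref_r, ref_allele = ref_allele,
                              primary_pos = render_range(img, img + m - 1L),
                              primary_allele = alt_allele,
                              duplication_pos = NA_character_,
                              duplication_allele = NA_character_, copy = copy))
      }
      pi <- lift_ref_to_new(x, p, "primary")
      di <- lift_ref_to_new(x, p, "duplication")
      tibble::tibble(ref_pos = ref_r, ref_allele = ref_allele,
                     primary_pos = render_range(pi, pi + m - 1L),
                     primary_allele = if (copy == "primary") alt_allele else ref_allele,
                     duplication_pos = render_range(di, di + m - 1L),
                     duplication_allele = if (copy == "duplication") alt_allele else ref_allele,
                     copy = copy)
    } else if (kind == "insertion") {
      m <- nchar(alt_allele)
      ref_r <- paste0(p, "^", p + 1L)
      anch_p <- lift_ref_to_new(x, p, "primary")
      anch_d <- lift_ref_to_new(x, p, "duplication")
      if (copy == "primary") {
        tibble::tibble(ref_pos = ref_r, ref_allele = "-",
                       primary_pos = render_range(anch_p + 1L, anch_p + m),
                       primary_allele = alt_allele,
                       duplication_pos = paste0(anch_d, "^", anch_d + 1L),
                       duplication_allele = "-", copy = copy)
      } else if (copy == "duplication") {
        tibble::tibble(ref_pos = ref_r, ref_allele = "-",
                       primary_pos = paste0(anch_p, "^", anch_p + 1L),
                       primary_allele = "-",
                       duplication_pos = render_range(anch_d + 1L, anch_d + m),
                       duplication_allele = alt_allele, copy = copy)
      } else {
        img <- lift_ref_to_new(x, p)
        tibble::tibble(ref_pos = ref_r, ref_allele = "-",
                       primary_pos = render_range(img + 1L, img + m),
                       primary_allele = alt_allele,
                       duplication_pos = NA_character_,
                       duplication_allele = NA_character_, copy = copy)
      }
    } else {  # deletion
      m <- nchar(ref_allele)
      ref_r <- render_range(p, p + m - 1L)
      if (copy == "unique") {
        img <- lift_ref_to_new(x, max(1L, p - 1L))
        return(tibble::tibble(ref_pos = ref_r, ref_allele = ref_allele,
                              primary_pos = paste0(img, "^", img + 1L),
                              primary_allele = strrep("-", m),
                              duplication_pos = NA_character_,
                              duplication_allele = NA_character_, copy = copy))
      }
      # anchor = image of the base before the deleted run in the deleted copy
      pi_a <- lift_ref_to_new(x, p - 1L, "primary")
      di_a <- lift_ref_to_new(x, p - 1L, "duplication")
      pi <- lift_ref_to_new(x, p, "primary")
      di <- lift_ref_to_new(x, p, "duplication")
      if (copy == "primary") {
        tibble::tibble(ref_pos = ref_r, ref_allele = ref_allele,
                       primary_pos = paste0(pi_a, "^", pi_a + 1L),
                       primary_allele = strrep("-", m),
                       duplication_pos = render_range(di, di + m - 1L),
                       duplication_allele = ref_allele, copy = copy)
      } else {
        tibble::tibble(ref_pos = ref_r, ref_allele = ref_allele,
                       primary_pos = render_range(pi, pi + m - 1L),
                       primary_allele = ref_allele,
                       duplication_pos = paste0(di_a, "^", di_a + 1L),
                       duplication_allele = strrep("-", m), copy = copy)
      }
    }
  })
  dplyr::bind_rows(rows)
}

#' One-row summary of a duplication model
#'
#' @param x a [dup_model()].
#' @param ... unused.
#' @return tibble with reference/derived lengths, junction coordinates,
#'   repeat copy lengths and copy identity.
#' @export
glance.dup_model <- function(x, ...) {
  cs <- copy_sequences(x)
  maps <- model_maps(x)
  tibble::tibble(reference_length = genome_length(x$reference),
                 derived_length = nchar(maps$seq),
                 donor = x$donor, acceptor = x$acceptor,
                 insert = x$insert,
                 terminal_ext5 = x$terminal_ext5,
                 segment_length = x$donor - x$acceptor + 1L,
                 primary_length = nchar(cs$primary),
                 duplication_length = nchar(cs$duplication),
                 primary_start = maps$primary_range[1],
                 primary_end = maps$primary_range[2],
                 duplication_start = maps$duplication_range[1],
                 duplication_end = maps$duplication_range[2],
                 n_edits = nrow(x$edits),
                 copy_identity_pct = copy_identity(x))
}
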