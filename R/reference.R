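#' Circular reference genome
#'
#' Container for a (typically mitochondrial) reference sequence with circular
#' coordinate arithmetic: positions wrap modulo the genome length and slices
#' crossing the origin are returned as contiguous strings.
#'
#' @param sequence Character scalar, DNA over the alphabet `A C G T N`.
#'   Lower case is accepted and normalised to upper case.
#' @param name Sequence name (FASTA header word).
#' @param circular Logical; mitochondrial mode is always circular.
#' @return An object of class `CircularReference` with fields `name`, `seq`,
#'   `length`, `circular`.
#' @examples
#' ref <- circular_reference(paste(rep("ACGT", 300), collapse = ""))
#' circ_slice(ref, 1199, 4) # wraps across the origin
#' @export
circular_reference <- function(sequence, name = "ref", circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence contains symbols outside the A/C/G/T/N alphabet")
  }
  if (nchar(sequence) < 1000L) {
    stop("reference sequence must be at least 1000 bp")
  }
  structure(
    list(name = name, seq = sequence, length = nchar(sequence),
         circular = isTRUE(circular)),
    class = "CircularReference"
  )
}

#' @export
print.CircularReference <- function(x, ...) {
  cat(sprintf("<CircularReference> %s: %d bp%s\n", x$name, x$length,
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

#' Extract a slice from a circular reference
#'
#' @param ref A [circular_reference()].
#' @param start 1-based start position (taken modulo the genome length).
#' @param len Slice length; may wrap across the origin.
#' @return Character scalar of length `len`.
#' @export
circ_slice <- function(ref, start, len) {
  stopifnot(inherits(ref, "CircularReference"), len >= 0)
  if (len == 0) return("")
  L <- ref$length
  if (len > L) stop("slice longer than the genome")
  s <- ((start - 1) %% L) + 1
  if (s + len - 1 <= L) {
    substr(ref$seq, s, s + len - 1)
  } else {
    paste0(substr(ref$seq, s, L), substr(ref$seq, 1, s + len - 1 - L))
  }
}

#' Deletion event on the linearised circle
#'
#' Internally deletions are 0-based half-open intervals `[start, end)`;
#' human-readable reports use the 1-based inclusive first and last deleted
#' base (`report_first = start + 1`, `report_last = end`).
#'
#' @param start,end 0-based half-open deleted interval. `end` may exceed the
#'   genome length to denote an origin-spanning deletion.
#' @param canonical Logical, whether this is the left-aligned representative
#'   of its breakpoint equivalence class.
#' @return An object of class `DeletionEvent`.
#' @export
deletion_event <- function(start, end, canonical = FALSE) {
  stopifnot(is.numeric(start), is.numeric(end), length(start) == 1L,
            length(end) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (end - start < 1L) stop("deletion length must be at least 1")
  if (start < 0L) stop("deletion start must be non-negative")
  structure(
    list(start = start, end = end, length = end - start,
         canonical = isTRUE(canonical),
         report_first = start + 1L, report_last = end),
    class = "DeletionEvent"
  )
}

#' @export
print.DeletionEvent <- function(x, ...) {
  cat(sprintf("<DeletionEvent> %d-%d (%d bp%s)\n", x$report_first,
              x$report_last, x$length,
              if (x$canonical) ", canonical" else ""))
  invisible(x)
}

#' @export
format.DeletionEvent <- function(x, ...) {
  sprintf("%d-%d", x$report_first, x$report_last)
}

event_key <- function(ev) paste0(ev$start, ":", ev$end)

check_event_in_genome <- function(ref, ev) {
  if (ev$start >= ref$length) stop("deletion start outside the genome")
  if (ev$length >= ref$length) stop("deletion removes the whole genome")
}

#' Direct-repeat pair annotation
#'
#' Describes two identical, same-orientation copies of a motif (for human
#' mtDNA the 9-bp `CCCCCTCTA` pair in the COII/tRNA-Lys intergenic region).
#'
#' @param motif Repeat motif string.
#' @param left_start,right_start 1-based starts of the two copies.
#' @param region_start,region_end 1-based inclusive bounds of the intergenic
#'   region of interest containing both copies.
#' @param ref Optional [circular_reference()]; when given, the motif is
#'   verified at both positions.
#' @return An object of class `RepeatPair`.
#' @export
repeat_pair <- function(motif, left_start, right_start,
                        region_start, region_end, ref = NULL) {
  motif <- toupper(motif)
  stopifnot(nchar(motif) >= 1, left_start < right_start)
  if (right_start - (left_start + nchar(motif)) >= 100) {
    stop("repeat copies must be adjacent or separated by fewer than 100 bp")
  }
  if (left_start < region_start || right_start + nchar(motif) - 1 > region_end) {
    stop("both repeat copies must lie inside [region_start, region_end]")
  }
  if (!is.null(ref)) {
    for (s in c(left_start, right_start)) {
      if (circ_slice(ref, s, nchar(motif)) != motif) {
        stop(sprintf("motif not found at position %d of the reference", s))
      }
    }
  }
  structure(
    list(motif = motif, motif_len = nchar(motif),
         left_start = as.integer(left_start),
         right_start = as.integer(right_start),
         right_end = as.integer(right_start + nchar(motif) - 1L),
         region_start = as.integer(region_start),
         region_end = as.integer(region_end)),
    class = "RepeatPair"
  )
}

#' @export
print.RepeatPair <- function(x, ...) {
  cat(sprintf("<RepeatPair> %s at %d and %d (region %d-%d)\n", x$motif,
              x$left_start, x$right_start, x$region_start, x$region_end))
  invisible(x)
}

#' Find direct-repeat pairs in a region
#'
#' Enumerates all pairs of identical non-overlapping substrings of length at
#' least `min_len` inside a region, longest first. Exact string identity only:
#' direct-repeat deletion loci such as the mtDNA 9-bp repeat are exact copies.
#'
#' @param ref A [circular_reference()].
#' @param region Length-2 numeric, 1-based inclusive bounds within the genome.
#' @param min_len Minimum repeat length (at least 4).
#' @return A data frame with columns `motif`, `left_start`, `right_start`,
#'   `length` (genome coordinates, 1-based), sorted by decreasing length then
#'   position; zero rows if the region holds no repeat.
#' @export
find_direct_repeats <- function(ref, region, min_len = 9L) {
  stopifnot(inherits(ref, "CircularReference"), length(region) == 2L)
  if (min_len < 4) stop("min_len must be at least 4")
  if (region[1] < 1 || region[2] > ref$length || region[1] > region[2]) {
    stop("region outside the genome")
  }
  rs <- as.integer(region[1]); re <- as.integer(region[2])
  s <- substr(ref$seq, rs, re)
  n <- nchar(s)
  out <- list()
  for (len in seq(min(n %/% 2L, n - 1L), min_len)) {
    if (len < min_len) break
    starts <- seq_len(n - len + 1L)
    subs <- substring(s, starts, starts + len - 1L)
    for (grp in split(starts, subs)) {
      if (length(grp) < 2L) next
      for (i in seq_len(length(grp) - 1L)) {
        for (j in seq(i + 1L, length(grp))) {
          if (grp[j] - grp[i] >= len) { # non-overlapping copies only
            out[[length(out) + 1L]] <- data.frame(
              motif = subs[grp[i]],
              left_start = rs + grp[i] - 1L,
              right_start = rs + grp[j] - 1L,
              length = len
            )
          }
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(motif = character(), left_start = integer(),
                      right_start = integer(), length = integer()))
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$length, res$left_start, res$right_start), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

base_at <- function(ref, pos0) {
  # 0-based circular single-base access
  i <- (pos0 %% ref$length) + 1L
  substr(ref$seq, i, i)
}

#' Equivalence class of a deletion's placements
#'
#' A deletion inside a repeated tract has no unique breakpoint: every
#' placement of the same length whose application yields the identical
#' sequence is equivalent. The class is the maximal run of single-base
#' shifts satisfying `base(start - 1) == base(end - 1)` (left) and
#' `base(start) == base(end)` (right), which is exactly string equality of
#' the deleted genomes.
#'
#' @param ref A [circular_reference()].
#' @param ev A [deletion_event()].
#' @return List of `DeletionEvent`s sorted by start; always contains `ev`.
#'   The first (leftmost) element is flagged canonical.
#' @export
equivalent_placements <- function(ref, ev) {
  stopifnot(inherits(ref, "CircularReference"), inherits(ev, "DeletionEvent"))
  check_event_in_genome(ref, ev)
  s <- ev$start; e <- ev$end
  # shift left while the base entering the deletion equals the base leaving it
  s_min <- s; e_min <- e
  while (s_min > 0L && base_at(ref, s_min - 1L) == base_at(ref, e_min - 1L)) {
    s_min <- s_min - 1L; e_min <- e_min - 1L
  }
  # shift right symmetrically (stay on the linearised circle)
  s_max <- s; e_max <- e
  while (e_max < ref$length && base_at(ref, s_max) == base_at(ref, e_max)) {
    s_max <- s_max + 1L; e_max <- e_max + 1L
  }
  starts <- seq(s_min, s_max)
  lapply(starts, function(si) {
    deletion_event(si, si + ev$length, canonical = (si == s_min))
  })
}

#' Left-align a deletion to its canonical placement
#'
#' Returns the member of [equivalent_placements()] with the smallest start,
#' flagged canonical. Idempotent.
#'
#' @inheritParams equivalent_placements
#' @return A canonical `DeletionEvent`.
#' @export
left_align_deletion <- function(ref, ev) {
  equivalent_placements(ref, ev)[[1L]]
}

#' Apply a deletion to a circular reference
#'
#' Excises the deleted interval and returns the shorter circular genome (the
#' deletion haplotype used by the read simulator).
#'
#' @inheritParams equivalent_placements
#' @return A `CircularReference` of length `ref$length - ev$length`.
#' @export
apply_deletion <- function(ref, ev) {
  stopifnot(inherits(ref, "CircularReference"), inherits(ev, "DeletionEvent"))
  check_event_in_genome(ref, ev)
  L <- ref$length
  if (ev$end <= L) {
    newseq <- paste0(substr(ref$seq, 1L, ev$start),
                     substr(ref$seq, ev$end + 1L, L))
  } else {
    # origin-spanning deletion: remove [start, L) and [0, end - L)
    wrap <- ev$end - L
    newseq <- substr(ref$seq, wrap + 1L, ev$start)
  }
  circular_reference(newseq, name = paste0(ref$name, "_del",
                                           format(ev)),
                     circular = ref$circular)
}
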