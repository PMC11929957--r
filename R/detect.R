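#' Split-read mapping score of one evidence read
#'
#' The score of a junction-supporting read is the length of its shortest
#' anchor penalised by mismatches: `min(left, right) - 2 * mismatches`,
#' floored at 0. Thresholds then read naturally as "shortest clean anchor of
#' at least that many bases": 25 for deep present-day libraries, 20 for
#' ancient libraries, 15 for the ancient sensitivity re-check.
#'
#' @param left_anchor,right_anchor Matched bases up/downstream of the
#'   junction (vectors, each >= 1).
#' @param mismatches Mismatch count across both anchors.
#' @return Integer vector of scores.
#' @examples
#' score_split_evidence(45, 55, 0) # 45
#' score_split_evidence(20, 20, 0) # passes the ancient threshold 20 only
#' @export
score_split_evidence <- function(left_anchor, right_anchor, mismatches = 0L) {
  if (any(left_anchor < 1L) || any(right_anchor < 1L)) {
    stop("anchors must be at least 1 bp")
  }
  as.integer(pmax(0L, pmin(left_anchor, right_anchor) - 2L * mismatches))
}

empty_evidence <- function() {
  data.frame(read_id = character(), event_start = integer(),
             event_end = integer(), event_len = integer(),
             left_anchor = integer(), right_anchor = integer(),
             mismatches = integer(), score = integer(),
             read_len = integer())
}

#' Turn window-space mapping results into canonical split-read evidence
#'
#' Each mapped read carrying a deletion gap becomes one evidence row. The raw
#' gap is left-aligned into its breakpoint equivalence class and anchors are
#' re-expressed relative to the canonical junction; reads that do not reach
#' the canonical junction with at least one base on each side carry no
#' breakpoint information and are dropped.
#'
#' @param mapping Data frame from [map_reads()].
#' @param ref A [circular_reference()].
#' @param window_start 1-based genome position of the first window base.
#' @param read_ids Optional read identifiers (default `read<i>`).
#' @return Evidence data frame: `read_id`, canonical `event_start`/`event_end`
#'   (0-based half-open genome interval), `event_len`, `left_anchor`,
#'   `right_anchor`, `mismatches`, `score`, `read_len`.
#' @export
evidence_from_mapping <- function(mapping, ref, window_start,
                                  read_ids = NULL) {
  stopifnot(inherits(ref, "CircularReference"))
  if (is.null(read_ids)) read_ids <- paste0("read", seq_len(nrow(mapping)))
  keep <- which(mapping$aligned & mapping$gap_len >= 1L)
  if (!length(keep)) return(empty_evidence())
  m <- mapping[keep, , drop = FALSE]
  ids <- read_ids[keep]
  # raw 0-based genome interval of each gap
  raw_start <- (window_start - 1L) + m$offset + m$gap_start
  raw_end <- raw_start + m$gap_len
  canon <- canonicalize_events(ref, raw_start, raw_end)
  read_start0 <- (window_start - 1L) + m$offset
  left <- canon$start - read_start0
  right <- m$read_len - left
  ok <- left >= 1L & right >= 1L
  if (!any(ok)) return(empty_evidence())
  data.frame(
    read_id = ids[ok],
    event_start = canon$start[ok], event_end = canon$end[ok],
    event_len = (canon$end - canon$start)[ok],
    left_anchor = as.integer(left[ok]), right_anchor = as.integer(right[ok]),
    mismatches = m$mismatches[ok],
    score = score_split_evidence(left[ok], right[ok], m$mismatches[ok]),
    read_len = m$read_len[ok]
  )
}

# vectorised left-alignment with memoisation over unique raw intervals
canonicalize_events <- function(ref, raw_start, raw_end) {
  key <- paste0(raw_start, ":", raw_end)
  uniq <- !duplicated(key)
  canon_map <- lapply(which(uniq), function(i) {
    ev <- left_align_deletion(ref, deletion_event(raw_start[i], raw_end[i]))
    c(ev$start, ev$end)
  })
  names(canon_map) <- key[uniq]
  mat <- do.call(rbind, canon_map[key])
  list(start = as.integer(mat[, 1]), end = as.integer(mat[, 2]))
}

#' Ingest pre-mapped alignments as split-read evidence
#'
#' Extracts deletion operations (CIGAR `D` or `N`) overlapping a region from
#' SAM/BAM alignments, canonicalises them and computes anchors as the aligned
#' read lengths flanking the gap. Records without a CIGAR are skipped with a
#' warning; unmapped records are ignored.
#'
#' @param alignments A [GenomicAlignments::GAlignments] object (see
#'   [read_sam()]), ideally carrying the `NM` tag for mismatch counts.
#' @param ref A [circular_reference()].
#' @param region Length-2 numeric, 1-based inclusive region of interest.
#' @return Evidence data frame as in [evidence_from_mapping()].
#' @export
ingest_alignments <- function(alignments, ref, region) {
  stopifnot(inherits(ref, "CircularReference"), length(region) == 2L)
  if (region[1] < 1 || region[2] > ref$length) stop("region outside genome")
  cig <- GenomicAlignments::cigar(alignments)
  bad <- is.na(cig) | cig == "*"
  if (any(bad)) {
    warning(sprintf("%d record(s) without a CIGAR skipped", sum(bad)))
    alignments <- alignments[!bad]
    cig <- cig[!bad]
  }
  if (!length(alignments)) return(empty_evidence())
  pos <- GenomicAlignments::start(alignments)
  qname <- S4Vectors::mcols(alignments)$qname
  if (is.null(qname)) qname <- paste0("rec", seq_along(alignments))
  nm <- S4Vectors::mcols(alignments)$NM
  ops <- GenomicAlignments::explodeCigarOps(cig)
  lens <- GenomicAlignments::explodeCigarOpLengths(cig)
  rows <- vector("list", length(cig))
  for (i in seq_along(cig)) {
    op <- ops[[i]]; ln <- lens[[i]]
    gaps <- which(op %in% c("D", "N"))
    if (!length(gaps)) next
    # reference-consuming ops before each element
    ref_consume <- op %in% c("M", "D", "N", "=", "X")
    ref_before <- cumsum(c(0L, ln * ref_consume))[seq_along(op)]
    for (g in gaps) {
      gstart <- pos[i] + ref_before[g] - 1L      # 0-based genome gap start
      gend <- gstart + ln[g]
      if (gend <= region[1] - 1L || gstart >= region[2]) next
      aligned_ops <- op %in% c("M", "=", "X")
      head_idx <- seq_len(g - 1L)
      tail_idx <- if (g < length(op)) seq(g + 1L, length(op)) else integer(0)
      la <- sum(ln[head_idx][aligned_ops[head_idx]])
      ra <- sum(ln[tail_idx][aligned_ops[tail_idx]])
      if (la < 1L || ra < 1L) next
      mm <- if (!is.null(nm) && !is.na(nm[i])) {
        max(0L, nm[i] - sum(ln[which(op %in% c("D", "N", "I"))]))
      } else 0L
      rows[[i]] <- data.frame(read_id = qname[i], raw_start = gstart,
                              raw_end = gend, left_anchor = la,
                              right_anchor = ra, mismatches = mm,
                              read_len = la + ra)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_evidence())
  d <- do.call(rbind, rows)
  canon <- canonicalize_events(ref, d$raw_start, d$raw_end)
  # re-express anchors relative to the canonical junction
  shift <- d$raw_start - canon$start
  left <- d$left_anchor - shift
  right <- d$right_anchor + shift
  ok <- left >= 1L & right >= 1L
  d <- d[ok, , drop = FALSE]
  if (!nrow(d)) return(empty_evidence())
  data.frame(
    read_id = d$read_id,
    event_start = canon$start[ok], event_end = canon$end[ok],
    event_len = (canon$end - canon$start)[ok],
    left_anchor = as.integer(left[ok]), right_anchor = as.integer(right[ok]),
    mismatches = d$mismatches,
    score = score_split_evidence(left[ok], right[ok], d$mismatches),
    read_len = d$read_len
  )
}

#' Call deletion events from split-read evidence
#'
#' Groups canonicalised evidence by event, discards reads below the
#' split-read score threshold, de-duplicates read identifiers within an
#' event (a read pair never supports the same event twice) and emits a call
#' for every event with at least `min_reads` surviving supporters.
#'
#' @param evidence Evidence data frame ([evidence_from_mapping()] or
#'   [ingest_alignments()]).
#' @param min_reads Minimum surviving supporting reads (inclusive).
#' @param min_score Split-read score threshold (inclusive): 25 present-day,
#'   20 ancient, 15 ancient sensitivity re-check.
#' @param sample_id Optional sample label attached to the calls.
#' @return Data frame of calls sorted by support: `event_start`, `event_end`,
#'   `report_first`, `report_last`, `event_len`, `n_support` (score-passing,
#'   deduplicated), `n_total` (all evidence reads), `mean_score`, `sample_id`.
#' @examples
#' ev <- data.frame(read_id = paste0("r", 1:5), event_start = 100,
#'                  event_end = 109, event_len = 9, left_anchor = 40,
#'                  right_anchor = 60, mismatches = 0, score = 40,
#'                  read_len = 100)
#' call_deletions(ev) # one call with n_support 5
#' @export
call_deletions <- function(evidence, min_reads = 5L, min_score = 25L,
                           sample_id = NA_character_) {
  empty <- data.frame(event_start = integer(), event_end = integer(),
                      report_first = integer(), report_last = integer(),
                      event_len = integer(), n_support = integer(),
                      n_total = integer(), mean_score = numeric(),
                      sample_id = character())
  if (!nrow(evidence)) return(empty)
  key <- paste0(evidence$event_start, ":", evidence$event_end)
  rows <- lapply(split(seq_len(nrow(evidence)), key), function(idx) {
    ev <- evidence[idx, , drop = FALSE]
    ev <- ev[!duplicated(ev$read_id), , drop = FALSE]
    pass <- ev[ev$score >= min_score, , drop = FALSE]
    if (nrow(pass) < min_reads) return(NULL)
    data.frame(event_start = ev$event_start[1], event_end = ev$event_end[1],
               report_first = ev$event_start[1] + 1L,
               report_last = ev$event_end[1],
               event_len = ev$event_len[1],
               n_support = nrow(pass), n_total = nrow(ev),
               mean_score = mean(pass$score), sample_id = sample_id)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_support, out$event_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
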