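#' Exact single-gap split alignment of a read against a reference window
#'
#' Exhaustively scores every placement of `read` on `ref_window` with at most
#' one internal deletion gap (match +1, mismatch -2; gap length 0 means
#' ungapped), and returns the best one. Ties are broken deterministically:
#' smallest offset, then smallest gap start (ungapped counts as gap start 0),
#' then smallest gap length. This is the reference aligner; [map_reads()] is
#' the seeded fast path that defers to it when seeds fail.
#'
#' @param ref_window Reference window string (plain DNA, `A C G T N`).
#' @param read Read sequence, 20-500 bp.
#' @param max_del Largest deletion gap considered (bp).
#' @param min_score Minimum accepted score; below it the read is reported as
#'   unaligned. Defaults to 60% of the read length (a random read's best
#'   chance score is far lower; a 1% error read scores ~97%).
#' @return A list with `offset` (0-based on the window), `gap_start` (read
#'   bases before the gap; 0 when ungapped), `gap_len`, `mismatches`, `score`;
#'   or `NULL` when no placement reaches `min_score`.
#' @examples
#' win <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
#' align_read_split(win, substr(win, 41, 100), max_del = 15)
#' @export
align_read_split <- function(ref_window, read, max_del = 20L,
                             min_score = ceiling(0.6 * nchar(read))) {
  stopifnot(is.character(ref_window), is.character(read),
            length(ref_window) == 1L, length(read) == 1L)
  ref_window <- toupper(ref_window); read <- toupper(read)
  if (grepl("[^ACGTN]", read)) stop("read contains non-ACGTN symbols")
  if (grepl("[^ACGTN]", ref_window)) stop("window contains non-ACGTN symbols")
  nr <- nchar(read)
  if (nr < 20L || nr > 500L) stop("read length must be in [20, 500]")
  if (nchar(ref_window) < nr + max_del) {
    stop("ref_window must be at least read length + max_del")
  }
  v <- cpp_split_align_exact(ref_window, read, as.integer(max_del),
                             as.integer(min_score))
  if (v[["aligned"]] == 0L) return(NULL)
  list(offset = v[["offset"]], gap_start = v[["gap_start"]],
       gap_len = v[["gap_len"]], mismatches = v[["mismatches"]],
       score = v[["score"]])
}

#' Map a batch of reads onto a reference window
#'
#' Seed-and-extend mapper restricted to a window around the locus of
#' interest: exact k-mer seeds propose candidate offsets, candidates are
#' evaluated ungapped and as single-deletion splits between candidate offset
#' pairs, and reads that the seeds cannot place fall back to the exhaustive
#' [align_read_split()] search. Reads whose best score stays below
#' `min_score_frac * read length` are reported unaligned.
#'
#' @param ref_window Reference window string.
#' @param reads Character vector of read sequences.
#' @param max_del Largest deletion gap considered (bp).
#' @param seed_k Seed k-mer length (<= 16).
#' @param seed_step Spacing between seed start positions along the read.
#' @param accept_ungapped_mm An ungapped candidate placement with at most
#'   this many mismatches is accepted without attempting a split. The
#'   default 0 means only perfect ungapped placements bypass the split
#'   search, so junction reads with short (but informative) overhangs are
#'   never swallowed by a near-perfect ungapped placement.
#' @param min_score_frac Minimum accepted score as a fraction of read length.
#' @return A data frame with one row per read: `aligned`, `offset` (0-based),
#'   `gap_start`, `gap_len`, `mismatches`, `score`, `read_len`.
#' @export
map_reads <- function(ref_window, reads, max_del = 20L, seed_k = 13L,
                      seed_step = 7L, accept_ungapped_mm = 0L,
                      min_score_frac = 0.6) {
  stopifnot(is.character(ref_window), length(ref_window) == 1L)
  if (!length(reads)) {
    return(data.frame(aligned = logical(), offset = integer(),
                      gap_start = integer(), gap_len = integer(),
                      mismatches = integer(), score = integer(),
                      read_len = integer()))
  }
  m <- cpp_map_reads(toupper(ref_window), toupper(reads),
                     as.integer(max_del), as.integer(seed_k),
                     as.integer(seed_step), as.integer(accept_ungapped_mm),
                     min_score_frac)
  data.frame(aligned = m[, "aligned"] == 1L, offset = m[, "offset"],
             gap_start = m[, "gap_start"], gap_len = m[, "gap_len"],
             mismatches = m[, "mismatches"], score = m[, "score"],
             read_len = nchar(reads))
}
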