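#' Per-position depth profile over a window
#'
#' Counts, for every reference position of a window, the reads whose aligned
#' segments cover it. Deletion gaps inside a read contribute no depth to the
#' gapped positions. Coverage is accumulated with [IRanges::coverage()].
#'
#' @param alignments Either a mapping data frame ([map_reads()]) together
#'   with `window_start`, or a [GenomicAlignments::GAlignments] object (then
#'   `window_start` still names the first profile position).
#' @param window_start 1-based genome position of the first profile entry.
#' @param window_len Profile length in positions.
#' @return An object of class `DepthProfile`: list with `depth` (integer
#'   vector of length `window_len`), `start` (genome position of entry 1) and
#'   `source`.
#' @export
compute_depth_profile <- function(alignments, window_start, window_len) {
  if (inherits(alignments, "GAlignments")) {
    cov <- GenomicAlignments::coverage(alignments)[[1]]
    depth <- integer(window_len)
    upto <- min(length(cov), window_start + window_len - 1L)
    if (upto >= window_start) {
      got <- as.integer(cov[window_start:upto])
      depth[seq_along(got)] <- got
    }
    return(structure(list(depth = depth, start = as.integer(window_start),
                          source = "alignments"), class = "DepthProfile"))
  }
  m <- alignments[alignments$aligned, , drop = FALSE]
  if (!nrow(m)) {
    return(structure(list(depth = integer(window_len),
                          start = as.integer(window_start),
                          source = "mapping"), class = "DepthProfile"))
  }
  segs <- alignment_segments(m, window_start)
  ir <- IRanges::IRanges(start = segs$start, end = segs$end)
  cov <- IRanges::coverage(ir)
  depth <- integer(window_len)
  upto <- min(length(cov), window_start + window_len - 1L)
  if (upto >= window_start) {
    got <- as.integer(cov[window_start:upto])
    depth[seq_along(got)] <- got
  }
  structure(list(depth = depth, start = as.integer(window_start),
                 source = "mapping"), class = "DepthProfile")
}

#' @export
print.DepthProfile <- function(x, ...) {
  cat(sprintf("<DepthProfile> %d positions from %d, mean depth %.1f\n",
              length(x$depth), x$start, mean(x$depth)))
  invisible(x)
}

# aligned segments of mapped reads in 1-based genome coordinates:
# one segment for ungapped reads, two for split reads
alignment_segments <- function(mapping, window_start) {
  m <- mapping
  rs <- window_start + m$offset                 # 1-based read start
  gapped <- m$gap_len >= 1L
  s1 <- rs
  e1 <- ifelse(gapped, rs + m$gap_start - 1L, rs + m$read_len - 1L)
  out <- data.frame(read = seq_len(nrow(m)), start = s1, end = e1)
  if (any(gapped)) {
    g <- m[gapped, , drop = FALSE]
    out <- rbind(out, data.frame(
      read = which(gapped),
      start = rs[gapped] + g$gap_start + g$gap_len,
      end = rs[gapped] + g$read_len + g$gap_len - 1L
    ))
  }
  out
}

#' Mean local depth at the windows flanking a direct-repeat pair
#'
#' The heteroplasmy benchmark depth: the mean per-position depth pooled over
#' the `flank` positions immediately upstream of the left repeat copy and
#' the `flank` positions immediately downstream of the right copy. The
#' inter-copy positions sit inside the deletion and are deliberately
#' excluded from the denominator.
#'
#' @param profile A [compute_depth_profile()] result.
#' @param pair A [repeat_pair()].
#' @param flank Flank width in nucleotides (default 50).
#' @return Positive mean depth, or 0 when the flanks carry no coverage (the
#'   no-coverage condition: heteroplasmy is undefined for such a sample).
#' @export
local_depth <- function(profile, pair, flank = 50L) {
  stopifnot(inherits(profile, "DepthProfile"), inherits(pair, "RepeatPair"),
            flank >= 1L)
  pos <- flank_positions(pair, flank)
  idx <- pos - profile$start + 1L
  if (any(idx < 1L | idx > length(profile$depth))) {
    stop("flanking windows fall outside the depth profile")
  }
  mean(profile$depth[idx])
}

flank_positions <- function(pair, flank = 50L) {
  c(seq(pair$left_start - flank, pair$left_start - 1L),
    seq(pair$right_end + 1L, pair$right_end + flank))
}

# Poisson-thinning coefficient of variation of the local-depth estimate:
# each read contributes its overlap length with the flank windows; treating
# read counts as Poisson gives Var(total) ~ sum(overlap^2).
local_depth_cv <- function(mapping, window_start, pair, flank = 50L) {
  m <- mapping[mapping$aligned, , drop = FALSE]
  if (!nrow(m)) return(0)
  segs <- alignment_segments(m, window_start)
  pos <- flank_positions(pair, flank)
  blocks <- list(range(pos[seq_len(flank)]), range(pos[flank + seq_len(flank)]))
  ov <- numeric(nrow(segs))
  for (b in blocks) {
    ov <- ov + pmax(0, pmin(segs$end, b[2]) - pmax(segs$start, b[1]) + 1)
  }
  per_read <- rowsum(ov, segs$read)             # both segments of a split read
  tot <- sum(per_read)
  if (tot <= 0) return(0)
  sqrt(sum(per_read^2)) / tot
}
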