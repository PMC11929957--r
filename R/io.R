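#' Read a single-record FASTA reference
#'
#' @param path FASTA file with exactly one record.
#' @param circular Treat the sequence as circular (default, mtDNA mode).
#' @return A [circular_reference()].
#' @export
read_fasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("FASTA format error: no records in ", path)
  if (length(set) != 1L) {
    stop("expected a single reference record, found ", length(set))
  }
  seq <- as.character(set[[1]])
  if (grepl("[a-z]", seq)) {
    message("mixed-case sequence normalised to upper case")
  }
  circular_reference(seq, name = strsplit(names(set)[1], "\\s+")[[1]][1],
                     circular = circular)
}

#' Write a reference to FASTA
#' @param ref A [circular_reference()].
#' @param path Output path.
#' @export
write_fasta <- function(ref, path) {
  x <- Biostrings::DNAStringSet(ref$seq)
  names(x) <- ref$name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read FASTQ reads
#'
#' @param path FASTQ file.
#' @return Data frame with `read_id` and `seq` (upper case).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  nl <- length(readLines(path, warn = FALSE))
  if (nl == 0L) stop("FASTQ format error: no records in ", path)
  if (nl %% 4L != 0L) {
    stop(sprintf("FASTQ format error: truncated record %d in %s",
                 nl %/% 4L + 1L, path))
  }
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) {
      stop("FASTQ format error in ", path, ": ", conditionMessage(e))
    })
  if (length(set) == 0L) stop("FASTQ format error: no records in ", path)
  data.frame(read_id = sub("\\s.*$", "", names(set)),
             seq = toupper(as.character(set)))
}

#' Write reads to FASTQ
#'
#' Quality strings are constant Q30 — the detection path does not consume
#' qualities; they are emitted for format validity.
#'
#' @param reads Data frame with `read_id` and `seq`.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  qual <- Biostrings::BStringSet(vapply(nchar(reads$seq), function(n) {
    strrep("?", n) # '?' = Phred+33 quality 30
  }, character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read SAM/BAM alignments
#'
#' SAM text input is converted with [Rsamtools::asBam()] and loaded with
#' [GenomicAlignments::readGAlignments()], keeping the query name and the
#' `NM` tag for mismatch-aware evidence scores.
#'
#' @param path `.sam` or `.bam` file.
#' @return A `GAlignments` object (possibly empty for a header-only file).
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(what = "qname", tag = "NM")
  GenomicAlignments::readGAlignments(bam, param = param)
}

#' Write window-space mapping results as SAM
#'
#' One alignment line per mapped read: split reads get a `M D M` CIGAR, the
#' `NM` tag counts mismatches plus deleted bases. Intended for export and
#' round-trip ingestion via [read_sam()] / [ingest_alignments()].
#'
#' @param mapping Data frame from [map_reads()].
#' @param reads Data frame with `read_id` and `seq` in mapping order.
#' @param ref The [circular_reference()] mapped against.
#' @param window_start 1-based genome position of the window's first base.
#' @param path Output path (`.sam`).
#' @export
write_sam <- function(mapping, reads, ref, window_start, path) {
  stopifnot(nrow(mapping) == nrow(reads))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", ref$name, ref$length)), con)
  m <- mapping
  for (i in seq_len(nrow(m))) {
    if (!m$aligned[i]) next
    cigar <- if (m$gap_len[i] >= 1L) {
      sprintf("%dM%dD%dM", m$gap_start[i], m$gap_len[i],
              m$read_len[i] - m$gap_start[i])
    } else sprintf("%dM", m$read_len[i])
    nm <- m$mismatches[i] + m$gap_len[i]
    writeLines(sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                       reads$read_id[i], ref$name,
                       window_start + m$offset[i], cigar,
                       reads$seq[i], nm), con)
  }
  invisible(path)
}

#' Write deletion calls as VCF
#'
#' Standard VCF deletion normalisation: `POS` is the 1-based anchor base
#' preceding the canonical left-aligned deletion, `REF` the anchor plus the
#' deleted bases, `ALT` the anchor. `INFO/SPAN` carries the 1-based
#' inclusive first-last deleted span for human-readable cross-reference.
#'
#' @param calls Detection calls ([call_deletions()]).
#' @param ref A [circular_reference()].
#' @param path Output path.
#' @export
write_vcf <- function(calls, ref, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.3",
    sprintf("##contig=<ID=%s,length=%d>", ref$name, ref$length),
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Score-passing supporting reads\">",
    "##INFO=<ID=MEANSCORE,Number=1,Type=Float,Description=\"Mean split-read score of supporting reads\">",
    "##INFO=<ID=SPAN,Number=1,Type=String,Description=\"1-based inclusive deleted span\">",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample identifier\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (i in seq_len(nrow(calls))) {
    anchor_pos <- calls$report_first[i] - 1L
    if (anchor_pos < 1L) anchor_pos <- ref$length # circular anchor fallback
    refal <- paste0(circ_slice(ref, anchor_pos, 1L),
                    circ_slice(ref, calls$report_first[i], calls$event_len[i]))
    alt <- substr(refal, 1L, 1L)
    info <- sprintf("SUPPORT=%d;MEANSCORE=%.2f;SPAN=%d-%d",
                    calls$n_support[i], calls$mean_score[i],
                    calls$report_first[i], calls$report_last[i])
    if (!is.na(calls$sample_id[i])) {
      info <- paste0(info, ";SAMPLE=", calls$sample_id[i])
    }
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                       ref$name, anchor_pos, refal, alt, info), con)
  }
  invisible(path)
}

#' Write / read a tab-separated table
#'
#' Round-trip-safe TSV used for every tabular report (per-sample calls,
#' cohort summary, pairwise tests).
#'
#' @param x Data frame.
#' @param path File path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Resolve the repeat-region configuration
#'
#' YAML with keys `region_start`, `region_end` and `motif` (a motif string,
#' or `auto` to locate the longest direct-repeat pair in the region with
#' [find_direct_repeats()]).
#'
#' @param path YAML file.
#' @param ref A [circular_reference()].
#' @return A [repeat_pair()].
#' @export
load_region_config <- function(path, ref) {
  cfg <- yaml::read_yaml(path)
  for (k in c("region_start", "region_end", "motif")) {
    if (is.null(cfg[[k]])) stop("region config misses key: ", k)
  }
  region <- c(cfg$region_start, cfg$region_end)
  if (identical(tolower(cfg$motif), "auto")) {
    hits <- find_direct_repeats(ref, region, min_len = 4L)
    if (!nrow(hits)) stop("no direct repeat found in the configured region")
    top <- hits[1, ]
    return(repeat_pair(top$motif, top$left_start, top$right_start,
                       region[1], region[2], ref = ref))
  }
  motif <- toupper(cfg$motif)
  s <- substr(ref$seq, region[1], region[2])
  hits <- gregexpr(motif, s, fixed = TRUE)[[1]]
  if (identical(as.integer(hits), -1L) || length(hits) < 2L) {
    stop("motif does not occur twice in the configured region")
  }
  repeat_pair(motif, region[1] + hits[1] - 1L, region[1] + hits[2] - 1L,
              region[1], region[2], ref = ref)
}
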