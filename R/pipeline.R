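#' Pipeline configuration
#'
#' Collects every effective threshold of the detection / quantification
#' chain. The mode sets the default split-read score threshold — 25 for
#' deep present-day libraries, 20 for ancient libraries, 15 for the ancient
#' sensitivity re-check — and every default can be overridden explicitly.
#'
#' @param mode `"present-day"`, `"ancient"` or `"ancient-sensitivity"`.
#' @param min_reads Minimum score-passing supporting reads for a call.
#' @param min_score Split-read score threshold; `NULL` = by mode.
#' @param high_het_threshold High-heteroplasmy reporting filter (fraction).
#' @param flank Local-depth flank width (nt).
#' @param alpha Significance level for cohort tests.
#' @param min_n_for_sem Minimum carriers for a reported SEM.
#' @param max_del Largest deletion gap the aligner considers (bp).
#' @param quant_margin Anchor margin (bases beyond the breakpoint ambiguity
#'   tract) required of quantification-grade junction reads. The default 8
#'   keeps only junction reads whose overhangs the mapper recognises
#'   essentially always, so the junction-fraction depth correction stays
#'   unbiased; the denominator is scaled accordingly.
#' @param cluster_tol Junction-clustering tolerance (bp): same-length
#'   evidence whose canonical breakpoint lies within this distance of the
#'   target's equivalence class is attributed to the target during
#'   quantification (sequencing errors at junction-critical bases shift a
#'   read's best placement by a base or two).
#' @param window_pad Mapping window: repeat region padded by this many bases.
#' @param conf Confidence level of heteroplasmy intervals.
#' @param targeted Quantify the configured repeat-pair deletion in every
#'   sample (re-genotyping of a known event) rather than only in samples
#'   where discovery filters fire.
#' @param seed Optional seed recorded in run logs.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(mode = c("present-day", "ancient",
                                     "ancient-sensitivity"),
                            min_reads = 5L, min_score = NULL,
                            high_het_threshold = 0.15, flank = 50L,
                            alpha = 0.05, min_n_for_sem = 4L, max_del = 20L,
                            quant_margin = 8L, cluster_tol = 3L,
                            window_pad = 500L,
                            conf = 0.95, targeted = TRUE, seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(min_score)) {
    min_score <- switch(mode, "present-day" = 25L, "ancient" = 20L,
                        "ancient-sensitivity" = 15L)
  }
  stopifnot(min_reads >= 1, min_score >= 0, high_het_threshold > 0,
            flank >= 1, alpha > 0, alpha < 1, max_del >= 1, quant_margin >= 1)
  structure(list(mode = mode, min_reads = as.integer(min_reads),
                 min_score = as.integer(min_score),
                 high_het_threshold = high_het_threshold,
                 flank = as.integer(flank), alpha = alpha,
                 min_n_for_sem = as.integer(min_n_for_sem),
                 max_del = as.integer(max_del),
                 quant_margin = as.integer(quant_margin),
                 cluster_tol = as.integer(cluster_tol),
                 window_pad = as.integer(window_pad), conf = conf,
                 targeted = isTRUE(targeted), seed = seed),
            class = "PipelineConfig")
}

#' @export
print.PipelineConfig <- function(x, ...) {
  cat("<PipelineConfig>\n")
  for (k in names(x)) {
    cat(sprintf("  %-18s %s\n", k,
                if (is.null(x[[k]])) "NULL" else format(x[[k]])))
  }
  invisible(x)
}

sample_mode <- function(config) {
  if (config$mode == "present-day") "present-day" else "ancient"
}

segments_from_galignments <- function(aln) {
  rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    GenomicAlignments::cigar(aln), pos = GenomicAlignments::start(aln),
    ops = c("M", "=", "X"))
  flat <- unlist(rl, use.names = FALSE)
  data.frame(read = rep(seq_along(aln), lengths(rl)),
             start = IRanges::start(flat), end = IRanges::end(flat))
}

#' Detect and quantify the repeat-pair deletion in one sample
#'
#' Runs the per-sample chain: map reads onto the locus window (or ingest
#' pre-mapped alignments), canonicalise junction evidence, call deletions
#' with the mode's discovery filters, and estimate the heteroplasmy of the
#' configured repeat-pair deletion against the local-depth benchmark.
#'
#' Two read counts are kept deliberately separate. Discovery uses the strict
#' score filter (`min(anchor) - 2*mismatches >= min_score`, at least
#' `min_reads` reads). Quantification counts every breakpoint-informative
#' junction read — anchors clearing the ambiguity tract by `quant_margin`
#' bases — and divides by the local depth scaled to junction-expressing
#' placements, which keeps the estimator unbiased across read lengths (see
#' [estimate_heteroplasmy()]).
#'
#' @param reads Read set: data frame with `read_id` and `seq`, a character
#'   vector of sequences, or a FASTQ path. Alternatively pass `alignments`.
#' @param ref A [circular_reference()].
#' @param pair A [repeat_pair()].
#' @param config A [pipeline_config()].
#' @param sample_id Sample label.
#' @param alignments Optional pre-mapped `GAlignments` (SAM/BAM path input;
#'   used instead of `reads`).
#' @return One-row data frame: `sample_id`, `mode`, `event_first`,
#'   `event_last`, `n_support` (quantification-grade junction reads),
#'   `n_detect` (score-passing reads of the target event), `local_depth`,
#'   `h`, `ci_low`, `ci_high`, `passes_high_het`, `detected`, `note`;
#'   with attributes `evidence`, `calls` and `profile`.
#' @export
quantify_sample <- function(reads = NULL, ref, pair,
                            config = pipeline_config(), sample_id = "S1",
                            alignments = NULL) {
  stopifnot(inherits(ref, "CircularReference"), inherits(pair, "RepeatPair"),
            inherits(config, "PipelineConfig"))
  win <- c(max(1L, pair$region_start - config$window_pad),
           min(ref$length, pair$region_end + config$window_pad))
  win_len <- win[2] - win[1] + 1L
  target <- target_deletion_event(ref, pair)
  eq_starts <- vapply(equivalent_placements(ref, target), `[[`, integer(1),
                      "start")
  amb <- length(eq_starts) - 1L

  if (!is.null(alignments)) {
    evidence <- ingest_alignments(alignments, ref,
                                  c(pair$region_start, pair$region_end))
    profile <- compute_depth_profile(alignments, win[1], win_len)
    segs <- segments_from_galignments(alignments)
    rlens <- GenomicAlignments::qwidth(alignments)
    cv <- segment_depth_cv(segs, pair, config$flank)
  } else {
    if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
      reads <- read_fastq(reads)
    }
    if (is.character(reads)) {
      reads <- data.frame(read_id = paste0("read", seq_along(reads)),
                          seq = reads)
    }
    mapping <- map_reads(substr(ref$seq, win[1], win[2]), reads$seq,
                         max_del = config$max_del)
    evidence <- evidence_from_mapping(mapping, ref, win[1],
                                      read_ids = reads$read_id)
    profile <- compute_depth_profile(mapping, win[1], win_len)
    rlens <- mapping$read_len[mapping$aligned]
    cv <- local_depth_cv(mapping, win[1], pair, config$flank)
  }

  calls <- call_deletions(evidence, min_reads = config$min_reads,
                          min_score = config$min_score,
                          sample_id = sample_id)
  ld <- local_depth(profile, pair, config$flank)

  # quantification-grade junction reads: same deletion length, canonical
  # breakpoint within a small tolerance of the equivalence class (a read
  # with a sequencing error at a junction-critical base legitimately matches
  # an adjacent placement better; clustering re-attributes it, as indel
  # realignment would)
  near_class <- vapply(evidence$event_start, function(s) {
    min(abs(s - eq_starts)) <= config$cluster_tol
  }, logical(1))
  is_target <- evidence$event_len == target$length & near_class
  quant <- evidence[is_target &
                      evidence$left_anchor >= config$quant_margin &
                      evidence$right_anchor >= amb + config$quant_margin, ,
                    drop = FALSE]
  quant <- quant[!duplicated(quant$read_id), , drop = FALSE]
  n_quant <- nrow(quant)
  n_detect <- 0L
  detected <- FALSE
  if (nrow(calls)) {
    hit <- calls$event_start == target$start & calls$event_end == target$end
    if (any(hit)) {
      detected <- TRUE
      n_detect <- calls$n_support[which(hit)[1]]
    }
  }
  # junction-expressing fraction of read placements (empirical over lengths)
  c_span <- amb + 2L * config$quant_margin
  jf <- if (length(rlens)) {
    max(1e-6, mean(pmax(0, rlens - c_span + 1)) / mean(rlens))
  } else 1

  note <- ""
  if (ld <= 0) {
    out <- data.frame(sample_id = sample_id, mode = sample_mode(config),
                      event_first = target$report_first,
                      event_last = target$report_last,
                      n_support = n_quant, n_detect = n_detect,
                      local_depth = 0, h = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, passes_high_het = FALSE,
                      detected = detected, note = "no-coverage")
  } else if (n_quant >= 1L && (detected || config$targeted)) {
    est <- estimate_heteroplasmy(n_quant, ld, junction_fraction = jf,
                                 depth_cv = cv, conf = config$conf,
                                 high_het_threshold = config$high_het_threshold,
                                 mode = sample_mode(config),
                                 poisson_numerator = TRUE)
    if (!detected) note <- "subthreshold evidence (targeted estimate)"
    out <- data.frame(sample_id = sample_id, mode = est$mode,
                      event_first = target$report_first,
                      event_last = target$report_last,
                      n_support = n_quant, n_detect = n_detect,
                      local_depth = ld, h = est$h, ci_low = est$ci_low,
                      ci_high = est$ci_high,
                      passes_high_het = est$passes_high_het,
                      detected = detected, note = note)
  } else {
    if (n_quant >= 1L) note <- "subthreshold evidence"
    ci <- wilson_interval(0, max(1L, round(ld * jf)), config$conf)
    out <- data.frame(sample_id = sample_id, mode = sample_mode(config),
                      event_first = target$report_first,
                      event_last = target$report_last,
                      n_support = n_quant, n_detect = n_detect,
                      local_depth = ld, h = 0, ci_low = 0,
                      ci_high = unname(ci[2]), passes_high_het = FALSE,
                      detected = detected, note = note)
  }
  attr(out, "evidence") <- evidence
  attr(out, "calls") <- calls
  attr(out, "profile") <- profile
  out
}

segment_depth_cv <- function(segs, pair, flank) {
  if (!nrow(segs)) return(0)
  pos <- flank_positions(pair, flank)
  blocks <- list(range(pos[seq_len(flank)]), range(pos[flank + seq_len(flank)]))
  ov <- numeric(nrow(segs))
  for (b in blocks) {
    ov <- ov + pmax(0, pmin(segs$end, b[2]) - pmax(segs$start, b[1]) + 1)
  }
  per_read <- rowsum(ov, segs$read)
  tot <- sum(per_read)
  if (tot <= 0) return(0)
  sqrt(sum(per_read^2)) / tot
}

#' Run the full detection / quantification / cohort chain
#'
#' Quantifies every sample, aggregates high-heteroplasmy carriers by
#' haplogroup, computes pairwise group contrasts and, when the metadata
#' carries case/healthy labels, disease-association tests. Samples failing
#' the no-coverage check are marked failed and the run continues; the run
#' fails only when every sample fails.
#'
#' @param samples Named list of per-sample inputs: read data frames,
#'   [simulate_reads()] bundles (the `reads` element is used), FASTQ paths,
#'   or `GAlignments`.
#' @param meta Sample metadata (`sample_id`, `dataset`, `haplogroup`, ...).
#' @param ref A [circular_reference()].
#' @param pair A [repeat_pair()].
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for the report bundle (calls
#'   TSV, VCF of detected events, cohort and pairwise TSVs, run log).
#' @return List with `calls` (per-sample), `detections` (event-level),
#'   `cohort`, `pairwise`, `disease`, `failed` (sample ids).
#' @export
run_pipeline <- function(samples, meta, ref, pair,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(is.list(samples), length(samples) >= 1L)
  if (is.null(names(samples)) || anyNA(names(samples)) ||
      any(names(samples) == "")) {
    stop("samples must be a named list (names = sample ids)")
  }
  if (is.null(meta) || !nrow(meta)) stop("sample metadata is required")
  calls <- list(); detections <- list(); failed <- character()
  for (sid in names(samples)) {
    s <- samples[[sid]]
    res <- tryCatch({
      if (inherits(s, "GAlignments")) {
        quantify_sample(ref = ref, pair = pair, config = config,
                        sample_id = sid, alignments = s)
      } else {
        if (is.list(s) && !is.data.frame(s) && !is.null(s$reads)) s <- s$reads
        quantify_sample(s, ref = ref, pair = pair, config = config,
                        sample_id = sid)
      }
    }, error = function(e) e)
    if (inherits(res, "error") ||
        (is.data.frame(res) && identical(res$note, "no-coverage"))) {
      failed <- c(failed, sid)
      next
    }
    calls[[sid]] <- res
    det <- attr(res, "calls")
    if (nrow(det)) detections[[sid]] <- det
  }
  if (!length(calls)) stop("all samples failed quantification")
  calls_df <- do.call(rbind, calls)
  rownames(calls_df) <- NULL
  detections_df <- if (length(detections)) {
    d <- do.call(rbind, detections); rownames(d) <- NULL; d
  } else call_deletions(empty_evidence())
  cohort <- summarize_by_haplogroup(calls_df, meta,
                                    min_n_for_sem = config$min_n_for_sem)
  pairwise <- suppressMessages(
    compare_haplogroups(cohort, alpha = config$alpha,
                        min_n = config$min_n_for_sem))
  disease <- if ("disease_status" %in% names(meta)) {
    suppressMessages(disease_association(calls_df, meta,
                                         alpha = config$alpha))
  } else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(calls_df, file.path(out_dir, "heteroplasmy_calls.tsv"))
    write_tsv(as.data.frame(cohort), file.path(out_dir, "cohort_summary.tsv"))
    write_tsv(pairwise, file.path(out_dir, "pairwise_tests.tsv"))
    if (!is.null(disease) && nrow(disease)) {
      write_tsv(disease, file.path(out_dir, "disease_tests.tsv"))
    }
    if (nrow(detections_df)) {
      write_vcf(detections_df, ref, file.path(out_dir, "detections.vcf"))
    }
    log <- c(sprintf("mitohet run %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             "config:",
             vapply(names(unclass(config)), function(k) {
               sprintf("  %s: %s", k,
                       if (is.null(config[[k]])) "NULL" else format(config[[k]]))
             }, character(1)),
             sprintf("samples: %d ok, %d failed", nrow(calls_df),
                     length(failed)),
             if (length(failed)) paste("failed:", paste(failed, collapse = ", ")))
    writeLines(log, file.path(out_dir, "run.log"))
  }
  list(calls = calls_df, detections = detections_df, cohort = cohort,
       pairwise = pairwise, disease = disease, failed = failed)
}
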