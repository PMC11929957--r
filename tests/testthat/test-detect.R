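make_evidence <- function(n, event_start = 100L, event_end = 109L,
                          left = 40L, right = 60L, mm = 0L,
                          ids = paste0("r", seq_len(n))) {
  data.frame(read_id = ids, event_start = event_start,
             event_end = event_end, event_len = event_end - event_start,
             left_anchor = left, right_anchor = right, mismatches = mm,
             score = score_split_evidence(rep(left, n), rep(right, n),
                                          rep(mm, n)),
             read_len = left + right)
}

test_that("split-read score is the mismatch-penalised shortest anchor", {
  expect_identical(score_split_evidence(45, 55, 0), 45L)
  sc <- score_split_evidence(20, 20, 0)
  expect_identical(sc, 20L)
  expect_true(sc >= 20 && sc < 25) # ancient threshold passes, present-day not
  expect_identical(score_split_evidence(30, 30, 3), 24L)
  expect_identical(score_split_evidence(10, 90, 8), 0L) # floored
  expect_error(score_split_evidence(0, 10, 0), "at least 1")
})

test_that("call thresholds are inclusive at 5 reads and the score cut", {
  ev5 <- make_evidence(5, left = 30L, right = 70L) # score 30 >= 25
  calls <- call_deletions(ev5, min_reads = 5, min_score = 25)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$n_support, 5L)
  expect_identical(calls$report_first, 101L)
  expect_identical(calls$report_last, 109L)

  ev4 <- make_evidence(4, left = 30L, right = 70L)
  expect_identical(nrow(call_deletions(ev4, 5, 25)), 0L)

  # 6 reads, 2 scoring 24: only 4 survive the score filter -> no call
  ev6 <- rbind(make_evidence(4, left = 30L, right = 70L),
               make_evidence(2, left = 30L, right = 70L, mm = 3L,
                             ids = c("q1", "q2")))
  expect_identical(nrow(call_deletions(ev6, 5, 25)), 0L)
  # at the ancient threshold of 20 all six survive
  expect_identical(call_deletions(ev6, 5, 20)$n_support, 6L)
})

test_that("calls are grouped by event, deduplicated, and support-sorted", {
  a <- make_evidence(7, event_start = 100L, event_end = 109L)
  b <- make_evidence(5, event_start = 300L, event_end = 311L,
                     ids = paste0("s", 1:5))
  dup <- make_evidence(2, ids = c("r1", "r1")) # same read twice
  ev <- rbind(b, a, dup)
  calls <- call_deletions(ev, 5, 25)
  expect_identical(calls$event_start, c(100L, 300L))
  expect_identical(calls$n_support, c(7L, 5L)) # r1 counted once
  # stable under permutation of evidence order
  set.seed(3)
  perm <- ev[sample(nrow(ev)), ]
  expect_identical(call_deletions(perm, 5, 25), calls)
  # below-minimum events never emit a call (boundary inclusive)
  for (n in 1:4) {
    expect_identical(nrow(call_deletions(make_evidence(n), 5, 25)), 0L)
  }
})

test_that("mapping gaps become canonical evidence with junction anchors", {
  g <- fixture_genome()
  win1 <- 7700L
  # a read placed so its raw gap sits mid-tract: must left-align to 8271
  mapping <- data.frame(aligned = TRUE, offset = 530L, gap_start = 45L,
                        gap_len = 9L, mismatches = 0L, score = 100L,
                        read_len = 100L)
  raw_start <- (win1 - 1L) + 530L + 45L
  stopifnot(raw_start %in% 8271:8280) # inside the ambiguity class
  ev <- evidence_from_mapping(mapping, g$ref, win1, read_ids = "x1")
  expect_identical(ev$event_start, 8271L)
  expect_identical(ev$event_end, 8280L)
  # anchors re-expressed against the canonical junction
  read_start0 <- (win1 - 1L) + 530L
  expect_identical(ev$left_anchor, 8271L - read_start0)
  expect_identical(ev$left_anchor + ev$right_anchor, 100L)
  # oracle: the canonical event is the min-start member of the class
  cls <- equivalent_placements(g$ref, deletion_event(raw_start, raw_start + 9L))
  expect_identical(ev$event_start, cls[[1]]$start)
  # ungapped rows contribute nothing
  m0 <- data.frame(aligned = TRUE, offset = 10L, gap_start = 0L,
                   gap_len = 0L, mismatches = 1L, score = 97L,
                   read_len = 100L)
  expect_identical(nrow(evidence_from_mapping(m0, g$ref, win1)), 0L)
})

test_that("SAM records with deletion CIGARs are ingested as evidence", {
  g <- fixture_genome()
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", g$ref$name, g$ref$length))
  s1 <- paste0(circ_slice(g$ref, 8227, 45), circ_slice(g$ref, 8281, 55))
  rec1 <- sprintf("d1\t0\t%s\t8227\t60\t45M9D55M\t*\t0\t0\t%s\t*\tNM:i:9",
                  g$ref$name, s1)
  rec2 <- sprintf("u1\t0\t%s\t8000\t60\t100M\t*\t0\t0\t%s\t*\tNM:i:0",
                  g$ref$name, circ_slice(g$ref, 8000, 100))
  rec3 <- sprintf("un\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*", circ_slice(g$ref, 1, 50))
  writeLines(c(hdr, rec1, rec2, rec3), sam)
  aln <- read_sam(sam)
  expect_identical(length(aln), 2L) # unmapped record ignored
  ev <- ingest_alignments(aln, g$ref, c(8200, 8400))
  expect_identical(nrow(ev), 1L) # the 100M read has no gap
  expect_identical(ev$read_id, "d1")
  expect_identical(ev$event_len, 9L)
  # raw gap 8272..8280 (1-based): left-aligns to the canonical event
  expect_identical(ev$event_start, 8271L)
  expect_identical(ev$left_anchor, 45L)
  expect_identical(ev$right_anchor, 55L)
  expect_identical(ev$mismatches, 0L) # NM 9 = deleted bases only
  # gaps outside the region are ignored
  expect_identical(nrow(ingest_alignments(aln, g$ref, c(100, 500))), 0L)
  # header-only SAM: empty alignments, empty evidence
  sam2 <- tempfile(fileext = ".sam")
  writeLines(hdr, sam2)
  aln2 <- read_sam(sam2)
  expect_identical(length(aln2), 0L)
  expect_identical(nrow(ingest_alignments(aln2, g$ref, c(8200, 8400))), 0L)
})
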