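test_that("circular slicing wraps across the origin", {
  ref <- ref_with("ACGTACGTAC", at = 100, seed = 1)
  # doubled-string oracle
  doubled <- paste0(ref$seq, ref$seq)
  for (start in c(1L, ref$length - 3L, ref$length, 500L)) {
    for (len in c(1L, 8L, 20L)) {
      expect_identical(circ_slice(ref, start, len),
                       substr(doubled, start, start + len - 1))
      expect_identical(nchar(circ_slice(ref, start, len)), len)
    }
  }
  expect_identical(circ_slice(ref, 5, 0), "")
  expect_error(circ_slice(ref, 1, ref$length + 1), "longer than the genome")
})

test_that("reference construction validates its input", {
  expect_error(circular_reference("ACGT"), "at least 1000")
  expect_error(circular_reference(paste(rep("Q", 1200), collapse = "")),
               "alphabet")
  ref <- circular_reference(tolower(random_dna(1200, seed = 2)))
  expect_false(grepl("[a-z]", ref$seq)) # normalised to upper case
})

test_that("find_direct_repeats recovers the planted tandem pair", {
  g <- fixture_genome()
  hits <- find_direct_repeats(g$ref, c(8200, 8400), min_len = 9)
  expect_gt(nrow(hits), 0)
  top <- hits[hits$length == 9 & hits$motif == g$pair$motif, ]
  expect_true(any(top$left_start == 8272 & top$right_start == 8281))
  # longest-first ordering
  expect_true(all(diff(hits$length) <= 0))
  # with a lower min_len the 9-mer pair is still present plus shorter pairs
  hits4 <- find_direct_repeats(g$ref, c(8200, 8400), min_len = 4)
  expect_true(any(hits4$motif == g$pair$motif))
  expect_gt(nrow(hits4), nrow(hits))
  expect_true(all(diff(hits4$length) <= 0))
  # every reported pair is a genuine identical non-overlapping pair
  for (i in seq_len(min(20, nrow(hits4)))) {
    r <- hits4[i, ]
    expect_identical(circ_slice(g$ref, r$left_start, r$length), r$motif)
    expect_identical(circ_slice(g$ref, r$right_start, r$length), r$motif)
    expect_gte(r$right_start - r$left_start, r$length)
  }
})

test_that("find_direct_repeats handles empty and invalid regions", {
  # all-distinct sequence: no repeated 9-mer by construction
  ref <- circular_reference(random_dna(1200, seed = 33))
  empty_region <- c(10, 40) # 31 bp cannot hold two 16-mers
  expect_identical(nrow(find_direct_repeats(ref, empty_region, 16)), 0L)
  expect_error(find_direct_repeats(ref, c(0, 50), 9), "region")
  expect_error(find_direct_repeats(ref, c(10, 5000), 9), "region")
  expect_error(find_direct_repeats(ref, c(10, 100), 3), "min_len")
})

test_that("breakpoint equivalence class matches the string-equality oracle", {
  g <- fixture_genome()
  ev <- deletion_event(8271, 8280) # delete one repeat copy
  eq <- equivalent_placements(g$ref, ev)
  expect_length(eq, 10) # 18-bp tandem tract: start offsets 0..9
  expect_identical(vapply(eq, `[[`, integer(1), "start"),
                   oracle_equivalent_starts(g$ref, ev))
  # every member applies to the identical genome string
  applied <- vapply(eq, function(e) apply_deletion(g$ref, e)$seq, character(1))
  expect_length(unique(applied), 1L)
})

test_that("homopolymer deletions have k equivalent placements", {
  for (k in c(4, 7, 11)) {
    ref <- ref_with(paste0("G", strrep("A", k), "G"), at = 700, seed = k)
    ev <- deletion_event(700 + 3, 700 + 4) # 1-bp deletion inside the run
    eq <- equivalent_placements(ref, ev)
    expect_length(eq, k)
    expect_identical(vapply(eq, `[[`, integer(1), "start"),
                     oracle_equivalent_starts(ref, ev))
  }
  # non-repetitive context: singleton class
  ref <- circular_reference(random_dna(1200, seed = 5))
  ev <- deletion_event(830, 839)
  if (length(oracle_equivalent_starts(ref, ev)) == 1L) {
    expect_length(equivalent_placements(ref, ev), 1L)
  }
})

test_that("left alignment picks the minimal start and is idempotent", {
  g <- fixture_genome()
  class_starts <- 8271:8280
  for (s in class_starts) {
    can <- left_align_deletion(g$ref, deletion_event(s, s + 9))
    expect_identical(can$start, 8271L)
    expect_true(can$canonical)
    # idempotent
    again <- left_align_deletion(g$ref, can)
    expect_identical(again$start, can$start)
  }
  # non-repeat deletion maps to itself
  ref <- circular_reference(random_dna(1500, seed = 9))
  ev <- deletion_event(777, 786)
  can <- left_align_deletion(ref, ev)
  expect_identical(can$start, oracle_equivalent_starts(ref, ev)[1])
})

test_that("random planted-repeat genomes left-align to the oracle minimum", {
  set.seed(101)
  for (i in 1:25) {
    mlen <- sample(3:10, 1)
    motif <- random_dna(mlen)
    at <- sample(300:900, 1)
    ref <- ref_with(paste0(motif, motif), at = at, L = 1200,
                    seed = 1000 + i)
    s0 <- at - 1L + sample(0:mlen, 1) # any placement inside the tract
    ev <- deletion_event(s0, s0 + mlen)
    oracle_min <- min(oracle_equivalent_starts(ref, ev))
    expect_identical(left_align_deletion(ref, ev)$start, oracle_min)
  }
})

test_that("apply_deletion excises the interval", {
  g <- fixture_genome()
  ev <- left_align_deletion(g$ref, deletion_event(8271, 8280))
  del <- apply_deletion(g$ref, ev)
  expect_identical(del$length, g$ref$length - 9L)
  # exactly one motif copy survives at the locus
  hits <- gregexpr(g$pair$motif, del$seq, fixed = TRUE)[[1]]
  expect_length(hits, 1L)
  # all class members produce the identical deleted genome
  for (s in c(8274, 8280)) {
    expect_identical(apply_deletion(g$ref, deletion_event(s, s + 9))$seq,
                     del$seq)
  }
  expect_error(deletion_event(100, 100), "at least 1")
  expect_error(apply_deletion(g$ref, deletion_event(0, g$ref$length)),
               "whole genome")
  expect_error(apply_deletion(g$ref, deletion_event(g$ref$length + 5,
                                                    g$ref$length + 9)),
               "outside")
})

test_that("origin-spanning deletions are excised with wrap-around", {
  ref <- circular_reference(random_dna(1500, seed = 12))
  L <- ref$length
  ev <- deletion_event(L - 4, L + 3) # removes last 4 and first 3 bases
  del <- apply_deletion(ref, ev)
  expect_identical(del$length, L - 7L)
  expect_identical(del$seq, substr(ref$seq, 4, L - 4))
})
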