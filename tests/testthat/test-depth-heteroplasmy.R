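test_that("depth profiles conserve aligned bases and skip deletion gaps", {
  # 20 ungapped reads tiling a window
  m <- data.frame(aligned = TRUE, offset = seq(0, 190, by = 10),
                  gap_start = 0L, gap_len = 0L, mismatches = 0L,
                  score = 50L, read_len = 50L)
  prof <- compute_depth_profile(m, window_start = 1000L, window_len = 300L)
  expect_identical(sum(prof$depth), sum(m$read_len)) # conservation
  # one split read: depth 1 on matched positions, 0 inside the gap
  m1 <- data.frame(aligned = TRUE, offset = 5L, gap_start = 45L,
                   gap_len = 9L, mismatches = 0L, score = 100L,
                   read_len = 100L)
  p1 <- compute_depth_profile(m1, 1L, 130L)
  expect_identical(sum(p1$depth), 100L)
  expect_true(all(p1$depth[6:50] == 1L))       # left anchor
  expect_true(all(p1$depth[51:59] == 0L))      # deleted positions
  expect_true(all(p1$depth[60:114] == 1L))     # right anchor
  # no reads: all zero, not an error
  p0 <- compute_depth_profile(m[0, ], 1L, 50L)
  expect_identical(p0$depth, integer(50))
})

test_that("local depth pools the two flanking windows", {
  g <- fixture_genome()
  prof <- structure(list(depth = rep(100L, 1201), start = 7700L,
                         source = "test"), class = "DepthProfile")
  expect_equal(local_depth(prof, g$pair, flank = 50), 100)
  # asymmetric flanks average position-wise: 80 upstream, 120 downstream
  d <- rep(0L, 1201)
  up <- (g$pair$left_start - 50):(g$pair$left_start - 1) - 7699L
  dn <- (g$pair$right_end + 1):(g$pair$right_end + 50) - 7699L
  d[up] <- 80L; d[dn] <- 120L
  prof2 <- structure(list(depth = d, start = 7700L, source = "test"),
                     class = "DepthProfile")
  expect_equal(local_depth(prof2, g$pair, flank = 50), 100)
  expect_equal(local_depth(prof2, g$pair, flank = 25), 100)
  # flanks outside the profile
  short <- structure(list(depth = rep(1L, 10), start = 8220L,
                          source = "test"), class = "DepthProfile")
  expect_error(local_depth(short, g$pair), "outside")
})

test_that("simulated local depth matches the configured depth", {
  g <- fixture_genome()
  d <- 300
  devs <- vapply(1:20, function(s) {
    p <- sim_params("present-day", true_h = 0, depth = d)
    sr <- simulate_reads(g, p, seed = 4000 + s)
    q <- quantify_sample(sr$reads, ref = g$ref, pair = g$pair,
                         config = pipeline_config())
    q$local_depth - d
  }, numeric(1))
  expect_true(all(abs(devs) <= 3 * sqrt(d)))
})

test_that("Wilson interval matches its closed form and prop.test", {
  ci <- wilson_interval(0.5, 10)
  expect_equal(unname(ci), c(0.2366, 0.7634), tolerance = 1e-3)
  # independent oracle: stats::prop.test without continuity correction
  for (x in c(1, 5, 9)) {
    for (n in c(10, 40)) {
      ours <- wilson_interval(x / n, n)
      ref <- suppressWarnings(prop.test(x, n, correct = FALSE))$conf.int
      expect_equal(unname(ours), as.numeric(ref), tolerance = 1e-9)
    }
  }
  expect_error(wilson_interval(0.5, 0), "n >= 1")
})

test_that("heteroplasmy is support over junction-scaled local depth", {
  est <- estimate_heteroplasmy(740, 1000)
  expect_equal(est$h, 0.74)
  expect_true(est$passes_high_het)
  est2 <- estimate_heteroplasmy(5, 10)
  expect_equal(est2$h, 0.5)
  expect_equal(est2$ci_low, 0.2366, tolerance = 1e-3)
  expect_equal(est2$ci_high, 0.7634, tolerance = 1e-3)
  # clamped at 1 and interval stays ordered
  est3 <- estimate_heteroplasmy(120, 100)
  expect_equal(est3$h, 1)
  expect_true(est3$ci_low <= est3$h && est3$h <= est3$ci_high)
  # junction fraction rescales the denominator
  est4 <- estimate_heteroplasmy(370, 1000, junction_fraction = 0.5)
  expect_equal(est4$h, 0.74)
  # denominator uncertainty widens the interval
  narrow <- estimate_heteroplasmy(300, 1000, poisson_numerator = TRUE)
  wide <- estimate_heteroplasmy(300, 1000, depth_cv = 0.1,
                                poisson_numerator = TRUE)
  expect_gt(wide$ci_high - wide$ci_low, narrow$ci_high - narrow$ci_low)
  expect_error(estimate_heteroplasmy(5, 0), "no coverage")
  expect_error(estimate_heteroplasmy(0, 100), "at least 1")
})

test_that("the 15% reporting filter is boundary-inclusive", {
  calls <- data.frame(sample_id = c("a", "b", "c"),
                      h = c(0.15, 0.149, 0.9))
  kept <- filter_high_heteroplasmy(calls)
  expect_identical(kept$sample_id, c("a", "c"))
  expect_identical(nrow(filter_high_heteroplasmy(calls[0, ])), 0L)
  # custom threshold
  expect_identical(nrow(filter_high_heteroplasmy(calls, 0.5)), 1L)
})

test_that("estimates are stable under read subsampling in expectation", {
  g <- fixture_genome()
  p <- sim_params("present-day", true_h = 0.5, depth = 600)
  sr <- simulate_reads(g, p, seed = 61)
  cfg <- pipeline_config()
  full <- quantify_sample(sr$reads, ref = g$ref, pair = g$pair, config = cfg)
  set.seed(62)
  halves <- vapply(1:25, function(i) {
    idx <- sample(nrow(sr$reads), nrow(sr$reads) %/% 2)
    quantify_sample(sr$reads[idx, ], ref = g$ref, pair = g$pair,
                    config = cfg)$h
  }, numeric(1))
  expect_lt(abs(mean(halves) - full$h), 0.03)
})
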