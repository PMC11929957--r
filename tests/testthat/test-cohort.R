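carriers <- function(ds, hg, hs, status = "healthy") {
  n <- length(hs)
  ids <- sprintf("%s_%s_%02d", ds, hg, seq_len(n))
  list(calls = data.frame(sample_id = ids, h = hs,
                          passes_high_het = hs >= 0.15),
       meta = data.frame(sample_id = ids, dataset = ds, haplogroup = hg,
                         disease_status = status, era = "present-day"))
}

test_that("haplogroup summaries report mean and gated SEM", {
  a <- carriers("D1", "B2", c(0.6, 0.7, 0.8))
  tab <- summarize_by_haplogroup(a$calls, a$meta)
  expect_identical(tab$n_carriers, 3L)
  expect_equal(tab$mean_h, 0.7)
  expect_equal(tab$sem_internal, 0.1 / sqrt(3), tolerance = 1e-9)
  expect_true(is.na(tab$sem_h)) # below the 4-carrier reporting gate
  # a 4-carrier group reports its SEM
  b <- carriers("D1", "L0a2", c(0.5, 0.55, 0.5, 0.57))
  tab2 <- summarize_by_haplogroup(rbind(a$calls, b$calls),
                                  rbind(a$meta, b$meta))
  expect_equal(tab2$sem_h[tab2$haplogroup == "L0a2"],
               sd(c(0.5, 0.55, 0.5, 0.57)) / 2)
  # single-carrier group: mean only
  cgl <- carriers("D1", "A2", 0.8)
  tab3 <- summarize_by_haplogroup(cgl$calls, cgl$meta)
  expect_equal(tab3$mean_h, 0.8)
  expect_true(is.na(tab3$sem_h))
})

test_that("grouping is by dataset and haplogroup jointly", {
  a <- carriers("BTMX", "B2", c(0.7, 0.75))
  b <- carriers("ARG", "B2", c(0.65, 0.7))
  tab <- summarize_by_haplogroup(rbind(a$calls, b$calls),
                                 rbind(a$meta, b$meta))
  expect_identical(nrow(tab), 2L)
  expect_setequal(tab$dataset, c("BTMX", "ARG"))
  # permutation invariance of input order
  calls <- rbind(b$calls, a$calls)
  set.seed(8)
  tab2 <- summarize_by_haplogroup(calls[sample(nrow(calls)), ],
                                  rbind(a$meta, b$meta))
  expect_identical(tab, tab2)
})

test_that("sub-threshold carriers are excluded and missing metadata is fatal", {
  a <- carriers("D1", "B2", c(0.6, 0.1)) # second is below 15%
  tab <- summarize_by_haplogroup(a$calls, a$meta)
  expect_identical(tab$n_carriers, 1L)
  bad_calls <- rbind(a$calls, data.frame(sample_id = "ghost", h = 0.5,
                                         passes_high_het = TRUE))
  expect_error(summarize_by_haplogroup(bad_calls, a$meta), "ghost")
})

test_that("pairwise contrasts flag the low-vs-high haplogroup difference", {
  set.seed(81)
  lo <- carriers("SA", "L0a2", pmin(1, pmax(0, rnorm(21, 0.53, 0.05))))
  hi <- carriers("MX", "B2", pmin(1, pmax(0, rnorm(23, 0.74, 0.05))))
  tab <- summarize_by_haplogroup(rbind(lo$calls, hi$calls),
                                 rbind(lo$meta, hi$meta))
  res <- compare_haplogroups(tab)
  expect_identical(nrow(res), 1L)
  expect_true(res$significant_t)
  expect_true(res$significant_ranksum)
  expect_lt(res$p_t, 0.001)
  expect_equal(abs(res$diff), abs(mean(hi$calls$h) - mean(lo$calls$h)),
               tolerance = 1e-9)
})

test_that("identical groups yield p = 1 and small groups are ineligible", {
  a <- carriers("D", "G1", rep(0.5, 5))
  b <- carriers("D", "G2", rep(0.5, 6))
  small <- carriers("D", "G3", rep(0.9, 3)) # n = 3 < 4
  tab <- summarize_by_haplogroup(rbind(a$calls, b$calls, small$calls),
                                 rbind(a$meta, b$meta, small$meta))
  res <- compare_haplogroups(tab)
  expect_identical(nrow(res), 1L) # G3 excluded
  expect_equal(res$p_t, 1)
  expect_equal(res$p_ranksum, 1)
  expect_false(res$significant_t)
  # fewer than two eligible groups: empty with a notice
  expect_message(r2 <- compare_haplogroups(summarize_by_haplogroup(
    small$calls, small$meta)), "fewer than two")
  expect_identical(nrow(r2), 0L)
})

test_that("disease association uses rank-sum, pairs use signed-rank", {
  # all carriers are cases, all controls at h = 0
  cs <- carriers("DS", "B2", rep(0.6, 6), status = "case")
  ct <- carriers("DS", "H", rep(0, 6), status = "healthy")
  ct$calls$h <- 0; ct$calls$passes_high_het <- FALSE
  res <- disease_association(rbind(cs$calls, ct$calls),
                             rbind(cs$meta, ct$meta))
  expect_identical(res$test, "rank-sum")
  expect_equal(res$p, oracle_rank_sum_p(rep(0.6, 6), rep(0, 6)))
  expect_true(res$significant)
  # non-carrier samples enter at h = 0 even without a call row
  res2 <- disease_association(cs$calls, rbind(cs$meta, ct$meta))
  expect_equal(res2$p, res$p)
  # single-class dataset is skipped with a notice
  expect_message(r0 <- disease_association(cs$calls, cs$meta), "skipped")
  expect_identical(nrow(r0), 0L)
  # paired design: mother-offspring keys route to the signed-rank test
  prs <- carriers("ARG", "B2", c(0.7, 0.72, 0.68, 0.75, 0.71), "case")
  mot <- carriers("ARG", "B2", c(0.6, 0.66, 0.61, 0.7, 0.64), "healthy")
  mot$calls$sample_id <- paste0("m_", mot$calls$sample_id)
  mot$meta$sample_id <- mot$calls$sample_id
  prs$meta$pair_id <- mot$meta$pair_id <- paste0("p", 1:5)
  res3 <- disease_association(rbind(prs$calls, mot$calls),
                              rbind(prs$meta, mot$meta))
  expect_match(res3$test, "signed-rank")
  expect_equal(res3$p, oracle_signed_rank_p(prs$calls$h - mot$calls$h))
})

test_that("null case-control cohorts are rarely flagged", {
  set.seed(82)
  flagged <- vapply(1:30, function(i) {
    hs <- rnorm(16, 0.5, 0.1)
    cc <- carriers("NL", "B2", hs,
                   status = rep(c("case", "healthy"), each = 8))
    disease_association(cc$calls, cc$meta)$significant
  }, logical(1))
  expect_lte(mean(flagged), 0.2)
})
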