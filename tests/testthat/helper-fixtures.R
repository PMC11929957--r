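# Shared fixtures and independent oracles, all built in code.

# one default synthetic genome per test run (deterministic)
fixture_genome <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_synthetic_genome(seed = 42)
    cache
  }
})

# small circular genome with a given cassette embedded at position `at`
ref_with <- function(cassette, at = 600L, L = 1500L, seed = 7L) {
  set.seed(seed)
  bg <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  cas <- strsplit(toupper(cassette), "")[[1]]
  bg[at:(at + length(cas) - 1L)] <- cas
  circular_reference(paste(bg, collapse = ""))
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# ---- oracle 1: breakpoint equivalence by direct string comparison ---------
# every same-length deletion placement whose applied genome equals the
# target's applied genome, searched over a generous neighbourhood
oracle_equivalent_starts <- function(ref, ev, radius = 60L) {
  target <- apply_deletion(ref, ev)$seq
  lo <- max(0L, ev$start - radius)
  hi <- min(ref$length - ev$length, ev$start + radius)
  starts <- lo:hi
  starts[vapply(starts, function(s) {
    identical(apply_deletion(ref, deletion_event(s, s + ev$length))$seq,
              target)
  }, logical(1))]
}

# ---- oracle 2: exhaustive single-gap alignment ----------------------------
# full candidate table over (offset, gap_start, gap_length), ordered by the
# documented tie-break; cumulative mismatch arrays make it affordable while
# staying a separate implementation from the package's search
oracle_split_align <- function(win, rd, max_del) {
  wn <- strsplit(toupper(win), "")[[1]]
  rn <- strsplit(toupper(rd), "")[[1]]
  nw <- length(wn); nr <- length(rn)
  noff <- nw - nr
  M <- vapply(0:noff, function(o) {
    seg <- wn[(o + 1):(o + nr)]
    c(0L, cumsum(seg != rn | seg == "N" | rn == "N"))
  }, integer(nr + 1))  # column o+1 = offset o
  cand <- list()
  for (o in 0:noff) {
    cand[[length(cand) + 1L]] <-
      data.frame(o = o, g = 0L, l = 0L, mm = M[nr + 1, o + 1])
    for (l in seq_len(max_del)) {
      if (o + l > noff) break
      g <- 1:(nr - 1)
      mm <- M[g + 1, o + 1] + M[nr + 1, o + l + 1] - M[g + 1, o + l + 1]
      cand[[length(cand) + 1L]] <- data.frame(o = o, g = g, l = l, mm = mm)
    }
  }
  tab <- do.call(rbind, cand)
  tab$score <- nr - 3L * tab$mm
  tab <- tab[order(-tab$score, tab$o, tab$g, tab$l), ]
  tab[1, ]
}

# fully naive version (string surgery per candidate) for tiny cases
oracle_split_align_naive <- function(win, rd, max_del) {
  wn <- strsplit(toupper(win), "")[[1]]
  rn <- strsplit(toupper(rd), "")[[1]]
  nw <- length(wn); nr <- length(rn)
  best <- NULL
  for (o in 0:(nw - nr)) {
    for (g in 0:(nr - 1)) {
      for (l in 0:max_del) {
        if (g == 0 && l > 0) next
        if (g > 0 && l == 0) next
        if (o + nr + l > nw) next
        ref <- if (l == 0) wn[(o + 1):(o + nr)]
               else c(wn[(o + 1):(o + g)], wn[(o + g + l + 1):(o + nr + l)])
        mm <- sum(ref != rn | ref == "N" | rn == "N")
        sc <- nr - 3 * mm
        if (is.null(best) || sc > best$score ||
            (sc == best$score && (o < best$o ||
              (o == best$o && (g < best$g ||
                (g == best$g && l < best$l)))))) {
          best <- list(o = o, g = g, l = l, mm = mm, score = sc)
        }
      }
    }
  }
  best
}

# ---- oracle 3: exact rank tests by naive enumeration ----------------------
oracle_rank_sum_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  mu <- n1 * (n - n1) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- combn(n, n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

oracle_signed_rank_p <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  w_all <- vapply(0:(2^n - 1), function(mask) {
    sum(r[bitwAnd(mask, 2^(0:(n - 1))) > 0])
  }, numeric(1))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# quantify one simulated sample end to end (convenience for recovery tests)
quantify_sim <- function(genome, true_h, depth, seed, mode = "present-day",
                         config = NULL) {
  p <- sim_params(mode, true_h = true_h, depth = depth)
  sr <- simulate_reads(genome, p, seed = seed)
  if (is.null(config)) {
    config <- pipeline_config(if (mode == "ancient") "ancient" else "present-day")
  }
  quantify_sample(sr$reads, ref = genome$ref, pair = genome$pair,
                  config = config)
}
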