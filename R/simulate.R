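#' Simulation parameters for synthetic mitochondrial read sets
#'
#' Defaults emulate the two library classes the pipeline is designed for:
#' `present-day` — deep whole-mtDNA sequencing with fixed 100-bp reads, 1%
#' base error, no deamination; `ancient` — short fragments (truncated normal,
#' mean 55, sd 15, bounded 30-100 bp), low local depth, and mild residual
#' 5' C-to-T deamination (libraries of interest are UDG-treated, so the
#' default damage rate is small).
#'
#' @param mode `"present-day"` or `"ancient"`.
#' @param true_h True deletion heteroplasmy fraction in `[0, 1]`.
#' @param depth Target mean local depth (reads per base) at the repeat locus.
#' @param read_len Fixed read length, present-day mode.
#' @param read_len_mean,read_len_sd,read_len_range Ancient fragment-length
#'   model (truncated normal).
#' @param base_error Per-base substitution error rate.
#' @param damage_rate 5'-terminal C-to-T deamination probability at read
#'   position 1; decays geometrically with factor `damage_decay` per
#'   position. Both rates must lie in `[0, 0.3]`.
#' @param damage_decay Geometric decay factor of the damage rate.
#' @param window_pad Reads are simulated from the repeat region padded by
#'   this many bases on each side.
#' @return A `SimParams` list.
#' @export
sim_params <- function(mode = c("present-day", "ancient"), true_h = 0,
                       depth = 2000, read_len = 100L, read_len_mean = 55,
                       read_len_sd = 15, read_len_range = c(30L, 100L),
                       base_error = 0.01,
                       damage_rate = if (mode[1] == "ancient") 0.02 else 0,
                       damage_decay = 0.5, window_pad = 500L) {
  mode <- match.arg(mode)
  stopifnot(true_h >= 0, true_h <= 1, depth > 0,
            base_error >= 0, base_error <= 0.3,
            damage_rate >= 0, damage_rate <= 0.3,
            damage_decay > 0, damage_decay < 1)
  structure(list(mode = mode, true_h = true_h, depth = depth,
                 read_len = as.integer(read_len),
                 read_len_mean = read_len_mean, read_len_sd = read_len_sd,
                 read_len_range = as.integer(read_len_range),
                 base_error = base_error, damage_rate = damage_rate,
                 damage_decay = damage_decay,
                 window_pad = as.integer(window_pad)),
            class = "SimParams")
}

#' Synthetic circular genome with an embedded tandem direct-repeat pair
#'
#' A random background sequence (seeded, hence reproducible) with the exact
#' tandem motif pair embedded at the configured positions — a stand-in for
#' the mitochondrial reference so the pipeline is testable without any
#' download. The construction guarantees (re-drawing the background when
#' violated) that the motif occurs nowhere else on the circle and that the
#' bases immediately flanking the tandem tract do not extend the breakpoint
#' ambiguity class beyond the tract itself.
#'
#' @param L Genome length (default 16569, the human mtDNA length).
#' @param motif Repeat motif (default `CCCCCTCTA`).
#' @param left_start 1-based start of the left copy (default 8272).
#' @param region 1-based bounds of the intergenic region of interest.
#' @param seed Integer seed.
#' @return List with `ref` (a [circular_reference()]) and `pair`
#'   (a [repeat_pair()]); the copies are adjacent
#'   (`right_start = left_start + nchar(motif)`).
#' @export
make_synthetic_genome <- function(L = 16569L, motif = "CCCCCTCTA",
                                  left_start = 8272L,
                                  region = c(8200L, 8400L), seed = 1L) {
  motif <- toupper(motif)
  mlen <- nchar(motif)
  right_start <- left_start + mlen
  if (left_start < region[1] || right_start + mlen - 1 > region[2] ||
      region[2] > L || left_start <= mlen + 1) {
    stop("impossible motif placement for this genome configuration")
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  mchars <- strsplit(motif, "")[[1]]
  for (attempt in 1:100) {
    bg <- sample(bases, L, replace = TRUE)
    # plant the tandem pair
    bg[left_start:(left_start + 2L * mlen - 1L)] <- c(mchars, mchars)
    # keep the ambiguity class confined to the tract: the base before the
    # tract must differ from the motif's last base, the base after it from
    # the motif's first base
    bg[left_start - 1L] <- sample(setdiff(bases, mchars[mlen]), 1L)
    bg[right_start + mlen] <- sample(setdiff(bases, mchars[1L]), 1L)
    seq <- paste(bg, collapse = "")
    # motif must occur exactly twice, counting across the origin
    wrapped <- paste0(seq, substr(seq, 1L, mlen - 1L))
    hits <- gregexpr(motif, wrapped, fixed = TRUE)[[1]]
    if (length(hits) == 2L && !identical(as.integer(hits), -1L)) {
      ref <- circular_reference(seq, name = sprintf("synthetic_mt_seed%d", seed))
      pair <- repeat_pair(motif, left_start, right_start,
                         region[1], region[2], ref = ref)
      return(list(ref = ref, pair = pair))
    }
  }
  stop("could not draw a background without a third motif copy")
}

#' Canonical deletion of one repeat copy
#'
#' The left-aligned deletion event corresponding to loss of one copy of the
#' pair's motif (the canonical representative of every placement inside the
#' tandem tract).
#'
#' @param ref A [circular_reference()].
#' @param pair A [repeat_pair()].
#' @return A canonical `DeletionEvent`.
#' @export
target_deletion_event <- function(ref, pair) {
  left_align_deletion(ref, deletion_event(pair$left_start - 1L,
                                          pair$left_start - 1L + pair$motif_len))
}

truncnorm_lengths <- function(n, mu, sd, range) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(n, mu, sd)
    out <- c(out, draw[draw >= range[1] & draw <= range[2]])
  }
  as.integer(round(out[seq_len(n)]))
}

#' Simulate reads from a wild-type / deletion genome mixture
#'
#' Builds the deletion haplotype by excising one motif copy, assigns each
#' read a haplotype by a Bernoulli draw at the true heteroplasmy, places
#' read starts uniformly over the locus window on the respective haplotype,
#' then applies substitution errors and (ancient mode) 5' C-to-T damage.
#' The read count is chosen so the expected depth at the flanking windows
#' equals `params$depth`.
#'
#' @param genome List from [make_synthetic_genome()] (fields `ref`, `pair`),
#'   or a [circular_reference()] together with `pair`.
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @param sample_id Sample label used in read names.
#' @param pair A [repeat_pair()] when `genome` is a bare reference.
#' @return List with `reads` (data frame: `read_id`, `seq`, `hap` with 1 =
#'   deletion haplotype), `truth` (sample_id, true_h, realized counts,
#'   canonical event coordinates), and `window` (1-based genome bounds the
#'   reads were drawn from).
#' @export
simulate_reads <- function(genome, params, seed = 1L, sample_id = "S1",
                           pair = NULL) {
  if (inherits(genome, "CircularReference")) {
    ref <- genome
    stopifnot(inherits(pair, "RepeatPair"))
  } else {
    ref <- genome$ref; pair <- genome$pair
  }
  stopifnot(inherits(params, "SimParams"))
  set.seed(seed)
  ev <- target_deletion_event(ref, pair)
  del <- apply_deletion(ref, ev)
  win <- c(max(1L, pair$region_start - params$window_pad),
           min(ref$length, pair$region_end + params$window_pad))
  wt_window <- substr(ref$seq, win[1], win[2])
  del_window <- substr(del$seq, win[1], win[2] - ev$length)
  rbar <- if (params$mode == "present-day") params$read_len else {
    a <- (params$read_len_range[1] - params$read_len_mean) / params$read_len_sd
    b <- (params$read_len_range[2] - params$read_len_mean) / params$read_len_sd
    params$read_len_mean + params$read_len_sd *
      (stats::dnorm(a) - stats::dnorm(b)) / (stats::pnorm(b) - stats::pnorm(a))
  }
  span <- nchar(wt_window)
  if (span < max(params$read_len, params$read_len_range[2]) + 10L) {
    stop("window shorter than the maximum read length")
  }
  n_reads <- max(1L, as.integer(round(params$depth * (span - rbar + 1) / rbar)))
  lens <- if (params$mode == "present-day") {
    rep(params$read_len, n_reads)
  } else {
    truncnorm_lengths(n_reads, params$read_len_mean, params$read_len_sd,
                      params$read_len_range)
  }
  hap <- rbinom(n_reads, 1L, params$true_h)
  hap_span <- ifelse(hap == 1L, nchar(del_window), span)
  # draw starts with sample.int per start-range value: uniform over the
  # admissible starts of each read's haplotype/length combination
  nstart <- hap_span - lens + 1L
  starts <- integer(n_reads)
  for (k in unique(nstart)) {
    idx <- which(nstart == k)
    starts[idx] <- sample.int(k, length(idx), replace = TRUE)
  }
  seqs <- ifelse(hap == 1L,
                 substring(del_window, starts, starts + lens - 1L),
                 substring(wt_window, starts, starts + lens - 1L))
  seqs <- inject_errors(seqs, lens, params$base_error)
  if (params$mode == "ancient" && params$damage_rate > 0) {
    seqs <- inject_damage(seqs, lens, params$damage_rate, params$damage_decay)
  }
  reads <- data.frame(
    read_id = sprintf("%s_r%06d", sample_id, seq_len(n_reads)),
    seq = seqs, hap = hap, start = starts, len = lens
  )
  truth <- list(sample_id = sample_id, true_h = params$true_h,
                event_first = ev$report_first, event_last = ev$report_last,
                n_del = sum(hap == 1L), n_wt = sum(hap == 0L),
                n_reads = n_reads, mode = params$mode, depth = params$depth,
                seed = seed)
  list(reads = reads, truth = truth, window = win)
}

inject_errors <- function(seqs, lens, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  n_err <- rbinom(length(seqs), lens, rate)
  tot <- sum(n_err)
  if (tot == 0L) return(seqs)
  idx <- rep.int(seq_along(seqs), n_err)
  pos <- ceiling(runif(tot) * lens[idx])
  shift <- sample.int(3L, tot, replace = TRUE)
  # process one error per read per round so substr<- assignments never clash
  rank <- stats::ave(idx, idx, FUN = seq_along)
  for (r in seq_len(max(rank))) {
    sel <- rank == r
    i <- idx[sel]; p <- pos[sel]
    cur <- match(substring(seqs[i], p, p), bases)
    cur[is.na(cur)] <- 1L # N and friends mutate like A
    repl <- bases[(cur - 1L + shift[sel]) %% 4L + 1L]
    substr(seqs[i], p, p) <- repl
  }
  seqs
}

inject_damage <- function(seqs, lens, rate, decay) {
  # C->T transitions at 5' terminal positions, geometrically decaying
  maxpos <- min(max(lens), 1L + ceiling(log(1e-4 / rate) / log(decay)))
  for (p in seq_len(max(1L, maxpos))) {
    pr <- rate * decay^(p - 1)
    hit <- runif(length(seqs)) < pr & lens >= p & substring(seqs, p, p) == "C"
    if (any(hit)) substr(seqs[hit], p, p) <- "T"
  }
  seqs
}

#' Simulate a multi-group cohort
#'
#' One sample per scenario row entry, with per-sample seeds derived as
#' `seed + index` so the bundle is reproducible end to end. Per-sample true
#' heteroplasmy is drawn from a normal around the group mean (truncated to
#' `[0, 1]`); depth is fixed or drawn uniformly from `[depth_min,
#' depth_max]` when those columns are present.
#'
#' @param scenario Data frame with one row per group: `dataset`,
#'   `haplogroup`, `n`, `true_h`, and optionally `h_sd` (default 0.05 when
#'   `true_h > 0`, else 0), `mode`, `depth` or `depth_min`/`depth_max`,
#'   `disease_status`.
#' @param genome List from [make_synthetic_genome()].
#' @param seed Integer base seed.
#' @param depth Default depth for groups without a depth column.
#' @return List with `meta` (sample metadata), `truth` (per-sample truth
#'   table), and `samples` (named list of per-sample read sets as returned
#'   by [simulate_reads()]).
#' @export
simulate_cohort <- function(scenario, genome, seed = 1L, depth = 2000) {
  stopifnot(is.data.frame(scenario), nrow(scenario) >= 1L,
            all(c("dataset", "haplogroup", "n", "true_h") %in% names(scenario)))
  if (any(scenario$n < 1L)) stop("every scenario group needs n >= 1")
  set.seed(seed)
  samples <- list()
  meta <- list(); truth <- list()
  idx <- 0L
  for (g in seq_len(nrow(scenario))) {
    row <- scenario[g, ]
    h_sd <- if ("h_sd" %in% names(scenario) && !is.na(row$h_sd)) row$h_sd
            else if (row$true_h > 0) 0.05 else 0
    mode <- if ("mode" %in% names(scenario) && !is.na(row$mode)) row$mode
            else "present-day"
    status <- if ("disease_status" %in% names(scenario) &&
                  !is.na(row$disease_status)) row$disease_status else "healthy"
    hs <- pmin(1, pmax(0, rnorm(row$n, row$true_h, h_sd)))
    if (row$true_h == 0) hs <- rep(0, row$n)
    ds <- if (all(c("depth_min", "depth_max") %in% names(scenario)) &&
              !is.na(row$depth_min)) {
      runif(row$n, row$depth_min, row$depth_max)
    } else if ("depth" %in% names(scenario) && !is.na(row$depth)) {
      rep(row$depth, row$n)
    } else rep(depth, row$n)
    for (i in seq_len(row$n)) {
      idx <- idx + 1L
      sid <- sprintf("%s_%s_%02d", row$dataset, row$haplogroup, i)
      p <- sim_params(mode = mode, true_h = hs[i], depth = ds[i])
      samples[[sid]] <- simulate_reads(genome, p, seed = seed + idx,
                                       sample_id = sid)
      meta[[idx]] <- data.frame(sample_id = sid, dataset = row$dataset,
                                haplogroup = row$haplogroup,
                                disease_status = status,
                                era = if (mode == "ancient") "ancient"
                                      else "present-day")
      truth[[idx]] <- data.frame(sample_id = sid, true_h = hs[i],
                                 depth = ds[i], mode = mode)
    }
  }
  list(meta = do.call(rbind, meta), truth = do.call(rbind, truth),
       samples = samples)
}
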