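#' Summarise heteroplasmy carriers by dataset and haplogroup
#'
#' Groups high-heteroplasmy carriers by `(dataset, haplogroup)` and reports
#' the carrier count, arithmetic mean heteroplasmy, and the standard error
#' of the mean. Following common reporting practice for small lineages, the
#' SEM column is only populated for groups with at least `min_n_for_sem`
#' carriers (the internal value is kept in `sem_internal`).
#'
#' @param calls Per-sample heteroplasmy calls: data frame with at least
#'   `sample_id`, `h`, `passes_high_het`.
#' @param meta Sample metadata: `sample_id`, `dataset`, `haplogroup`, and
#'   optionally `disease_status`, `era`, `pair_id`.
#' @param min_n_for_sem Minimum carriers for a reported SEM (default 4).
#' @param carriers_only If `TRUE` (default) only calls passing the
#'   high-heteroplasmy filter enter the summary, mirroring carrier-level
#'   reporting; set `FALSE` to summarise every sample.
#' @return A `CohortTable` data frame: `dataset`, `haplogroup`, `n_carriers`,
#'   `mean_h`, `sem_h` (NA below `min_n_for_sem`), `sem_internal`,
#'   `samples`. The carrier-level rows are attached as
#'   `attr(, "samples")` for downstream tests.
#' @export
summarize_by_haplogroup <- function(calls, meta, min_n_for_sem = 4L,
                                    carriers_only = TRUE) {
  stopifnot(is.data.frame(calls), is.data.frame(meta))
  if (!nrow(calls)) stop("no heteroplasmy calls supplied")
  missing_meta <- setdiff(calls$sample_id, meta$sample_id)
  if (length(missing_meta)) {
    stop("calls without sample metadata: ",
         paste(missing_meta, collapse = ", "))
  }
  d <- merge(calls, meta, by = "sample_id")
  if (carriers_only && "passes_high_het" %in% names(d)) {
    d <- d[d$passes_high_het, , drop = FALSE]
  }
  if (!nrow(d)) {
    out <- data.frame(dataset = character(), haplogroup = character(),
                      n_carriers = integer(), mean_h = numeric(),
                      sem_h = numeric(), sem_internal = numeric(),
                      samples = character())
    attr(out, "samples") <- d
    class(out) <- c("CohortTable", "data.frame")
    return(out)
  }
  key <- interaction(d$dataset, d$haplogroup, drop = TRUE)
  rows <- lapply(split(d, key), function(g) {
    n <- nrow(g)
    sem <- if (n >= 2) sd(g$h) / sqrt(n) else NA_real_
    data.frame(dataset = g$dataset[1], haplogroup = g$haplogroup[1],
               n_carriers = n, mean_h = mean(g$h),
               sem_h = if (n >= min_n_for_sem) sem else NA_real_,
               sem_internal = sem,
               samples = paste(sort(g$sample_id), collapse = ","))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$dataset, out$haplogroup), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "samples") <- d
  class(out) <- c("CohortTable", "data.frame")
  out
}

#' Pairwise heteroplasmy contrasts between haplogroup groups
#'
#' For every pair of eligible groups (at least `min_n` carriers) reports
#' both the least-squares-means style contrast — a one-way fixed-effects
#' linear model with pooled error variance, the pairwise t contrasts taken
#' with [emmeans::emmeans()], the single-factor completely-randomised-design
#' analogue of a SAS GLM analysis — and the exact [rank_sum_test()].
#' Raw p-values are flagged at `alpha` (no multiplicity correction, matching
#' the conventional reporting for this design); Holm-adjusted p-values are
#' emitted alongside.
#'
#' @param table A `CohortTable` from [summarize_by_haplogroup()] (its
#'   carrier-level attribute is used), or a data frame with `dataset`,
#'   `haplogroup`, `h` per sample.
#' @param alpha Significance level (default 0.05).
#' @param min_n Minimum group size for eligibility (default 4).
#' @return Data frame with one row per group pair: `group_a`, `group_b`,
#'   `diff`, `se`, `t`, `p_t`, `U`, `p_ranksum`, `p_t_holm`,
#'   `p_ranksum_holm`, `significant_t`, `significant_ranksum`; zero rows
#'   (with a message) when fewer than two groups are eligible.
#' @export
compare_haplogroups <- function(table, alpha = 0.05, min_n = 4L) {
  d <- if (inherits(table, "CohortTable")) attr(table, "samples") else table
  stopifnot(is.data.frame(d), all(c("dataset", "haplogroup", "h") %in% names(d)))
  empty <- data.frame(group_a = character(), group_b = character(),
                      diff = numeric(), se = numeric(), t = numeric(),
                      p_t = numeric(), U = numeric(), p_ranksum = numeric(),
                      p_t_holm = numeric(), p_ranksum_holm = numeric(),
                      significant_t = logical(),
                      significant_ranksum = logical())
  if (!nrow(d)) {
    message("no carrier-level data; nothing to compare")
    return(empty)
  }
  d$group <- paste(d$dataset, d$haplogroup, sep = ":")
  sizes <- table(d$group)
  eligible <- names(sizes)[sizes >= min_n]
  if (length(eligible) < 2L) {
    message("fewer than two groups with n >= ", min_n, "; nothing to compare")
    return(empty)
  }
  d <- d[d$group %in% eligible, , drop = FALSE]
  d$group <- factor(d$group)
  fit <- lm(h ~ group, data = d)
  emm <- suppressWarnings(emmeans::emmeans(fit, "group"))
  ctr <- suppressWarnings(
    as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                    adjust = "none")))
  degenerate <- stats::sigma(fit) < 1e-9 * max(abs(d$h), 1)
  # pairwise contrasts are emitted in combn(levels, 2) order
  pr <- combn(levels(d$group), 2)
  stopifnot(ncol(pr) == nrow(ctr))
  ga <- pr[1, ]; gb <- pr[2, ]
  rs <- mapply(function(a, b) {
    t <- suppressWarnings(rank_sum_test(d$h[d$group == a],
                                        d$h[d$group == b]))
    c(t$statistic, t$p.value)
  }, ga, gb)
  p_t <- ctr$p.value
  # zero pooled variance: identical values give p = 1, a real difference
  # with zero residual noise is (numerically) certain
  if (degenerate) {
    p_t <- ifelse(abs(ctr$estimate) < 1e-9 * max(abs(d$h), 1), 1, 0)
  }
  p_t[!is.finite(p_t)] <- 1
  out <- data.frame(group_a = ga, group_b = gb,
                    diff = ctr$estimate, se = ctr$SE, t = ctr$t.ratio,
                    p_t = p_t, U = rs[1, ], p_ranksum = rs[2, ])
  out$p_t_holm <- p.adjust(out$p_t, "holm")
  out$p_ranksum_holm <- p.adjust(out$p_ranksum, "holm")
  out$significant_t <- out$p_t <= alpha
  out$significant_ranksum <- out$p_ranksum <= alpha
  rownames(out) <- NULL
  out
}

#' Disease association of deletion heteroplasmy within each dataset
#'
#' Compares heteroplasmy between case and healthy samples of every dataset.
#' Samples without a call enter at h = 0 (absence of the event is
#' informative). Datasets with a complete pairing key (`pair_id`, e.g.
#' mother-offspring pairs) are tested with the exact [signed_rank_test()] on
#' within-pair differences; unpaired datasets use the exact
#' [rank_sum_test()]. Datasets lacking one of the two classes are skipped
#' with a notice.
#'
#' @param calls Per-sample calls (`sample_id`, `h`).
#' @param meta Metadata with `sample_id`, `dataset`, `disease_status`
#'   (`case`/`healthy`/`unknown`) and optionally `pair_id`.
#' @param alpha Significance level.
#' @return Data frame: `dataset`, `test`, `statistic`, `p`, `n_case`,
#'   `n_healthy`, `significant`.
#' @export
disease_association <- function(calls, meta, alpha = 0.05) {
  stopifnot(is.data.frame(meta), all(c("sample_id", "dataset",
                                       "disease_status") %in% names(meta)))
  h <- calls$h[match(meta$sample_id, calls$sample_id)]
  meta$h <- ifelse(is.na(h), 0, h)
  rows <- lapply(split(meta, meta$dataset), function(g) {
    cases <- g[g$disease_status == "case", , drop = FALSE]
    ctrl <- g[g$disease_status == "healthy", , drop = FALSE]
    if (!nrow(cases) || !nrow(ctrl)) {
      message("dataset ", g$dataset[1],
              ": single-class (no case/healthy contrast), skipped")
      return(NULL)
    }
    paired <- "pair_id" %in% names(g) && !anyNA(g$pair_id) &&
      all(cases$pair_id %in% ctrl$pair_id)
    if (paired) {
      diffs <- cases$h - ctrl$h[match(cases$pair_id, ctrl$pair_id)]
      t <- suppressWarnings(signed_rank_test(diffs))
      data.frame(dataset = g$dataset[1], test = "signed-rank (paired)",
                 statistic = unname(t$statistic), p = t$p.value,
                 n_case = nrow(cases), n_healthy = nrow(ctrl),
                 significant = t$p.value <= alpha)
    } else {
      t <- suppressWarnings(rank_sum_test(cases$h, ctrl$h))
      data.frame(dataset = g$dataset[1], test = "rank-sum",
                 statistic = unname(t$statistic), p = t$p.value,
                 n_case = nrow(cases), n_healthy = nrow(ctrl),
                 significant = t$p.value <= alpha)
    }
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(dataset = character(), test = character(),
                      statistic = numeric(), p = numeric(),
                      n_case = integer(), n_healthy = integer(),
                      significant = logical()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bar plot of mean heteroplasmy by haplogroup
#'
#' Optional figure: mean heteroplasmy per `(dataset, haplogroup)` group with
#' SEM error bars where reported. Requires ggplot2.
#'
#' @param table A `CohortTable`.
#' @return A ggplot object.
#' @export
plot_cohort <- function(table) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  stopifnot(inherits(table, "CohortTable"))
  d <- as.data.frame(table)
  ggplot2::ggplot(d, ggplot2::aes(x = haplogroup, y = mean_h)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = mean_h - sem_h, ymax = mean_h + sem_h),
      width = 0.3, na.rm = TRUE) +
    ggplot2::geom_text(ggplot2::aes(label = n_carriers), vjust = -0.5) +
    ggplot2::facet_grid(~dataset, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "haplogroup", y = "mean heteroplasmy") +
    ggplot2::theme_minimal()
}
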