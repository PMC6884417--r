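#' High/low count ratio for one twin pair and germ layer
#'
#' The arithmetic ratio of the higher cell count over the lower
#' (C-high/C-low): near 1 indicates a balanced allocation between twin and
#' co-twin, well above 1 an imbalance. Order-symmetric by construction.
#' Degenerate pairs are flagged rather than forced into a number: a zero low
#' count with a positive high count is `"unbounded"`, a both-zero pair is
#' `"undefined"`; both are excluded from ratio summaries and tallied
#' separately.
#'
#' @param count_a,count_b non-negative integer cell counts of the two members.
#' @return list: `c_high`, `c_low`, `ratio` (`NA` unless status `"ok"`),
#'   `status` in `"ok"`, `"unbounded"`, `"undefined"`.
#' @examples
#' high_low_ratio(6, 3)   # ratio 2
#' high_low_ratio(4, 0)   # unbounded
#' @export
high_low_ratio <- function(count_a, count_b) {
  for (v in list(count_a, count_b))
    if (!.is_count(v))
      .stopf("counts must be non-negative integers (got %s)", format(v))
  hi <- max(count_a, count_b); lo <- min(count_a, count_b)
  if (hi == 0) list(c_high = 0L, c_low = 0L, ratio = NA_real_,
                    status = "undefined")
  else if (lo == 0) list(c_high = as.integer(hi), c_low = 0L,
                         ratio = NA_real_, status = "unbounded")
  else list(c_high = as.integer(hi), c_low = as.integer(lo),
            ratio = hi / lo, status = "ok")
}

#' Per-pair, per-layer C-high/C-low ratios of a lineage count table
#'
#' @param table a lineage count table (see [generate_twin_counts()]); intact
#'   control rows are ignored.
#' @return `data.frame` with one row per pair and germ layer: `pair_id`,
#'   `layer` (`cdx2`, `sox17`, `nanog`), `c_high`, `c_low`, `ratio`, `status`.
#' @export
pair_ratios <- function(table) {
  tw <- table[table$member %in% c("a", "b"), ]
  if (nrow(tw) == 0L) .stopf("no twin rows in table")
  bad <- names(which(table(tw$pair_id) != 2))
  if (length(bad))
    .stopf("pair(s) without exactly 2 members: %s", paste(bad, collapse = ", "))
  out <- list()
  for (pid in unique(tw$pair_id)) {
    pr <- tw[tw$pair_id == pid, ]
    for (layer in c("cdx2", "sox17", "nanog")) {
      r <- high_low_ratio(pr[[layer]][1], pr[[layer]][2])
      out[[length(out) + 1L]] <- data.frame(
        pair_id = pid, layer = layer, c_high = r$c_high, c_low = r$c_low,
        ratio = r$ratio, status = r$status)
    }
  }
  do.call(rbind, out)
}

#' Proportion of blastocysts with a sufficient epiblast
#'
#' Classifies each blastocyst by whether its NANOG-positive (EPI) count
#' reaches the threshold regarded as a prerequisite for post-blastocyst
#' development (default 4 cells, an absolute criterion), per group
#' (treatment x twin/intact). Proportions are normalized to the number of
#' blastocysts, not the number of cells. An optional total-cell-count filter
#' (`min_total`, e.g. 50) is applied first; a group emptied by the filter is
#' reported as absent, not as 0/0.
#'
#' @param table a lineage count table.
#' @param threshold minimum EPI (NANOG) count deemed sufficient.
#' @param min_total optional minimum total cell count per blastocyst.
#' @return `data.frame`: `group`, `n`, `n_sufficient`, `proportion`.
#' @export
epi_sufficiency <- function(table, threshold = 4L, min_total = NULL) {
  if (nrow(table) == 0L) .stopf("empty count table")
  if (!.is_count(threshold)) .stopf("threshold must be a non-negative integer")
  tab <- as.data.frame(table)
  if (!is.null(min_total)) tab <- tab[tab$total >= min_total, ]
  if (nrow(tab) == 0L)
    return(data.frame(group = character(0), n = integer(0),
                      n_sufficient = integer(0), proportion = numeric(0)))
  grp <- paste(tab$treatment,
               ifelse(tab$member == "intact", "intact", "twin"))
  agg <- lapply(split(tab, grp), function(g)
    data.frame(group = unique(paste(g$treatment,
                                    ifelse(g$member[1] == "intact", "intact",
                                           "twin"))),
               n = nrow(g), n_sufficient = sum(g$nanog >= threshold),
               proportion = mean(g$nanog >= threshold)))
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Singleton / complete-pair accounting of per-pair endpoints
#'
#' Given one record per twin pair with a boolean endpoint for each member
#' (e.g. "gave rise to a pup", "formed a mature egg-cylinder structure"),
#' tallies pairs where both members reached the endpoint (complete /
#' concordant), exactly one did (singleton / discordant) and neither did.
#' The headline percentage is the singleton share among represented pairs,
#' `100 * n_singleton / (n_complete + n_singleton)`.
#'
#' @param records `data.frame` with logical columns `a` and `b` (one row per
#'   pair), or a 2-column logical matrix.
#' @return list of class `"pair_outcome_summary"`: `n_pairs_total`,
#'   `n_complete`, `n_singleton`, `n_neither`,
#'   `pct_singleton_among_represented`, plus concordance fractions over all
#'   pairs (`pct_concordant`, `pct_discordant`, `pct_neither`).
#' @examples
#' # 46 pups of which 16 form 8 complete pairs, 30 singletons, out of 143
#' recs <- rbind(matrix(TRUE, 8, 2),
#'               cbind(rep(TRUE, 30), rep(FALSE, 30)),
#'               matrix(FALSE, 105, 2))
#' pair_outcomes(recs)
#' @export
pair_outcomes <- function(records) {
  m <- as.matrix(as.data.frame(records)[, c(1, 2)])
  if (!is.logical(m)) {
    if (!all(m %in% c(0, 1))) .stopf("endpoints must be logical")
    m <- m > 0
  }
  both <- rowSums(m)
  n_complete <- sum(both == 2L)
  n_singleton <- sum(both == 1L)
  n_neither <- sum(both == 0L)
  n_rep <- n_complete + n_singleton
  structure(list(
    n_pairs_total = nrow(m), n_complete = n_complete,
    n_singleton = n_singleton, n_neither = n_neither,
    pct_singleton_among_represented =
      if (n_rep > 0) round(100 * n_singleton / n_rep, 1) else NA_real_,
    pct_concordant = round(100 * n_complete / nrow(m), 1),
    pct_discordant = round(100 * n_singleton / nrow(m), 1),
    pct_neither = round(100 * n_neither / nrow(m), 1)),
    class = "pair_outcome_summary")
}

#' @export
print.pair_outcome_summary <- function(x, ...) {
  cat(sprintf("<pair outcomes> %d pairs: %d complete, %d singleton, %d neither\n",
              x$n_pairs_total, x$n_complete, x$n_singleton, x$n_neither))
  cat(sprintf("  singletons among represented pairs: %.1f%%\n",
              x$pct_singleton_among_represented))
  invisible(x)
}

#' Fisher exact test of an observed vs expected pair allocation
#'
#' Two-sided Fisher exact test of the 2x2 table `rbind(observed,
#' expected_alternative)` — e.g. an observed 8:30 split of complete vs
#' incomplete pairs against the 38:0 split expected were every pair
#' developmentally complete in both members.
#'
#' @param observed integer vector `c(a, b)`.
#' @param expected_alternative integer vector `c(c, d)`.
#' @return the two-sided p-value.
#' @export
allocation_test <- function(observed, expected_alternative) {
  cells <- c(observed, expected_alternative)
  if (length(cells) != 4L || any(!vapply(cells, .is_count, logical(1))))
    .stopf("both arguments must be pairs of non-negative integer counts")
  if (sum(cells) == 0) .stopf("all-zero table")
  stats::fisher.test(rbind(observed, expected_alternative))$p.value
}

#' Bisection survival percentage
#'
#' Percentage of bisections in which both blastomeres survived, rounded to
#' one decimal.
#'
#' @param n_bisected number of bisections performed.
#' @param n_both_survived number with both blastomeres intact afterwards.
#' @return percentage (one decimal).
#' @examples
#' survival_summary(1624, 1584)   # 97.5
#' @export
survival_summary <- function(n_bisected, n_both_survived) {
  if (!.is_count(n_bisected) || !.is_count(n_both_survived))
    .stopf("counts must be non-negative integers")
  if (n_bisected == 0) .stopf("zero bisections: percentage undefined")
  if (n_both_survived > n_bisected)
    .stopf("survivors (%d) exceed bisections (%d)", n_both_survived, n_bisected)
  round(100 * n_both_survived / n_bisected, 1)
}

#' Compare twin-pair summed totals with intact-control totals
#'
#' Convenience two-sample t-test of the per-pair (twin + co-twin) total cell
#' count against intact control totals — the check that bisection conserves
#' the summed cell number.
#'
#' @param table a lineage count table containing both twin and intact rows.
#' @return `htest` object from [stats::t.test()].
#' @export
half_sum_vs_intact <- function(table) {
  tw <- table[table$member %in% c("a", "b"), ]
  ic <- table[table$member == "intact", ]
  if (nrow(ic) == 0L) .stopf("table has no intact control rows")
  pair_sums <- tapply(tw$total, tw$pair_id, sum)
  stats::t.test(pair_sums, ic$total)
}
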