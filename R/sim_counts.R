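#' Parameters for the twin lineage-count generator
#'
#' Describes blastocyst pairs obtained by bisecting 2-cell embryos and
#' culturing twin and co-twin apart, scored for the three germ layers:
#' trophectoderm (CDX2), primitive endoderm (SOX17) and epiblast (NANOG).
#' The generative model:
#' \itemize{
#'   \item pair total `T ~ round(Normal(mu_total, sigma_total))`, truncated
#'     at 2, so the expected twin + co-twin sum equals `mu_total`;
#'   \item germ-layer totals: largest-remainder apportionment of `T` by
#'     `lineage_fractions` (deterministic given `T`);
#'   \item trophectoderm split: twin fraction `~ Normal(0.5, te_split_sd)`,
#'     truncated to \[0, 1\];
#'   \item epiblast split: twin fraction `q ~ Beta(1/beta, 1/beta)` with
#'     `beta = epi_imbalance_beta`; `beta = 0` means an exactly balanced
#'     split. The primitive endoderm split reuses `q`, reflecting the
#'     FGF4-mediated dependence of PE formation on the EPI.
#' }
#' The default `epi_imbalance_beta = 0.46` was calibrated by Monte Carlo at
#' `n_pairs = 1000` so the median per-pair EPI C-high/C-low ratio is
#' approximately 2 while the median trophectoderm ratio stays below 1.2 —
#' the imbalance structure the analysis is designed to detect.
#'
#' @param n_pairs number of twin pairs.
#' @param mu_total mean total cell count of a reconstituted pair
#'   (twin + co-twin).
#' @param sigma_total SD of the pair total.
#' @param lineage_fractions mean fractions of (TE, PE, EPI); must sum to 1.
#' @param epi_imbalance_beta imbalance dial >= 0 (0 = balanced EPI split).
#' @param te_split_sd SD of the trophectoderm twin fraction around 0.5.
#' @param n_intact number of intact (non-bisected) control blastocysts whose
#'   totals are drawn from the same `Normal(mu_total, sigma_total)`.
#' @param seed integer RNG seed.
#' @return a validated list of class `"count_sim_params"`.
#' @export
count_sim_params <- function(n_pairs = 36L,
                             mu_total = 60,
                             sigma_total = 10,
                             lineage_fractions = c(te = 0.65, pe = 0.20,
                                                   epi = 0.15),
                             epi_imbalance_beta = 0.46,
                             te_split_sd = 0.04,
                             n_intact = 0L,
                             seed = 1L) {
  if (!.is_count(n_pairs) || n_pairs < 1) .stopf("n_pairs must be a positive integer")
  if (!.is_count(n_intact)) .stopf("n_intact must be a non-negative integer")
  if (!is.numeric(mu_total) || mu_total < 2) .stopf("mu_total must be >= 2")
  if (!is.numeric(sigma_total) || sigma_total < 0) .stopf("sigma_total must be >= 0")
  if (length(lineage_fractions) != 3L || any(lineage_fractions < 0) ||
      abs(sum(lineage_fractions) - 1) > 1e-8)
    .stopf("lineage_fractions must be 3 non-negative values summing to 1")
  if (!is.numeric(epi_imbalance_beta) || epi_imbalance_beta < 0)
    .stopf("epi_imbalance_beta must be >= 0")
  if (!is.numeric(te_split_sd) || te_split_sd < 0)
    .stopf("te_split_sd must be >= 0")
  names(lineage_fractions) <- c("te", "pe", "epi")
  structure(list(n_pairs = as.integer(n_pairs), mu_total = mu_total,
                 sigma_total = sigma_total,
                 lineage_fractions = lineage_fractions,
                 epi_imbalance_beta = epi_imbalance_beta,
                 te_split_sd = te_split_sd, n_intact = as.integer(n_intact),
                 seed = as.integer(seed)),
            class = "count_sim_params")
}

# largest-remainder apportionment of total n into parts with given fractions
.apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

#' Generate a synthetic twin lineage-count table
#'
#' Produces a per-blastocyst count table with two rows per pair (members
#' `"a"` and `"b"`) and optionally intact control rows, with CDX2 / SOX17 /
#' NANOG counts drawn from the model described in [count_sim_params()].
#'
#' @param params a [count_sim_params()] object.
#' @param treatment label stored in the `treatment` column (e.g. a culture
#'   medium name).
#' @return a `data.frame` of class `c("lineage_count_table", "data.frame")`
#'   with columns `embryo_id`, `pair_id`, `member`, `treatment`, `cdx2`,
#'   `sox17`, `nanog`, `total`.
#' @examples
#' tab <- generate_twin_counts(count_sim_params(n_pairs = 5, seed = 3))
#' head(tab)
#' @export
generate_twin_counts <- function(params, treatment = "KSOM") {
  if (!inherits(params, "count_sim_params"))
    .stopf("params must come from count_sim_params()")
  set.seed(params$seed)
  n <- params$n_pairs
  totals <- pmax(2, round(stats::rnorm(n, params$mu_total,
                                       params$sigma_total)))
  a_epi <- if (params$epi_imbalance_beta > 0) {
    shp <- 1 / params$epi_imbalance_beta
    stats::rbeta(n, shp, shp)
  } else rep(0.5, n)
  p_te <- pmin(1, pmax(0, stats::rnorm(n, 0.5, params$te_split_sd)))

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    layer <- .apportion(totals[i], params$lineage_fractions)
    te_a <- round(p_te[i] * layer[1])
    pe_a <- round(a_epi[i] * layer[2])   # PE split coupled to the EPI split
    epi_a <- round(a_epi[i] * layer[3])
    rows[[i]] <- data.frame(
      embryo_id = paste0(i, c("a", "b")),
      pair_id = i, member = c("a", "b"), treatment = treatment,
      cdx2 = c(te_a, layer[1] - te_a),
      sox17 = c(pe_a, layer[2] - pe_a),
      nanog = c(epi_a, layer[3] - epi_a))
  }
  tab <- do.call(rbind, rows)
  if (params$n_intact > 0) {
    it <- pmax(2, round(stats::rnorm(params$n_intact, params$mu_total,
                                     params$sigma_total)))
    irows <- lapply(seq_len(params$n_intact), function(i) {
      layer <- .apportion(it[i], params$lineage_fractions)
      data.frame(embryo_id = paste0("intact", i), pair_id = NA_integer_,
                 member = "intact", treatment = treatment,
                 cdx2 = layer[1], sox17 = layer[2], nanog = layer[3])
    })
    tab <- rbind(tab, do.call(rbind, irows))
  }
  tab$total <- tab$cdx2 + tab$sox17 + tab$nanog
  class(tab) <- c("lineage_count_table", "data.frame")
  rownames(tab) <- NULL
  tab
}
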