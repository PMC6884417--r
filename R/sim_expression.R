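#' Parameters for the blastomere-pair expression generator
#'
#' Emulates the statistical structure of sister-blastomere transcriptomes:
#' a gene x sample matrix for `n_pairs` 2-cell embryos, two blastomeres per
#' embryo, with a shared between-pair effect and an independent within-pair
#' deviation, both on the log2 scale (log-normal expression; no
#' platform-specific microarray noise model — clustering and CV behaviour,
#' not platform realism, is what downstream analyses consume). A designated
#' subset of genes receives a 10x inflated within-pair SD, emulating
#' transcripts whose abundance diverges between sister blastomeres.
#'
#' @param n_pairs number of blastomere pairs (default 9, matching a typical
#'   blastomere-pair transcriptome series).
#' @param n_genes number of genes.
#' @param pair_effect_sd between-pair SD on the log2 scale (shared by both
#'   members of a pair, per gene).
#' @param within_pair_sd per-member within-pair SD on the log2 scale; the SD
#'   of the log2 member difference is `sqrt(2)` times this value.
#' @param high_cv_genes integer indices of genes given 10x `within_pair_sd`.
#' @param seed integer RNG seed.
#' @return a validated list of class `"expr_sim_params"`.
#' @export
expr_sim_params <- function(n_pairs = 9L,
                            n_genes = 2000L,
                            pair_effect_sd = 0.25,
                            within_pair_sd = 0.25,
                            high_cv_genes = integer(0),
                            seed = 1L) {
  if (!.is_count(n_pairs) || n_pairs < 1) .stopf("n_pairs must be a positive integer")
  if (!.is_count(n_genes) || n_genes < 1) .stopf("n_genes must be a positive integer")
  if (!is.numeric(pair_effect_sd) || pair_effect_sd < 0)
    .stopf("pair_effect_sd must be >= 0")
  if (!is.numeric(within_pair_sd) || within_pair_sd < 0)
    .stopf("within_pair_sd must be >= 0")
  high_cv_genes <- as.integer(high_cv_genes)
  if (length(high_cv_genes) &&
      (any(high_cv_genes < 1) || any(high_cv_genes > n_genes)))
    .stopf("high_cv_genes must be gene indices in 1..n_genes")
  structure(list(n_pairs = as.integer(n_pairs), n_genes = as.integer(n_genes),
                 pair_effect_sd = pair_effect_sd,
                 within_pair_sd = within_pair_sd,
                 high_cv_genes = high_cv_genes, seed = as.integer(seed)),
            class = "expr_sim_params")
}

#' Generate a synthetic blastomere-pair expression matrix
#'
#' @param params an [expr_sim_params()] object.
#' @return a numeric gene x sample matrix (non-negative expression). Columns
#'   are named `"<pair><letter>"` (`"1a"`, `"1b"`, `"2a"`, ...); rows are
#'   named `g0001`, `g0002`, ... The hidden pair labels are attached as
#'   `attr(x, "pair_labels")` (integer per column).
#' @examples
#' m <- generate_expression_pairs(expr_sim_params(n_pairs = 4, n_genes = 50))
#' dim(m)
#' @export
generate_expression_pairs <- function(params) {
  if (!inherits(params, "expr_sim_params"))
    .stopf("params must come from expr_sim_params()")
  set.seed(params$seed)
  ng <- params$n_genes; np <- params$n_pairs
  sd_g <- rep(params$within_pair_sd, ng)
  sd_g[params$high_cv_genes] <- 10 * params$within_pair_sd
  baseline <- stats::rnorm(ng, mean = 6, sd = 2)          # log2 abundance
  pair_eff <- matrix(stats::rnorm(ng * np, 0, params$pair_effect_sd), ng, np)
  log2x <- matrix(0, ng, 2L * np)
  for (p in seq_len(np)) {
    mu <- baseline + pair_eff[, p]
    for (m in 1:2) {
      j <- 2L * (p - 1L) + m
      log2x[, j] <- mu + stats::rnorm(ng, 0, sd_g)
    }
  }
  x <- 2^log2x
  colnames(x) <- paste0(rep(seq_len(np), each = 2), rep(c("a", "b"), np))
  rownames(x) <- sprintf("g%04d", seq_len(ng))
  attr(x, "pair_labels") <- rep(seq_len(np), each = 2)
  x
}
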