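#' Interblastomere expression ratios and CV ranking
#'
#' For every gene, the expression ratio between the two sister blastomeres of
#' each pair, always dividing the higher value by the lower. Genes are then
#' summarized by the mean ratio across pairs and the coefficient of variation
#' of the ratios (CV = sample SD / mean) and ranked by CV (rank 1 = highest
#' CV, ties broken by gene order). Transcripts whose abundance differs
#' erratically between sister cells surface at the top of this ranking.
#' Pairs with a zero expression value for a gene yield an unbounded ratio:
#' they are excluded from that gene's mean and CV and tallied in
#' `n_unbounded`.
#'
#' @param matrix numeric gene x sample matrix; column names identify samples
#'   as `"<embryo><letter>"` (`"7a"`, `"7b"`) so each embryo number appears
#'   exactly twice.
#' @param gene_subset optional character vector of gene ids (or integer
#'   indices) restricting the summary, e.g. an EPI-related panel.
#' @return `data.frame`, one row per gene: `gene`, `n_pairs_used`,
#'   `n_unbounded`, `mean_ratio`, `cv`, `cv_rank`.
#' @export
interblastomere_ratios <- function(matrix, gene_subset = NULL) {
  if (is.null(colnames(matrix))) .stopf("matrix must have sample labels as colnames")
  embryo <- sub("[ab]$", "", colnames(matrix))
  counts <- table(embryo)
  bad <- names(counts)[counts != 2]
  if (length(bad))
    .stopf("unpaired sample label(s): embryo %s", paste(bad, collapse = ", "))
  if (!is.null(gene_subset)) matrix <- matrix[gene_subset, , drop = FALSE]
  pairs <- unique(embryo)
  a_idx <- match(pairs, embryo)
  b_idx <- length(embryo) + 1L - match(pairs, rev(embryo))

  hi <- pmax(matrix[, a_idx, drop = FALSE], matrix[, b_idx, drop = FALSE])
  lo <- pmin(matrix[, a_idx, drop = FALSE], matrix[, b_idx, drop = FALSE])
  ratios <- hi / lo
  ratios[lo == 0] <- NA          # unbounded: excluded, tallied separately

  mean_ratio <- rowMeans(ratios, na.rm = TRUE)
  n_used <- rowSums(!is.na(ratios))
  sds <- apply(ratios, 1, stats::sd, na.rm = TRUE)
  cv <- ifelse(n_used >= 2 & mean_ratio > 0, sds / mean_ratio, NA_real_)
  out <- data.frame(gene = rownames(matrix), n_pairs_used = n_used,
                    n_unbounded = length(pairs) - n_used,
                    mean_ratio = mean_ratio, cv = cv)
  ord <- order(-out$cv, seq_len(nrow(out)), na.last = TRUE)
  out$cv_rank <- NA_integer_
  out$cv_rank[ord] <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# sibling sample pairs of an hclust tree: merges joining two singletons
.dendrogram_siblings <- function(hc) {
  singleton <- hc$merge[, 1] < 0 & hc$merge[, 2] < 0
  cbind(-hc$merge[singleton, 1], -hc$merge[singleton, 2])
}

#' Twin-pair recovery by hierarchical clustering
#'
#' Agglomerative clustering of the samples; a pair counts as recovered if and
#' only if its two members are dendrogram siblings, i.e. merged with each
#' other before either merges with anything else. This sibling criterion —
#' not the metric — carries the meaning of "the clustering returned the
#' original pair associations". Defaults: Euclidean distance on per-feature
#' z-scored values with average linkage for count vectors; (1 - Pearson
#' correlation) distance with average linkage for expression matrices.
#' Agglomeration ties are broken deterministically (lowest-index merge
#' first), so repeated runs are identical.
#'
#' @param values numeric feature x sample matrix (an even number of sample
#'   columns, at least 2 pairs).
#' @param pair_labels vector, one label per sample column; each label occurs
#'   exactly twice.
#' @param distance `"euclidean"` (with optional per-feature z-scoring) or
#'   `"correlation"` (1 - Pearson).
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @param standardize z-score each feature across samples before Euclidean
#'   distances (ignored for correlation distance, which is scale-free).
#' @return list of class `"pair_recovery_result"`: `n_pairs`, `n_recovered`,
#'   `fraction_recovered`, `recovered_pairs`, `linkage_record` (the hclust
#'   merge history).
#' @export
cluster_pair_recovery <- function(values, pair_labels,
                                  distance = c("euclidean", "correlation"),
                                  linkage = "average",
                                  standardize = TRUE) {
  distance <- match.arg(distance)
  values <- as.matrix(values)
  ns <- ncol(values)
  if (ns %% 2L != 0L) .stopf("sample count must be even")
  if (length(pair_labels) != ns)
    .stopf("pair_labels length (%d) != sample count (%d)", length(pair_labels), ns)
  if (any(table(pair_labels) != 2L)) .stopf("each pair label must occur exactly twice")
  n_pairs <- ns %/% 2L
  if (n_pairs < 2L) .stopf("need at least 2 pairs")

  if (distance == "euclidean") {
    x <- values
    if (standardize) {
      sds <- apply(x, 1, stats::sd)
      mus <- rowMeans(x)
      keep <- sds > 0
      x <- (x - mus) / ifelse(sds > 0, sds, 1)
      x[!keep, ] <- 0
    }
    d <- stats::dist(t(x))
  } else {
    d <- stats::as.dist(1 - stats::cor(values))
  }

  dm <- as.matrix(d)
  same_pair <- outer(pair_labels, pair_labels, `==`)
  if (any(dm[!same_pair & upper.tri(dm)] == 0))
    .warnf("identical samples across different pairs: sibling assignment relies on deterministic tie-breaks")

  hc <- stats::hclust(d, method = linkage)
  sib <- .dendrogram_siblings(hc)
  recovered <- sib[pair_labels[sib[, 1]] == pair_labels[sib[, 2]], ,
                   drop = FALSE]
  structure(list(n_pairs = n_pairs, n_recovered = nrow(recovered),
                 fraction_recovered = nrow(recovered) / n_pairs,
                 recovered_pairs = unique(pair_labels[recovered[, 1]]),
                 linkage_record = hc$merge),
            class = "pair_recovery_result")
}

#' @export
print.pair_recovery_result <- function(x, ...) {
  cat(sprintf("<pair recovery> %d / %d pairs recovered (%.1f%%)\n",
              x$n_recovered, x$n_pairs, 100 * x$fraction_recovered))
  invisible(x)
}

#' Null distribution of the pair-recovery fraction
#'
#' Empirical chance-level reference: recovery fractions of
#' [cluster_pair_recovery()] applied to matrices of i.i.d. standard normal
#' features carrying no pair effect whatsoever.
#'
#' @param n_pairs number of pairs per replicate.
#' @param n_features number of i.i.d. features.
#' @param reps number of replicates (>= 100).
#' @param seed integer RNG seed (reproducible: same seed, same distribution).
#' @param ... further arguments to [cluster_pair_recovery()].
#' @return list: `fractions` (length `reps`), `mean`, `quantiles`
#'   (2.5/50/97.5%).
#' @export
recovery_null <- function(n_pairs, n_features, reps = 1000L, seed = 1L, ...) {
  if (!.is_count(reps) || reps < 100) .stopf("reps must be an integer >= 100")
  if (!.is_count(n_pairs) || n_pairs < 1) .stopf("n_pairs must be >= 1")
  set.seed(seed)
  labels <- rep(seq_len(n_pairs), each = 2)
  fr <- vapply(seq_len(reps), function(i) {
    x <- matrix(stats::rnorm(n_features * 2 * n_pairs), n_features)
    if (n_pairs == 1L) return(1)   # two samples are forcibly siblings
    cluster_pair_recovery(x, labels, ...)$fraction_recovered
  }, numeric(1))
  list(fractions = fr, mean = mean(fr),
       quantiles = stats::quantile(fr, c(0.025, 0.5, 0.975)))
}
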