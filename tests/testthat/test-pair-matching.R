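test_that("interblastomere ratio summaries match hand arithmetic", {
  # identical expression in every pair: all ratios 1, CV 0, ties by gene order
  m <- matrix(rep(c(3, 3, 7, 7, 2, 2), each = 4), nrow = 4, byrow = FALSE)
  colnames(m) <- c("1a", "1b", "2a", "2b", "3a", "3b")
  rownames(m) <- paste0("g", 1:4)
  ir <- interblastomere_ratios(m)
  expect_true(all(ir$mean_ratio == 1))
  expect_true(all(ir$cv == 0))
  expect_equal(ir$cv_rank, 1:4)

  # toy gene with per-pair ratios {1, 2, 3}: mean 2, sample SD 1, CV 0.5
  toy <- rbind(g1 = c(4, 4, 4, 8, 4, 12), g2 = c(5, 5, 5, 5, 5, 5))
  colnames(toy) <- c("1a", "1b", "2a", "2b", "3a", "3b")
  ir2 <- interblastomere_ratios(toy)
  expect_equal(ir2$mean_ratio[1], 2)
  expect_equal(ir2$cv[1], 0.5)
  expect_equal(ir2$cv_rank[1], 1)

  # zero expression: unbounded ratio excluded and tallied
  toy0 <- rbind(g1 = c(0, 4, 2, 8, 4, 12))
  colnames(toy0) <- colnames(toy)
  ir3 <- interblastomere_ratios(toy0)
  expect_equal(ir3$n_unbounded, 1)
  expect_equal(ir3$n_pairs_used, 2)
  expect_equal(ir3$mean_ratio, mean(c(4, 3)))

  # unpaired sample is named in the error
  bad <- toy; colnames(bad) <- c("1a", "1b", "2a", "2b", "3a", "4b")
  expect_error(interblastomere_ratios(bad), "3")
})

test_that("a high-variability gene ranks first by CV in >= 95% of 200 seeds", {
  hits <- vapply(1:200, function(s) {
    m <- generate_expression_pairs(
      expr_sim_params(n_pairs = 9, n_genes = 80, high_cv_genes = 17L,
                      seed = s))
    ir <- interblastomere_ratios(m)
    ir$gene[ir$cv_rank == 1] == "g0017"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("pair recovery is exact in the zero-noise limit and label-invariant", {
  set.seed(5)
  centres <- matrix(stats::rnorm(6 * 5, sd = 3), 6, 5)
  x <- centres[, rep(1:5, each = 2)]      # each pair duplicated exactly
  colnames(x) <- paste0(rep(1:5, each = 2), c("a", "b"))
  labels <- rep(1:5, each = 2)
  rec <- cluster_pair_recovery(x, labels)
  expect_equal(rec$fraction_recovered, 1.0)

  # invariance under sample permutation and pair relabelling
  perm <- sample(10)
  rec_p <- cluster_pair_recovery(x[, perm], labels[perm])
  expect_equal(rec_p$fraction_recovered, 1.0)
  rec_r <- cluster_pair_recovery(x, c(9, 9, 4, 4, 7, 7, 1, 1, 2, 2))
  expect_equal(rec_r$fraction_recovered, 1.0)

  # scaling standardized data leaves the merge order identical
  set.seed(6)
  y <- matrix(stats::rnorm(8 * 12), 8, 12)
  lab <- rep(1:6, each = 2)
  r1 <- cluster_pair_recovery(y, lab)
  r2 <- cluster_pair_recovery(2 * y, lab)
  expect_identical(r1$linkage_record, r2$linkage_record)

  # duplicates across different pairs warn but stay well-defined
  dup <- cbind(x, x[, 1:2])
  expect_warning(
    rec_d <- cluster_pair_recovery(dup, c(labels, 6, 6)),
    "identical samples")
  expect_true(rec_d$n_recovered <= rec_d$n_pairs)

  expect_error(cluster_pair_recovery(x[, 1:3], labels[1:3]), "even")
  expect_error(cluster_pair_recovery(x[, 1:2], labels[1:2]), "2 pairs")
})

test_that("chance-level recovery of 9 i.i.d. pairs matches an independent oracle", {
  reps <- 400
  labels <- rep(1:9, each = 2)
  set.seed(31)
  impl <- vapply(seq_len(reps), function(i) {
    x <- matrix(stats::rnorm(4 * 18), 4, 18)
    cluster_pair_recovery(x, labels)$fraction_recovered
  }, numeric(1))
  set.seed(87)
  orac <- vapply(seq_len(reps), function(i) {
    x <- matrix(stats::rnorm(4 * 18), 4, 18)
    # oracle operates on the same standardization as the implementation
    xs <- t(scale(t(x)))
    oracle_recovery_fraction(xs, labels)
  }, numeric(1))
  se <- sqrt(stats::var(impl) / reps + stats::var(orac) / reps)
  expect_lt(abs(mean(impl) - mean(orac)), 2 * se)
})

test_that("the recovery null distribution behaves as derived", {
  # a single pair is forcibly recovered
  n1 <- recovery_null(n_pairs = 1, n_features = 3, reps = 100, seed = 4)
  expect_true(all(n1$fractions == 1))

  # same seed, same distribution
  a <- recovery_null(4, 5, reps = 120, seed = 9)
  b <- recovery_null(4, 5, reps = 120, seed = 9)
  expect_identical(a$fractions, b$fractions)

  # n_pairs = 2: mean matches a brute-force agglomeration oracle
  n2 <- recovery_null(2, 4, reps = 1000, seed = 15)
  set.seed(99)
  orac <- vapply(1:1000, function(i) {
    x <- matrix(stats::rnorm(4 * 4), 4, 4)
    oracle_recovery_fraction(t(scale(t(x))), c(1, 1, 2, 2))
  }, numeric(1))
  se <- sqrt(stats::var(n2$fractions) / 1000 + stats::var(orac) / 1000)
  expect_lt(abs(n2$mean - mean(orac)), 3 * se)

  expect_error(recovery_null(3, 4, reps = 50), ">= 100")
})
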