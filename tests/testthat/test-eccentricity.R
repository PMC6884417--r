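test_that("uniform intensity gives exactly zero eccentricity", {
  img <- matrix(2.5, 20, 20)
  masks <- list(matrix(TRUE, 20, 20),
                blastoquant:::.disk_mask(20, 20, 9.5, 9.5, 7),
                blastoquant:::.disk_mask(20, 20, 5, 12, 4))
  for (m in masks) {
    e <- eccentricity(img, roi(m, kind = "oocyte", label = "u"))
    expect_lt(e$E_px, 1e-9)
  }
})

test_that("the hand-computed 3x3 case is reproduced", {
  img <- matrix(1, 3, 3)
  img[3, 3] <- 10   # (x = 2, y = 2) in 0-based coordinates
  e <- eccentricity(img, roi(matrix(TRUE, 3, 3), kind = "oocyte", label = "t"))
  expect_equal(unname(e$centroid), c(1, 1))
  expect_equal(unname(e$centre_of_mass), c(1.5, 1.5))
  expect_equal(e$E_px, sqrt(0.5), tolerance = 1e-12)
})

test_that("implementation matches the per-pixel summation oracle on 100 random cases", {
  set.seed(101)
  for (i in 1:100) {
    nr <- sample(3:9, 1); nc <- sample(3:9, 1)
    img <- matrix(stats::runif(nr * nc, 0.1, 5), nr, nc)
    mask <- matrix(stats::runif(nr * nc) < 0.7, nr, nc)
    if (sum(mask) < 2) mask[1:2] <- TRUE
    e <- eccentricity(img, roi(mask, kind = "oocyte", label = "r"))
    o <- ecc_oracle(img, mask)
    expect_lt(abs(e$E_px - o$E), 1e-9)
    expect_lt(max(abs(e$centroid - o$centroid)), 1e-9)
    expect_lt(max(abs(e$centre_of_mass - o$com)), 1e-9)
  }
})

test_that("eccentricity is scale invariant and detects degenerate input", {
  set.seed(7)
  img <- matrix(stats::runif(64, 0, 3), 8, 8)
  m <- roi(matrix(TRUE, 8, 8), kind = "oocyte", label = "s")
  e1 <- eccentricity(img, m)
  for (cst in c(0.25, 3, 1000))
    expect_equal(eccentricity(cst * img, m)$E_px, e1$E_px, tolerance = 1e-12)
  # zero total intensity is an error, not E = 0
  expect_error(eccentricity(matrix(0, 8, 8), m), "zero total intensity")
  # mask not matching the image frame
  expect_error(eccentricity(img, roi(matrix(TRUE, 9, 9), kind = "oocyte",
                                     label = "x")), "bounds")
})

test_that("eccentricity is equivariant under grid rotations and translations", {
  set.seed(11)
  n <- 12
  img <- matrix(stats::runif(n * n, 0, 4), n, n)
  mask <- blastoquant:::.disk_mask(n, n, (n - 1) / 2, (n - 1) / 2, 5)
  e0 <- eccentricity(img, roi(mask, kind = "oocyte", label = "0"))

  rot90 <- function(m) t(m[nrow(m):1, ])   # exact grid rotation
  img_r <- img; mask_r <- mask; prev <- e0
  for (k in 1:3) {
    img_r <- rot90(img_r); mask_r <- rot90(mask_r)
    ek <- eccentricity(img_r, roi(mask_r, kind = "oocyte", label = "r"))
    expect_lt(abs(ek$E_px - e0$E_px), 1e-9)
    # the delta vector rotates with the grid: (dx, dy) -> (-dy, dx)
    expect_lt(max(abs(ek$delta - c(-prev$delta[["dy"]], prev$delta[["dx"]]))),
              1e-9)
    prev <- ek
  }

  # integer translation into a larger frame leaves E unchanged exactly
  big <- matrix(0, n + 7, n + 9)
  big[4 + seq_len(n), 6 + seq_len(n)] <- img
  bmask <- matrix(FALSE, n + 7, n + 9)
  bmask[4 + seq_len(n), 6 + seq_len(n)] <- mask
  et <- eccentricity(big, roi(bmask, kind = "oocyte", label = "t"))
  expect_equal(et$E_px, e0$E_px, tolerance = 1e-12)
})

test_that("an added constant background strictly dilutes eccentricity", {
  set.seed(13)
  img <- matrix(stats::runif(100, 0, 2), 10, 10)
  img[3:5, 6:8] <- img[3:5, 6:8] + 6   # non-uniform
  m <- roi(matrix(TRUE, 10, 10), kind = "oocyte", label = "b")
  es <- vapply(c(0, 1, 2, 5, 10),
               function(b) eccentricity(img + b, m)$E_px, numeric(1))
  expect_true(all(diff(es) < 0))
})

test_that("group comparison reproduces exact rank-sum enumeration", {
  # identical groups: p = 1
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  # fully separated small groups: exact two-sided p by exhaustive enumeration
  a <- c(1, 2, 3); b <- c(10, 11, 12)
  g <- compare_groups(a, b)
  pooled <- c(a, b)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[1:3])
  combos <- utils::combn(6, 3)
  w_all <- apply(combos, 2, function(idx) sum(ranks[idx]))
  mu <- mean(w_all)
  p_enum <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
  expect_equal(g$p_value, p_enum)
  expect_equal(g$p_value, 0.1)

  expect_error(compare_groups(c(1, 2), c(3, 4, 5)), "n >= 3")
})

test_that("batch eccentricity yields one deterministic row per ROI", {
  specs <- lapply(1:4, function(s)
    make_specimen(small_two_cell_params(s, "gradient", 0.6, n_spots = 250),
                  id = paste0("e", s)))
  b1 <- batch_eccentricity(specs, level = "blastomere",
                           roi_mode = "ground_truth")
  expect_equal(nrow(b1), 8)               # 2 blastomeres per embryo
  expect_true(all(b1$kind == "blastomere"))
  b2 <- batch_eccentricity(specs, level = "blastomere",
                           roi_mode = "ground_truth")
  expect_identical(b1, b2)                # bit-level determinism
  b3 <- batch_eccentricity(specs, level = "embryo")
  expect_equal(nrow(b3), 4)
  expect_true(all(b3$kind == "whole_embryo"))
})

test_that("gradient batches show higher eccentricity than uniform batches", {
  grad <- lapply(1:8, function(s)
    make_specimen(small_oocyte_params(s, "gradient", 0.8, n_spots = 200)))
  unif <- lapply(9:13, function(s)
    make_specimen(small_oocyte_params(s, n_spots = 200)))
  b <- batch_eccentricity(c(grad, unif), level = "oocyte",
                          roi_mode = "ground_truth")
  eg <- b$E_px[1:8]; eu <- b$E_px[9:13]
  expect_gt(stats::median(eg), stats::median(eu))
  # generator-truth oracle: the gradient group's truth offset is positive
  expect_gt(grad[[1]]$truth$density_com_offset$offset_px, 0)
  expect_identical(unif[[1]]$truth$density_com_offset$offset_px, 0)
})
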