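test_that("stacks round-trip through TIFF + sidecar bit-identically", {
  sim <- generate_embryo_stack(small_oocyte_params(13, n_spots = 150))
  f <- withr::local_tempfile(fileext = ".tif")
  write_stack(sim$stack, f)
  s2 <- load_stack(f)
  expect_identical(s2$voxels, sim$stack$voxels)
  expect_identical(s2$channel_names, c("FISH", "DAPI"))
  expect_equal(s2$slice_interval_um, 0.22)
  expect_equal(s2$pixel_size_um, sim$stack$pixel_size_um)
})

test_that("corrupt or incomplete stack files fail loudly, without partial objects", {
  sim <- generate_embryo_stack(small_oocyte_params(13, n_spots = 50))
  f <- withr::local_tempfile(fileext = ".tif")
  write_stack(sim$stack, f)
  # missing sidecar
  file.remove(paste0(f, ".yml"))
  expect_error(load_stack(f), "sidecar")
  # sidecar missing a required field
  yaml::write_yaml(list(pixel_size_um = 0.2, channel_names = list("FISH", "DAPI"),
                        n_slices = 12, image_shape = list(96L, 96L)),
                   paste0(f, ".yml"))
  expect_error(load_stack(f), "slice_interval_um")
  # truncated TIFF
  write_stack(sim$stack, f)
  raw_bytes <- readBin(f, "raw", file.info(f)$size)
  writeBin(raw_bytes[seq_len(1000)], f)
  expect_error(load_stack(f))
})

test_that("equatorial projection selects a window and takes per-pixel maxima", {
  # span bookkeeping: 10 slices at 0.222 um
  v <- array(stats::runif(8 * 8 * 12 * 1), dim = c(8, 8, 12, 1))
  st <- zstack(v, "FISH", pixel_size_um = 0.2, slice_interval_um = 0.222)
  pr <- equatorial_projection(st, "FISH", 10)
  expect_equal(pr$span_um, 2.22)

  # brute-force triple-loop oracle on a 4x4x4 single-channel stack
  set.seed(42)
  v <- array(stats::runif(4 * 4 * 4), dim = c(4, 4, 4, 1))
  st <- zstack(v, "FISH", 0.2, 0.22)
  pr <- equatorial_projection(st, "FISH", 4)
  manual <- matrix(0, 4, 4)
  for (r in 1:4) for (c in 1:4) for (z in 1:4)
    manual[r, c] <- max(manual[r, c], v[r, c, z, 1])
  expect_equal(pr$pixels, manual)

  # constant stack projects to the same constant
  vc <- array(7, dim = c(5, 5, 6, 1))
  prc <- equatorial_projection(zstack(vc, "FISH", 0.2, 0.22), "FISH", 3)
  expect_true(all(prc$pixels == 7))

  # projecting a single-slice stack is the identity
  v1 <- array(stats::runif(6 * 6), dim = c(6, 6, 1, 1))
  pr1 <- equatorial_projection(zstack(v1, "FISH", 0.2, 0.22), "FISH", 1)
  expect_equal(pr1$pixels, v1[, , 1, 1])

  expect_error(equatorial_projection(zstack(v1, "FISH", 0.2, 0.22), "FISH", 5),
               "fewer")
})

test_that("the projection window is centred on the maximal-area slice", {
  # foreground blob only on slices 7..9, largest cross-section on slice 8
  v <- array(0, dim = c(32, 32, 12, 1))
  for (z in 7:9) {
    r <- c(3, 8, 3)[z - 6]
    m <- blastoquant:::.disk_mask(32, 32, 15, 15, r)
    v[, , z, 1][m] <- 100
  }
  st <- zstack(v, "FISH", 0.2, 0.22)
  pr <- equatorial_projection(st, "FISH", 4)
  expect_true(8 %in% pr$source_slices)
  expect_equal(length(pr$source_slices), 4)
})

test_that("orientation aligns the long axis with the y-axis (moments oracle)", {
  nr <- 121; nc <- 121
  xg <- blastoquant:::.xgrid(nr, nc); yg <- blastoquant:::.ygrid(nr, nc)
  mk_ellipse <- function(deg_from_y) {
    th <- deg_from_y * pi / 180
    u <- (xg - 60) * sin(th) + (yg - 60) * cos(th)
    v <- -(xg - 60) * cos(th) + (yg - 60) * sin(th)
    (u / 40)^2 + (v / 15)^2 <= 1
  }
  proj_of <- function(mask) blastoquant:::.projection(mask * 1.0, 1L, 0.22, "FISH")

  # already aligned: angle ~ 0
  aligned <- mk_ellipse(0)
  o0 <- orient_long_axis(proj_of(aligned), aligned)
  expect_lt(abs(o0$rotation_angle), 0.5)

  # drawn 30 degrees from the y-axis: detected magnitude 30 +- 1, and the
  # rotated mask's major axis is y-parallel per an independent moments oracle
  tilted <- mk_ellipse(30)
  o30 <- orient_long_axis(proj_of(tilted), tilted)
  expect_lt(abs(abs(o30$rotation_angle) - 30), 1)
  post <- blastoquant:::.mask_orientation(o30$embryo_mask)
  expect_lt(abs(abs(post$angle) - 90), 1)

  # orientation is involution-consistent: re-orienting gives ~ 0
  o_again <- orient_long_axis(o30$projection, o30$embryo_mask)
  expect_lt(abs(o_again$rotation_angle), 0.5)

  # total intensity conserved within 1% (content fits the frame)
  expect_lt(abs(sum(o30$projection$pixels) / sum(tilted) - 1), 0.01)

  # degenerate circular mask: tie-break angle 0 with a warning
  circ <- blastoquant:::.disk_mask(nr, nc, 60, 60, 25)
  expect_warning(oc <- orient_long_axis(proj_of(circ), circ), "circular")
  expect_equal(oc$rotation_angle, 0)
})

test_that("ROI derivation matches generator masks", {
  p <- small_two_cell_params(3, n_spots = 3000, psf_sigma_px = 0.8,
                             background_level = 0, poisson_noise = FALSE)
  sim <- generate_embryo_stack(p)
  fish <- equatorial_projection(sim$stack, "FISH", 10)
  dapi <- equatorial_projection(sim$stack, "DAPI", 10)

  # ground truth mode: IoU 1 by construction
  gt <- derive_rois(fish, dapi, mode = "ground_truth",
                    truth_masks = sim$truth$cell_masks, geometry = "two_cell")
  expect_length(gt, 2)
  expect_identical(gt[[1]]$mask, sim$truth$cell_masks[[1]])

  # segment mode: exactly 2 disjoint components, areas within 5% of truth,
  # inside the embryo neighbourhood
  seg <- derive_rois(fish, dapi, mode = "segment", geometry = "two_cell")
  expect_length(seg, 2)
  truth_area <- sum(sim$truth$cell_masks[[1]])
  for (k in 1:2)
    expect_lt(abs(sum(seg[[k]]$mask) / truth_area - 1), 0.05)
  expect_false(any(seg[[1]]$mask & seg[[2]]$mask))

  # oocyte circle fit covers >= 99% of the true mask
  po <- small_oocyte_params(4, n_spots = 3000, radius = 45, shape = c(140, 140),
                            psf_sigma_px = 0.8, background_level = 0,
                            poisson_noise = FALSE)
  so <- generate_embryo_stack(po)
  fo <- equatorial_projection(so$stack, "FISH", 10)
  cf <- derive_rois(fo, equatorial_projection(so$stack, "DAPI", 10),
                    mode = "circle_fit", geometry = "oocyte")
  cover <- sum(cf[[1]]$mask & so$truth$cell_masks[[1]]) /
    sum(so$truth$cell_masks[[1]])
  expect_gte(cover, 0.99)
  expect_equal(cf[[1]]$shape_spec$type, "circle")
})

test_that("batch normalization applies one shared bound pair", {
  mk <- function(seed) equatorial_projection(
    generate_embryo_stack(small_oocyte_params(seed, n_spots = 100))$stack,
    "FISH", 10)
  a <- mk(1); b <- mk(2)

  # identical inputs give identical outputs
  nn <- normalize_intensity(list(a, a))
  expect_identical(nn[[1]]$pixels, nn[[2]]$pixels)

  # all pixels in [0, 1], shared bounds recorded
  nab <- normalize_intensity(list(a, b))
  expect_true(all(vapply(nab, function(p) all(p$pixels >= 0 & p$pixels <= 1),
                         logical(1))))
  expect_identical(nab[[1]]$normalization, nab[[2]]$normalization)

  # scale invariance of percentile normalization
  a2 <- a; a2$pixels <- 2 * a$pixels
  b2 <- b; b2$pixels <- 2 * b$pixels
  n2 <- normalize_intensity(list(a2, b2))
  expect_equal(n2[[1]]$pixels, nab[[1]]$pixels, tolerance = 1e-12)

  # degenerate constant batch maps to 0 with a warning
  cst <- a; cst$pixels[] <- 3
  expect_warning(nc <- normalize_intensity(list(cst)), "degenerate")
  expect_true(all(nc[[1]]$pixels == 0))

  expect_error(normalize_intensity(list(a), bounds = c(5, 2)), "low < high")
})
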