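# Small phantom constructors shared across test files. Geometry is scaled
# down from the acquisition defaults so a full pipeline run takes
# milliseconds; the acceptance suite exercises near-acquisition scale.

small_oocyte_params <- function(seed, distribution = "uniform",
                                gradient_strength = 0, n_spots = 400,
                                radius = 30, shape = c(96, 96),
                                background_level = 2, read_noise_sd = 0,
                                psf_sigma_px = 1.0, n_slices = 12, ...) {
  image_sim_params(image_shape = shape, n_slices = n_slices,
                   geometry = "oocyte", blastomere_radii_px = radius,
                   n_spots = n_spots, distribution = distribution,
                   gradient_strength = gradient_strength,
                   psf_sigma_px = psf_sigma_px,
                   background_level = background_level,
                   read_noise_sd = read_noise_sd, seed = seed, ...)
}

small_two_cell_params <- function(seed, distribution = "uniform",
                                  gradient_strength = 0, n_spots = 400,
                                  radius = 36, shape = c(176, 176),
                                  background_level = 2, read_noise_sd = 0,
                                  psf_sigma_px = 1.0, n_slices = 12, ...) {
  image_sim_params(image_shape = shape, n_slices = n_slices,
                   geometry = "two_cell", blastomere_radii_px = radius,
                   n_spots = n_spots, distribution = distribution,
                   gradient_strength = gradient_strength,
                   psf_sigma_px = psf_sigma_px,
                   background_level = background_level,
                   read_noise_sd = read_noise_sd, seed = seed, ...)
}

make_specimen <- function(params, id = NULL) {
  sim <- generate_embryo_stack(params)
  list(stack = sim$stack, truth = sim$truth, id = id)
}

# independent per-pixel summation oracle for the eccentricity statistic
ecc_oracle <- function(img, mask) {
  sx <- 0; sy <- 0; n <- 0; sw <- 0; swx <- 0; swy <- 0
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    if (mask[r, c]) {
      x <- c - 1; y <- r - 1; w <- img[r, c]
      n <- n + 1; sx <- sx + x; sy <- sy + y
      sw <- sw + w; swx <- swx + w * x; swy <- swy + w * y
    }
  }
  list(centroid = c(sx / n, sy / n), com = c(swx / sw, swy / sw),
       E = sqrt((swx / sw - sx / n)^2 + (swy / sw - sy / n)^2))
}

# independent average-linkage agglomeration returning sibling index pairs
# (straight O(n^3) loop over the original distance matrix)
oracle_siblings <- function(x) {
  d <- as.matrix(stats::dist(t(x)))
  clusters <- as.list(seq_len(ncol(x)))
  singleton <- rep(TRUE, ncol(x))
  sibs <- NULL
  while (length(clusters) > 1L) {
    best <- c(Inf, 0L, 0L)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      dij <- mean(d[clusters[[i]], clusters[[j]]])
      if (dij < best[1]) best <- c(dij, i, j)
    }
    i <- best[2]; j <- best[3]
    if (singleton[i] && singleton[j])
      sibs <- rbind(sibs, c(clusters[[i]], clusters[[j]]))
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    singleton[i] <- FALSE
    clusters <- clusters[-j]; singleton <- singleton[-j]
  }
  sibs
}

oracle_recovery_fraction <- function(x, labels) {
  sibs <- oracle_siblings(x)
  if (is.null(sibs)) return(0)
  sum(labels[sibs[, 1]] == labels[sibs[, 2]]) / (length(labels) / 2)
}
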