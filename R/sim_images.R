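#' Parameters for the synthetic confocal stack generator
#'
#' Describes an Airyscan-like, post-deconvolution two-channel acquisition of a
#' single MII oocyte or a 2-cell embryo, with a configurable spatial
#' distribution of mRNA FISH spots. Defaults emulate the acquisition geometry
#' of the study conditions: 512 x 512-pixel slices at a 0.22 um slice
#' interval, the FISH channel imaged together with a DAPI counterstain.
#'
#' Spatial distribution families (all defined over each cell's cross-sectional
#' disk of radius r; `gradient_strength` g in \[0, 1\] sets the inhomogeneity,
#' g = 0 reduces every family to uniform):
#' \describe{
#'   \item{uniform}{constant spot density.}
#'   \item{gradient}{linear ramp along a random (seeded) in-plane direction,
#'     density proportional to 1 + g u / r with u the signed coordinate along
#'     the ramp.}
#'   \item{cortical}{annular shell: weight (1 - g) inside, 1 within the outer
#'     25\% annulus. Radially symmetric, so its density centre of mass stays
#'     on the centroid — inhomogeneous yet zero-eccentricity by design.}
#'   \item{polarized_cap}{von-Mises-weighted angular density, concentration
#'     4 g, towards a random (seeded) direction.}
#' }
#'
#' @param image_shape integer vector `c(nrow, ncol)` of each slice.
#' @param n_slices number of z slices.
#' @param slice_interval_um axial step, micrometres.
#' @param pixel_size_um lateral pixel size, micrometres.
#' @param geometry `"oocyte"` (one cell) or `"two_cell"` (two touching
#'   blastomeres side by side).
#' @param blastomere_radii_px cell radius per cell, pixels. Default: 180 for
#'   an oocyte, `c(115, 115)` for a 2-cell embryo.
#' @param n_spots expected FISH spot count per cell (Poisson).
#' @param distribution spatial density family, see Details.
#' @param gradient_strength dimensionless inhomogeneity in \[0, 1\].
#' @param psf_sigma_px isotropic in-plane Gaussian spot width, pixels.
#' @param spot_photons photons per rendered spot.
#' @param background_level mean background, photons.
#' @param poisson_noise apply Poisson shot noise.
#' @param read_noise_sd Gaussian read noise SD, photons.
#' @param injected_cell_factor spot-count multiplier applied to the first
#'   blastomere only (emulates the mRNA-microinjection specificity control).
#' @param rnase_mode if TRUE the FISH channel carries background only
#'   (emulates the RNase specificity control: no hybridizable transcript).
#' @param seed integer RNG seed; identical seeds give bit-identical stacks.
#' @return a validated parameter list of class `"image_sim_params"`.
#' @export
image_sim_params <- function(image_shape = c(512L, 512L),
                             n_slices = 20L,
                             slice_interval_um = 0.22,
                             pixel_size_um = 0.2,
                             geometry = c("two_cell", "oocyte"),
                             blastomere_radii_px = NULL,
                             n_spots = 2000,
                             distribution = c("uniform", "gradient",
                                              "cortical", "polarized_cap"),
                             gradient_strength = 0.5,
                             psf_sigma_px = 1.2,
                             spot_photons = 150,
                             background_level = 5,
                             poisson_noise = TRUE,
                             read_noise_sd = 2,
                             injected_cell_factor = 1,
                             rnase_mode = FALSE,
                             seed = 1L) {
  geometry <- match.arg(geometry)
  distribution <- match.arg(distribution)
  if (is.null(blastomere_radii_px))
    blastomere_radii_px <- if (geometry == "oocyte") 180 else c(115, 115)
  n_cells <- if (geometry == "oocyte") 1L else 2L
  if (length(blastomere_radii_px) == 1L)
    blastomere_radii_px <- rep(blastomere_radii_px, n_cells)
  if (length(blastomere_radii_px) != n_cells)
    .stopf("geometry '%s' needs %d radii, got %d", geometry, n_cells,
           length(blastomere_radii_px))
  num_pos <- c(slice_interval_um = slice_interval_um,
               pixel_size_um = pixel_size_um, spot_photons = spot_photons)
  for (nm in names(num_pos))
    if (!is.numeric(num_pos[[nm]]) || num_pos[[nm]] <= 0)
      .stopf("%s must be positive", nm)
  num_nonneg <- c(n_spots = n_spots, gradient_strength = gradient_strength,
                  psf_sigma_px = psf_sigma_px,
                  background_level = background_level,
                  read_noise_sd = read_noise_sd,
                  injected_cell_factor = injected_cell_factor)
  for (nm in names(num_nonneg))
    if (!is.numeric(num_nonneg[[nm]]) || !is.finite(num_nonneg[[nm]]) ||
        num_nonneg[[nm]] < 0)
      .stopf("%s must be a non-negative number", nm)
  if (gradient_strength > 1) .stopf("gradient_strength must be in [0, 1]")
  if (any(blastomere_radii_px <= 0)) .stopf("cell radii must be positive")
  if (length(image_shape) != 2L || any(image_shape < 8))
    .stopf("image_shape must be c(nrow, ncol), each >= 8")
  if (!.is_count(n_slices) || n_slices < 1) .stopf("n_slices must be a positive integer")
  if (!.is_count(abs(seed))) .stopf("seed must be an integer")

  structure(list(image_shape = as.integer(image_shape),
                 n_slices = as.integer(n_slices),
                 slice_interval_um = slice_interval_um,
                 pixel_size_um = pixel_size_um,
                 geometry = geometry,
                 blastomere_radii_px = blastomere_radii_px,
                 n_spots = n_spots,
                 distribution = distribution,
                 gradient_strength = gradient_strength,
                 psf_sigma_px = psf_sigma_px,
                 spot_photons = spot_photons,
                 background_level = background_level,
                 poisson_noise = isTRUE(poisson_noise),
                 read_noise_sd = read_noise_sd,
                 injected_cell_factor = injected_cell_factor,
                 rnase_mode = isTRUE(rnase_mode),
                 seed = as.integer(seed)),
            class = "image_sim_params")
}

# density weight in [0, 1] at in-plane offsets (dx, dy) from the cell centre;
# phi is the seeded ramp / cap direction
.density_weight <- function(dx, dy, radius, distribution, g, phi) {
  switch(distribution,
    uniform = rep(1, length(dx)),
    gradient = {
      u <- dx * cos(phi) + dy * sin(phi)
      (1 + g * u / radius) / (1 + g)
    },
    cortical = {
      rho <- sqrt(dx^2 + dy^2)
      (1 - g) + g * (rho >= 0.75 * radius)
    },
    polarized_cap = {
      theta <- atan2(dy, dx)
      exp(4 * g * (cos(theta - phi) - 1))
    })
}

# analytic (numerically integrated) centre-of-mass offset of the density over
# the cell disk, in pixels; sub-pixel quadrature grid
.density_com_offset <- function(radius, distribution, g, phi, step = 0.25) {
  if (distribution %in% c("uniform", "cortical") || g == 0)
    return(list(vector = c(dx = 0, dy = 0), offset_px = 0))
  s <- seq(-radius, radius, by = step)
  dx <- rep(s, times = length(s))
  dy <- rep(s, each = length(s))
  inside <- dx^2 + dy^2 <= radius^2
  dx <- dx[inside]; dy <- dy[inside]
  w <- .density_weight(dx, dy, radius, distribution, g, phi)
  v <- c(dx = sum(w * dx) / sum(w), dy = sum(w * dy) / sum(w))
  list(vector = v, offset_px = sqrt(sum(v^2)))
}

# rejection-sample n spot positions from the in-plane density (0-based coords)
.sample_spots <- function(n, cx, cy, radius, distribution, g, phi) {
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n) {
    m <- max(2L * (n - length(xs)), 64L)
    rho <- radius * sqrt(stats::runif(m))
    th <- stats::runif(m, 0, 2 * pi)
    dx <- rho * cos(th); dy <- rho * sin(th)
    keep <- stats::runif(m) <
      .density_weight(dx, dy, radius, distribution, g, phi)
    xs <- c(xs, cx + dx[keep]); ys <- c(ys, cy + dy[keep])
  }
  cbind(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

# add Gaussian spot images to a (nr, nc, nz) volume, in place semantics via
# return. Spots occupy one z slice plus Gaussian spread over +-2 slices.
.render_spots <- function(vol, x, y, z, sigma, photons) {
  if (length(x) == 0L) return(vol)
  nr <- dim(vol)[1]; nc <- dim(vol)[2]; nz <- dim(vol)[3]
  R <- max(2L, ceiling(4 * sigma))
  zw <- stats::dnorm(-2:2); zw <- zw / sum(zw)
  for (i in seq_along(x)) {
    x0 <- x[i]; y0 <- y[i]
    cols <- max(1L, floor(x0) - R + 1L):min(nc, ceiling(x0) + R + 1L)
    rows <- max(1L, floor(y0) - R + 1L):min(nr, ceiling(y0) + R + 1L)
    gx <- exp(-((cols - 1L - x0)^2) / (2 * sigma^2))
    gy <- exp(-((rows - 1L - y0)^2) / (2 * sigma^2))
    stamp <- (gy %o% gx)
    stamp <- stamp * (photons / sum(stamp))
    for (dz in -2:2) {
      zi <- z[i] + dz
      if (zi >= 1L && zi <= nz)
        vol[rows, cols, zi] <- vol[rows, cols, zi] + stamp * zw[dz + 3L]
    }
  }
  vol
}

#' Generate a synthetic two-channel embryo or oocyte z-stack
#'
#' Renders a FISH + DAPI confocal stack of one oocyte or one 2-cell embryo:
#' spot positions are sampled from the configured spatial density within each
#' cell's cross-sectional disk, convolved with an isotropic Gaussian PSF
#' (spread over +-2 neighbouring slices axially), then background, Poisson
#' shot noise and Gaussian read noise are applied and intensities quantized
#' to a 16-bit camera range. Alongside the stack, the ground truth needed to
#' validate downstream measurements is returned: per-cell masks, nucleus
#' masks, 3-d spot positions and the analytic offset of the spot-density
#' centre of mass from each cell centroid.
#'
#' @param params an [image_sim_params()] object.
#' @return list with elements `stack` (a [zstack()]) and `truth` (class
#'   `"ground_truth"`: `cell_masks`, `nucleus_masks`, `spot_positions`,
#'   `density_com_offset`, `ramp_direction`).
#' @examples
#' p <- image_sim_params(image_shape = c(96, 96), n_slices = 12,
#'                       geometry = "oocyte", blastomere_radii_px = 30,
#'                       n_spots = 200, seed = 42)
#' sim <- generate_embryo_stack(p)
#' sim$stack
#' @export
generate_embryo_stack <- function(params) {
  if (!inherits(params, "image_sim_params"))
    .stopf("params must come from image_sim_params()")
  nr <- params$image_shape[1]; nc <- params$image_shape[2]
  nz <- params$n_slices
  rads <- params$blastomere_radii_px
  cy <- (nr - 1) / 2
  if (params$geometry == "oocyte") {
    centres <- cbind(x = (nc - 1) / 2, y = cy)
  } else {
    cx <- (nc - 1) / 2
    centres <- cbind(x = c(cx - rads[1], cx + rads[2]), y = c(cy, cy))
  }
  # cells must fit inside the frame
  for (k in seq_len(nrow(centres))) {
    if (centres[k, "x"] - rads[k] < 0 || centres[k, "x"] + rads[k] > nc - 1 ||
        centres[k, "y"] - rads[k] < 0 || centres[k, "y"] + rads[k] > nr - 1)
      .stopf("cell %d (radius %.1f px) overlaps the image frame boundary", k,
             rads[k])
  }

  set.seed(params$seed)
  phi <- stats::runif(1, 0, 2 * pi)   # seeded in-plane direction

  fish <- array(0, dim = c(nr, nc, nz))
  spots <- vector("list", nrow(centres))
  offsets <- vector("list", nrow(centres))
  cell_masks <- vector("list", nrow(centres))
  nucleus_masks <- vector("list", nrow(centres))
  dapi <- array(0, dim = c(nr, nc, nz))
  xg <- .xgrid(nr, nc); yg <- .ygrid(nr, nc)

  for (k in seq_len(nrow(centres))) {
    ckx <- centres[k, "x"]; cky <- centres[k, "y"]; r <- rads[k]
    cell_masks[[k]] <- .disk_mask(nr, nc, ckx, cky, r)
    rn <- 0.32 * r
    nucleus_masks[[k]] <- .disk_mask(nr, nc, ckx, cky, rn)
    # soft-edged nucleus, constant across slices
    rho <- sqrt((xg - ckx)^2 + (yg - cky)^2)
    nuc <- 400 / (1 + exp((rho - rn) / 1.5))
    for (z in seq_len(nz)) dapi[, , z] <- dapi[, , z] + nuc

    mult <- if (k == 1L) params$injected_cell_factor else 1
    n_k <- if (params$rnase_mode) 0L else stats::rpois(1, params$n_spots * mult)
    if (n_k > 0) {
      xy <- .sample_spots(n_k, ckx, cky, r, params$distribution,
                          params$gradient_strength, phi)
      z <- sample.int(nz, n_k, replace = TRUE)
      spots[[k]] <- data.frame(cell = k, x = xy[, "x"], y = xy[, "y"], z = z)
      fish <- .render_spots(fish, xy[, "x"], xy[, "y"], z,
                            params$psf_sigma_px, params$spot_photons)
    } else {
      spots[[k]] <- data.frame(cell = integer(0), x = numeric(0),
                               y = numeric(0), z = integer(0))
    }
    off <- .density_com_offset(r, params$distribution,
                               params$gradient_strength, phi)
    offsets[[k]] <- data.frame(cell = k, dx = off$vector[["dx"]],
                               dy = off$vector[["dy"]],
                               offset_px = off$offset_px)
  }

  fish <- fish + params$background_level
  dapi <- dapi + params$background_level
  if (params$poisson_noise) {
    fish[] <- stats::rpois(length(fish), fish)
    dapi[] <- stats::rpois(length(dapi), dapi)
  }
  if (params$read_noise_sd > 0) {
    fish <- fish + stats::rnorm(length(fish), 0, params$read_noise_sd)
    dapi <- dapi + stats::rnorm(length(dapi), 0, params$read_noise_sd)
  }
  # 16-bit camera quantization
  fish <- pmin(round(pmax(fish, 0)), 65535)
  dapi <- pmin(round(pmax(dapi, 0)), 65535)

  voxels <- array(0, dim = c(nr, nc, nz, 2L))
  voxels[, , , 1L] <- fish
  voxels[, , , 2L] <- dapi
  stack <- zstack(voxels, c("FISH", "DAPI"),
                  pixel_size_um = params$pixel_size_um,
                  slice_interval_um = params$slice_interval_um)
  truth <- structure(list(cell_masks = cell_masks,
                          nucleus_masks = nucleus_masks,
                          spot_positions = do.call(rbind, spots),
                          density_com_offset = do.call(rbind, offsets),
                          ramp_direction = phi,
                          params = params),
                     class = "ground_truth")
  list(stack = stack, truth = truth)
}
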