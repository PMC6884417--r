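# Shared internal helpers.
#
# Coordinate convention used throughout: 0-based, x = column index increasing
# rightward, y = row index increasing downward, pixel centres at integer
# coordinates. All centroid / centre-of-mass arithmetic uses this convention.

# x (column) coordinates of every pixel of an nr x nc image, as a matrix
.xgrid <- function(nr, nc) matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)

.ygrid <- function(nr, nc) matrix(rep(seq_len(nr) - 1, nc), nr, nc)

# boolean disk mask; (cx, cy) in 0-based pixel coordinates
.disk_mask <- function(nr, nc, cx, cy, radius) {
  (.xgrid(nr, nc) - cx)^2 + (.ygrid(nr, nc) - cy)^2 <= radius^2
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.warnf <- function(...) warning(sprintf(...), call. = FALSE)

.is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)
}

# Otsu threshold of an arbitrary numeric array: maximize the between-class
# variance over a 256-bin histogram (direct tabulate-based scan; called per
# specimen, so kept allocation-light)
.otsu <- function(v, levels = 256L) {
  v <- as.numeric(v)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  bin <- pmin(floor((v - rng[1]) / (rng[2] - rng[1]) * levels) + 1L, levels)
  h <- as.numeric(tabulate(bin, nbins = levels))
  w1 <- cumsum(h)
  m1 <- cumsum(h * seq_len(levels))
  tot <- w1[levels]; mtot <- m1[levels]
  w2 <- tot - w1
  between <- (mtot * w1 - m1 * tot)^2 / (w1 * w2)
  between[w1 == 0 | w2 == 0] <- -Inf
  k <- which.max(between)     # split after bin k
  rng[1] + (k / levels) * (rng[2] - rng[1])
}

# map an angle in degrees into (-90, 90]
.wrap_half <- function(a) {
  a <- a %% 180
  if (a > 90) a <- a - 180
  a
}
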