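# Shared fixtures, all built in code.

# Coarse grid + kinetics used throughout the oxygen tests (keeps runs fast
# while staying >= 3 nodes per layer).
coarse_res <- function() domain_resolution(nx = 31, nz_medium = 12, nz_tissue = 8)

# Image with a centred disk of given radius (value inside = fg).
disk_image <- function(size, radius, fg = 0.8, bg = 0.05) {
  x <- matrix(seq_len(size), size, size)
  y <- t(x)
  img <- matrix(bg, size, size)
  img[(x - size / 2)^2 + (y - size / 2)^2 <= radius^2] <- fg
  img
}

# Gaussian spot centred at (cx, cy).
gaussian_spot <- function(size, cx, cy, sigma = 2.5) {
  x <- matrix(seq_len(size), size, size)
  y <- t(x)
  exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma^2))
}

# Image with n well-separated Gaussian nuclei on a jittered grid
# (guarantees the separation without rejection sampling).
nuclei_image <- function(size = 128, n = 12, seed = 4) {
  side <- ceiling(sqrt(n))
  pitch <- (size - 30) / side
  stopifnot(pitch > 12)
  grid <- expand.grid(i = seq_len(side), j = seq_len(side))[seq_len(n), ]
  withr::with_seed(seed, {
    ctr <- cbind(
      round(15 + (grid$i - 0.5) * pitch + stats::runif(n, -2, 2)),
      round(15 + (grid$j - 0.5) * pitch + stats::runif(n, -2, 2))
    )
  })
  img <- matrix(0, size, size)
  for (i in seq_len(n)) img <- img + gaussian_spot(size, ctr[i, 1], ctr[i, 2])
  list(img = img, centers = ctr)
}
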