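# Shared fixtures: everything is generated in code at test time.

tiny_phantom_spec <- function(seed = 11L, lesion_count = 1L, ...) {
  phantom_spec(image_size = 32L, n_slices = 4L, lesion_count = lesion_count,
               seed = seed, ...)
}

disk_image <- function(n = 64L, radius = 15, inside_hu = 0, outside_hu = -1000) {
  ctr <- (n + 1) / 2
  x <- matrix(seq_len(n), n, n)
  y <- t(x)
  r <- sqrt((x - ctr)^2 + (y - ctr)^2)
  img <- matrix(outside_hu, n, n)
  img[r <= radius] <- inside_hu
  attr(img, "r") <- r
  img
}

tiny_generator <- function(seed = 3L, ...) {
  cyclect:::with_seed(seed, cyclect:::build_generator(
    generator_spec(n_res_blocks = 1L, base_channels = 2L, n_down = 1L, ...)))
}

tiny_discriminator <- function(seed = 4L) {
  cyclect:::with_seed(seed, cyclect:::build_discriminator(
    discriminator_spec(n_layers = 2L, base_channels = 2L)))
}

# brute-force GLCM co-occurrence oracle: exhaustive loop over voxel pairs
brute_glcm_counts <- function(levels, ng, dx, dy, dz) {
  d <- dim(levels)
  counts <- matrix(0, ng, ng)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    a <- levels[x, y, z]
    if (is.na(a)) next
    for (s in c(1, -1)) {
      x2 <- x + s * dx; y2 <- y + s * dy; z2 <- z + s * dz
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3]) next
      b <- levels[x2, y2, z2]
      if (is.na(b)) next
      counts[a, b] <- counts[a, b] + 1
    }
  }
  counts
}

# exhaustive rank-sum null distribution for small n (no ties assumed)
exact_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)])
  combos <- utils::combn(n, na)
  ws <- apply(combos, 2, function(ix) sum(r[ix]))
  mu <- mean(ws)
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}
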