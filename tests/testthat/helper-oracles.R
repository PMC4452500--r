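# Independent brute-force oracles, written as literal scalar-loop
# transcriptions of the filter definition. They deliberately share no code
# with the package internals (own reflection helper, own kernel evaluation,
# scalar loops only) so that agreement is evidence, not tautology.

# 0-based symmetric reflection onto [0, n-1], scalar, by folding.
oracle_reflect <- function(i, n) {
  if (n == 1L) return(0L)
  while (i < 0L || i >= n) {
    if (i < 0L) i <- -i - 1L
    if (i >= n) i <- 2L * n - 1L - i
  }
  i
}

oracle_kernel_at <- function(dx, dy) {
  if (dx == 0L && dy == 0L) 2 else 1 / (dx^2 + dy^2)
}

# Weighted L1 patch distance by scalar double loop; p, q are 0-based c(x, y).
oracle_patch_distance <- function(img, p, q, B) {
  m <- nrow(img); n <- ncol(img)
  acc <- 0
  for (dy in -B:B) {
    for (dx in -B:B) {
      yp <- img[oracle_reflect(p[2] + dy, m) + 1L,
                oracle_reflect(p[1] + dx, n) + 1L]
      yq <- img[oracle_reflect(q[2] + dy, m) + 1L,
                oracle_reflect(q[1] + dx, n) + 1L]
      acc <- acc + abs(yp - yq) * oracle_kernel_at(dx, dy)
    }
  }
  acc
}

# Full filter by scalar triple loop: pixels x offsets x patch.
oracle_nlm <- function(img, T, B, h) {
  m <- nrow(img); n <- ncol(img)
  out <- matrix(0, m, n)
  for (py in 0:(m - 1L)) {
    for (px in 0:(n - 1L)) {
      wsum <- 0; vsum <- 0
      for (iy in -T:T) {
        for (ix in -T:T) {
          qx <- px + ix; qy <- py + iy
          if (qx < 0L || qx >= n || qy < 0L || qy >= m) next
          d <- oracle_patch_distance(img, c(px, py), c(qx, qy), B)
          w <- exp(-d / (h^2 * (2 * B + 1)^2))
          wsum <- wsum + w
          vsum <- vsum + w * img[qy + 1L, qx + 1L]
        }
      }
      out[py + 1L, px + 1L] <- vsum / wsum
    }
  }
  out
}

# Truncated-window box mean (the h -> Inf limit), computed directly.
oracle_box_mean <- function(img, T) {
  m <- nrow(img); n <- ncol(img)
  out <- matrix(0, m, n)
  for (py in 0:(m - 1L)) {
    for (px in 0:(n - 1L)) {
      rows <- max(0L, py - T):min(m - 1L, py + T)
      cols <- max(0L, px - T):min(n - 1L, px + T)
      out[py + 1L, px + 1L] <- mean(img[rows + 1L, cols + 1L])
    }
  }
  out
}

rand_image <- function(m, n, seed) {
  withr::with_seed(seed, matrix(stats::runif(m * n, 0, 255), m, n))
}

max_rel_diff <- function(a, b) max(abs(a - b)) / max(abs(a), 1e-300)
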