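# Literal reference engine. Deliberately unoptimized: it transcribes the
# filter definition pixel by pixel and is the oracle the optimized engines
# are tested against.

#' Weighted patch distance between two pixels
#'
#' Sums, over all patch displacements `(dx, dy)` in `[-B..B]^2`, the absolute
#' intensity difference between the two patches multiplied by the distance
#' kernel: `sum |Y(p + d) - Y(q + d)| * G(dx, dy)`. Note the *absolute* (not
#' squared) difference: this filter variant deliberately uses L1 patch
#' distances. Distances are evaluated on the mirror-padded image so that
#' patches overhanging the border are well defined.
#'
#' @param padded the `B`-padded image, as returned by [pad_symmetric()].
#' @param p,q pixel centers in the *unpadded* image, each a 0-based `c(x, y)`
#'   pair (`x` = column, `y` = row).
#' @param B patch radius.
#' @param kernel kernel table from [gaussian_kernel()] built for the same `B`.
#' @return A non-negative scalar; 0 iff the two patches are identical.
#'   Symmetric in `p` and `q`.
#' @export
patch_distance <- function(padded, p, q, B, kernel) {
  B <- check_scalar_int(B, "B")
  m <- nrow(padded) - 2L * B
  n <- ncol(padded) - 2L * B
  p <- check_offset(p); q <- check_offset(q)
  for (pt in list(p, q))
    if (pt[1L] < 0L || pt[1L] >= n || pt[2L] < 0L || pt[2L] >= m)
      stop("patch center outside the image", call. = FALSE)
  # patch block of center (x, y): padded rows y+1 .. y+2B+1, cols x+1 .. x+2B+1
  rows_p <- seq.int(p[2L] + 1L, p[2L] + 2L * B + 1L)
  cols_p <- seq.int(p[1L] + 1L, p[1L] + 2L * B + 1L)
  rows_q <- seq.int(q[2L] + 1L, q[2L] + 2L * B + 1L)
  cols_q <- seq.int(q[1L] + 1L, q[1L] + 2L * B + 1L)
  sum(abs(padded[rows_p, cols_p, drop = FALSE] -
            padded[rows_q, cols_q, drop = FALSE]) * unclass(kernel))
}

#' Patch-similarity weight
#'
#' Maps a weighted patch distance to a similarity weight
#' `exp(-dist / (h^2 (2B+1)^2))`: the per-pair distance is normalized by the
#' patch area `(2B+1)^2` and the squared smoothing strength. The weight is 1
#' for identical patches and strictly decreasing in the distance; the self
#' weight `w(p, p)` is exactly 1 (no max-weight substitution is applied).
#'
#' @param dist non-negative patch distance (vectorized).
#' @param h smoothing strength, `> 0`.
#' @param B patch radius.
#' @return Weight(s) in `(0, 1]`.
#' @examples
#' nlm_weight(0, h = 10, B = 4)              # 1
#' nlm_weight(10^2 * 81, h = 10, B = 4)      # exp(-1)
#' @export
nlm_weight <- function(dist, h, B) {
  if (!is.numeric(h) || length(h) != 1L || is.na(h) || h <= 0)
    stop("`h` must be a single positive number", call. = FALSE)
  B <- check_scalar_int(B, "B")
  if (any(dist < 0)) stop("`dist` must be non-negative", call. = FALSE)
  exp(-dist / (h^2 * (2 * B + 1)^2))
}

#' Naive non-local means filter (reference oracle)
#'
#' A literal transcription of the filter: for every pixel `p`, the output is
#' the weighted average of the intensities of all search-window partners `q`
#' that lie inside the image (the window is truncated at the border), with
#' weights `exp(-d(p, q) / (h^2 (2B+1)^2))` and patch distances computed on
#' the mirror-padded image. Triple loop over pixels and offsets, in fixed
#' row-major order; clarity over speed - this engine is the correctness
#' oracle for [nlm_filter_conventional()] and [nlm_filter_optimized()].
#'
#' @param img numeric matrix of intensities.
#' @param params an [nlm_params()] object.
#' @return A matrix of the same shape; every output value lies within the
#'   range of the in-window input intensities at that pixel.
#' @examples
#' img <- matrix(runif(36, 0, 255), 6, 6)
#' out <- nlm_filter_naive(img, nlm_params(T = 2, B = 1, h = 10))
#' @export
nlm_filter_naive <- function(img, params) {
  check_image(img)
  stopifnot(inherits(params, "nlm_params"))
  m <- nrow(img); n <- ncol(img)
  T <- params$T; B <- params$B; h <- params$h
  padded <- pad_symmetric(img, B)
  kernel <- gaussian_kernel(B)
  out <- matrix(0, m, n)
  for (py in 0:(m - 1L)) {
    for (px in 0:(n - 1L)) {
      wsum <- 0
      vsum <- 0
      for (iy in seq.int(-T, T)) {
        qy <- py + iy
        if (qy < 0L || qy >= m) next
        for (ix in seq.int(-T, T)) {
          qx <- px + ix
          if (qx < 0L || qx >= n) next
          d <- patch_distance(padded, c(px, py), c(qx, qy), B, kernel)
          w <- nlm_weight(d, h, B)
          wsum <- wsum + w
          vsum <- vsum + w * img[qy + 1L, qx + 1L]
        }
      }
      out[py + 1L, px + 1L] <- vsum / wsum
    }
  }
  out
}
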