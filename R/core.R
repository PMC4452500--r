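# Shared types and helpers: the distance kernel, mirror padding, offset
# enumeration, filter parameters, and the operation counter.

check_scalar_int <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min)
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

check_image <- function(img, name = "img") {
  if (!is.matrix(img) || !is.numeric(img) || nrow(img) < 1L || ncol(img) < 1L)
    stop(sprintf("`%s` must be a non-empty numeric matrix", name), call. = FALSE)
  if (!all(is.finite(img)))
    stop(sprintf("`%s` must contain only finite values", name), call. = FALSE)
  invisible(img)
}

#' NLM filter parameters
#'
#' Bundles the three tunables of the filter: the search radius `T` (the search
#' window holds `(2T+1)^2` candidate positions), the patch radius `B` (the
#' comparison patch holds `(2B+1)^2` pixels), and the smoothing strength `h`
#' (same units as the image intensities). The defaults are the clinical LDCT
#' setting: an 81x81 window (`T = 40`), a 9x9 patch (`B = 4`) and `h = 10` on
#' a 0-255 display-intensity scale. `h` is scale-relative: images on another
#' intensity scale need a proportionally scaled `h`.
#'
#' @param T search radius in pixels, integer `>= 0`.
#' @param B patch radius in pixels, integer `>= 0`.
#' @param h smoothing strength, `> 0`, in intensity units.
#' @return An object of class `nlm_params` (a named list with `T`, `B`, `h`).
#' @examples
#' nlm_params(T = 10, B = 2, h = 10)
#' @export
nlm_params <- function(T = 40L, B = 4L, h = 10) {
  T <- check_scalar_int(T, "T")
  B <- check_scalar_int(B, "B")
  if (!is.numeric(h) || length(h) != 1L || is.na(h) || h <= 0)
    stop("`h` must be a single positive number", call. = FALSE)
  structure(list(T = T, B = B, h = as.numeric(h)), class = "nlm_params")
}

#' @export
print.nlm_params <- function(x, ...) {
  cat(sprintf("NLM parameters: search window %dx%d (T = %d), patch %dx%d (B = %d), h = %g\n",
              2L * x$T + 1L, 2L * x$T + 1L, x$T,
              2L * x$B + 1L, 2L * x$B + 1L, x$B, x$h))
  invisible(x)
}

#' Distance-dependent patch kernel
#'
#' Builds the `(2B+1) x (2B+1)` table of distance-dependent weights applied to
#' the per-pixel intensity differences inside a patch comparison: the center
#' entry is 2, and an off-center entry at displacement `(dx, dy)` is
#' `1 / (dx^2 + dy^2)`. The table is symmetric under all eight symmetries of
#' the square and attains its maximum at the center.
#'
#' @param B patch radius, integer `>= 0`.
#' @return A `(2B+1) x (2B+1)` numeric matrix of class `kernel_table`, indexed
#'   so that entry `[dx + B + 1, dy + B + 1]` is the weight at displacement
#'   `(dx, dy)` (the table is symmetric, so the axis order is immaterial).
#' @examples
#' gaussian_kernel(1)
#' @export
gaussian_kernel <- function(B) {
  B <- check_scalar_int(B, "B")
  d <- seq.int(-B, B)
  g <- outer(d, d, function(dx, dy) ifelse(dx == 0 & dy == 0, 2, 1 / (dx^2 + dy^2)))
  structure(g, class = "kernel_table", B = B)
}

# Symmetric (edge-duplicating) reflection of 0-based indices onto [0, n-1].
# Works for any displacement magnitude, including pads wider than the image.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep.int(0L, length(i)))
  p <- i %% (2L * n)
  ifelse(p < n, p, 2L * n - 1L - p)
}

#' Mirror-pad an image
#'
#' Pads an image by `B` pixels on every side using edge-duplicating symmetric
#' reflection (the first reflected sample repeats the edge pixel, so a 1x1
#' image pads to a constant block). Patch differences near the border are
#' computed on this padded image; search-window partners, by contrast, are
#' truncated at the border and never invented.
#'
#' @param img numeric matrix.
#' @param B pad width in pixels, integer `>= 0`.
#' @return A `(m + 2B) x (n + 2B)` numeric matrix whose central block equals
#'   `img`.
#' @examples
#' pad_symmetric(matrix(1:6, 2, 3), 1)
#' @export
pad_symmetric <- function(img, B) {
  check_image(img)
  B <- check_scalar_int(B, "B")
  if (B == 0L) return(img)
  m <- nrow(img); n <- ncol(img)
  img[reflect_index(seq.int(-B, m - 1L + B), m) + 1L,
      reflect_index(seq.int(-B, n - 1L + B), n) + 1L,
      drop = FALSE]
}

#' Enumerate search-window offsets
#'
#' Lists the integer displacements `(i_x, i_y)` of the `(2T+1)^2` candidate
#' positions in the search window, in deterministic row-major order (`i_y`
#' ascending, then `i_x` ascending). `mode = "half"` returns the half list
#' used by the symmetric engine: all offsets with `i_y > 0` plus those with
#' `i_y = 0, i_x > 0` - exactly `((2T+1)^2 - 1) / 2` offsets. The self offset
#' `(0, 0)` is never in the half list; the union of the half list, its
#' negations and `(0, 0)` is the full list.
#'
#' @param T search radius, integer `>= 0`.
#' @param mode `"full"` or `"half"`.
#' @return An integer matrix with columns `ix`, `iy`, one offset per row.
#' @examples
#' enumerate_offsets(1, "half")
#' @export
enumerate_offsets <- function(T, mode = c("full", "half")) {
  T <- check_scalar_int(T, "T")
  mode <- match.arg(mode)
  g <- expand.grid(ix = seq.int(-T, T), iy = seq.int(-T, T),
                   KEEP.OUT.ATTRS = FALSE)
  off <- cbind(ix = as.integer(g$ix), iy = as.integer(g$iy))
  if (mode == "half")
    off <- off[off[, "iy"] > 0L | (off[, "iy"] == 0L & off[, "ix"] > 0L), ,
               drop = FALSE]
  off
}

#' Operation counter
#'
#' A mutable counter implementing the memory-bound cost accounting used to
#' compare the engines. Counts are *per pixel* (multiply by `m * n` for image
#' totals) and separate:
#'
#' * `intensity_reads` - fresh fetches of image intensities from the
#'   (conceptually global) image buffer; reads of cached row sums are free,
#' * `madds` - multiply-add / absolute-difference arithmetic,
#' * `exp_evals` - exponential evaluations,
#' * `charged` - the charged total under the published accounting scheme
#'   (each pass charges its nominal per-pixel cost; this is the quantity the
#'   closed-form complexity formulas predict),
#' * `passes` - number of per-offset pass iterations executed.
#'
#' @return An environment of class `op_count` with the fields above, all 0.
#' @seealso [conventional_complexity()], [improved_complexity()]
#' @examples
#' ctr <- op_counter()
#' img <- matrix(runif(16, 0, 255), 4, 4)
#' nlm_filter_optimized(img, nlm_params(T = 1, B = 1, h = 10), counter = ctr)
#' ctr$charged
#' @export
op_counter <- function() {
  e <- new.env(parent = emptyenv())
  e$intensity_reads <- 0
  e$madds <- 0
  e$exp_evals <- 0
  e$charged <- 0
  e$passes <- 0
  class(e) <- "op_count"
  e
}

counter_add <- function(counter, reads = 0, madds = 0, exps = 0, charged = 0,
                        passes = 0) {
  if (is.null(counter)) return(invisible(NULL))
  stopifnot(inherits(counter, "op_count"))
  counter$intensity_reads <- counter$intensity_reads + reads
  counter$madds <- counter$madds + madds
  counter$exp_evals <- counter$exp_evals + exps
  counter$charged <- counter$charged + charged
  counter$passes <- counter$passes + passes
  invisible(counter)
}

#' @export
print.op_count <- function(x, ...) {
  cat("Per-pixel operation counts\n")
  cat(sprintf("  intensity reads : %g\n", x$intensity_reads))
  cat(sprintf("  multiply-adds   : %g\n", x$madds))
  cat(sprintf("  exp evaluations : %g\n", x$exp_evals))
  cat(sprintf("  charged total   : %g\n", x$charged))
  cat(sprintf("  offset passes   : %g\n", x$passes))
  invisible(x)
}

#' @export
as.list.op_count <- function(x, ...) {
  list(intensity_reads = x$intensity_reads, madds = x$madds,
       exp_evals = x$exp_evals, charged = x$charged, passes = x$passes)
}

check_offset <- function(off, T = NULL) {
  if (!is.numeric(off) || length(off) != 2L || any(is.na(off)) ||
      any(off != floor(off)))
    stop("`off` must be an integer pair (i_x, i_y)", call. = FALSE)
  off <- as.integer(off)
  if (!is.null(T) && any(abs(off) > T))
    stop(sprintf("offset (%d, %d) outside the search radius T = %d",
                 off[1L], off[2L], T), call. = FALSE)
  off
}

# 1-based row/column index vectors of the pixels p for which p + off lies
# inside an m x n image; empty when the shift exceeds the image size.
inbounds_rows <- function(m, iy) {
  lo <- 1L + max(0L, -iy); hi <- m - max(0L, iy)
  if (lo > hi) integer(0) else seq.int(lo, hi)
}
inbounds_cols <- function(n, ix) inbounds_rows(n, ix)
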