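# Conventional per-offset engine: for each of the (2T+1)^2 window offsets, a
# cascade of whole-image passes computes the per-pixel difference plane (U1),
# the weight plane (U2) and the running sums (U3 = weights, U4 = weighted
# intensities); a final pass divides U4 by U3. Each pass is a deterministic
# whole-plane sweep; results are independent of how the sweep is chunked.

#' Per-offset pass state
#'
#' Mutable state for the conventional engine: scratch planes `U1` (per-pixel
#' intensity differences for the current offset) and `U2` (per-pixel weights),
#' plus the running accumulators `U3` (weight sums, `>= 0` everywhere) and
#' `U4` (weighted-intensity sums), both initialized to zero.
#'
#' @param m,n image dimensions (rows, columns).
#' @return An environment of class `nlm_pass_state`.
#' @export
pass_state <- function(m, n) {
  m <- check_scalar_int(m, "m", min = 1)
  n <- check_scalar_int(n, "n", min = 1)
  e <- new.env(parent = emptyenv())
  e$U1 <- NULL
  e$U2 <- NULL
  e$U3 <- matrix(0, m, n)
  e$U4 <- matrix(0, m, n)
  class(e) <- "nlm_pass_state"
  e
}

#' Intensity-difference pass
#'
#' For the current offset, computes the plane of per-pixel intensity
#' differences `Y(t) - Y(t + off)`. The plane is evaluated over the `B`-padded
#' domain (all centers within `B` pixels of the image) so that the weight pass
#' can read it at patch-shifted coordinates near the border; reads outside the
#' image use mirror reflection. The central `m x n` block is the per-pixel
#' difference plane proper. Charged cost: 1 intensity read per pixel.
#'
#' @param img numeric matrix.
#' @param off integer offset `c(i_x, i_y)`.
#' @param params an [nlm_params()] object (supplies `B` for the padded domain
#'   and `T` for offset validation).
#' @param counter optional [op_counter()].
#' @return A `(m + 2B) x (n + 2B)` difference plane with attribute `offset`.
#' @export
diff_pass <- function(img, off, params, counter = NULL) {
  check_image(img)
  stopifnot(inherits(params, "nlm_params"))
  off <- check_offset(off, params$T)
  m <- nrow(img); n <- ncol(img); B <- params$B
  rows0 <- seq.int(-B, m - 1L + B)
  cols0 <- seq.int(-B, n - 1L + B)
  A <- img[reflect_index(rows0, m) + 1L, reflect_index(cols0, n) + 1L,
           drop = FALSE]
  S <- img[reflect_index(rows0 + off[2L], m) + 1L,
           reflect_index(cols0 + off[1L], n) + 1L, drop = FALSE]
  counter_add(counter, reads = 1, charged = 1)
  structure(A - S, offset = off)
}

#' Weight pass
#'
#' For the current offset, computes the plane of patch-similarity weights
#' `U2(p) = w(p, p + off)` by summing `(2B+1)^2` kernel-weighted absolute
#' values of the difference plane at patch-shifted coordinates. Pixels whose
#' partner `p + off` falls outside the image record 0 (truncated window:
#' out-of-bounds partners contribute nothing). Charged cost: `(2B+1)^2`
#' multiply-adds per pixel.
#'
#' @param img numeric matrix.
#' @param off integer offset `c(i_x, i_y)`.
#' @param params an [nlm_params()] object.
#' @param kernel kernel table for `params$B`; built on the fly if missing.
#' @param U1 difference plane from [diff_pass()] for the same offset;
#'   computed on the fly if missing.
#' @param counter optional [op_counter()].
#' @return An `m x n` weight plane.
#' @export
weight_pass <- function(img, off, params, kernel = NULL, U1 = NULL,
                        counter = NULL) {
  check_image(img)
  stopifnot(inherits(params, "nlm_params"))
  off <- check_offset(off, params$T)
  m <- nrow(img); n <- ncol(img)
  B <- params$B; h <- params$h
  if (is.null(kernel)) kernel <- gaussian_kernel(B)
  if (is.null(U1)) U1 <- diff_pass(img, off, params)
  absU1 <- abs(U1)
  S <- matrix(0, m, n)
  for (dy in seq.int(-B, B))
    for (dx in seq.int(-B, B))
      S <- S + absU1[seq_len(m) + B + dy, seq_len(n) + B + dx, drop = FALSE] *
        kernel[dx + B + 1L, dy + B + 1L]
  U2 <- exp(-S / (h^2 * (2 * B + 1)^2))
  # truncated window: zero out pixels whose partner is outside the image
  mask <- matrix(0, m, n)
  fr <- inbounds_rows(m, off[2L]); fc <- inbounds_cols(n, off[1L])
  if (length(fr) && length(fc)) mask[fr, fc] <- 1
  counter_add(counter, madds = (2 * B + 1)^2, exps = 1,
              charged = (2 * B + 1)^2)
  U2 * mask
}

#' Accumulation pass
#'
#' Adds the current offset's weights into the running sums:
#' `U3(p) += U2(p)` and `U4(p) += U2(p) * Y(p + off)` for pixels whose
#' partner is inside the image (elsewhere `U2` is 0 and nothing is added).
#' Charged cost: 1 per pixel.
#'
#' @param state a [pass_state()] whose `U2` holds the current offset's
#'   weights.
#' @param img numeric matrix.
#' @param off integer offset `c(i_x, i_y)`.
#' @param counter optional [op_counter()].
#' @return The updated state, invisibly (modified in place).
#' @export
accumulate_pass <- function(state, img, off, counter = NULL) {
  stopifnot(inherits(state, "nlm_pass_state"))
  check_image(img)
  off <- check_offset(off)
  if (is.null(state$U2)) stop("state$U2 has not been computed", call. = FALSE)
  m <- nrow(img); n <- ncol(img)
  Yshift <- img[reflect_index(seq.int(0L, m - 1L) + off[2L], m) + 1L,
                reflect_index(seq.int(0L, n - 1L) + off[1L], n) + 1L,
                drop = FALSE]
  state$U3 <- state$U3 + state$U2
  state$U4 <- state$U4 + state$U2 * Yshift
  counter_add(counter, reads = 1, charged = 1)
  invisible(state)
}

#' Finalize pass state into the output image
#'
#' Divides the accumulated weighted-intensity sums by the weight sums,
#' `X(p) = U4(p) / U3(p)`. With the self offset included `U3 >= 1`
#' everywhere; a zero entry signals an internal error. Charged cost: 1 per
#' pixel.
#'
#' @param state a [pass_state()] (or any state with `U3`, `U4` planes) after
#'   all offsets have been processed.
#' @param counter optional [op_counter()].
#' @return The filtered image matrix.
#' @export
finalize_state <- function(state, counter = NULL) {
  if (!all(state$U3 > 0))
    stop("internal invariant violated: zero weight sum encountered",
         call. = FALSE)
  counter_add(counter, charged = 1)
  state$U4 / state$U3
}

#' Conventional per-offset non-local means engine
#'
#' Runs the difference / weight / accumulate cascade over the full list of
#' `(2T+1)^2` window offsets (row-major order), then finalizes. Output is
#' identical to [nlm_filter_naive()] up to floating-point reassociation
#' (within `1e-10` relative). With a counter attached, the charged per-pixel
#' total equals [conventional_complexity()]`(T, B)` exactly.
#'
#' @param img numeric matrix of intensities.
#' @param params an [nlm_params()] object.
#' @param counter optional [op_counter()].
#' @return The filtered image matrix.
#' @examples
#' img <- matrix(runif(64, 0, 255), 8, 8)
#' out <- nlm_filter_conventional(img, nlm_params(T = 2, B = 1, h = 10))
#' @export
nlm_filter_conventional <- function(img, params, counter = NULL) {
  check_image(img)
  stopifnot(inherits(params, "nlm_params"))
  m <- nrow(img); n <- ncol(img)
  kernel <- gaussian_kernel(params$B)
  offs <- enumerate_offsets(params$T, "full")
  state <- pass_state(m, n)
  for (k in seq_len(nrow(offs))) {
    off <- offs[k, ]
    state$U1 <- diff_pass(img, off, params, counter = counter)
    state$U2 <- weight_pass(img, off, params, kernel = kernel, U1 = state$U1,
                            counter = counter)
    accumulate_pass(state, img, off, counter = counter)
    counter_add(counter, passes = 1)
  }
  finalize_state(state, counter = counter)
}
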