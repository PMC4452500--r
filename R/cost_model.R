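# Closed-form operation-count model. The unit is one charged per-pixel
# operation under the memory-bound accounting: the weight pass of the
# conventional engine charges (2B+1)^2 per offset, the difference and
# accumulation passes 1 each, and the final division 1; the optimized engine
# charges 2B+1 fresh reads for the row cache, 2B+1 cache reads for the
# weight, and 1 for the symmetric accumulation, over half the window.

#' Serial filtering complexity
#'
#' Total operation count of the serial (single-CPU, pixel-by-pixel) filter on
#' an `m x n` image: `m * n * (2T+1)^2 * (2B+1)^2`. For a 512x512 image with
#' an 81x81 window and a 9x9 patch this is about `1.3931e11`.
#'
#' @param m,n image dimensions.
#' @param T search radius.
#' @param B patch radius.
#' @return The exact count (a double; exact for all practical sizes).
#' @examples
#' serial_complexity(512, 512, T = 40, B = 4)
#' @export
serial_complexity <- function(m, n, T, B) {
  m <- check_scalar_int(m, "m", min = 1)
  n <- check_scalar_int(n, "n", min = 1)
  T <- check_scalar_int(T, "T")
  B <- check_scalar_int(B, "B")
  as.numeric(m) * n * (2 * T + 1)^2 * (2 * B + 1)^2
}

#' Conventional parallel engine complexity (charged per-pixel count)
#'
#' `(2T+1)^2 * ((2B+1)^2 + 2) + 1`: per window offset, `(2B+1)^2` for the
#' weight pass plus 2 for the difference and accumulation passes, plus 1 for
#' the final division.
#'
#' @param T search radius.
#' @param B patch radius.
#' @return The exact per-pixel count.
#' @examples
#' conventional_complexity(40, 4)  # 544564
#' @export
conventional_complexity <- function(T, B) {
  T <- check_scalar_int(T, "T")
  B <- check_scalar_int(B, "B")
  (2 * T + 1)^2 * ((2 * B + 1)^2 + 2) + 1
}

#' Optimized engine complexity (charged per-pixel count)
#'
#' `0.5 * (2T+1)^2 * (2(2B+1) + 1) + 1`: per offset, `2B+1` fresh reads for
#' the row cache plus `2B+1` cache reads for the weight plus 1 for the
#' accumulation, over half the window (weight symmetry), plus 1 for the final
#' division. The half-window factor yields half-integer counts; they are
#' reported exactly, without rounding.
#'
#' @param T search radius.
#' @param B patch radius.
#' @return The exact per-pixel count (possibly a half-integer).
#' @examples
#' improved_complexity(40, 4)  # 62330.5
#' @export
improved_complexity <- function(T, B) {
  T <- check_scalar_int(T, "T")
  B <- check_scalar_int(B, "B")
  0.5 * (2 * T + 1)^2 * (2 * (2 * B + 1) + 1) + 1
}

#' Acceleration ratio of the optimized over the conventional engine
#'
#' With `asymptotic = TRUE`, returns the large-window limit `2B + 1` (for
#' `B = 4`, a 9-fold reduction). Otherwise returns the exact finite-window
#' ratio [conventional_complexity()]` / `[improved_complexity()], which
#' increases with `T` at fixed `B` and is bounded above by
#' `((2B+1)^2 + 2) / ((2(2B+1) + 1) / 2)` (about 8.74 for `B = 4`), itself
#' approximately `2B + 1`.
#'
#' @param T search radius (ignored when `asymptotic = TRUE`).
#' @param B patch radius.
#' @param asymptotic return the large-window limit instead of the finite
#'   ratio.
#' @return A positive number.
#' @examples
#' acceleration_ratio(B = 4, asymptotic = TRUE)  # 9
#' acceleration_ratio(T = 40, B = 4)             # ~8.74
#' @export
acceleration_ratio <- function(T = NULL, B, asymptotic = FALSE) {
  B <- check_scalar_int(B, "B")
  if (isTRUE(asymptotic)) return(2 * B + 1)
  if (is.null(T)) stop("`T` is required for the finite-window ratio", call. = FALSE)
  conventional_complexity(T, B) / improved_complexity(T, B)
}

#' Complexity report
#'
#' Evaluates the whole cost model for one configuration: the serial total,
#' the charged per-pixel counts of both parallel engines, their exact ratio
#' and the asymptotic ratio `2B + 1`.
#'
#' @param m,n image dimensions.
#' @param T search radius.
#' @param B patch radius.
#' @return A list of class `complexity_report` with fields `m`, `n`, `T`,
#'   `B`, `serial_total`, `conventional_per_pixel`, `improved_per_pixel`,
#'   `ratio`, `asymptotic_ratio`.
#' @examples
#' complexity_report(512, 512, T = 40, B = 4)
#' @export
complexity_report <- function(m, n, T, B) {
  structure(list(
    m = m, n = n, T = T, B = B,
    serial_total = serial_complexity(m, n, T, B),
    conventional_per_pixel = conventional_complexity(T, B),
    improved_per_pixel = improved_complexity(T, B),
    ratio = acceleration_ratio(T, B),
    asymptotic_ratio = acceleration_ratio(B = B, asymptotic = TRUE)
  ), class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("NLM complexity model: %d x %d image, window %dx%d (T = %d), patch %dx%d (B = %d)\n",
              x$m, x$n, 2 * x$T + 1, 2 * x$T + 1, x$T,
              2 * x$B + 1, 2 * x$B + 1, x$B))
  cat(sprintf("  serial total operations      : %s\n",
              format(x$serial_total, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  conventional, per pixel      : %s\n",
              format(x$conventional_per_pixel, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  optimized, per pixel         : %s\n",
              format(x$improved_per_pixel, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  acceleration ratio (finite)  : %.4f\n", x$ratio))
  cat(sprintf("  acceleration ratio (2B + 1)  : %d\n", x$asymptotic_ratio))
  invisible(x)
}
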