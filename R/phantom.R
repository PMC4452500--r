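# Synthetic low-dose CT phantom. A clean ellipse phantom (anatomy-scale
# structures on a 0-255 display scale) is degraded with Gaussian mottled
# noise plus additive oriented streaks through the image center - the
# structured, correlated degradation characteristic of reduced tube current,
# without simulating projection/FBP physics.

#' Phantom specification
#'
#' Describes a synthetic test image: a background intensity, a list of
#' (possibly rotated) ellipses painted over it in order, and the degradation
#' to apply - Gaussian noise of standard deviation `noise_sigma` plus
#' `streak_count` oriented ridge artifacts of peak amplitude
#' `streak_amplitude` through the image center. Intensities live on a 0-255
#' display scale so that the default smoothing strength `h = 10` has the
#' same relative meaning as on display-windowed CT images. The defaults
#' (`noise_sigma = 15`, 8 streaks) are the degradation level used throughout
#' the package's tests and demonstrations.
#'
#' @param size image side length in pixels, `>= 8`.
#' @param ellipses data frame with columns `cx`, `cy` (center, 0-based pixel
#'   coordinates), `a`, `b` (semi-axes in pixels), `angle` (degrees,
#'   counter-clockwise) and `intensity`. `NULL` selects a built-in body /
#'   lungs / spine / lesion layout scaled to `size`, with organ contrasts of
#'   15-70 display units - the low-contrast regime of soft-tissue-window CT,
#'   where the mottled low-dose noise is comparable to the tissue contrast.
#' @param background base intensity.
#' @param noise_sigma Gaussian noise standard deviation, `>= 0`.
#' @param streak_count number of additive line artifacts, `>= 0`.
#' @param streak_amplitude peak streak intensity.
#' @param seed integer seed controlling the degradation (not the clean
#'   phantom, which is deterministic).
#' @return A list of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(size = 64, seed = 7)
#' @export
phantom_spec <- function(size = 128L, ellipses = NULL, background = 30,
                         noise_sigma = 15, streak_count = 8L,
                         streak_amplitude = 25, seed = 1L) {
  size <- check_scalar_int(size, "size", min = 8)
  if (is.null(ellipses)) {
    s <- size
    ellipses <- data.frame(
      cx = c(0.50, 0.34, 0.66, 0.50, 0.39, 0.625) * s,
      cy = c(0.50, 0.44, 0.44, 0.77, 0.63, 0.610) * s,
      a = c(0.41, 0.14, 0.14, 0.065, 0.040, 0.025) * s,
      b = c(0.34, 0.19, 0.19, 0.055, 0.030, 0.025) * s,
      angle = c(0, 8, -8, 0, 30, 0),
      intensity = c(100, 70, 70, 150, 120, 85)
    )
  }
  need <- c("cx", "cy", "a", "b", "angle", "intensity")
  if (!is.data.frame(ellipses) || !all(need %in% names(ellipses)))
    stop("`ellipses` must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(ellipses) && any(ellipses$a <= 0 | ellipses$b <= 0))
    stop("ellipse semi-axes must be positive", call. = FALSE)
  if (!is.numeric(noise_sigma) || noise_sigma < 0)
    stop("`noise_sigma` must be >= 0", call. = FALSE)
  streak_count <- check_scalar_int(streak_count, "streak_count")
  if (!all(is.finite(c(background, streak_amplitude, ellipses$intensity))))
    stop("intensities must be finite", call. = FALSE)
  structure(list(size = size, ellipses = ellipses, background = background,
                 noise_sigma = as.numeric(noise_sigma),
                 streak_count = streak_count,
                 streak_amplitude = as.numeric(streak_amplitude),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Render the clean phantom
#'
#' Deterministic function of the spec (no randomness): paints the background
#' and then each ellipse in order (later ellipses overwrite earlier ones
#' where they overlap); values are clipped to `[0, 255]`. A pixel belongs to
#' an ellipse when its center lies inside it.
#'
#' @param spec a [phantom_spec()].
#' @return A `size x size` intensity matrix.
#' @examples
#' img <- make_phantom(phantom_spec(size = 64))
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- spec$size
  img <- matrix(spec$background, s, s)
  X <- matrix(rep(seq.int(0L, s - 1L), each = s), s, s)   # column index x
  Y <- matrix(rep(seq.int(0L, s - 1L), times = s), s, s)  # row index y
  for (k in seq_len(nrow(spec$ellipses))) {
    e <- spec$ellipses[k, ]
    th <- e$angle * pi / 180
    dx <- X - e$cx; dy <- Y - e$cy
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    img[(u / e$a)^2 + (v / e$b)^2 <= 1] <- e$intensity
  }
  clip255(img)
}

#' Degrade an image with low-dose-like noise and streaks
#'
#' Adds seeded Gaussian noise (`sd = noise_sigma`) and `streak_count`
#' straight ridge artifacts through the image center at seeded random
#' orientations. Each streak is a narrow Gaussian cross-profile (about 1-2
#' pixels wide) of peak amplitude `streak_amplitude`, with a seeded random
#' sign so both bright and dark streaks occur. Output is clipped to
#' `[0, 255]`; the same seed always yields the same output, and the caller's
#' RNG state is left untouched.
#'
#' @param img intensity matrix (typically from [make_phantom()]).
#' @param spec a [phantom_spec()] supplying `noise_sigma`, `streak_count`,
#'   `streak_amplitude` and `seed`.
#' @return The degraded matrix, same shape as `img`.
#' @examples
#' spec <- phantom_spec(size = 64, seed = 3)
#' noisy <- add_low_dose_noise(make_phantom(spec), spec)
#' @export
add_low_dose_noise <- function(img, spec) {
  check_image(img)
  stopifnot(inherits(spec, "phantom_spec"))
  m <- nrow(img); n <- ncol(img)
  out <- withr::with_seed(spec$seed, {
    res <- img
    if (spec$noise_sigma > 0)
      res <- res + matrix(stats::rnorm(m * n, 0, spec$noise_sigma), m, n)
    if (spec$streak_count > 0) {
      X <- matrix(rep(seq.int(0L, n - 1L), each = m), m, n)
      Y <- matrix(rep(seq.int(0L, m - 1L), times = n), m, n)
      cx <- (n - 1) / 2; cy <- (m - 1) / 2
      angles <- stats::runif(spec$streak_count, 0, pi)
      signs <- sample(c(-1, 1), spec$streak_count, replace = TRUE)
      for (k in seq_len(spec$streak_count)) {
        d <- abs((X - cx) * sin(angles[k]) - (Y - cy) * cos(angles[k]))
        res <- res + signs[k] * spec$streak_amplitude * exp(-d^2 / (2 * 0.6^2))
      }
    }
    res
  })
  clip255(out)
}

#' Clean/degraded phantom pair
#'
#' Convenience wrapper returning the clean phantom and its degraded version
#' for one spec.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `clean`, `degraded` and `spec`.
#' @export
phantom_pair <- function(spec = phantom_spec()) {
  clean <- make_phantom(spec)
  list(clean = clean, degraded = add_low_dose_noise(clean, spec), spec = spec)
}
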