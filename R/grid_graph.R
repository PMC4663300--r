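#' Generate the synthetic grid-graph benchmark image
#'
#' Builds an artificial grayscale test image made of uniform square "lumps"
#' arranged on a rectangular grid, together with its ground-truth label
#' image. The default is the classic 4 x 4 arrangement of 16 lumps of
#' 64 x 64 pixels taking the three gray levels 0 (black), 127 (gray) and
#' 255 (white), i.e. a 256 x 256 image with three well-separated clusters
#' and sharp lump boundaries.
#'
#' Lump `(r, s)` (zero-based) receives `levels[((r + s) %% length(levels)) + 1]`,
#' a deterministic cyclic layout under which horizontally and vertically
#' adjacent lumps always carry different levels, so every lump boundary is a
#' true cluster boundary.
#'
#' @param lump_rows,lump_cols Number of lump rows / columns (default 4 x 4).
#' @param lump_size Side length of each square lump in pixels (default 64).
#' @param levels Ordered vector of at least two distinct gray values in
#'   `[0, 255]` assigned cyclically to lumps.
#' @return A list with components `image` (numeric matrix of gray values) and
#'   `labels` (integer matrix; label `i` marks pixels at `levels[i]`).
#' @examples
#' gg <- grid_graph(lump_size = 8)
#' table(gg$labels)
#' @export
grid_graph <- function(lump_rows = 4, lump_cols = 4, lump_size = 64,
                       levels = c(0, 127, 255)) {
  stopifnot(lump_rows >= 1, lump_cols >= 1, lump_size >= 1)
  if (length(levels) < 2)
    stop("`levels` must contain at least 2 gray values")
  if (anyDuplicated(levels)) stop("`levels` must be distinct")
  if (min(levels) < 0 || max(levels) > 255)
    stop("`levels` must lie in [0, 255]")
  if (lump_rows * lump_cols < 2)
    warning("single-lump grid graph is degenerate: only one level is used")

  lump_level <- outer(seq_len(lump_rows) - 1L, seq_len(lump_cols) - 1L, "+") %%
    length(levels) + 1L
  labels <- lump_level[rep(seq_len(lump_rows), each = lump_size),
                       rep(seq_len(lump_cols), each = lump_size), drop = FALSE]
  image <- matrix(levels[labels], nrow = nrow(labels))
  storage.mode(labels) <- "integer"
  list(image = image, labels = labels)
}

#' Add Gaussian noise to a grayscale image
#'
#' Corrupts an image with additive Gaussian noise parameterized on the
#' `[0, 1]` intensity scale: `out = x + 255 * intensity + 255 * sqrt(variance) * eta`
#' with `eta ~ N(0, 1)`, clipped to `[0, 255]`. "x% Gaussian noise" therefore
#' means a mean offset of `x` on the unit scale with a fixed noise variance
#' of `variance` (default 0.01, i.e. a standard deviation of 25.5 gray
#' levels), the single-knob convention of classic MATLAB-era segmentation
#' benchmarks.
#'
#' @param image Numeric matrix of gray values in `[0, 255]`.
#' @param intensity Nonnegative mean offset as a fraction of full scale
#'   (0.05 for "5% noise").
#' @param variance Variance of the zero-mean fluctuation on the `[0, 1]`
#'   scale (default 0.01).
#' @param seed Optional RNG seed; the caller's RNG state is untouched.
#' @return The noisy image, same shape, values in `[0, 255]`.
#' @seealso [add_speckle_noise()], [add_salt_pepper()]
#' @export
add_gaussian_noise <- function(image, intensity, variance = 0.01, seed = NULL) {
  image <- as_gray_image(image)
  if (intensity < 0) stop("`intensity` must be nonnegative")
  if (variance < 0) stop("`variance` must be nonnegative")
  with_seed(seed, {
    eta <- matrix(rnorm(length(image)), nrow(image))
    clip_gray(image + 255 * intensity + 255 * sqrt(variance) * eta)
  })
}

#' Add multiplicative speckle noise
#'
#' `out = x + x * eta` with `eta` uniform, zero mean, variance `intensity`
#' (i.e. `eta ~ U(-sqrt(3 * intensity), sqrt(3 * intensity))`), clipped to
#' `[0, 255]`. Black pixels are a fixed point of the model.
#'
#' @inheritParams add_gaussian_noise
#' @param intensity Variance of the multiplicative uniform noise.
#' @return The noisy image.
#' @export
add_speckle_noise <- function(image, intensity, seed = NULL) {
  image <- as_gray_image(image)
  if (intensity < 0) stop("`intensity` must be nonnegative")
  half <- sqrt(3 * intensity)
  with_seed(seed, {
    eta <- matrix(runif(length(image), -half, half), nrow(image))
    clip_gray(image + image * eta)
  })
}

#' Add salt-and-pepper (impulse) noise
#'
#' Replaces a fraction `density` of the pixels, chosen uniformly without
#' replacement, half by pepper (0) and half by salt (255).
#'
#' @inheritParams add_gaussian_noise
#' @param density Fraction of pixels to corrupt, in `[0, 1]`.
#' @return The noisy image.
#' @export
add_salt_pepper <- function(image, density, seed = NULL) {
  image <- as_gray_image(image)
  if (density < 0 || density > 1) stop("`density` must lie in [0, 1]")
  n_bad <- round(density * length(image))
  if (n_bad == 0) return(image)
  with_seed(seed, {
    idx <- sample.int(length(image), n_bad)
    n_pepper <- floor(n_bad / 2)
    image[idx[seq_len(n_pepper)]] <- 0
    image[idx[seq.int(n_pepper + 1, n_bad)]] <- 255
    image
  })
}
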