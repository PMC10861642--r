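# Reproducible synthetic grayscale textures in three separable classes,
# plus the analytic fixture images used throughout the test suite.

#' Specification of one synthetic texture class
#'
#' Three generator kinds, chosen to be distinguishable by second-order
#' texture statistics (exactly what GLCM and LBP measure), stand in for the
#' three tumor classes:
#' \describe{
#'   \item{smooth_field}{Gaussian white noise low-pass filtered with a
#'     Gaussian kernel of standard deviation `corr_length` pixels —
#'     spatially correlated, low local contrast.}
#'   \item{fine_noise}{i.i.d. uniform noise — maximal local contrast, flat
#'     LBP structure.}
#'   \item{oriented_grating}{A sinusoid of the given `period` (pixels) and
#'     `angle` (degrees) plus mild i.i.d. noise — strongly anisotropic.}
#' }
#'
#' @param name Class label (unique within a dataset).
#' @param kind One of `"smooth_field"`, `"fine_noise"`,
#'   `"oriented_grating"`.
#' @param corr_length Correlation length in pixels (smooth_field), > 0.
#' @param period Grating period in pixels (oriented_grating), > 1.
#' @param angle Grating orientation in degrees (oriented_grating).
#' @param noise_amplitude Additive noise fraction of the intensity range
#'   (oriented_grating), in `[0, 1]`.
#' @param intensity_range Output gray-level range before quantization.
#' @return A `texture_class_spec` list.
#' @export
texture_class_spec <- function(name,
                               kind = c("smooth_field", "fine_noise",
                                        "oriented_grating"),
                               corr_length = 8, period = 8, angle = 0,
                               noise_amplitude = 0.1,
                               intensity_range = c(0L, 255L)) {
  kind <- match.arg(kind)
  if (corr_length <= 0) stop("corr_length must be > 0", call. = FALSE)
  if (period <= 1) stop("period must be > 1 pixel", call. = FALSE)
  if (noise_amplitude < 0 || noise_amplitude > 1)
    stop("noise_amplitude must be in [0, 1]", call. = FALSE)
  if (intensity_range[1L] < 0 || intensity_range[2L] > 255L ||
      intensity_range[1L] >= intensity_range[2L])
    stop("intensity_range must be increasing within [0, 255]", call. = FALSE)
  structure(list(name = as.character(name), kind = kind,
                 corr_length = corr_length, period = period, angle = angle,
                 noise_amplitude = noise_amplitude,
                 intensity_range = as.integer(intensity_range)),
            class = "texture_class_spec")
}

#' Default three-class texture specification
#'
#' The reference study conditions for all end-to-end tests: a smooth
#' correlated field (correlation length 8 px), fine i.i.d. noise, and a
#' horizontal grating of period 8 px with 10% additive noise, all spanning
#' the full 8-bit range.
#'
#' @return List of three [texture_class_spec()] objects.
#' @export
default_texture_specs <- function() {
  list(texture_class_spec("smooth", "smooth_field", corr_length = 8),
       texture_class_spec("noise", "fine_noise"),
       texture_class_spec("grating", "oriented_grating", period = 8,
                          angle = 0, noise_amplitude = 0.1))
}

# deterministic per-image seed from (seed, class name, index); < 2^31
derive_seed <- function(seed, class_name, index) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(paste0(class_name, ":", index)))
    h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# separable Gaussian blur with reflecting edges
gaussian_blur <- function(x, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur1 <- function(m) {   # along rows of each column
    n <- nrow(m)
    idx <- outer(seq_len(n), -half:half, "+")
    idx <- ifelse(idx < 1L, 2L - idx, idx)          # reflect top
    idx <- ifelse(idx > n, 2L * n - idx, idx)       # reflect bottom
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
    out
  }
  t(blur1(t(blur1(x))))
}

rescale_quantize <- function(x, intensity_range) {
  rng <- range(x)
  u <- if (rng[2L] > rng[1L]) (x - rng[1L]) / (rng[2L] - rng[1L])
       else matrix(0.5, nrow(x), ncol(x))
  lo <- intensity_range[1L]; hi <- intensity_range[2L]
  gray_image(matrix(as.integer(floor(lo + u * (hi - lo) + 0.5)),
                    nrow(x), ncol(x)), levels = 256L)
}

#' Generate one synthetic texture image
#'
#' A pure function of `(spec, seed, index)`: the per-image RNG seed is
#' derived deterministically from the three, so any image of a dataset can
#' be regenerated in isolation. Output is quantized to 8-bit integers in
#' the spec's intensity range.
#'
#' @param spec A [texture_class_spec()].
#' @param seed Integer dataset seed.
#' @param index Image index within the class.
#' @param size `c(height, width)`, each at least 32.
#' @return A [gray_image].
#' @export
generate_texture_image <- function(spec, seed, index = 1L,
                                   size = c(64L, 64L)) {
  stopifnot(inherits(spec, "texture_class_spec"))
  if (any(size < 32L)) stop("size must be at least 32 x 32", call. = FALSE)
  h <- size[1L]; w <- size[2L]
  img_seed <- derive_seed(seed, spec$name, index)
  field <- with_local_seed(img_seed, {
    switch(spec$kind,
      smooth_field = gaussian_blur(matrix(stats::rnorm(h * w), h, w),
                                   spec$corr_length),
      fine_noise = matrix(stats::runif(h * w), h, w),
      oriented_grating = {
        th <- spec$angle * pi / 180
        rc <- outer(seq_len(h), rep(1, w)) - 1
        cc <- outer(rep(1, h), seq_len(w)) - 1
        # angle = stripe orientation; the wave vector is normal to it, so
        # angle 0 gives horizontal stripes (intensity varies down rows)
        phase <- 2 * pi * (rc * cos(th) + cc * sin(th)) / spec$period
        sin(phase) / 2 + 0.5 +
          spec$noise_amplitude * (matrix(stats::runif(h * w), h, w) - 0.5)
      })
  })
  rescale_quantize(field, spec$intensity_range)
}

#' Generate a balanced labeled synthetic dataset
#'
#' @param specs List of [texture_class_spec()] with unique names (>= 2).
#' @param n_per_class Images per class (>= 2).
#' @param seed Integer seed; identical `(specs, n_per_class, seed, size)`
#'   yields a bit-identical dataset.
#' @param size Image size `c(height, width)`.
#' @return A list with `images` (list of lists `image`, `label`,
#'   `source_id`), `specs`, `n_per_class`, `seed`.
#' @examples
#' ds <- generate_dataset(default_texture_specs(), n_per_class = 3, seed = 1)
#' table(vapply(ds$images, `[[`, "", "label"))
#' @export
generate_dataset <- function(specs, n_per_class, seed,
                             size = c(64L, 64L)) {
  if (length(specs) < 2L) stop("need at least 2 class specs", call. = FALSE)
  nms <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate class names", call. = FALSE)
  if (n_per_class < 2L) stop("n_per_class must be >= 2", call. = FALSE)
  images <- list()
  for (spec in specs) {
    for (i in seq_len(n_per_class)) {
      images[[length(images) + 1L]] <- list(
        image = generate_texture_image(spec, seed, i, size),
        label = spec$name,
        source_id = sprintf("%s_%03d", spec$name, i))
    }
  }
  list(images = images, specs = specs, n_per_class = as.integer(n_per_class),
       seed = as.integer(seed), size = as.integer(size))
}

#' Analytic fixture images
#'
#' Small deterministic images with hand-computable texture statistics:
#' `constant` (64x64, value 7), `checkerboard` (64x64, 0/255 alternating
#' every pixel), `hramp` (64x64, pixel value = 0-based column index) and
#' `tiny_glcm` (the 3x3 three-level matrix whose horizontal co-occurrence
#' counts can be enumerated by hand).
#'
#' @return Named list of [gray_image] objects.
#' @export
fixture_images <- function() {
  cb <- outer(0:63, 0:63, function(r, c) ((r + c) %% 2L) * 255L)
  list(
    constant = gray_image(matrix(7L, 64L, 64L)),
    checkerboard = gray_image(cb),
    hramp = gray_image(outer(rep(1L, 64L), 0:63, function(r, c) c)),
    tiny_glcm = gray_image(matrix(c(0L, 0L, 0L,
                                    0L, 0L, 2L,
                                    1L, 1L, 2L), 3L, 3L), levels = 3L)
  )
}
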