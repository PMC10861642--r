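# Second-order texture descriptors: gray-level co-occurrence matrices with
# the five Haralick-style properties, and classic 3x3 local binary patterns.

# pixel offsets (drow, dcol), row 0 at top, for the four standard angles
.glcm_offsets <- list(
  `0`   = c(0L,  1L),
  `45`  = c(-1L, 1L),
  `90`  = c(-1L, 0L),
  `135` = c(-1L, -1L)
)

#' GLCM configuration
#'
#' @param distance Pixel-pair distance `S` (default 1; the reference
#'   configuration).
#' @param angles Offset angles in degrees, a subset of
#'   `c(0, 45, 90, 135)`: 0 is horizontal, 45 the positive diagonal, 90
#'   vertical, 135 the negative diagonal.
#' @param levels Number of gray levels of the co-occurrence matrix.
#' @param symmetric Count each pixel pair in both orders (default `TRUE`).
#' @param normalized Divide by the total weight so entries sum to 1
#'   (default `TRUE`; required by [glcm_properties()]).
#' @param energy Either `"sqrt_asm"` (energy is `sqrt(sum(P^2))`, the
#'   default) or `"asm"` (the angular second moment `sum(P^2)` itself).
#' @return A `glcm_config` list.
#' @export
glcm_config <- function(distance = 1L, angles = c(0, 45, 90, 135),
                        levels = 256L, symmetric = TRUE, normalized = TRUE,
                        energy = c("sqrt_asm", "asm")) {
  distance <- as.integer(distance)
  if (is.na(distance) || distance < 1L) stop("distance S must be >= 1", call. = FALSE)
  if (length(angles) == 0L || !all(angles %in% c(0, 45, 90, 135)))
    stop("angles must be a non-empty subset of {0, 45, 90, 135}", call. = FALSE)
  structure(list(distance = distance, angles = angles,
                 levels = as.integer(levels),
                 symmetric = isTRUE(symmetric),
                 normalized = isTRUE(normalized),
                 energy = match.arg(energy)),
            class = "glcm_config")
}

#' Compute a gray-level co-occurrence matrix at one angle
#'
#' Counts ordered pixel pairs `(p, p + offset)` where the offset is the
#' configured distance `S` along the given angle. With `symmetric = TRUE`
#' the transpose counts are added; with `normalized = TRUE` the matrix is
#' divided by its total so entries are joint frequencies.
#'
#' @param image A [gray_image] (or plain integer matrix) whose values fit
#'   `config$levels`.
#' @param config A [glcm_config()].
#' @param angle One of the configured angles, in degrees.
#' @return A `glcm` object: list with `P` (levels x levels matrix), the
#'   config and the angle.
#' @examples
#' img <- fixture_images()$tiny_glcm
#' cfg <- glcm_config(levels = 3, symmetric = FALSE, normalized = FALSE)
#' compute_glcm(img, cfg, 0)$P
#' @export
compute_glcm <- function(image, config = glcm_config(), angle = 0) {
  image <- as_gray_image(image, config$levels)
  if (image$levels > config$levels || max(image$pixels) > config$levels - 1L)
    stop("image gray levels exceed config$levels", call. = FALSE)
  if (!as.character(angle) %in% names(.glcm_offsets) ||
      !angle %in% config$angles)
    stop("angle ", angle, " not in the configured angle set", call. = FALSE)
  off <- .glcm_offsets[[as.character(angle)]] * config$distance
  px <- image$pixels
  nr <- nrow(px); nc <- ncol(px)
  if (nr <= abs(off[1L]) || nc <= abs(off[2L]))
    stop("image smaller than the co-occurrence offset reach", call. = FALSE)

  # index ranges of the "from" pixel so that from + offset stays in bounds
  r1 <- max(1L, 1L - off[1L]):min(nr, nr - off[1L])
  c1 <- max(1L, 1L - off[2L]):min(nc, nc - off[2L])
  from <- px[r1, c1, drop = FALSE]
  to <- px[r1 + off[1L], c1 + off[2L], drop = FALSE]

  L <- config$levels
  counts <- tabulate(as.vector(from) * L + as.vector(to) + 1L, nbins = L * L)
  P <- matrix(counts, L, L, byrow = TRUE)  # row = first pixel's level
  if (config$symmetric) P <- P + t(P)
  if (config$normalized) P <- P / sum(P)
  structure(list(P = P, config = config, angle = angle), class = "glcm")
}

#' Haralick-style properties of a normalized GLCM
#'
#' For a normalized co-occurrence matrix `P(i, j)` over gray levels
#' `i, j = 0..L-1`, returns the five statistics in fixed order:
#' \describe{
#'   \item{contrast}{`sum P(i,j) (i - j)^2` — local intensity variation.}
#'   \item{dissimilarity}{`sum P(i,j) |i - j|`.}
#'   \item{homogeneity}{`sum P(i,j) / (1 + |i - j|)`.}
#'   \item{energy}{`sqrt(sum P(i,j)^2)` (or the angular second moment
#'     itself when the config sets `energy = "asm"`).}
#'   \item{correlation}{`sum P(i,j)(i - mu_i)(j - mu_j) / (sigma_i sigma_j)`
#'     with the marginal means/SDs of `P`; defined as 1 when
#'     `sigma_i * sigma_j = 0` (a constant image is perfectly
#'     self-correlated).}
#' }
#'
#' @param glcm A normalized `glcm` from [compute_glcm()].
#' @return Named numeric vector `(contrast, dissimilarity, homogeneity,
#'   energy, correlation)`.
#' @export
glcm_properties <- function(glcm) {
  stopifnot(inherits(glcm, "glcm"))
  P <- glcm$P
  if (!glcm$config$normalized || abs(sum(P) - 1) > 1e-9)
    stop("glcm_properties requires a normalized GLCM", call. = FALSE)
  L <- nrow(P)
  lev <- 0:(L - 1L)
  D <- abs(outer(lev, lev, "-"))            # |i - j|
  contrast <- sum(P * D^2)
  dissimilarity <- sum(P * D)
  homogeneity <- sum(P / (1 + D))
  asm <- sum(P^2)
  energy <- if (glcm$config$energy == "asm") asm else sqrt(asm)
  pi_ <- rowSums(P); pj <- colSums(P)
  mu_i <- sum(lev * pi_); mu_j <- sum(lev * pj)
  sd_i <- sqrt(sum(pi_ * (lev - mu_i)^2))
  sd_j <- sqrt(sum(pj * (lev - mu_j)^2))
  correlation <- if (sd_i * sd_j == 0) 1 else
    sum(P * outer(lev - mu_i, lev - mu_j)) / (sd_i * sd_j)
  c(contrast = contrast, dissimilarity = dissimilarity,
    homogeneity = homogeneity, energy = energy, correlation = correlation)
}

#' Angle-averaged GLCM feature vector
#'
#' Computes [glcm_properties()] at every configured angle and returns the
#' element-wise mean, yielding one 5-vector per image regardless of the
#' number of angles. Averaging reconciles the four-angle computation with a
#' five-element descriptor; see the methods vignette.
#'
#' @inheritParams compute_glcm
#' @return Named numeric 5-vector `(contrast, dissimilarity, homogeneity,
#'   energy, correlation)`.
#' @export
glcm_feature_vector <- function(image, config = glcm_config()) {
  image <- as_gray_image(image, config$levels)
  per_angle <- vapply(config$angles,
                      function(a) glcm_properties(compute_glcm(image, config, a)),
                      numeric(5))
  rowMeans(per_angle)
}

#' Local binary pattern code image
#'
#' Classic 8-neighbor LBP on the 3x3 square (the `P = 8, R = 1` circle with
#' nearest-neighbor sampling): every interior pixel gets the code
#' `sum_p s(g_p - g_c) 2^p`, where `s(x) = 1` iff `x >= 0` (ties count as
#' set) and the neighbors `p = 0..7` are enumerated clockwise from the
#' top-left. Border pixels are excluded.
#'
#' @param image A [gray_image] (or integer matrix), at least 3x3.
#' @param sampling_points Number of neighbors; only 8 is supported.
#' @param radius Neighborhood radius; only 1 is supported.
#' @return Integer matrix of codes in `[0, 255]`, dimensions
#'   `(nrow - 2) x (ncol - 2)`.
#' @examples
#' codes <- lbp_code_image(fixture_images()$constant)
#' unique(as.vector(codes))  # 255: every neighbor ties with the center
#' @export
lbp_code_image <- function(image, sampling_points = 8L, radius = 1L) {
  if (sampling_points != 8L || radius != 1L)
    stop("only the 8-point, radius-1 configuration is supported", call. = FALSE)
  image <- as_gray_image(image)
  px <- image$pixels
  nr <- nrow(px); nc <- ncol(px)
  if (nr < 3L || nc < 3L) stop("image must be at least 3x3", call. = FALSE)
  ctr <- px[2:(nr - 1L), 2:(nc - 1L), drop = FALSE]
  # clockwise from top-left: (dr, dc) relative to the center
  nb <- list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, 1L),
             c(1L, 1L), c(1L, 0L), c(1L, -1L), c(0L, -1L))
  wts <- as.integer(2^(0:7))
  codes <- matrix(0L, nr - 2L, nc - 2L)
  for (p in seq_along(nb)) {
    d <- nb[[p]]
    neigh <- px[2:(nr - 1L) + d[1L], 2:(nc - 1L) + d[2L], drop = FALSE]
    codes <- codes + (neigh >= ctr) * wts[p]
  }
  codes
}

#' Normalized 256-bin LBP histogram
#'
#' Bins the code image over values 0..255 and normalizes to relative
#' frequencies summing to 1.
#'
#' @param codes Integer matrix (or vector) of LBP codes in `[0, 255]`.
#' @return Numeric vector of length 256, named `lbp_000` .. `lbp_255`.
#' @export
lbp_histogram <- function(codes) {
  codes <- as.vector(codes)
  if (length(codes) == 0L) stop("empty code grid", call. = FALSE)
  if (min(codes) < 0L || max(codes) > 255L)
    stop("LBP codes must lie in [0, 255]", call. = FALSE)
  h <- tabulate(codes + 1L, nbins = 256L) / length(codes)
  names(h) <- sprintf("lbp_%03d", 0:255)
  h
}
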