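#' Grayscale image container
#'
#' A `gray_image` wraps a 2-D matrix of integer gray levels in
#' `[0, levels - 1]` together with the number of quantization levels. It is
#' the sole raw input accepted by every feature extractor in the package.
#'
#' @param pixels Numeric matrix of integer gray levels, row 1 at the top.
#' @param levels Number of gray levels `L`; pixel values must lie in
#'   `[0, L - 1]`. Default 256 (8-bit).
#' @return An object of class `gray_image` with elements `pixels` (integer
#'   matrix) and `levels`.
#' @examples
#' img <- gray_image(matrix(0:24 %% 8, 5, 5), levels = 8)
#' dim(img$pixels)
#' @export
gray_image <- function(pixels, levels = 256L) {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty matrix", call. = FALSE)
  if (nrow(pixels) < 3L || ncol(pixels) < 3L)
    stop("image must be at least 3x3 (LBP needs an interior)", call. = FALSE)
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 2L)
    stop("`levels` must be an integer >= 2", call. = FALSE)
  if (anyNA(pixels) || any(pixels != round(pixels)))
    stop("pixel values must be integers", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > levels - 1L)
    stop("pixel values must lie in [0, levels - 1]", call. = FALSE)
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, levels = levels), class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, %d levels>\n",
              nrow(x$pixels), ncol(x$pixels), x$levels))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

as_gray_image <- function(x, levels = 256L) {
  if (inherits(x, "gray_image")) x else gray_image(x, levels)
}
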