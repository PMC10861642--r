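# Raster input, the Figshare .mat dialect, and feature-table persistence.

#' Load a raster image as a quantized grayscale matrix
#'
#' Reads a PNG, TIFF or JPEG file and converts it to the canonical
#' [gray_image] representation. RGB input is collapsed to a single channel
#' with ITU-R BT.601 luma weights (0.299, 0.587, 0.114); an alpha channel,
#' if present, is ignored. Intensities are then scaled to `[0, levels - 1]`
#' and rounded half-up to integers. Already-gray input is only quantized, so
#' loading a PNG written from a `gray_image` reproduces its pixels exactly.
#'
#' @param path Path to a PNG/TIFF/JPEG file.
#' @param levels Number of output gray levels (default 256).
#' @return A [gray_image].
#' @examples
#' img <- fixture_images()$hramp
#' f <- tempfile(fileext = ".png")
#' write_gray_png(img, f)
#' identical(load_grayscale(f)$pixels, img$pixels)
#' @export
load_grayscale <- function(path, levels = 256L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("the 'jpeg' package is required to read JPEG files", call. = FALSE)
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(arr) == 0L) stop("zero-size image: ", path, call. = FALSE)
  gray <- if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3L]
    if (nc >= 3L) {
      0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L]
    } else {
      arr[, , 1L]  # gray (+ alpha) stored as planes
    }
  } else {
    arr
  }
  quantize_unit(gray, levels)
}

# round-half-up quantization of values in [0, 1] to integers in [0, L-1]
quantize_unit <- function(x, levels) {
  q <- floor(x * (levels - 1L) + 0.5)
  gray_image(matrix(pmin(pmax(q, 0), levels - 1L), nrow(x), ncol(x)),
             levels = levels)
}

#' Write a grayscale image to PNG
#'
#' Inverse of [load_grayscale()] for 8-bit images: pixel `v` is stored as
#' `v / (levels - 1)` so a write/load round trip is the identity.
#'
#' @param image A [gray_image].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(image, path) {
  image <- as_gray_image(image)
  png::writePNG(image$pixels / (image$levels - 1L), path)
  invisible(path)
}

#' Read one slice of the Figshare brain-tumor archive
#'
#' Reads a MATLAB v7.3 (HDF5) `.mat` file holding a `cjdata` struct with
#' `image` and `label` members, as distributed with the 3064-slice
#' T1-weighted brain-tumor collection. The numeric label is mapped
#' 1 = meningioma, 2 = glioma, 3 = pituitary, and the image is min-max
#' rescaled to 8-bit integers.
#'
#' HDF5 decoding is delegated to the system `python` interpreter's `h5py`
#' module, which must be on the `PATH`; the reader is an optional
#' convenience and nothing else in the package depends on it.
#'
#' @param path Path to a cjdata-style `.mat` file.
#' @return A list with elements `image` (a [gray_image]), `label`
#'   (character) and `source_id` (the file name).
#' @export
read_figshare_mat <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  script <- system.file("python", "read_cjdata.py", package = "tumortexture",
                        mustWork = TRUE)
  out_csv <- tempfile(fileext = ".csv")
  on.exit(unlink(out_csv), add = TRUE)
  res <- suppressWarnings(system2("python", shQuote(c(script, path, out_csv)),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0L)
    stop("failed to read ", path, ": ", paste(res, collapse = " "),
         call. = FALSE)
  lab_num <- as.integer(res[[length(res)]])
  lab_map <- c("meningioma", "glioma", "pituitary")
  if (is.na(lab_num) || !lab_num %in% 1:3)
    stop("cjdata label outside {1,2,3}: ", res[[length(res)]], call. = FALSE)
  px <- as.matrix(data.table::fread(out_csv, header = FALSE))
  dimnames(px) <- NULL
  rng <- range(px)
  px <- if (rng[2L] > rng[1L]) (px - rng[1L]) / (rng[2L] - rng[1L])
        else matrix(0, nrow(px), ncol(px))
  img <- quantize_unit(px, 256L)
  list(image = img, label = lab_map[lab_num], source_id = basename(path))
}

#' Feature tables: construction, CSV persistence
#'
#' A feature table holds one composite feature vector per image together
#' with its source identifier and class label. On disk it is an RFC-4180
#' CSV whose header is `source_id,label,<feature names>`; numeric values
#' are written with enough digits that a write/read round trip is exact.
#'
#' @param source_id Character vector of image identifiers.
#' @param label Character vector of class labels.
#' @param features Numeric matrix, one row per image; column names are the
#'   feature names.
#' @return A `feature_table`: a data.frame with columns `source_id`,
#'   `label`, then the features.
#' @export
feature_table <- function(source_id, label, features) {
  if (!is.matrix(features) || nrow(features) == 0L)
    stop("`features` must be a non-empty matrix", call. = FALSE)
  if (length(source_id) != nrow(features) || length(label) != nrow(features))
    stop("source_id/label length must match feature rows", call. = FALSE)
  if (is.null(colnames(features)))
    stop("`features` must have column names", call. = FALSE)
  df <- data.frame(source_id = as.character(source_id),
                   label = as.character(label),
                   features, check.names = FALSE,
                   stringsAsFactors = FALSE, row.names = NULL)
  class(df) <- c("feature_table", "data.frame")
  df
}

feature_matrix <- function(table) {
  as.matrix(table[, -(1:2), drop = FALSE])
}

#' @rdname feature_table
#' @param table A `feature_table`.
#' @param path CSV file path.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "data.frame"))
  if (nrow(table) == 0L) stop("empty feature table", call. = FALSE)
  out <- table
  # 17 significant digits: doubles survive the text round trip exactly
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = TRUE, check.names = FALSE,
                          integer64 = "double")
  if (!all(c("source_id", "label") %in% names(dt)[1:2]))
    stop("not a feature table: missing source_id/label columns",
         call. = FALSE)
  df <- as.data.frame(dt, check.names = FALSE)
  df$source_id <- as.character(df$source_id)
  df$label <- as.character(df$label)
  class(df) <- c("feature_table", "data.frame")
  df
}
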