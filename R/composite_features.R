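# Fused descriptors built from the GLCM vector g and LBP histogram l, and
# their concatenation into the fixed-length composite vector.

#' Outer-product interaction features
#'
#' Fuses the GLCM vector `g` (length m) and LBP histogram `l` (length n)
#' into the matrix `M = g %o% l` with `M[i, j] = g_i * l_j`: every entry
#' couples one second-order texture statistic with one local-pattern
#' frequency. The flattened form is row-major (all products of `g_1`
#' first).
#'
#' @param g Numeric GLCM feature vector.
#' @param l Numeric LBP histogram (any length).
#' @return List with `M` (m x n matrix) and `flat` (length m*n named
#'   vector, names `ix_<i>_<j>` with 0-based indices).
#' @examples
#' interaction_features(c(10, 20, 30, 40, 50), c(0.01, 0.02, 0.03, 0.04, 0.05))$M
#' @export
interaction_features <- function(g, l) {
  if (length(g) < 1L || length(l) < 1L)
    stop("g and l must be non-empty", call. = FALSE)
  if (!all(is.finite(g)) || !all(is.finite(l)))
    stop("non-finite feature values", call. = FALSE)
  M <- outer(as.numeric(g), as.numeric(l))
  flat <- as.vector(t(M))  # row-major
  names(flat) <- sprintf("ix_%d_%d",
                         rep(seq_along(g) - 1L, each = length(l)),
                         rep(seq_along(l) - 1L, times = length(g)))
  list(M = M, flat = flat)
}

#' Aggregated GLCM features: sum, mean, median
#'
#' The median uses the midpoint of the two central order statistics for
#' even length.
#'
#' @param g Numeric GLCM feature vector.
#' @return Named numeric vector `(agg_sum, agg_mean, agg_median)`.
#' @export
aggregated_features <- function(g) {
  if (length(g) == 0L || !all(is.finite(g)))
    stop("g must be non-empty and finite", call. = FALSE)
  c(agg_sum = sum(g), agg_mean = mean(g), agg_median = stats::median(g))
}

#' Statistical GLCM features: population variance, skewness, excess kurtosis
#'
#' All moments use the population convention (divide by m, not m - 1):
#' `variance = mean((g - mean(g))^2)`,
#' `skewness = mean(((g - mean(g)) / sd)^3)`,
#' `kurtosis = mean(((g - mean(g)) / sd)^4) - 3` (excess). For a constant
#' vector (sd = 0) skewness and kurtosis are defined as 0 so degenerate
#' textures still yield finite vectors.
#'
#' @param g Numeric GLCM feature vector.
#' @return Named numeric vector `(stat_var, stat_skew, stat_kurt)`.
#' @examples
#' statistical_features(c(10, 20, 30, 40, 50))  # var 200, skew 0, kurt -1.3
#' @export
statistical_features <- function(g) {
  m <- length(g)
  if (m == 0L || !all(is.finite(g)))
    stop("g must be non-empty and finite", call. = FALSE)
  mu <- mean(g)
  v <- mean((g - mu)^2)
  s <- sqrt(v)
  if (s == 0) {
    skew <- 0; kurt <- 0
  } else {
    z <- (g - mu) / s
    skew <- mean(z^3)
    kurt <- mean(z^4) - 3
  }
  c(stat_var = v, stat_skew = skew, stat_kurt = kurt)
}

#' Log-transform (non-linear) GLCM features
#'
#' Element-wise `log(1 + g)` (natural log); the +1 shift keeps the
#' transform defined at 0. Strictly increasing in each input.
#'
#' @param g Numeric vector with every element > -1.
#' @return Named numeric vector `nl_*`, same length as `g`.
#' @export
nonlinear_features <- function(g) {
  if (any(g <= -1)) stop("log(1 + g) undefined for g <= -1", call. = FALSE)
  out <- log1p(as.numeric(g))
  nm <- if (!is.null(names(g))) names(g) else as.character(seq_along(g) - 1L)
  names(out) <- paste0("nl_", nm)
  out
}

glcm_feature_names <- c("glcm_contrast", "glcm_dissimilarity",
                        "glcm_homogeneity", "glcm_energy",
                        "glcm_correlation")

#' Composite feature vector of one image
#'
#' Runs the full extraction pipeline on a grayscale image and concatenates
#' the blocks in fixed order: `glcm` (5, angle-averaged), `lbp` (256),
#' `interaction` (5 x 256 = 1280 outer products of the raw GLCM vector with
#' the LBP histogram), `aggregated` (3) and `statistical` (3) — 1547 values
#' in the reference configuration. The optional log-transform block adds
#' (`nonlinear_mode = "append"`, length 1552) or replaces
#' (`"substitute"`, length 1547) the raw GLCM block's derived entries; the
#' interaction block always uses the raw GLCM vector.
#'
#' @param image A [gray_image] or integer matrix.
#' @param config A [pipeline_config()].
#' @return Named numeric vector; `attr(, "blocks")` gives the block
#'   lengths.
#' @examples
#' v <- composite_vector(fixture_images()$checkerboard,
#'                       pipeline_config(glcm = glcm_config(levels = 256)))
#' length(v)  # 1547
#' @export
composite_vector <- function(image, config = pipeline_config()) {
  image <- as_gray_image(image, config$glcm$levels)
  g <- glcm_feature_vector(image, config$glcm)
  l <- lbp_histogram(lbp_code_image(image, config$lbp$sampling_points,
                                    config$lbp$radius))
  ix <- interaction_features(g, l)$flat
  agg <- aggregated_features(g)
  st <- statistical_features(g)

  g_block <- g
  names(g_block) <- glcm_feature_names
  blocks <- list(glcm = g_block, lbp = l, interaction = ix,
                 aggregated = agg, statistical = st)
  if (config$include_nonlinear) {
    nl <- unname(nonlinear_features(g))
    names(nl) <- sub("^glcm_", "nl_", glcm_feature_names)
    if (config$nonlinear_mode == "substitute") {
      blocks$glcm <- nl
      names(blocks)[1L] <- "nonlinear"
    } else {
      blocks$nonlinear <- nl
    }
  }
  out <- unlist(blocks, use.names = TRUE)
  names(out) <- sub("^[a-z]+\\.", "", names(out))  # drop block prefix
  attr(out, "blocks") <- lengths(blocks)
  out
}
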