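# Independent brute-force oracles, each deliberately written as the naive
# definition so they share no code with the package implementation.

# GLCM properties by an explicit double loop over all matrix cells
oracle_glcm_properties <- function(P, energy = "sqrt_asm") {
  L <- nrow(P)
  C <- D <- H <- asm <- 0
  for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
    p <- P[i + 1, j + 1]
    C <- C + p * (i - j)^2
    D <- D + p * abs(i - j)
    H <- H + p / (1 + abs(i - j))
    asm <- asm + p^2
  }
  mu_i <- mu_j <- 0
  for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
    mu_i <- mu_i + i * P[i + 1, j + 1]
    mu_j <- mu_j + j * P[i + 1, j + 1]
  }
  v_i <- v_j <- 0
  for (i in 0:(L - 1)) for (j in 0:(L - 1)) {
    v_i <- v_i + (i - mu_i)^2 * P[i + 1, j + 1]
    v_j <- v_j + (j - mu_j)^2 * P[i + 1, j + 1]
  }
  corr <- if (v_i * v_j == 0) 1 else {
    s <- 0
    for (i in 0:(L - 1)) for (j in 0:(L - 1))
      s <- s + P[i + 1, j + 1] * (i - mu_i) * (j - mu_j)
    s / sqrt(v_i * v_j)
  }
  c(contrast = C, dissimilarity = D, homogeneity = H,
    energy = if (energy == "asm") asm else sqrt(asm), correlation = corr)
}

# LBP code of one pixel by the eight explicit comparisons, clockwise from
# the top-left neighbor
oracle_lbp_codes <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  out <- matrix(NA_integer_, nr - 2, nc - 2)
  nb <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
             c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  for (r in 2:(nr - 1)) for (c in 2:(nc - 1)) {
    code <- 0L
    for (p in 1:8) {
      d <- nb[[p]]
      if (px[r + d[1], c + d[2]] >= px[r, c])
        code <- code + as.integer(2^(p - 1))
    }
    out[r - 1, c - 1] <- code
  }
  out
}

# population moments by explicit summation
oracle_moments <- function(g) {
  m <- length(g)
  mu <- sum(g) / m
  v <- sum((g - mu)^2) / m
  s <- sqrt(v)
  if (s == 0) return(c(stat_var = v, stat_skew = 0, stat_kurt = 0))
  c(stat_var = v,
    stat_skew = sum(((g - mu) / s)^3) / m,
    stat_kurt = sum(((g - mu) / s)^4) / m - 3)
}

# AUC as the pairwise win rate over all positive-negative score pairs,
# ties counting half
oracle_pairwise_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  wins <- 0
  for (a in pos) for (b in neg)
    wins <- wins + if (a > b) 1 else if (a == b) 0.5 else 0
  wins / (length(pos) * length(neg))
}

random_gray_image <- function(nr, nc, levels) {
  gray_image(matrix(sample(0:(levels - 1), nr * nc, replace = TRUE), nr, nc),
             levels = levels)
}

# small ready-made synthetic feature table shared by classifier tests
make_synth_table <- function(n_per_class = 12, seed = 42, size = c(48, 48)) {
  ds <- generate_dataset(default_texture_specs(), n_per_class, seed,
                         size = size)
  X <- do.call(rbind, lapply(ds$images, function(im)
    composite_vector(im$image)))
  feature_table(vapply(ds$images, `[[`, "", "source_id"),
                vapply(ds$images, `[[`, "", "label"), X)
}

random_confusion <- function(K = 3, max_count = 40) {
  matrix(sample(0:max_count, K * K, replace = TRUE), K, K,
         dimnames = list(truth = letters[1:K], predicted = letters[1:K]))
}
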