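test_that("GLCM counts match hand enumeration on the tiny fixture", {
  img <- fixture_images()$tiny_glcm
  cfg <- glcm_config(levels = 3, symmetric = FALSE, normalized = FALSE)
  P <- compute_glcm(img, cfg, 0)$P
  expected <- matrix(0, 3, 3)
  expected[1, 1] <- 2; expected[1, 2] <- 2; expected[1, 3] <- 1
  expected[3, 3] <- 1
  expect_equal(P, expected, ignore_attr = TRUE)

  # symmetrization adds the transpose
  cfg_s <- glcm_config(levels = 3, symmetric = TRUE, normalized = FALSE)
  expect_equal(compute_glcm(img, cfg_s, 0)$P, expected + t(expected),
               ignore_attr = TRUE)
})

test_that("constant image GLCM puts all mass on one diagonal cell", {
  img <- fixture_images()$constant
  cfg <- glcm_config(levels = 256)
  for (a in c(0, 45, 90, 135)) {
    P <- compute_glcm(img, cfg, a)$P
    expect_equal(P[8, 8], 1)           # gray level 7
    expect_equal(sum(P), 1)
  }
})

test_that("normalized GLCMs sum to 1 and symmetric GLCMs equal their transpose", {
  set.seed(11)
  for (i in 1:10) {
    img <- random_gray_image(12, 15, 8)
    cfg <- glcm_config(levels = 8)
    for (a in c(0, 45, 90, 135)) {
      g <- compute_glcm(img, cfg, a)
      expect_equal(sum(g$P), 1, tolerance = 1e-12)
      expect_equal(g$P, t(g$P))
      expect_true(all(g$P >= 0))
    }
  }
})

test_that("glcm_properties agrees with the brute-force double-loop oracle", {
  set.seed(23)
  for (i in 1:20) {
    img <- random_gray_image(16, 16, 8)
    g <- compute_glcm(img, glcm_config(levels = 8), sample(c(0, 45, 90, 135), 1))
    expect_equal(glcm_properties(g), oracle_glcm_properties(g$P),
                 tolerance = 1e-10)
  }
})

test_that("GLCM property ranges hold on random images", {
  set.seed(37)
  for (i in 1:100) {
    img <- random_gray_image(10, 10, 8)
    v <- glcm_feature_vector(img, glcm_config(levels = 8))
    expect_gte(v[["contrast"]], 0)
    expect_gte(v[["dissimilarity"]], 0)
    expect_true(v[["homogeneity"]] > 0 && v[["homogeneity"]] <= 1)
    expect_true(v[["energy"]] > 0 && v[["energy"]] <= 1)
    expect_true(v[["correlation"]] >= -1 && v[["correlation"]] <= 1 + 1e-12)
  }
})

test_that("degenerate and analytic property values are exact", {
  f <- fixture_images()
  v <- glcm_properties(compute_glcm(f$constant, glcm_config(), 0))
  expect_equal(unname(v), c(0, 0, 1, 1, 1))
  # uniform diagonal matrix: identity / L
  L <- 8
  g <- structure(list(P = diag(L) / L,
                      config = glcm_config(levels = L), angle = 0),
                 class = "glcm")
  v <- glcm_properties(g)
  expect_equal(unname(v[1:4]), c(0, 0, 1, 1 / sqrt(L)))
  # checkerboard at 0 degrees: all mass on (0,255)/(255,0)
  v <- glcm_properties(compute_glcm(f$checkerboard, glcm_config(), 0))
  expect_equal(v[["contrast"]], 255^2)
  expect_equal(v[["correlation"]], -1)
})

test_that("energy config flag switches between ASM and its square root", {
  img <- random_gray_image(16, 16, 8)
  e_sqrt <- glcm_properties(compute_glcm(img, glcm_config(levels = 8), 0))
  g_asm <- compute_glcm(img, glcm_config(levels = 8, energy = "asm"), 0)
  e_asm <- glcm_properties(g_asm)
  expect_equal(e_sqrt[["energy"]]^2, e_asm[["energy"]], tolerance = 1e-12)
})

test_that("angle-averaged vector is the mean of the per-angle vectors", {
  img <- generate_texture_image(default_texture_specs()[[3]], 5, 1)
  cfg <- glcm_config()
  per <- sapply(c(0, 45, 90, 135),
                function(a) glcm_properties(compute_glcm(img, cfg, a)))
  expect_equal(glcm_feature_vector(img, cfg), rowMeans(per))
  # horizontal stripes: the vertical offset crosses them, the horizontal
  # offset does not
  expect_gt(per["contrast", 3], per["contrast", 1])
  # single-angle config returns that angle's properties
  cfg1 <- glcm_config(angles = 90)
  expect_equal(glcm_feature_vector(img, cfg1),
               glcm_properties(compute_glcm(img, cfg1, 90)))
})

test_that("compute_glcm validates levels, angle and image size", {
  img <- random_gray_image(8, 8, 256)
  expect_error(compute_glcm(img, glcm_config(levels = 8), 0), "levels")
  expect_error(compute_glcm(img, glcm_config(angles = 0), 90), "angle")
  tiny <- gray_image(matrix(0:8, 3, 3), levels = 16)
  expect_error(compute_glcm(tiny, glcm_config(levels = 16, distance = 5), 0),
               "offset")
  expect_error(glcm_properties(
    compute_glcm(img, glcm_config(normalized = FALSE), 0)), "normalized")
})

test_that("LBP codes match the per-pixel comparison oracle", {
  set.seed(51)
  for (i in 1:10) {
    img <- random_gray_image(16, 16, 256)
    expect_identical(lbp_code_image(img), oracle_lbp_codes(img$pixels))
  }
})

test_that("LBP analytic codes: constant, single peak, horizontal ramp", {
  f <- fixture_images()
  expect_true(all(lbp_code_image(f$constant) == 255L))  # ties count as set
  peak <- matrix(5L, 7, 7); peak[4, 4] <- 200L
  codes <- lbp_code_image(gray_image(peak))
  expect_identical(codes[3, 3], 0L)  # strictly greater than all neighbors
  ramp <- lbp_code_image(f$hramp)
  # neighbors with column >= center: bits 1..5 -> 2+4+8+16+32
  expect_true(all(ramp == 62L))
})

test_that("LBP is invariant to adding a constant to all pixels", {
  set.seed(77)
  img <- random_gray_image(16, 16, 128)
  shifted <- gray_image(img$pixels + 100L, levels = 256L)
  expect_identical(lbp_code_image(img), lbp_code_image(shifted))
})

test_that("LBP histogram is a 256-bin probability vector", {
  set.seed(91)
  for (img in list(random_gray_image(16, 16, 256),
                   fixture_images()$checkerboard)) {
    h <- lbp_histogram(lbp_code_image(img))
    expect_length(h, 256L)
    expect_equal(sum(h), 1, tolerance = 1e-12)
    expect_true(all(h >= 0))
  }
  h <- lbp_histogram(lbp_code_image(fixture_images()$constant))
  expect_equal(h[["lbp_255"]], 1)
  expect_equal(sum(h[-256]), 0)
  expect_equal(unname(lbp_histogram(c(rep(0L, 10), rep(255L, 10)))[c(1, 256)]),
               c(0.5, 0.5))
  expect_error(lbp_histogram(integer()), "empty")
})
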