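test_that("digital disk features match analytic values", {
  px <- 1
  d <- digital_disk(100L)
  fe <- extract_features(as_frame(d, px = px))
  expect_lt(abs(fe$area_um2 - pi * 100^2) / (pi * 100^2), 0.01)
  expect_lt(abs(fe$equivalent_diameter_um - 200), 1)
  expect_lt(abs(fe$major_axis_um - 200) / 200, 0.02)
})

test_that("disk compactness is 1.00 +/- 0.02 for radius >= 50 px", {
  for (r in c(50L, 100L, 150L)) {
    fe <- extract_features(as_frame(digital_disk(r), px = 1))
    cmp <- compactness(fe$area_um2, fe$perimeter_um)
    expect_lt(abs(cmp - 1), 0.02)
  }
})

test_that("ellipse moment axes match semi-axes within 2%", {
  fe <- extract_features(as_frame(digital_ellipse(100L, 40L), px = 1))
  expect_lt(abs(fe$major_axis_um / 2 - 100) / 100, 0.02)
  expect_lt(abs(fe$minor_axis_um / 2 - 40) / 40, 0.02)
})

test_that("feature extraction agrees with a brute-force pixel oracle", {
  # independent oracle: explicit per-pixel loops and eigen decomposition
  oracle <- function(mask, px) {
    n <- 0; sx <- 0; sy <- 0
    for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
      if (mask[i, j]) { n <- n + 1; sx <- sx + (j - 1); sy <- sy + (i - 1) }
    }
    cx <- sx / n; cy <- sy / n
    sxx <- 0; syy <- 0; sxy <- 0
    for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
      if (mask[i, j]) {
        sxx <- sxx + ((j - 1) - cx)^2
        syy <- syy + ((i - 1) - cy)^2
        sxy <- sxy + ((j - 1) - cx) * ((i - 1) - cy)
      }
    }
    ev <- eigen(matrix(c(sxx / n + 1 / 12, sxy / n, sxy / n, syy / n + 1 / 12), 2),
                symmetric = TRUE)$values
    list(area = n * px^2, centroid = c(cx, cy) * px,
         major = 4 * sqrt(ev[1]) * px, minor = 4 * sqrt(ev[2]) * px)
  }
  shapes <- list(digital_disk(12L), digital_ellipse(20L, 8L),
                 digital_bar(30L, 5L))
  for (m in shapes) {
    fe <- extract_features(as_frame(m, px = 2))
    o <- oracle(m, 2)
    expect_equal(fe$area_um2, o$area)
    expect_equal(c(fe$centroid_x_um, fe$centroid_y_um), o$centroid,
                 tolerance = 1e-12)
    expect_equal(fe$major_axis_um, o$major, tolerance = 1e-9)
    expect_equal(fe$minor_axis_um, o$minor, tolerance = 1e-9)
  }
})

test_that("features are unit-consistent across pixel sizes", {
  fe1 <- extract_features(as_frame(digital_disk(100L), px = 1))   # 200 um disk
  fe2 <- extract_features(as_frame(digital_disk(50L), px = 2))    # same, coarser
  for (col in c("area_um2", "perimeter_um", "major_axis_um",
                "equivalent_diameter_um")) {
    expect_lt(abs(fe1[[col]] - fe2[[col]]) / fe1[[col]], 0.05)
  }
})

test_that("compactness and SII satisfy their closed forms and identities", {
  r <- runif(5, 1, 500)
  expect_equal(compactness(pi * r^2, 2 * pi * r), rep(1, 5))
  s <- runif(5, 1, 500)
  expect_equal(compactness(s^2, 4 * s), rep(pi / 4, 5))
  expect_equal(shape_irregularity_index(pi * r^2, 2 * pi * r), rep(1, 5))
  expect_equal(shape_irregularity_index(s^2, 4 * s), rep(2 / sqrt(pi), 5))
  # algebraic identity, exact
  a <- runif(20, 0.1, 1000); p <- runif(20, 0.1, 1000)
  expect_equal(shape_irregularity_index(a, p)^2 * compactness(a, p),
               rep(1, 20), tolerance = 1e-12)
  # scale invariance: A -> k^2 A, P -> k P
  k <- 7.3
  expect_equal(compactness(k^2 * a, k * p), compactness(a, p))
  expect_equal(shape_irregularity_index(k^2 * a, k * p),
               shape_irregularity_index(a, p))
})

test_that("compactness and SII reject non-positive input", {
  expect_error(compactness(0, 1), "positive")
  expect_error(compactness(1, -2), "positive")
  expect_error(shape_irregularity_index(-1, 1), "positive")
})

test_that("hole filling applies to the droplet label only", {
  img <- matrix(0L, 40, 40)
  img[5:25, 5:25] <- 1L
  img[10:15, 10:15] <- 0L   # droplet hole: artifact, filled
  img[28:38, 28:38] <- 2L
  img[31:35, 31:35] <- 0L   # organoid lumen: kept, adds perimeter
  fr <- mask_frame(img, 1, validate = FALSE)
  fe <- extract_features(fr)
  drop <- fe[fe$label == 1L, ]
  org <- fe[fe$label == 2L, ]
  expect_equal(drop$area_um2, 21^2)             # hole filled
  expect_equal(org$area_um2, 11^2 - 5^2)        # lumen kept
  # lumen contributes boundary: perimeter exceeds the outer square's
  expect_gt(org$perimeter_um, 4 * 11 * 0.94)
})

test_that("mask_frame validates label images", {
  expect_error(mask_frame(matrix(-1L, 3, 3), 1), "non-negative")
  expect_error(mask_frame(matrix(0.5, 3, 3), 1), "integer-valued")
  expect_error(mask_frame(matrix(0L, 3, 3), -1), "positive scalar")
  two <- matrix(0L, 10, 10); two[2:3, 2:3] <- 1L; two[7:8, 7:8] <- 1L
  expect_error(mask_frame(two, 1), "single connected")
})
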