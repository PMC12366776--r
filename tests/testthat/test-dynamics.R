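concentric_frame <- function(R_px, r_px, px = 1) {
  n <- 2L * R_px + 9L
  c0 <- (n + 1) / 2
  img <- matrix(0L, n, n)
  dd <- outer(seq_len(n) - c0, seq_len(n) - c0, function(i, j) sqrt(i^2 + j^2))
  img[dd <= R_px] <- 1L
  img[dd <= r_px] <- 2L
  mask_frame(img, px, droplet_id = 1, day = 1, validate = FALSE)
}

test_that("normalized_min_distance is exact for concentric disks", {
  fr <- concentric_frame(100L, 40L)
  expect_lt(abs(normalized_min_distance(fr) - 0.60), 1.5 / 100)  # ~1 px
})

test_that("an organoid touching the droplet boundary gives distance ~0", {
  n <- 120L
  img <- matrix(0L, n, n)
  dd <- outer(seq_len(n) - 60, seq_len(n) - 60, function(i, j) sqrt(i^2 + j^2))
  img[dd <= 50] <- 1L
  ee <- outer(seq_len(n) - 60, seq_len(n) - 95, function(i, j) sqrt(i^2 + j^2))
  img[ee <= 15 & dd <= 50] <- 2L   # ellipse pressed against the boundary
  fr <- mask_frame(img, 1, validate = FALSE)
  # touching at pixel level opens the droplet bite, which is flagged
  expect_lt(suppressWarnings(normalized_min_distance(fr)), 0.03)
})

test_that("radial_position matches an analytic offset", {
  n <- 221L
  img <- matrix(0L, n, n)
  dd <- outer(seq_len(n) - 111, seq_len(n) - 111, function(i, j) sqrt(i^2 + j^2))
  img[dd <= 100] <- 1L
  ee <- outer(seq_len(n) - 111, seq_len(n) - 141, function(i, j) sqrt(i^2 + j^2))
  img[ee <= 20] <- 2L    # centroid offset 30 px in radius 100
  fr <- mask_frame(img, 1, validate = FALSE)
  expect_lt(abs(radial_position(fr) - 0.30), 0.02)
  expect_lt(radial_position(concentric_frame(80L, 30L)), 0.01)
})

test_that("partially escaped organoids are flagged and measured inside", {
  n <- 120L
  img <- matrix(0L, n, n)
  dd <- outer(seq_len(n) - 60, seq_len(n) - 60, function(i, j) sqrt(i^2 + j^2))
  img[dd <= 40] <- 1L
  img[55:65, 95:110] <- 2L            # mostly outside the droplet
  img[55:65, 85:95] <- 2L             # a bit inside
  fr <- mask_frame(img, 1, validate = FALSE)
  expect_warning(normalized_min_distance(fr), "outside")
  expect_warning(radial_position(fr), "outside")
})

test_that("distance and radial position agree with generator ground truth", {
  cfg <- config_large_droplets(seed = 11, n_droplets = 4)
  for (id in 1:4) {
    dr <- generate_droplet_mask(cfg, id, 2)
    og <- generate_organoid_mask(cfg, id, 2,
                                 if (id %% 2) "spheroid" else "branched",
                                 droplet = dr)
    img <- dr$label_image
    img[og$frame$label_image == 2L] <- 2L
    fr <- mask_frame(img, cfg$pixel_size_um, id, 2, validate = FALSE)
    r_px <- og$truth$true_diameter_um / 2 / cfg$pixel_size_um
    expect_lt(abs(normalized_min_distance(fr) - og$truth$true_min_boundary_distance),
              2 / r_px)   # within 2 px
    expect_lt(abs(radial_position(fr) - og$truth$true_radial_position), 0.03)
  }
})

test_that("radial placement follows the uniform-in-area square-root law", {
  # identical droplets and organoids: the only randomness is placement
  cfg <- synthetic_config(droplet_diameter_um = 400, diameter_cv = 0,
                          pixel_size_um = 2, size_cv = 0,
                          growth_curve = c("2" = 80),
                          contraction_schedule = c("2" = 0),
                          n_droplets = 60L, seed = 31)
  off <- vapply(1:60, function(id) {
    og <- generate_organoid_mask(cfg, id, 2, "spheroid")
    og$truth$true_radial_position * og$truth$true_diameter_um / 2
  }, numeric(1))
  s_max <- 200 - 40 - 6            # R_inner - a/2 - placement margin
  u <- (off / s_max)^2             # should be U(0, 1)
  expect_gt(stats::ks.test(u, "punif")$p.value, 0.01)
})

test_that("contraction_series handles constant and missing data", {
  cs <- contraction_series(rep(500, 10), rep(c(2, 6), 5))
  expect_equal(cs$contraction_percent, c(0, 0))
  expect_equal(cs$ci_lower, c(0, 0))
  expect_equal(cs$ci_upper, c(0, 0))
  expect_error(contraction_series(c(500, 490), c(4, 6), baseline_day = 2),
               "baseline")
})

test_that("contraction estimate is invariant to pixel size", {
  d_um <- c(700, 710, 690, 620, 610, 630)
  day <- c(2, 2, 2, 6, 6, 6)
  a <- contraction_series(d_um, day, n_boot = 10, seed = 1)
  b <- contraction_series(d_um, day, n_boot = 10, seed = 1)  # um in, um out
  expect_identical(a, b)
  expect_equal(a$contraction_percent[2], 100 * (1 - mean(c(620, 610, 630)) / 700))
})

test_that("bootstrap CI covers a known contraction in seeded replications", {
  # synthetic diameters: baseline N(700, 10), day 6 contracted 12%
  hits <- 0L
  n_rep <- 200L
  for (rep in seq_len(n_rep)) {
    set.seed(rep)
    base <- rnorm(23, 700, 10)
    d6 <- rnorm(23, 700 * 0.88, 10)
    cs <- contraction_series(c(base, d6), rep(c(2, 6), each = 23),
                             n_boot = 300, seed = rep)
    truth <- 12
    if (cs$ci_lower[2] <= truth && truth <= cs$ci_upper[2]) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.90)
})

test_that("droplet compactness decreases with deformation amplitude", {
  cfg <- synthetic_config(droplet_diameter_um = 500, diameter_cv = 0,
                          pixel_size_um = 2,
                          growth_curve = c("2" = 60, "4" = 90, "6" = 120),
                          contraction_schedule = c("2" = 0, "4" = 0.06, "6" = 0.16),
                          n_droplets = 6L, seed = 17)
  frames <- list()
  for (id in 1:6) for (day in c(2, 4, 6)) {
    frames[[length(frames) + 1L]] <- generate_droplet_mask(cfg, id, day)
  }
  cs <- droplet_compactness_series(frames)
  expect_equal(cs$day, c(2, 4, 6))
  expect_true(all(diff(cs$mean_compactness) < 0))
  # undeformed day: compactness 1.00 +/- 0.02
  expect_lt(abs(cs$mean_compactness[1] - 1), 0.02)
  # single-day input
  one <- droplet_compactness_series(frames[1])
  expect_equal(nrow(one), 1L)
})
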