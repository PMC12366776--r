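test_that("generation is deterministic: same seed and ids give identical masks", {
  cfg <- tiny_config(seed = 5)
  a <- generate_droplet_mask(cfg, 1, 6)
  b <- generate_droplet_mask(cfg, 1, 6)
  expect_identical(a$label_image, b$label_image)
  oa <- generate_organoid_mask(cfg, 1, 6, "branched")
  ob <- generate_organoid_mask(cfg, 1, 6, "branched")
  expect_identical(oa$frame$label_image, ob$frame$label_image)
  expect_identical(oa$truth, ob$truth)
  # different ids differ
  expect_false(identical(a$label_image,
                         generate_droplet_mask(cfg, 2, 6)$label_image))
})

test_that("droplet equivalent diameter follows the contraction schedule within 1 px", {
  cfg <- synthetic_config(droplet_diameter_um = 750, diameter_cv = 0,
                          pixel_size_um = 2,
                          growth_curve = c("2" = 60, "6" = 160),
                          contraction_schedule = c("2" = 0, "6" = 0.12),
                          seed = 2)
  d2 <- generate_droplet_mask(cfg, 1, 2)
  fe2 <- extract_features(d2)
  expect_lt(abs(fe2$equivalent_diameter_um - 750), cfg$pixel_size_um)
  d6 <- generate_droplet_mask(cfg, 1, 6)
  fe6 <- extract_features(d6)
  expect_lt(abs(fe6$equivalent_diameter_um - 0.88 * 750), cfg$pixel_size_um)
  expect_equal(attr(d6, "truth")$true_diameter_um, 0.88 * 750)
})

test_that("oversized droplets raise an explicit sizing error", {
  expect_error(synthetic_config(droplet_diameter_um = 750, pixel_size_um = 2,
                                image_shape_px = c(128, 128)),
               "fit inside the image")
  cfg <- tiny_config()
  expect_error(generate_droplet_mask(cfg, 1, 99), "not in contraction_schedule")
})

test_that("config invariants are enforced", {
  expect_error(tiny_config(branched_fraction = 1.2), "branched_fraction")
  expect_error(tiny_config(contraction_schedule = c("2" = 0.1, "6" = 0.05)),
               "non-decreasing")
  expect_error(tiny_config(contraction_schedule = c("2" = 0, "6" = 1.0)),
               "in \\[0, 1\\)")
  expect_error(tiny_config(spheroid_axis_ratio_range = c(0.5, 1.5)), "0, 1")
})

test_that("spheroid phantoms have the constructed major axis within 2 px", {
  cfg <- tiny_config(seed = 3, size_cv = 0)
  for (id in 1:3) {
    og <- generate_organoid_mask(cfg, id, 6, "spheroid")
    fe <- extract_features(og$frame)
    expect_lt(abs(fe$major_axis_um - og$truth$true_major_axis_um),
              2 * cfg$pixel_size_um)
    expect_gt(fe$minor_axis_um / fe$major_axis_um, 0.6)  # constructed margin
  }
})

test_that("spheroid major axes are non-decreasing along the growth curve", {
  cfg <- config_large_droplets(seed = 4, n_droplets = 3)
  for (id in 1:3) {
    axes <- vapply(c(2, 4, 5, 6), function(day) {
      extract_features(generate_organoid_mask(cfg, id, day, "spheroid")$frame)$major_axis_um
    }, numeric(1))
    expect_true(all(diff(axes) >= -1e-9))
  }
})

test_that("branched phantoms record >= 2 branch lengths above the census threshold", {
  cfg <- config_large_droplets(seed = 8)
  for (id in 1:5) {
    og <- generate_organoid_mask(cfg, id, 4, "branched")
    expect_gte(sum(og$truth$true_branch_lengths_um >= 35), 2)
  }
})

test_that("seeding simulation matches its Poisson mean and distribution", {
  cfg <- config_large_droplets(seed = 10)   # lambda ~ 1.13 for 756 um, 5000/ml
  n <- 1e5
  draws <- simulate_seeding(cfg, n)
  lambda <- cfg$cell_concentration_per_ml *
    droplet_volume_nl(cfg$droplet_diameter_um) / 1e6
  se <- sqrt(lambda / n)
  expect_lt(abs(mean(draws) - lambda), 3 * se)
  # chi-square goodness of fit, bins 0..5 and >= 6
  obs <- tabulate(pmin(draws, 6L) + 1L, nbins = 7L)
  p <- c(dpois(0:5, lambda), 1 - ppois(5, lambda))
  expect_gt(stats::chisq.test(obs, p = p)$p.value, 0.01)
  # zero concentration
  expect_true(all(simulate_seeding(tiny_config(cell_concentration_per_ml = 0),
                                   1000) == 0L))
})

test_that("write_dataset produces a complete, lossless, internally consistent set", {
  cfg <- tiny_config(seed = 6, n_droplets = 3L)
  dir <- tempfile("ds")
  man_path <- write_dataset(cfg, dir)
  man <- read_manifest(man_path)
  expect_equal(nrow(man), 3L * 2L)  # 3 droplets x 2 days
  expect_equal(sort(list.files(dir, pattern = "\\.tif$")), sort(basename(man$file)))
  # round-trip: arrays identical to the in-memory phantoms
  i <- 4L
  fr <- read_mask(man$file[i], man$pixel_size_um[i], man$droplet_id[i], man$day[i])
  dr <- generate_droplet_mask(cfg, man$droplet_id[i], man$day[i])
  expect_identical(fr$label_image > 0L, dr$label_image > 0L)
  # referential integrity manifest <-> ground truth
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_setequal(paste(gt$droplet_id, gt$day),
                  paste(man$droplet_id, man$day))
  unlink(dir, recursive = TRUE)
})

test_that("a fixed seed yields a byte-identical dataset", {
  cfg <- tiny_config(seed = 9, n_droplets = 2L)
  d1 <- tempfile("a"); d2 <- tempfile("b")
  write_dataset(cfg, d1); write_dataset(cfg, d2)
  for (f in list.files(d1)) {
    b1 <- readBin(file.path(d1, f), "raw", file.info(file.path(d1, f))$size)
    b2 <- readBin(file.path(d2, f), "raw", file.info(file.path(d2, f))$size)
    expect_identical(b1, b2)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("malformed manifests are rejected with the offending row", {
  cfg <- tiny_config(seed = 6, n_droplets = 2L)
  dir <- tempfile("ds")
  man_path <- write_dataset(cfg, dir)
  man <- utils::read.csv(man_path)
  man$pixel_size_um[2] <- -1
  bad <- file.path(dir, "bad.csv")
  utils::write.csv(man, bad, row.names = FALSE)
  expect_error(read_manifest(bad), "row 2")
  utils::write.csv(man[, -3], bad, row.names = FALSE)
  expect_error(read_manifest(bad), "lacks column")
  unlink(dir, recursive = TRUE)
})
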