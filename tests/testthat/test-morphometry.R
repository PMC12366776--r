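fake_features <- function(a, b) list(major_axis_um = a, minor_axis_um = b)
fake_census <- function(lengths) {
  structure(list(n_branches = sum(lengths >= 30),
                 branch_lengths_um = lengths,
                 skeleton_length_um = sum(lengths)),
            class = "branch_census")
}

test_that("classification reproduces the four threshold cases", {
  expect_equal(classify_structure(fake_features(50, 10), fake_census(c(45, 40, 35))),
               "spheroid")   # a < 60
  expect_equal(classify_structure(fake_features(100, 60), fake_census(c(45, 40, 35))),
               "spheroid")   # b > a/2
  expect_equal(classify_structure(fake_features(100, 30), fake_census(c(45, 40))),
               "branched")   # fails all three spheroid criteria
  expect_equal(classify_structure(fake_features(100, 30), fake_census(c(45, 25))),
               "spheroid")   # only one branch >= 30 um
})

test_that("classification is monotone across the major-axis threshold", {
  cen <- fake_census(c(45, 40))
  calls <- vapply(seq(20, 120, by = 5), function(a)
    classify_structure(fake_features(a, 0.3 * a), cen), character(1))
  # spheroid below 60, branched at and above (b/a fixed at 0.3, 2 branches)
  expect_true(all(calls[seq(20, 120, by = 5) < 60] == "spheroid"))
  expect_true(all(calls[seq(20, 120, by = 5) >= 60] == "branched"))
})

test_that("the conjunctive combination mode is available", {
  f <- fake_features(50, 10)       # a < 60 but b <= a/2 and 3 branches
  cen <- fake_census(c(45, 40, 35))
  expect_equal(classify_structure(f, cen, combine = "or"), "spheroid")
  expect_equal(classify_structure(f, cen, combine = "and"), "branched")
})

test_that("a disk has no qualifying branches", {
  cen <- branch_census(digital_disk(30L), 1)
  expect_equal(cen$n_branches, 0L)
})

test_that("a straight bar's skeleton length shows only end effects", {
  cen <- branch_census(digital_bar(100L, 10L), 1)
  # rectangle skeleton: length minus about one width of end effects
  expect_gt(cen$skeleton_length_um, 85)
  expect_lt(cen$skeleton_length_um, 102)
  # an open tube is two half-branches
  expect_equal(length(cen$branch_lengths_um), 2L)
  expect_equal(cen$n_branches, 2L)
})

test_that("branch census recovers generator ground truth", {
  cfg <- config_large_droplets(seed = 7)
  for (id in 1:6) {
    og <- generate_organoid_mask(cfg, id, 4, "branched")
    cen <- branch_census(og$frame$label_image == 2L, cfg$pixel_size_um)
    truth <- sort(og$truth$true_branch_lengths_um, decreasing = TRUE)
    meas <- sort(cen$branch_lengths_um, decreasing = TRUE)
    expect_equal(length(meas), length(truth))        # count: exact
    k <- min(2L, length(truth))
    expect_lt(max(abs(meas[1:k] - truth[1:k]) / truth[1:k]), 0.10)
  }
})

test_that("phantoms of both classes are classified correctly (class validity)", {
  for (maker in list(config_large_droplets, config_small_droplets)) {
    cfg <- maker(seed = 21)
    for (id in 1:4) {
      for (cls in c("spheroid", "branched")) {
        og <- generate_organoid_mask(cfg, id, 4, cls)
        fe <- extract_features(og$frame)
        cen <- branch_census(og$frame$label_image == 2L, cfg$pixel_size_um)
        expect_equal(classify_structure(fe, cen), cls,
                     label = paste(cls, "id", id))
      }
    }
  }
})

test_that("pdi follows its conventions and invariances", {
  expect_equal(pdi(rep(7, 10)), 0)
  expect_equal(pdi(c(5)), 0)
  expect_equal(pdi(c(1, 3)), 50)                       # population s.d. / mean
  expect_equal(pdi(c(1, 3), convention = "sample"), 100 * sd(c(1, 3)) / 2)
  expect_equal(pdi(c(1, 3), convention = "squared"), 25)
  set.seed(1); x <- rlnorm(50, 0, 0.5)
  expect_equal(pdi(10 * x), pdi(x))                    # scale invariance
  # winsorising towards the mean reduces PDI
  w <- pmin(pmax(x, quantile(x, 0.1)), quantile(x, 0.9))
  expect_lt(pdi(w), pdi(x))
  expect_error(pdi(numeric(0)), "empty")
  expect_error(pdi(c(1, -1)), "positive")
})

test_that("branched_fraction reports mean +/- sd across experiments", {
  # three experiments engineered to fractions 0.54, 0.59, 0.64
  mk <- function(f, n) c(rep("branched", round(f * n)),
                         rep("spheroid", n - round(f * n)))
  cls <- c(mk(0.54, 100), mk(0.59, 100), mk(0.64, 100))
  exp <- rep(c("e1", "e2", "e3"), each = 100)
  bf <- branched_fraction(cls, exp)
  expect_equal(bf$mean_percent, 59)
  expect_equal(bf$sd_percent, 100 * sd(c(0.54, 0.59, 0.64)))
  expect_equal(bf$n_structures, 300L)

  one <- branched_fraction(c("branched", "spheroid"), c(1, 1))
  expect_equal(one$mean_percent, 50)
  expect_equal(one$sd_percent, 0)

  expect_equal(branched_fraction(rep("spheroid", 5), rep(1, 5))$mean_percent, 0)
  expect_error(branched_fraction(character(0), character(0)), "no structures")
  expect_error(branched_fraction(c("weird"), 1), "unknown classification")
})

test_that("growth_summary handles degenerate day groups", {
  gs <- growth_summary(c(100, 120, 90), c(2, 2, 4))
  expect_equal(gs$day, c(2, 4))
  expect_equal(gs$sd_major_axis_um[2], 0)
  expect_true(gs$single_measurement[2])
  expect_warning(growth_summary(c(100, NA), c(2, 4)), "dropping")
  expect_equal(nrow(growth_summary(numeric(0), numeric(0))), 0L)
})

test_that("growth summary recovers the generator growth curve", {
  cfg <- config_large_droplets(seed = 13, size_cv = 0, n_droplets = 4)
  rows <- list()
  for (id in 1:4) for (day in c(2, 4, 6)) {
    og <- generate_organoid_mask(cfg, id, day, "spheroid")
    fe <- extract_features(og$frame)
    rows[[length(rows) + 1L]] <- data.frame(day = day, a = fe$major_axis_um,
                                            truth = og$truth$true_major_axis_um)
  }
  df <- do.call(rbind, rows)
  gs <- growth_summary(df$a, df$day)
  truth_means <- tapply(df$truth, df$day, mean)
  expect_true(all(abs(gs$mean_major_axis_um - truth_means) <=
                    2 * cfg$pixel_size_um))
})
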