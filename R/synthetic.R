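#' Synthetic droplet/organoid mask generator configuration
#'
#' Describes a stated world of droplet-confined organoid cultures from which
#' ground-truthed binary masks are generated: droplet size regime (with
#' relative diameter spread), per-day expected organoid major axis (growth
#' curve), per-day fractional droplet contraction, branching geometry, and
#' Poisson cell seeding. Defaults mirror the large-droplet regime
#' (756 +/- 30 um droplets, 5000 cells/ml); see [config_small_droplets()]
#' and [config_large_droplets()] for the two published regimes.
#'
#' Phantoms are constructed away from the classification thresholds so that
#' class membership is unambiguous: spheroids get minor/major axis ratio from
#' `spheroid_axis_ratio_range` (default well above 1/2), branched phantoms
#' get at least two branches of at least `branch_length_range_um[1]`
#' (default 35 um, above the 30 um census threshold) arranged along a common
#' axis so the whole structure is elongated.
#'
#' @param droplet_diameter_um Mean droplet diameter (um).
#' @param diameter_cv Relative s.d. of the per-droplet diameter.
#' @param pixel_size_um Pixel edge length (um).
#' @param image_shape_px Image (rows, cols); `NULL` = smallest comfortable fit.
#' @param n_droplets Number of droplets in a generated dataset.
#' @param branched_fraction Probability that a droplet's organoid is branched.
#' @param growth_curve Named numeric vector, day -> expected organoid major
#'   axis (um); must be non-decreasing.
#' @param contraction_schedule Named numeric vector, day -> fractional
#'   droplet diameter reduction in `[0, 1)`; must be non-decreasing.
#' @param branch_count_range Integer range of branch counts for branched
#'   phantoms (min >= 2).
#' @param branch_length_range_um Range of branch path lengths (um), min >= 35
#'   recommended to stay clear of the 30 um census threshold.
#' @param branch_width_um Tube width of phantom branches (um).
#' @param spheroid_axis_ratio_range Range of minor/major axis ratios for
#'   spheroid phantoms, within (0, 1].
#' @param size_cv Relative s.d. of the per-droplet organoid size multiplier
#'   (drives the polydispersity of the culture).
#' @param cell_concentration_per_ml Cell concentration of the dispersed phase.
#' @param organoids_per_droplet Structures per droplet (default 1).
#' @param seed Integer master seed; all randomness derives from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(droplet_diameter_um = 756,
                             diameter_cv = 30 / 756,
                             pixel_size_um = 2,
                             image_shape_px = NULL,
                             n_droplets = 24L,
                             branched_fraction = 0.59,
                             growth_curve = c("2" = 60, "4" = 200, "5" = 266, "6" = 300),
                             contraction_schedule = c("2" = 0, "4" = 0.02, "5" = 0.05, "6" = 0.12),
                             branch_count_range = c(2L, 4L),
                             branch_length_range_um = c(35, 65),
                             branch_width_um = 10,
                             spheroid_axis_ratio_range = c(0.65, 0.95),
                             size_cv = 0.25,
                             cell_concentration_per_ml = 5000,
                             organoids_per_droplet = 1L,
                             seed = 1L) {
  .check(droplet_diameter_um > 0, "droplet_diameter_um must be positive")
  .check(diameter_cv >= 0, "diameter_cv must be non-negative")
  .check(pixel_size_um > 0, "pixel_size_um must be positive")
  .check(n_droplets >= 1, "n_droplets must be a positive integer")
  .check(branched_fraction >= 0 && branched_fraction <= 1,
         "branched_fraction must be in [0, 1]")
  .check(all(contraction_schedule >= 0) && all(contraction_schedule < 1),
         "contraction fractions must be in [0, 1)")
  days_c <- as.numeric(names(contraction_schedule))
  .check(!anyNA(days_c), "contraction_schedule must be named by day")
  .check(!is.unsorted(contraction_schedule[order(days_c)]),
         "contraction_schedule must be non-decreasing in day")
  days_g <- as.numeric(names(growth_curve))
  .check(!anyNA(days_g), "growth_curve must be named by day")
  .check(!is.unsorted(growth_curve[order(days_g)]),
         "growth_curve must be non-decreasing in day")
  .check(length(branch_count_range) == 2 && branch_count_range[1] >= 2,
         "branch_count_range must be an integer interval with min >= 2")
  .check(all(branch_length_range_um > 0) && diff(branch_length_range_um) >= 0,
         "branch_length_range_um must be a positive interval")
  .check(branch_width_um > 0, "branch_width_um must be positive")
  .check(all(spheroid_axis_ratio_range > 0) && all(spheroid_axis_ratio_range <= 1),
         "spheroid_axis_ratio_range must lie in (0, 1]")
  .check(cell_concentration_per_ml >= 0, "cell_concentration_per_ml must be >= 0")
  worst_d <- droplet_diameter_um * (1 + 3 * diameter_cv)
  if (is.null(image_shape_px)) {
    n <- ceiling(worst_d / pixel_size_um) + 16L
    n <- as.integer(2L * ceiling(n / 2))
    image_shape_px <- c(n, n)
  }
  .check(length(image_shape_px) == 2 && all(image_shape_px >= 8),
         "image_shape_px must be two positive integers")
  if (worst_d + 8 * pixel_size_um > min(image_shape_px) * pixel_size_um)
    stop("droplet does not fit inside the image at all days: need >= ",
         ceiling((worst_d + 8 * pixel_size_um) / pixel_size_um),
         " px, image is ", min(image_shape_px), " px")
  structure(list(droplet_diameter_um = droplet_diameter_um,
                 diameter_cv = diameter_cv,
                 pixel_size_um = pixel_size_um,
                 image_shape_px = as.integer(image_shape_px),
                 n_droplets = as.integer(n_droplets),
                 branched_fraction = branched_fraction,
                 growth_curve = growth_curve,
                 contraction_schedule = contraction_schedule,
                 branch_count_range = as.integer(branch_count_range),
                 branch_length_range_um = branch_length_range_um,
                 branch_width_um = branch_width_um,
                 spheroid_axis_ratio_range = spheroid_axis_ratio_range,
                 size_cv = size_cv,
                 cell_concentration_per_ml = cell_concentration_per_ml,
                 organoids_per_droplet = as.integer(organoids_per_droplet),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Preset configurations for the two droplet regimes
#'
#' Small droplets: 373 +/- 21 um, 30 000 cells/ml, lower branched fraction
#' (0.44) and tighter size spread. Large droplets: 756 +/- 30 um,
#' 5000 cells/ml, branched fraction 0.59, wider size spread and stronger
#' day-6 contraction (12% vs 5%).
#'
#' @param seed Integer master seed.
#' @param ... Overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
config_small_droplets <- function(seed = 1L, ...) {
  args <- list(droplet_diameter_um = 373, diameter_cv = 21 / 373,
               cell_concentration_per_ml = 30000,
               branched_fraction = 0.44,
               growth_curve = c("2" = 40, "4" = 120, "5" = 150, "6" = 170),
               contraction_schedule = c("2" = 0, "4" = 0.02, "5" = 0.04, "6" = 0.05),
               size_cv = 0.14, seed = seed)
  do.call(synthetic_config, utils::modifyList(args, list(...)))
}

#' @rdname config_small_droplets
#' @export
config_large_droplets <- function(seed = 1L, ...) {
  do.call(synthetic_config, utils::modifyList(list(seed = seed), list(...)))
}

# ---- continuous droplet geometry -------------------------------------------

# radius of the (possibly deformed) droplet at polar angle theta
.geom_radius <- function(geom, theta) {
  r <- rep(geom$R0, length(theta))
  for (m in seq_along(geom$ks)) {
    r <- r + geom$R0 * geom$amps[m] * cos(geom$ks[m] * theta + geom$phases[m])
  }
  r
}

# Continuous geometry of droplet `droplet_id` at `day`: centre (um, 0-based
# pixel coordinates), base radius and Fourier perturbation. The equivalent
# diameter equals base diameter x (1 - contraction) exactly (the perturbation
# is area-compensated); amplitude = 0.5 x contraction fraction.
.droplet_geometry <- function(cfg, droplet_id, day) {
  key <- as.character(day)
  if (!key %in% names(cfg$contraction_schedule))
    stop("day ", day, " not in contraction_schedule")
  contraction <- cfg$contraction_schedule[[key]]
  z <- with_seed(derive_seed(cfg$seed, "droplet-size", droplet_id),
                 max(-3, min(3, stats::rnorm(1))))
  base_d <- cfg$droplet_diameter_um * (1 + cfg$diameter_cv * z)
  d_day <- base_d * (1 - contraction)
  amp <- 0.5 * contraction
  ks <- 2:4
  shape <- with_seed(derive_seed(cfg$seed, "droplet-shape", droplet_id, day), {
    raw <- stats::runif(length(ks))
    list(w = raw / sum(raw), phases = stats::runif(length(ks), 0, 2 * pi))
  })
  amps <- amp * shape$w
  R0 <- (d_day / 2) / sqrt(1 + 0.5 * sum(amps^2))
  nrp <- cfg$image_shape_px[1]; ncp <- cfg$image_shape_px[2]
  list(cx = (ncp - 1) / 2 * cfg$pixel_size_um,
       cy = (nrp - 1) / 2 * cfg$pixel_size_um,
       R0 = R0, ks = ks, amps = amps, phases = shape$phases,
       base_diameter_um = base_d, diameter_um = d_day,
       contraction = contraction, day = day)
}

# ---- rasterisers ------------------------------------------------------------

# evaluate `inside(x_um, y_um)` on the pixel window covering the disk of
# radius `r_um` around (cx, cy) and place the result into a full-size mask
.raster_window <- function(shape, px, cx, cy, r_um, inside) {
  i0 <- max(1L, floor(cy / px) + 1L - ceiling(r_um / px) - 1L)
  i1 <- min(shape[1], floor(cy / px) + 1L + ceiling(r_um / px) + 1L)
  j0 <- max(1L, floor(cx / px) + 1L - ceiling(r_um / px) - 1L)
  j1 <- min(shape[2], floor(cx / px) + 1L + ceiling(r_um / px) + 1L)
  mask <- matrix(FALSE, shape[1], shape[2])
  if (i0 > i1 || j0 > j1) return(mask)
  xw <- matrix((seq(j0, j1) - 1) * px, i1 - i0 + 1L, j1 - j0 + 1L, byrow = TRUE)
  yw <- matrix((seq(i0, i1) - 1) * px, i1 - i0 + 1L, j1 - j0 + 1L)
  mask[i0:i1, j0:j1] <- inside(xw, yw)
  mask
}

.rasterize_droplet <- function(geom, shape, px) {
  rmax <- geom$R0 * (1 + sum(abs(geom$amps)))
  .raster_window(shape, px, geom$cx, geom$cy, rmax, function(x, y) {
    dx <- x - geom$cx; dy <- y - geom$cy
    sqrt(dx^2 + dy^2) <= .geom_radius(geom, atan2(dy, dx))
  })
}

.rasterize_ellipse <- function(shape, px, cx, cy, a_full, b_full, theta0) {
  .raster_window(shape, px, cx, cy, a_full / 2, function(x, y) {
    dx <- x - cx; dy <- y - cy
    u <- (dx * cos(theta0) + dy * sin(theta0)) / (a_full / 2)
    v <- (-dx * sin(theta0) + dy * cos(theta0)) / (b_full / 2)
    u^2 + v^2 <= 1
  })
}

# stamp disks of radius `radius_um` at points (n x 2 matrix, um) into mask
.stamp_points <- function(mask, pts, radius_um, px) {
  r_px <- radius_um / px
  rr <- floor(r_px)
  off <- expand.grid(di = -rr:rr, dj = -rr:rr)
  off <- off[off$di^2 + off$dj^2 <= r_px^2, , drop = FALSE]
  i0 <- round(pts[, 2] / px) + 1L
  j0 <- round(pts[, 1] / px) + 1L
  ii <- rep(i0, each = nrow(off)) + rep(off$di, times = length(i0))
  jj <- rep(j0, each = nrow(off)) + rep(off$dj, times = length(j0))
  keep <- ii >= 1L & ii <= nrow(mask) & jj >= 1L & jj <= ncol(mask)
  mask[cbind(ii[keep], jj[keep])] <- TRUE
  mask
}

#' Generate a droplet mask
#'
#' Rasterises one droplet at one day: a filled, simply-connected disk whose
#' equivalent diameter equals the droplet's base diameter times
#' (1 - contraction at `day`), deformed by a smooth low-order Fourier radial
#' perturbation whose relative amplitude is half the contraction fraction
#' (undeformed at day of zero contraction, increasingly irregular as the
#' organoid pulls on the matrix). Same config, id and day always produce the
#' identical mask.
#'
#' @param cfg A [synthetic_config()].
#' @param droplet_id Droplet identifier (integer).
#' @param day Acquisition day; must be in the contraction schedule.
#' @return A [mask_frame()] with droplet label 1. Attribute `"truth"` holds
#'   `true_diameter_um` (the exact continuous equivalent diameter) and the
#'   contraction; attribute `"geom"` the continuous boundary geometry.
#' @export
generate_droplet_mask <- function(cfg, droplet_id, day) {
  stopifnot(inherits(cfg, "synthetic_config"))
  geom <- .droplet_geometry(cfg, droplet_id, day)
  px <- cfg$pixel_size_um
  max_r <- geom$R0 * (1 + sum(geom$amps))
  if (2 * max_r + 6 * px > min(cfg$image_shape_px) * px)
    stop("droplet too large for image (droplet_id=", droplet_id,
         ", diameter ", round(geom$diameter_um), " um)")
  m <- .rasterize_droplet(geom, cfg$image_shape_px, px)
  img <- matrix(0L, cfg$image_shape_px[1], cfg$image_shape_px[2])
  img[m] <- 1L
  fr <- mask_frame(img, px, droplet_id = droplet_id, day = day, validate = FALSE)
  attr(fr, "geom") <- geom
  attr(fr, "truth") <- list(droplet_id = droplet_id, day = day,
                            true_diameter_um = geom$diameter_um,
                            contraction = geom$contraction)
  fr
}

# persistent per-droplet organoid parameters (identical across days)
.organoid_params <- function(cfg, droplet_id) {
  with_seed(derive_seed(cfg$seed, "organoid", droplet_id), {
    list(size_mult = max(0.3, 1 + cfg$size_cv * max(-2.5, min(2.5, stats::rnorm(1)))),
         axis_ratio = stats::runif(1, cfg$spheroid_axis_ratio_range[1],
                                   cfg$spheroid_axis_ratio_range[2]),
         theta0 = stats::runif(1, 0, 2 * pi),
         place_u = stats::runif(1),
         place_phi = stats::runif(1, 0, 2 * pi),
         n_branches = sample(seq(cfg$branch_count_range[1],
                                 cfg$branch_count_range[2]), 1),
         main_jit = stats::runif(2, -pi / 18, pi / 18),
         len_jit = stats::runif(2, 0.92, 1.08),
         # alternate sides so extra branches do not pile up laterally; wide
         # enough that tubes separate from the mains within ~1 tube width
         extra_sign = sample(c(-1, 1), 1) * (-1)^(seq_len(4)),
         extra_ang = stats::runif(4, 50, 62) * pi / 180,
         extra_len = stats::runif(4, cfg$branch_length_range_um[1],
                                  cfg$branch_length_range_um[2]))
  })
}

# random-walk polyline of total length L from p0 in direction h0, constrained
# to stay inside the droplet with clearance; returns n x 2 matrix of points
# (1 um step) and the achieved length
.branch_walk <- function(geom, p0, h0, L, clearance, rng_seed) {
  with_seed(rng_seed, {
    step <- 1
    n_steps <- max(2L, ceiling(L / step))
    pts <- matrix(NA_real_, n_steps + 1L, 2L)
    pts[1L, ] <- p0
    h <- h0
    dev <- 0
    ok_len <- 0
    inside <- function(p) {
      dx <- p[1] - geom$cx; dy <- p[2] - geom$cy
      sqrt(dx^2 + dy^2) <= .geom_radius(geom, atan2(dy, dx)) - clearance
    }
    for (s in seq_len(n_steps)) {
      turn <- stats::rnorm(1, 0, 4 * pi / 180)
      turn <- max(-8, min(8, turn * 180 / pi)) * pi / 180
      # curvature cap, tighter near the root so the tube leaves the body
      # radially and cannot curl back along it
      dev_max <- min(20, 20 * ok_len / 30) * pi / 180
      if (abs(dev + turn) > dev_max) turn <- -sign(dev) * abs(turn)
      h_try <- h + turn
      len <- if (s == n_steps) L - ok_len else step
      cand <- pts[s, ] + len * c(cos(h_try), sin(h_try))
      if (!inside(cand)) {
        # bend towards the droplet centre until the step fits
        to_c <- atan2(geom$cy - pts[s, 2], geom$cx - pts[s, 1])
        fixed <- FALSE
        for (b in seq_len(9)) {
          frac <- b / 9
          h_b <- h_try + frac * (((to_c - h_try + pi) %% (2 * pi)) - pi)
          cand_b <- pts[s, ] + len * c(cos(h_b), sin(h_b))
          if (inside(cand_b)) { h_try <- h_b; cand <- cand_b; fixed <- TRUE; break }
        }
        if (!fixed) break  # walk truncated; caller validates achieved length
      }
      dev <- dev + (h_try - h)
      h <- h_try
      pts[s + 1L, ] <- cand
      ok_len <- ok_len + len
    }
    keep <- !is.na(pts[, 1])
    list(pts = pts[keep, , drop = FALSE], length = ok_len)
  })
}

# point on the boundary of a rotated ellipse in polar direction `ang`
.ellipse_boundary_point <- function(cx, cy, a_full, b_full, theta0, ang) {
  a <- a_full / 2; b <- b_full / 2
  rel <- ang - theta0
  r <- a * b / sqrt((b * cos(rel))^2 + (a * sin(rel))^2)
  c(cx + r * cos(ang), cy + r * sin(ang))
}

# outward surface normal direction at the boundary point of polar angle `ang`
.ellipse_normal_dir <- function(a_full, b_full, theta0, ang) {
  a <- a_full / 2; b <- b_full / 2
  rel <- ang - theta0
  t <- atan2(a * sin(rel), b * cos(rel))   # ellipse parameter of the point
  theta0 + atan2(a * sin(t), b * cos(t))   # normal ~ (b cos t, a sin t) rotated
}

.ellipse_boundary_samples <- function(cx, cy, a_full, b_full, theta0, n = 256L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-1L]
  a <- a_full / 2; b <- b_full / 2
  x <- a * cos(t); y <- b * sin(t)
  cbind(cx + x * cos(theta0) - y * sin(theta0),
        cy + x * sin(theta0) + y * cos(theta0))
}

# exact continuous minimal distance from organoid boundary samples to the
# droplet boundary polygon (dense vertex sampling)
.truth_min_distance <- function(geom, org_pts, n_poly = 1024L) {
  th <- seq(0, 2 * pi, length.out = n_poly + 1L)[-1L]
  r <- .geom_radius(geom, th)
  bx <- geom$cx + r * cos(th); by <- geom$cy + r * sin(th)
  mind <- Inf
  chunk <- 256L
  for (s in seq(1L, nrow(org_pts), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(org_pts))
    dd <- outer(org_pts[s:e, 1], bx, "-")^2 + outer(org_pts[s:e, 2], by, "-")^2
    mind <- min(mind, sqrt(min(dd)))
  }
  mind
}

#' Generate an organoid mask with ground truth
#'
#' Constructs an unambiguous member of the requested class inside the droplet
#' of the same `(droplet_id, day)`. Spheroids are rotated ellipses with
#' minor/major ratio drawn from `spheroid_axis_ratio_range`; branched
#' phantoms are an elliptical body with two opposed main branches (plus
#' optional extra branches) built as constant-width tubes along curvature-
#' capped random-walk polylines with recorded path lengths. The organoid is
#' placed uniformly in area within the feasible centre region and always lies
#' entirely inside the droplet.
#'
#' @inheritParams generate_droplet_mask
#' @param true_class `"spheroid"` or `"branched"`.
#' @param droplet Optional [generate_droplet_mask()] result for the same id
#'   and day (regenerated if omitted).
#' @return List with `frame` (a [mask_frame()], organoid label 2, no droplet
#'   label) and `truth` (ground-truth record: `droplet_id`, `day`,
#'   `true_class`, `true_diameter_um`, `true_major_axis_um`,
#'   `true_branch_lengths_um`, `true_min_boundary_distance_um` (normalised by
#'   the droplet equivalent radius), `true_radial_position`, `cells_seeded`).
#' @export
generate_organoid_mask <- function(cfg, droplet_id, day,
                                   true_class = c("spheroid", "branched"),
                                   droplet = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  true_class <- match.arg(true_class)
  # without a rasterised droplet the continuous geometry suffices: the
  # construction margins guarantee containment
  geom <- if (is.null(droplet)) .droplet_geometry(cfg, droplet_id, day)
  else attr(droplet, "geom")
  px <- cfg$pixel_size_um
  shape <- cfg$image_shape_px
  key <- as.character(day)
  if (!key %in% names(cfg$growth_curve))
    stop("day ", day, " not in growth_curve")
  par <- .organoid_params(cfg, droplet_id)
  target_a <- cfg$growth_curve[[key]] * par$size_mult
  th_grid <- seq(0, 2 * pi, length.out = 256L)
  R_inner <- min(.geom_radius(geom, th_grid))
  margin <- 6
  w <- cfg$branch_width_um

  if (true_class == "spheroid") {
    a <- target_a
    max_off <- R_inner - a / 2 - margin
    if (max_off < 0) {           # shrink to fit, centred
      a <- 2 * (R_inner - margin) * 0.98
      if (a < 10) stop("organoid does not fit inside droplet (droplet_id=",
                       droplet_id, ", day=", day, ")")
      max_off <- 0
    }
    b <- par$axis_ratio * a
    off <- sqrt(par$place_u) * max_off
    cx <- geom$cx + off * cos(par$place_phi)
    cy <- geom$cy + off * sin(par$place_phi)
    m <- .rasterize_ellipse(shape, px, cx, cy, a, b, par$theta0)
    org_pts <- .ellipse_boundary_samples(cx, cy, a, b, par$theta0)
    truth_a <- a
    branch_lengths <- numeric(0)
  } else {
    min_len <- max(35, cfg$branch_length_range_um[1])
    E <- max(target_a, 120)
    E_max <- 2 * (R_inner - margin - w / 2)
    if (E > E_max) E <- E_max
    # circular body: curvature radius (17 um) well above both the tube
    # half-width and the census body threshold, so the body/branch boundary
    # is sharp everywhere and the body stays light enough that the whole
    # structure remains elongated (b well below a/2)
    body_a <- 34
    body_b <- body_a
    L_main <- (E - body_a) / 2
    if (L_main < min_len)
      stop("requested branch length incompatible with droplet radius ",
           "(droplet_id=", droplet_id, ", day=", day, ")")
    max_off <- R_inner - E / 2 - w / 2 - margin
    off <- sqrt(par$place_u) * max(max_off, 0)
    cx <- geom$cx + off * cos(par$place_phi)
    cy <- geom$cy + off * sin(par$place_phi)
    dirs <- c(par$theta0 + par$main_jit[1], par$theta0 + pi + par$main_jit[2])
    lens <- pmax(min_len, L_main * par$len_jit[1:2])
    n_extra <- par$n_branches - 2L
    if (n_extra > 0L) {
      for (e in seq_len(n_extra)) {
        # extras only on structures long enough to host them unambiguously
        len_e <- min(par$extra_len[e], 0.7 * L_main)
        if (len_e < min_len + 3) next
        # anchored to the actual main direction: >= 50 degrees of separation
        base_dir <- dirs[if (e %% 2L == 1L) 1L else 2L]
        dir_e <- base_dir + par$extra_sign[e] * par$extra_ang[e]
        # lateral-extent cap: keep the whole structure elongated (b << a/2)
        lat <- abs(sin(dir_e - par$theta0)) * len_e + body_a / 2
        if (lat > 0.23 * E) next
        dirs <- c(dirs, dir_e)
        lens <- c(lens, len_e)
      }
    }
    m <- .rasterize_ellipse(shape, px, cx, cy, body_a, body_b, par$theta0)
    branch_lengths <- numeric(length(dirs))
    org_pts <- .ellipse_boundary_samples(cx, cy, body_a, body_b, par$theta0, 128L)
    for (k in seq_along(dirs)) {
      p0 <- .ellipse_boundary_point(cx, cy, body_a, body_b, par$theta0, dirs[k])
      # launch along the surface normal so the tube leaves the body cleanly
      h0 <- .ellipse_normal_dir(body_a, body_b, par$theta0, dirs[k])
      wk <- .branch_walk(geom, p0, h0, lens[k], clearance = w / 2 + 4,
                         rng_seed = derive_seed(cfg$seed, "walk", droplet_id, k))
      if (wk$length < min_len)
        stop("requested branch length incompatible with droplet radius ",
             "(droplet_id=", droplet_id, ", day=", day, ", branch ", k, ")")
      branch_lengths[k] <- wk$length
      m <- .stamp_points(m, wk$pts, w / 2, px)
      # tube envelope samples for the continuous distance truth
      nrm <- cbind(-diff(wk$pts[, 2]), diff(wk$pts[, 1]))
      nn <- sqrt(rowSums(nrm^2)); nrm <- nrm / pmax(nn, 1e-9)
      mid <- wk$pts[-1L, , drop = FALSE]
      org_pts <- rbind(org_pts, mid + (w / 2) * nrm, mid - (w / 2) * nrm,
                       wk$pts[nrow(wk$pts), , drop = FALSE] +
                         (w / 2) * c(cos(dirs[k]), sin(dirs[k])))
    }
    truth_a <- E
  }
  # guarantee containment in the rasterised droplet
  if (!is.null(droplet)) m <- m & (droplet$label_image == 1L)
  img <- matrix(0L, shape[1], shape[2])
  img[m] <- 2L
  fr <- mask_frame(img, px, droplet_id = droplet_id, day = day, validate = FALSE)
  cells <- with_seed(derive_seed(cfg$seed, "cells", droplet_id), {
    lambda <- cfg$cell_concentration_per_ml *
      droplet_volume_nl(geom$base_diameter_um) / 1e6
    stats::rpois(1, lambda)
  })
  R_eq <- geom$diameter_um / 2
  min_dist_um <- .truth_min_distance(geom, org_pts)
  off_um <- sqrt((cx - geom$cx)^2 + (cy - geom$cy)^2)
  truth <- list(droplet_id = droplet_id, day = day,
                true_class = true_class,
                true_diameter_um = geom$diameter_um,
                true_major_axis_um = truth_a,
                true_branch_lengths_um = branch_lengths,
                true_min_boundary_distance_um = min_dist_um,
                true_min_boundary_distance = min_dist_um / R_eq,
                true_radial_position = off_um / R_eq,
                cells_seeded = cells)
  list(frame = fr, truth = truth)
}

#' Generate a screening set of organoid structures
#'
#' Convenience wrapper for classification experiments: draws the class of
#' each structure from `cfg$branched_fraction` and generates the organoid
#' mask (without rasterising the droplet) at one screening day, as done when
#' screening droplets for spheroids versus branched structures.
#'
#' @param cfg A [synthetic_config()].
#' @param n_structures Number of structures to generate.
#' @param day Screening day (must be in the growth curve and contraction
#'   schedule).
#' @return List with one element per structure: `frame` (organoid
#'   [mask_frame()]) and `truth` (see [generate_organoid_mask()]).
#' @export
generate_screen <- function(cfg, n_structures, day) {
  stopifnot(inherits(cfg, "synthetic_config"), n_structures >= 1)
  lapply(seq_len(n_structures), function(id) {
    generate_organoid_mask(cfg, id, day, .droplet_class(cfg, id))
  })
}

#' Simulate Poisson cell seeding
#'
#' Independent Poisson counts of encapsulated cells per droplet with mean
#' \eqn{\lambda} = cell concentration x nominal droplet volume; the
#' brute-force counterpart of the analytic [occupancy()] model.
#'
#' @param cfg A [synthetic_config()].
#' @param n Number of droplets to draw (default `cfg$n_droplets`).
#' @return Integer vector of per-droplet cell counts.
#' @export
simulate_seeding <- function(cfg, n = cfg$n_droplets) {
  stopifnot(inherits(cfg, "synthetic_config"))
  lambda <- cfg$cell_concentration_per_ml *
    droplet_volume_nl(cfg$droplet_diameter_um) / 1e6
  with_seed(derive_seed(cfg$seed, "seeding", n), stats::rpois(n, lambda))
}

# class of the organoid in droplet `droplet_id` (fixed across days)
.droplet_class <- function(cfg, droplet_id) {
  u <- with_seed(derive_seed(cfg$seed, "class", droplet_id), stats::runif(1))
  if (u < cfg$branched_fraction) "branched" else "spheroid"
}

#' Write a synthetic dataset to disk
#'
#' Generates `cfg$n_droplets` droplets over every day present in both the
#' contraction schedule and the growth curve, and writes per-frame 16-bit
#' label TIFFs (droplet label 1, organoid label 2), a manifest CSV
#' (`droplet_id,day,file,pixel_size_um`), a ground-truth JSON and a config
#' echo. Fixed seed gives a byte-identical dataset; files round-trip
#' losslessly through [read_mask()].
#'
#' @param cfg A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @return Path of the manifest CSV, invisibly usable by the pipeline.
#' @export
write_dataset <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("directory not writable: ", out_dir)
  days <- sort(as.numeric(intersect(names(cfg$contraction_schedule),
                                    names(cfg$growth_curve))))
  if (length(days) == 0L) stop("no day present in both growth_curve and contraction_schedule")
  manifest <- list(); truths <- list()
  for (id in seq_len(cfg$n_droplets)) {
    cls <- .droplet_class(cfg, id)
    for (day in days) {
      dr <- generate_droplet_mask(cfg, id, day)
      og <- generate_organoid_mask(cfg, id, day, cls, droplet = dr)
      img <- dr$label_image
      img[og$frame$label_image == 2L] <- 2L
      file <- sprintf("droplet%03d_day%d.tif", id, day)
      write_label_tiff(img, file.path(out_dir, file))
      manifest[[length(manifest) + 1L]] <-
        data.frame(droplet_id = id, day = day, file = file,
                   pixel_size_um = cfg$pixel_size_um)
      truths[[length(truths) + 1L]] <- og$truth
    }
  }
  man <- do.call(rbind, manifest)
  man_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE)
  jsonlite::write_json(truths, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg_json <- cfg
  class(cfg_json) <- NULL
  jsonlite::write_json(cfg_json, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  man_path
}

#' Read a dataset manifest
#'
#' @param manifest_path Path to a `manifest.csv` written by [write_dataset()]
#'   (or following the same schema).
#' @return Data frame with columns `droplet_id`, `day`, `file`,
#'   `pixel_size_um`; `file` resolved relative to the manifest directory.
#' @export
read_manifest <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("no such manifest: ", manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("droplet_id", "day", "file", "pixel_size_um")
  missing <- setdiff(need, names(man))
  if (length(missing))
    stop("manifest ", manifest_path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  bad <- which(is.na(man$droplet_id) | is.na(man$day) | !nzchar(man$file) |
                 is.na(man$pixel_size_um) | man$pixel_size_um <= 0)
  if (length(bad))
    stop("malformed manifest row ", bad[1], " in ", manifest_path)
  man$file <- file.path(dirname(manifest_path), man$file)
  man
}
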