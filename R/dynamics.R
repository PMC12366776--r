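#' Droplet contraction over time
#'
#' Population-level contraction relative to a baseline day:
#' `100 * (1 - mean(d_day) / mean(d_baseline))` per day, with a seeded
#' percentile bootstrap confidence interval (resampling droplets within the
#' day and the baseline independently). The ratio of means is used because
#' droplets in a cross-sectional screen are not tracked individually across
#' days.
#'
#' @param diameter_um Droplet equivalent diameters (um).
#' @param day Acquisition day per diameter.
#' @param baseline_day Reference day; default the earliest observed.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return Data frame sorted by day: `day`, `n`, `mean_diameter_um`,
#'   `contraction_percent`, `ci_lower`, `ci_upper`.
#' @export
contraction_series <- function(diameter_um, day, baseline_day = NULL,
                               n_boot = 1000, level = 0.95, seed = 1L) {
  stopifnot(length(diameter_um) == length(day))
  if (length(day) == 0L) stop("no diameters")
  if (is.null(baseline_day)) baseline_day <- min(day)
  base <- diameter_um[day == baseline_day]
  if (length(base) == 0L) stop("baseline day ", baseline_day, " has no droplets")
  days <- sort(unique(day))
  rows <- lapply(days, function(d) {
    cur <- diameter_um[day == d]
    est <- 100 * (1 - mean(cur) / mean(base))
    boots <- with_seed(derive_seed(seed, "contraction", d), {
      vapply(seq_len(n_boot), function(i) {
        b <- base[sample.int(length(base), replace = TRUE)]
        cc <- cur[sample.int(length(cur), replace = TRUE)]
        100 * (1 - mean(cc) / mean(b))
      }, numeric(1))
    })
    ci <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE, type = 7)
    data.frame(day = d, n = length(cur), mean_diameter_um = mean(cur),
               contraction_percent = est, ci_lower = ci[1], ci_upper = ci[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# largest organoid component of a frame, as a logical mask (labels >= 2)
.largest_organoid <- function(frame) {
  org <- frame$label_image >= 2L
  if (!any(org)) return(NULL)
  comp <- label_components(org)
  sizes <- tabulate(comp[comp > 0L])
  comp == which.max(sizes)
}

# Droplet and organoid regions of a frame. The droplet label carves out the
# organoid, so an enclosed organoid is restored by hole filling; an organoid
# crossing the droplet boundary leaves the bite open, in which case the
# droplet outline is recovered by morphological closing, the frame is
# flagged, and only the interior organoid part is kept.
.frame_regions <- function(frame) {
  lab1 <- frame$label_image == 1L
  if (!any(lab1)) stop("frame has no droplet label")
  org <- .largest_organoid(frame)
  if (is.null(org)) stop("frame has no organoid component")
  drop <- fill_holes(lab1)
  flagged <- FALSE
  if (any(org & !drop)) {
    flagged <- TRUE
    r <- 12  # px; bridges openings narrower than ~2r
    dil <- dist_to_background(!drop) <= r
    ero <- dist_to_background(dil) > r
    drop <- fill_holes(drop | ero)
    org <- org & drop
    if (!any(org)) stop("organoid entirely outside droplet (droplet_id=",
                        frame$droplet_id, ", day=", frame$day, ")")
    warning("organoid extends outside the droplet (droplet_id=",
            frame$droplet_id, ", day=", frame$day, "); using interior part")
  }
  list(droplet = drop, organoid = org, flagged = flagged)
}

#' Normalised minimal organoid-droplet boundary distance
#'
#' Minimum Euclidean distance from the organoid boundary to the droplet
#' boundary, divided by the droplet's equivalent radius (the stable radius
#' choice for deformed droplets). With several organoid components, the
#' largest is used. An organoid touching the droplet boundary gives 0; an
#' organoid partly outside the droplet is flagged with a warning and measured
#' on its interior part.
#'
#' @param frame A [mask_frame()] containing a droplet (label 1) and at least
#'   one organoid component (labels >= 2).
#' @return Normalised distance in `[0, 1]`.
#' @export
normalized_min_distance <- function(frame) {
  stopifnot(inherits(frame, "mask_frame"))
  reg <- .frame_regions(frame)
  drop <- reg$droplet; org <- reg$organoid
  ob <- which(boundary_mask(org), arr.ind = TRUE)
  db <- which(boundary_mask(drop), arr.ind = TRUE)
  mind2 <- Inf
  for (s in seq(1L, nrow(ob), by = 512L)) {
    e <- min(s + 511L, nrow(ob))
    d2 <- outer(ob[s:e, 1], db[, 1], "-")^2 + outer(ob[s:e, 2], db[, 2], "-")^2
    mind2 <- min(mind2, min(d2))
  }
  r_eq <- sqrt(sum(drop) / pi)  # px
  min(1, sqrt(mind2) / r_eq)
}

#' Normalised radial position of the organoid
#'
#' Distance from the organoid centroid to the droplet centroid, divided by
#' the droplet equivalent radius: 0 for concentric placement, towards 1 near
#' the periphery.
#'
#' @inheritParams normalized_min_distance
#' @return Normalised radial position in `[0, 1]`.
#' @export
radial_position <- function(frame) {
  stopifnot(inherits(frame, "mask_frame"))
  reg <- .frame_regions(frame)
  drop <- reg$droplet; org <- reg$organoid
  oc <- which(org, arr.ind = TRUE)
  dc <- which(drop, arr.ind = TRUE)
  d_px <- sqrt(sum((colMeans(oc) - colMeans(dc))^2))
  r_eq <- sqrt(sum(drop) / pi)
  min(1, d_px / r_eq)
}

#' Per-day mean droplet compactness
#'
#' Mean of [compactness()] of the hole-filled droplet label per day; a
#' decrease over time captures the anisotropic deformation of droplets being
#' pulled on by growing organoids.
#'
#' @param frames List of [mask_frame()] objects (each with a droplet label).
#' @return Data frame sorted by day: `day`, `n`, `mean_compactness`.
#' @export
droplet_compactness_series <- function(frames) {
  stopifnot(length(frames) >= 1L)
  vals <- lapply(frames, function(fr) {
    fe <- extract_features(fr)
    fe <- fe[fe$label == 1L, , drop = FALSE]
    if (nrow(fe) == 0L) return(NULL)
    data.frame(day = fr$day,
               compactness = compactness(fe$area_um2, fe$perimeter_um))
  })
  vals <- do.call(rbind, vals)
  if (is.null(vals) || nrow(vals) == 0L) stop("no droplet labels in frames")
  groups <- split(vals$compactness, vals$day)
  out <- data.frame(day = as.numeric(names(groups)),
                    n = vapply(groups, length, integer(1)),
                    mean_compactness = vapply(groups, mean, numeric(1)))
  out <- out[order(out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}
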