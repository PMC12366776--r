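#' Skeleton-based branch census of a structure
#'
#' Computes the topological skeleton (Zhang-Suen thinning) of a single
#' connected component, prunes spurs shorter than `prune_um`, and measures
#' every branch as the geodesic path length along the skeleton from an
#' endpoint to the point where the branch ends: a skeleton junction, or the
#' entry into the structure's body. The body is where the local half-width
#' (Euclidean distance transform) exceeds `body_radius_um`; walking inward
#' from a branch tip, the walk stops where the transform reaches that depth
#' and the measured length is corrected by the predicted penetration
#' `sqrt(body_radius^2 - tube_halfwidth^2)` beyond the body boundary, so the
#' reported length runs from the tip to the body surface. A skeleton that is
#' a single open path with no junction and no body (an elongated tube) is
#' split at its midpoint into two branches.
#' Geodesic lengths use the same calibrated chain-code weights as the
#' perimeter estimator, so straight branches at arbitrary orientation are
#' measured without the staircase bias. Only branches of at least
#' `min_branch_um` count towards `n_branches`; all post-pruning branch
#' lengths are reported.
#'
#' @param mask Logical matrix (or 0/1 integer matrix), one connected component.
#' @param pixel_size_um Pixel edge length in micrometres.
#' @param min_branch_um Minimum qualifying branch length (um), default 30.
#' @param prune_um Spur-pruning length (um), default 10: removes pixelation
#'   artifacts far below the qualifying threshold without touching real
#'   branches.
#' @param body_radius_um Half-width above which a region counts as body (um);
#'   default 8, between typical branch half-widths (~5 um) and organoid body
#'   half-widths (>= 14 um).
#' @return List of class `branch_census`: `n_branches`, `branch_lengths_um`,
#'   `skeleton_length_um`.
#' @export
branch_census <- function(mask, pixel_size_um, min_branch_um = 30,
                          prune_um = 10, body_radius_um = 8) {
  if (is.numeric(mask)) mask <- mask > 0
  stopifnot(is.matrix(mask), pixel_size_um > 0)
  if (!any(mask)) stop("branch_census: empty component")
  cr <- crop_mask(mask, pad = 2L)
  m <- cr$mask
  skel <- skeletonize(m)
  px <- pixel_size_um
  edt <- dist_to_background(m)
  body <- edt >= body_radius_um / px

  paths <- .skeleton_paths(skel)
  # iterative spur pruning: drop endpoint->junction paths shorter than prune_um
  for (it in seq_len(6L)) {
    if (sum(skel) <= 2L) break
    spur <- FALSE
    for (p in paths$paths) {
      if (p$to_junction && p$length_px * px < prune_um) {
        skel[p$pixels] <- FALSE  # junction pixel itself is not on the path
        spur <- TRUE
      }
    }
    if (!spur) break
    paths <- .skeleton_paths(skel)
  }

  skl_len <- .skeleton_total_length(skel) * px
  lengths <- numeric(0)
  if (length(paths$paths)) {
    simple_path <- length(paths$paths) == 2L &&
      all(vapply(paths$paths, function(p) p$to_endpoint, logical(1)))
    for (p in paths$paths) {
      wsteps <- ifelse(abs(p$step_px - sqrt(2)) < 1e-9, PERIM_W_DIAG, PERIM_W_AXIAL)
      cum <- c(0, cumsum(wsteps))
      in_body <- body[p$pixels]
      hit <- which(in_body)
      if (in_body[1]) next  # endpoint already inside the body: not a branch
      if (length(hit)) {
        # tube half-width near the tip, for the penetration correction
        k <- min(5L, nrow(p$pixels))
        w_half <- stats::median(edt[p$pixels[seq_len(k), , drop = FALSE]]) * px
        pen <- sqrt(max(body_radius_um^2 - w_half^2, 0))
        lengths <- c(lengths, cum[hit[1]] * px - pen)
      } else if (p$to_junction) {
        lengths <- c(lengths, cum[length(cum)] * px)
      } else if (simple_path) {
        # open tube without a body: one path, counted once per endpoint;
        # each endpoint contributes its half of the path
        lengths <- c(lengths, cum[length(cum)] / 2 * px)
      } else {
        lengths <- c(lengths, cum[length(cum)] * px)
      }
    }
  }
  lengths <- lengths[lengths > 0]
  structure(list(n_branches = sum(lengths >= min_branch_um),
                 branch_lengths_um = lengths,
                 skeleton_length_um = skl_len),
            class = "branch_census")
}

#' @export
print.branch_census <- function(x, ...) {
  cat("<branch_census> ", x$n_branches, " qualifying branch(es); lengths (um): ",
      paste(round(x$branch_lengths_um, 1), collapse = ", "),
      "; skeleton ", round(x$skeleton_length_um, 1), " um\n", sep = "")
  invisible(x)
}

# Walk every endpoint path of a skeleton: from each endpoint along the
# skeleton until a junction (>= 3 neighbours) or another endpoint is reached.
# Returns for each path its pixel coordinates, per-step lengths (1 or sqrt 2)
# and flags. Paths are reported once per endpoint (a pure open path yields
# two mirror entries).
.skeleton_paths <- function(skel) {
  nb <- neighbour_count(skel)
  ep <- which(skel & nb == 1L, arr.ind = TRUE)
  nr <- nrow(skel); nc <- ncol(skel)
  paths <- list()
  if (nrow(ep)) {
    for (e in seq_len(nrow(ep))) {
      cur <- ep[e, ]
      pix <- matrix(cur, 1L, 2L)
      steps <- numeric(0)
      to_junction <- FALSE; to_endpoint <- FALSE
      repeat {
        # candidate next pixels: on the skeleton, not visited yet
        cand_r <- integer(0); cand_c <- integer(0); cand_d <- numeric(0)
        for (k in seq_len(8L)) {
          ri <- cur[1] + NEIGH8[k, 1]; ci <- cur[2] + NEIGH8[k, 2]
          if (ri < 1L || ri > nr || ci < 1L || ci > nc) next
          if (!skel[ri, ci]) next
          if (any(pix[, 1] == ri & pix[, 2] == ci)) next
          cand_r <- c(cand_r, ri); cand_c <- c(cand_c, ci)
          cand_d <- c(cand_d, if (all(NEIGH8[k, ] != 0L)) sqrt(2) else 1)
        }
        if (length(cand_r) == 0L) { to_endpoint <- nrow(pix) > 1L; break }
        if (length(cand_r) > 1L) {
          # mutually adjacent candidates are a staircase turn, not a junction
          mutual <- TRUE
          for (a in seq_along(cand_r)) for (b in seq_along(cand_r)) {
            if (a < b && max(abs(cand_r[a] - cand_r[b]), abs(cand_c[a] - cand_c[b])) > 1L)
              mutual <- FALSE
          }
          if (!mutual) { to_junction <- TRUE; break }
          pick <- which.min(cand_d)  # prefer the axial step through a staircase
        } else pick <- 1L
        steps <- c(steps, cand_d[pick])
        pix <- rbind(pix, c(cand_r[pick], cand_c[pick]))
        cur <- c(cand_r[pick], cand_c[pick])
        if (nb[cur[1], cur[2]] == 1L) { to_endpoint <- TRUE; break }
      }
      paths[[length(paths) + 1L]] <-
        list(pixels = pix, step_px = steps, length_px = sum(steps),
             to_junction = to_junction, to_endpoint = to_endpoint)
    }
  }
  list(paths = paths, endpoints = ep)
}

# total geodesic length of the skeleton: sum of 8-neighbour edges
# (1 for axial, sqrt(2) for diagonal), each edge counted once
.skeleton_total_length <- function(skel) {
  ax <- sum(skel & shift_mat(skel, 0L, 1L, FALSE)) +
    sum(skel & shift_mat(skel, 1L, 0L, FALSE))
  di <- sum(skel & shift_mat(skel, 1L, 1L, FALSE)) +
    sum(skel & shift_mat(skel, 1L, -1L, FALSE))
  ax + sqrt(2) * di
}

#' Spheroid versus branched classification
#'
#' A structure is a spheroid when any of the following holds (literal
#' disjunctive reading, the default): major axis \eqn{a} below `a_max_um`,
#' minor axis \eqn{b} above `axis_ratio` times \eqn{a}, or fewer than
#' `min_branches` branches of at least `min_branch_um`. Everything else is
#' branched (at least two qualifying branches, or an elongated invasive
#' phenotype). `combine = "and"` switches to the conjunctive reading.
#'
#' @param features One row of [extract_features()] output (or any list with
#'   `major_axis_um` and `minor_axis_um`).
#' @param census A [branch_census()] for the same component.
#' @param a_max_um Major-axis spheroid threshold (um), default 60.
#' @param axis_ratio Minor/major ratio threshold, default 1/2.
#' @param min_branch_um Qualifying branch length (um), default 30.
#' @param min_branches Minimum number of qualifying branches, default 2.
#' @param combine `"or"` (default) or `"and"`: how the three spheroid
#'   criteria are combined.
#' @return `"spheroid"` or `"branched"`.
#' @export
classify_structure <- function(features, census, a_max_um = 60, axis_ratio = 1 / 2,
                               min_branch_um = 30, min_branches = 2,
                               combine = c("or", "and")) {
  combine <- match.arg(combine)
  a <- features$major_axis_um
  b <- features$minor_axis_um
  n_q <- sum(census$branch_lengths_um >= min_branch_um)
  crit <- c(a < a_max_um, b > axis_ratio * a, n_q < min_branches)
  spheroid <- if (combine == "or") any(crit) else all(crit)
  if (spheroid) "spheroid" else "branched"
}

#' Polydispersity index of projected areas
#'
#' Relative spread of the projected organoid areas used as a homogeneity
#' measure of the culture: 100 x s.d.(A) / mean(A). The default uses the
#' population s.d. (divisor n); `convention = "sample"` divides by n - 1, and
#' `convention = "squared"` returns the squared relative spread
#' 100 x var/mean^2.
#'
#' @param areas Positive projected areas (any consistent unit).
#' @param convention `"population"` (default), `"sample"` or `"squared"`.
#' @return PDI in percent (0 for a constant or single-element population).
#' @export
pdi <- function(areas, convention = c("population", "sample", "squared")) {
  convention <- match.arg(convention)
  if (length(areas) == 0L) stop("pdi: empty input")
  if (any(!is.finite(areas)) || any(areas <= 0)) stop("pdi: areas must be positive")
  m <- mean(areas)
  n <- length(areas)
  if (n == 1L) return(0)
  v_pop <- sum((areas - m)^2) / n
  switch(convention,
         population = 100 * sqrt(v_pop) / m,
         sample = 100 * stats::sd(areas) / m,
         squared = 100 * v_pop / m^2)
}

#' Branched fraction across experiments
#'
#' Per-experiment fraction of structures classified branched, reported as
#' mean +/- sample s.d. across experiments (s.d. 0 when there is a single
#' experiment), mirroring how screening probabilities are reported with
#' N independent experiments.
#'
#' @param classifications Character vector of `"spheroid"`/`"branched"` calls.
#' @param experiment Experiment identifier per structure (same length).
#' @return List: `per_experiment` (named fractions in \[0,1\]),
#'   `mean_percent`, `sd_percent`, `n_structures`.
#' @export
branched_fraction <- function(classifications, experiment) {
  stopifnot(length(classifications) == length(experiment))
  if (length(classifications) == 0L) stop("branched_fraction: no structures")
  bad <- setdiff(unique(classifications), c("spheroid", "branched"))
  if (length(bad)) stop("unknown classification: ", paste(bad, collapse = ", "))
  groups <- split(classifications == "branched", experiment)
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes == 0L))
    stop("empty experiment group: ", paste(names(groups)[sizes == 0L], collapse = ", "))
  fr <- vapply(groups, mean, numeric(1))
  list(per_experiment = fr,
       mean_percent = 100 * mean(fr),
       sd_percent = 100 * (if (length(fr) > 1L) stats::sd(fr) else 0),
       n_structures = length(classifications))
}

#' Per-day growth summary of the major axis
#'
#' @param major_axis_um Major axis per structure (um).
#' @param day Acquisition day per structure.
#' @return Data frame sorted by day: `day`, `n`, `mean_major_axis_um`,
#'   `sd_major_axis_um` (0 with `single_measurement = TRUE` when n = 1).
#'   Days with no structures are dropped with a warning.
#' @export
growth_summary <- function(major_axis_um, day) {
  stopifnot(length(major_axis_um) == length(day))
  keep <- !is.na(major_axis_um) & !is.na(day)
  if (any(!keep)) warning("dropping ", sum(!keep), " structure(s) with missing values")
  major_axis_um <- major_axis_um[keep]; day <- day[keep]
  if (length(day) == 0L)
    return(data.frame(day = numeric(0), n = integer(0),
                      mean_major_axis_um = numeric(0),
                      sd_major_axis_um = numeric(0),
                      single_measurement = logical(0)))
  groups <- split(major_axis_um, day)
  out <- data.frame(day = as.numeric(names(groups)),
                    n = vapply(groups, length, integer(1)),
                    mean_major_axis_um = vapply(groups, mean, numeric(1)),
                    sd_major_axis_um = vapply(groups, function(g)
                      if (length(g) > 1L) stats::sd(g) else 0, numeric(1)),
                    single_measurement = vapply(groups, function(g)
                      length(g) == 1L, logical(1)))
  out <- out[order(out$day), , drop = FALSE]
  rownames(out) <- NULL
  out
}
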