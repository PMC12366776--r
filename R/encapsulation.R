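# Closed-form droplet physics and occupancy statistics.
# Unit constants used throughout (documented here once, tested):
#   1 nl  = 1e6  um^3
#   1 ul  = 1e3  nl
#   1 ml  = 1e6  nl
#   1 h   = 3600 s
.NL_PER_UM3 <- 1e-6
.NL_PER_UL <- 1e3
.NL_PER_ML <- 1e6
.S_PER_H <- 3600

#' Encapsulation configuration
#'
#' Operating point of a droplet-generation run: droplet diameter, cell
#' concentration in the dispersed (collagen) phase, and the two volumetric
#' flow rates. The continuous (oil) flow sets droplet spacing only; droplet
#' volume and production rate are governed by the dispersed flow.
#'
#' @param droplet_diameter_um Droplet diameter in micrometres (> 0).
#' @param cell_concentration_per_ml Cells per millilitre of dispersed phase (>= 0).
#' @param dispersed_flow_ul_per_h Dispersed-phase (collagen) flow, microlitres per hour (> 0).
#' @param continuous_flow_ul_per_h Continuous-phase (oil) flow, microlitres per hour (> 0).
#' @return An object of class `encapsulation_config`.
#' @examples
#' cfg <- encapsulation_config(750, 5000)
#' occupancy(cfg)$lambda_cells
#' @export
encapsulation_config <- function(droplet_diameter_um,
                                 cell_concentration_per_ml,
                                 dispersed_flow_ul_per_h = 1000,
                                 continuous_flow_ul_per_h = 1000) {
  stopifnot(droplet_diameter_um > 0, cell_concentration_per_ml >= 0,
            dispersed_flow_ul_per_h > 0, continuous_flow_ul_per_h > 0)
  structure(list(droplet_diameter_um = droplet_diameter_um,
                 cell_concentration_per_ml = cell_concentration_per_ml,
                 dispersed_flow_ul_per_h = dispersed_flow_ul_per_h,
                 continuous_flow_ul_per_h = continuous_flow_ul_per_h),
            class = "encapsulation_config")
}

#' Droplet volume from diameter
#'
#' Sphere volume \eqn{(\pi/6) d^3} converted to nanolitres. A 370 um droplet
#' holds 26.5 nl (prints as 27), a 750 um droplet 220.9 nl (prints as 221).
#'
#' @param diameter_um Droplet diameter in micrometres (> 0); vectorised.
#' @return Volume in nanolitres.
#' @export
droplet_volume_nl <- function(diameter_um) {
  if (any(!is.finite(diameter_um)) || any(diameter_um <= 0))
    stop("diameter must be positive")
  (pi / 6) * diameter_um^3 * .NL_PER_UM3
}

#' Collagen volume fold between two droplet sizes
#'
#' @param d_large_um,d_small_um Diameters in micrometres (> 0).
#' @return `(d_large/d_small)^3`, the fold difference in per-cell matrix volume.
#' @export
volume_ratio <- function(d_large_um, d_small_um) {
  stopifnot(d_large_um > 0, d_small_um > 0)
  (d_large_um / d_small_um)^3
}

#' Droplet production rate
#'
#' Dispersed-phase volumetric flow divided by droplet volume, in droplets per
#' second. At 1000 ul/h collagen flow this gives about 10 Hz for 370 um
#' droplets and about 1 Hz for 750 um droplets.
#'
#' @param cfg An [encapsulation_config()].
#' @return Production rate in Hz.
#' @export
production_rate_hz <- function(cfg) {
  stopifnot(inherits(cfg, "encapsulation_config"))
  flow_nl_s <- cfg$dispersed_flow_ul_per_h * .NL_PER_UL / .S_PER_H
  flow_nl_s / droplet_volume_nl(cfg$droplet_diameter_um)
}

#' Poisson occupancy of droplets
#'
#' Cells are partitioned into droplets at random during droplet formation, so
#' per-droplet counts are Poisson with mean
#' \eqn{\lambda = c \times V} (concentration times droplet volume). Returns
#' the probability of empty, single-cell and multi-cell (two or more)
#' droplets: \eqn{e^{-\lambda}}, \eqn{\lambda e^{-\lambda}} and the
#' complement.
#'
#' @param cfg An [encapsulation_config()].
#' @return An object of class `occupancy_distribution`: list with
#'   `lambda_cells`, `p_empty`, `p_single`, `p_multi` (sum to 1 to 1e-12).
#' @export
occupancy <- function(cfg) {
  stopifnot(inherits(cfg, "encapsulation_config"))
  vol_ml <- droplet_volume_nl(cfg$droplet_diameter_um) / .NL_PER_ML
  lambda <- cfg$cell_concentration_per_ml * vol_ml
  p0 <- exp(-lambda)
  p1 <- lambda * exp(-lambda)
  structure(list(lambda_cells = lambda, p_empty = p0, p_single = p1,
                 p_multi = 1 - p0 - p1),
            class = "occupancy_distribution")
}

#' @export
print.occupancy_distribution <- function(x, ...) {
  cat(sprintf("<occupancy> lambda=%.3f cells/droplet: empty %.1f%%, single %.1f%%, multi %.1f%%\n",
              x$lambda_cells, 100 * x$p_empty, 100 * x$p_single, 100 * x$p_multi))
  invisible(x)
}

#' Organoid formation efficiency
#'
#' From per-droplet screening records, the fraction of droplets containing at
#' least one three-dimensional structure, summarised per experiment
#' (mean +/- sample s.d. across experiments), and the derived
#' organoids-per-seeded-cell yield: fraction with organoid divided by the
#' mean number of cells per droplet.
#'
#' @param has_structure Logical vector, one entry per screened droplet.
#' @param experiment Experiment identifier per droplet (same length).
#' @param mean_cells_per_droplet Mean occupancy \eqn{\lambda} of the screened
#'   droplets (e.g. from [occupancy()] or the mean of observed counts).
#' @return List with `per_experiment` (named fractions), `mean_percent`,
#'   `sd_percent` (0 when a single experiment), and `organoids_per_cell`.
#' @export
organoid_efficiency <- function(has_structure, experiment, mean_cells_per_droplet) {
  stopifnot(length(has_structure) == length(experiment),
            mean_cells_per_droplet > 0)
  if (length(has_structure) == 0L) stop("no droplet records")
  groups <- split(as.logical(has_structure), experiment)
  empty <- names(groups)[vapply(groups, length, integer(1)) == 0L]
  if (length(empty)) stop("empty experiment group: ", paste(empty, collapse = ", "))
  fr <- vapply(groups, mean, numeric(1))
  m <- mean(fr)
  s <- if (length(fr) > 1L) stats::sd(fr) else 0
  list(per_experiment = fr,
       mean_percent = 100 * m,
       sd_percent = 100 * s,
       organoids_per_cell = m / mean_cells_per_droplet)
}

#' Percentile bootstrap confidence interval
#'
#' Seeded percentile bootstrap of an arbitrary statistic: `n_boot` resamples
#' with replacement, interval from the empirical quantiles at
#' `(1 - level)/2` and `1 - (1 - level)/2`.
#'
#' @param values Numeric vector (length >= 1).
#' @param statistic Function mapping a numeric vector to a scalar.
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level in (0, 1).
#' @param seed Integer seed; identical seeds give identical intervals.
#' @return Numeric vector `c(lower, upper)` with attribute `estimate`
#'   (statistic of the original sample).
#' @export
bootstrap_ci <- function(values, statistic = mean, n_boot = 1000, level = 0.95,
                         seed = 1L) {
  if (length(values) == 0L) stop("bootstrap_ci: empty input")
  stopifnot(level > 0, level < 1, n_boot >= 1)
  est <- statistic(values)
  stats <- with_seed(as.integer(seed), {
    n <- length(values)
    vapply(seq_len(n_boot),
           function(i) statistic(values[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(stats, c(alpha, 1 - alpha), type = 7))
  attr(ci, "estimate") <- est
  ci
}
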