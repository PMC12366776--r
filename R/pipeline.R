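#' Pipeline run configuration
#'
#' Bundles everything one analysis run needs: the input mode (`"synthetic"`
#' generates masks in memory from a [synthetic_config()]; `"masks"` reads a
#' manifest of label TIFFs), the classifier thresholds, contraction baseline,
#' bootstrap settings and output directory.
#'
#' @param mode `"synthetic"` or `"masks"`.
#' @param synthetic A [synthetic_config()] (required for synthetic mode;
#'   in masks mode used only for the occupancy report, optional).
#' @param manifest Path to a manifest CSV (masks mode).
#' @param a_max_um,axis_ratio,min_branch_um,min_branches,combine Classifier
#'   settings, see [classify_structure()].
#' @param prune_um Skeleton spur-pruning length, see [branch_census()].
#' @param baseline_day Contraction baseline day (default earliest).
#' @param n_boot,level Bootstrap settings, see [contraction_series()].
#' @param out_dir Output directory; `NULL` = return tables only.
#' @param seed Integer seed for bootstrap resampling.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "masks"), synthetic = NULL,
                       manifest = NULL, a_max_um = 60, axis_ratio = 1 / 2,
                       min_branch_um = 30, min_branches = 2,
                       combine = c("or", "and"), prune_um = 10,
                       baseline_day = NULL, n_boot = 1000, level = 0.95,
                       out_dir = NULL, seed = 1L) {
  mode <- match.arg(mode)
  combine <- match.arg(combine)
  .check(a_max_um > 0 && min_branch_um > 0 && min_branches >= 1 &&
           axis_ratio > 0 && prune_um >= 0, "thresholds must be positive")
  if (mode == "synthetic" && !inherits(synthetic, "synthetic_config"))
    stop("synthetic mode requires a synthetic_config")
  if (mode == "masks" && is.null(manifest))
    stop("masks mode requires a manifest path")
  structure(list(mode = mode, synthetic = synthetic, manifest = manifest,
                 a_max_um = a_max_um, axis_ratio = axis_ratio,
                 min_branch_um = min_branch_um, min_branches = min_branches,
                 combine = combine, prune_um = prune_um,
                 baseline_day = baseline_day, n_boot = n_boot, level = level,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

# all frames of a run as a list of mask_frames
.load_frames <- function(cfg) {
  if (cfg$mode == "synthetic") {
    sc <- cfg$synthetic
    days <- sort(as.numeric(intersect(names(sc$contraction_schedule),
                                      names(sc$growth_curve))))
    if (length(days) == 0L)
      stop("stage load: no day present in both growth_curve and contraction_schedule")
    frames <- list()
    for (id in seq_len(sc$n_droplets)) {
      cls <- .droplet_class(sc, id)
      for (day in days) {
        dr <- generate_droplet_mask(sc, id, day)
        og <- generate_organoid_mask(sc, id, day, cls, droplet = dr)
        img <- dr$label_image
        img[og$frame$label_image == 2L] <- 2L
        frames[[length(frames) + 1L]] <-
          mask_frame(img, sc$pixel_size_um, droplet_id = id, day = day,
                     validate = FALSE)
      }
    }
    frames
  } else {
    man <- read_manifest(cfg$manifest)
    lapply(seq_len(nrow(man)), function(i) {
      read_mask(man$file[i], man$pixel_size_um[i],
                droplet_id = man$droplet_id[i], day = man$day[i])
    })
  }
}

# analyse one frame -> list(droplet = df or NULL, structures = df)
.analyse_frame <- function(fr, cfg) {
  fe <- extract_features(fr)
  drop_row <- NULL
  dr <- fe[fe$label == 1L, , drop = FALSE]
  if (nrow(dr) == 1L) {
    drop_row <- data.frame(droplet_id = fr$droplet_id, day = fr$day,
                           equivalent_diameter_um = dr$equivalent_diameter_um,
                           compactness = compactness(dr$area_um2, dr$perimeter_um))
  }
  org <- fe[fe$label >= 2L, , drop = FALSE]
  st_rows <- NULL
  if (nrow(org) > 0L) {
    has_drop <- nrow(dr) == 1L
    nmd <- if (has_drop) normalized_min_distance(fr) else NA_real_
    rad <- if (has_drop) radial_position(fr) else NA_real_
    st_rows <- do.call(rbind, lapply(seq_len(nrow(org)), function(i) {
      lab <- org$label[i]
      m <- fr$label_image == lab
      comp <- label_components(m)
      if (max(comp) > 1L) m <- comp == which.max(tabulate(comp[comp > 0L]))
      cen <- branch_census(m, fr$pixel_size_um, min_branch_um = cfg$min_branch_um,
                           prune_um = cfg$prune_um)
      cls <- classify_structure(org[i, ], cen, a_max_um = cfg$a_max_um,
                                axis_ratio = cfg$axis_ratio,
                                min_branch_um = cfg$min_branch_um,
                                min_branches = cfg$min_branches,
                                combine = cfg$combine)
      data.frame(droplet_id = fr$droplet_id, day = fr$day, label = lab,
                 area_um2 = org$area_um2[i], perimeter_um = org$perimeter_um[i],
                 major_axis_um = org$major_axis_um[i],
                 minor_axis_um = org$minor_axis_um[i],
                 equivalent_diameter_um = org$equivalent_diameter_um[i],
                 sii = shape_irregularity_index(org$area_um2[i], org$perimeter_um[i]),
                 n_branches = cen$n_branches,
                 classification = cls,
                 normalized_min_distance = nmd,
                 radial_position = rad,
                 touches_border = org$touches_border[i])
    }))
  }
  list(droplet = drop_row, structures = st_rows)
}

# fixed column orders: the output schema is versioned and asserted in tests
.SCHEMA <- list(
  structures = c("droplet_id", "day", "label", "area_um2", "perimeter_um",
                 "major_axis_um", "minor_axis_um", "equivalent_diameter_um",
                 "sii", "n_branches", "classification",
                 "normalized_min_distance", "radial_position", "touches_border"),
  droplets = c("droplet_id", "day", "equivalent_diameter_um", "compactness"),
  day_summary = c("day", "n_structures", "mean_major_axis_um", "sd_major_axis_um",
                  "mean_sii", "pdi_percent", "branched_percent"),
  contraction = c("day", "n", "mean_diameter_um", "contraction_percent",
                  "ci_lower", "ci_upper"))

#' Run the full analysis pipeline
#'
#' Generates (synthetic mode) or reads (masks mode) all frames, extracts
#' droplet and structure features, classifies every structure, and summarises
#' growth, homogeneity (PDI), branched fraction, droplet contraction (with
#' bootstrap CI) and boundary proximity per day. Structures touching the
#' image border are flagged and excluded from the per-day summaries. With an
#' `out_dir`, tidy CSV tables, an occupancy JSON and a run-info echo are
#' written; re-running with identical config and seed reproduces the tables
#' byte for byte.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `structures`, `droplets`, `day_summary`,
#'   `contraction`, `occupancy` (if a synthetic config is available) and
#'   `run_info`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  frames <- .load_frames(cfg)
  if (length(frames) == 0L) stop("stage load: no frames")
  res <- lapply(frames, function(fr) {
    tryCatch(.analyse_frame(fr, cfg),
             error = function(e) stop("stage analyse (droplet_id=", fr$droplet_id,
                                      ", day=", fr$day, "): ", conditionMessage(e),
                                      call. = FALSE))
  })
  droplets <- do.call(rbind, lapply(res, `[[`, "droplet"))
  structures <- do.call(rbind, lapply(res, `[[`, "structures"))
  if (is.null(structures) || nrow(structures) == 0L)
    stop("stage summarise: no organoid structures found")
  keep <- !structures$touches_border
  st <- structures[keep, , drop = FALSE]
  gro <- growth_summary(st$major_axis_um, st$day)
  day_summary <- do.call(rbind, lapply(sort(unique(st$day)), function(d) {
    s <- st[st$day == d, , drop = FALSE]
    data.frame(day = d, n_structures = nrow(s),
               mean_major_axis_um = mean(s$major_axis_um),
               sd_major_axis_um = if (nrow(s) > 1L) stats::sd(s$major_axis_um) else 0,
               mean_sii = mean(s$sii),
               pdi_percent = pdi(s$area_um2),
               branched_percent = 100 * mean(s$classification == "branched"))
  }))
  contraction <- NULL
  if (!is.null(droplets) && nrow(droplets) > 0L) {
    contraction <- contraction_series(droplets$equivalent_diameter_um,
                                      droplets$day,
                                      baseline_day = cfg$baseline_day,
                                      n_boot = cfg$n_boot, level = cfg$level,
                                      seed = cfg$seed)
  }
  occ <- NULL
  if (!is.null(cfg$synthetic)) {
    ec <- encapsulation_config(cfg$synthetic$droplet_diameter_um,
                               cfg$synthetic$cell_concentration_per_ml)
    occ <- occupancy(ec)
  }
  run_info <- list(package = "dropletmorph",
                   version = as.character(utils::packageVersion("dropletmorph")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   mode = cfg$mode, seed = cfg$seed,
                   a_max_um = cfg$a_max_um, axis_ratio = cfg$axis_ratio,
                   min_branch_um = cfg$min_branch_um,
                   min_branches = cfg$min_branches, combine = cfg$combine,
                   n_frames = length(frames))
  out <- list(structures = structures[, .SCHEMA$structures],
              droplets = if (!is.null(droplets)) droplets[, .SCHEMA$droplets],
              growth = gro,
              day_summary = day_summary[, .SCHEMA$day_summary],
              contraction = if (!is.null(contraction)) contraction[, .SCHEMA$contraction],
              occupancy = occ, run_info = run_info)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out$structures, file.path(cfg$out_dir, "structures.csv"),
                     row.names = FALSE)
    if (!is.null(out$droplets))
      utils::write.csv(out$droplets, file.path(cfg$out_dir, "droplets.csv"),
                       row.names = FALSE)
    utils::write.csv(out$day_summary, file.path(cfg$out_dir, "day_summary.csv"),
                     row.names = FALSE)
    if (!is.null(out$contraction))
      utils::write.csv(out$contraction, file.path(cfg$out_dir, "contraction.csv"),
                       row.names = FALSE)
    if (!is.null(occ))
      jsonlite::write_json(unclass(occ), file.path(cfg$out_dir, "occupancy.json"),
                           auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(run_info, file.path(cfg$out_dir, "run_info.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
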