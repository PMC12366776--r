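# Programmatic fixtures: digital disks, ellipses and bars built in code.

digital_disk <- function(r_px, pad = 4L) {
  n <- 2L * r_px + 2L * pad + 1L
  c0 <- r_px + pad + 1L
  outer(seq_len(n) - c0, seq_len(n) - c0, function(i, j) i^2 + j^2 <= r_px^2)
}

digital_ellipse <- function(a_px, b_px, pad = 4L) {
  # axis-aligned, semi-axes in pixels
  nr <- 2L * b_px + 2L * pad + 1L
  nc <- 2L * a_px + 2L * pad + 1L
  ci <- b_px + pad + 1L; cj <- a_px + pad + 1L
  outer(seq_len(nr) - ci, seq_len(nc) - cj,
        function(i, j) (j / a_px)^2 + (i / b_px)^2 <= 1)
}

digital_bar <- function(len_px, width_px, pad = 6L) {
  nr <- width_px + 2L * pad
  nc <- len_px + 2L * pad
  m <- matrix(FALSE, nr, nc)
  m[pad + seq_len(width_px), pad + seq_len(len_px)] <- TRUE
  m
}

as_frame <- function(mask, label = 2L, px = 1, id = 1L, day = 1L) {
  img <- matrix(0L, nrow(mask), ncol(mask))
  img[mask] <- as.integer(label)
  mask_frame(img, px, droplet_id = id, day = day, validate = FALSE)
}

# small fast config for generator tests (two days, small images)
tiny_config <- function(seed = 1L, ...) {
  defaults <- list(seed = seed,
                   droplet_diameter_um = 500, diameter_cv = 0.02,
                   growth_curve = c("2" = 60, "6" = 160),
                   contraction_schedule = c("2" = 0, "6" = 0.12),
                   n_droplets = 2L)
  do.call(config_large_droplets, utils::modifyList(defaults, list(...)))
}
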