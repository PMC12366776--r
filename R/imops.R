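# Low-level raster primitives shared by the geometry and morphometry layers.
# All functions operate on logical or integer matrices indexed [row, col];
# pixel centres sit at 0-based integer coordinates, x = col - 1, y = row - 1.

# Shift a matrix by (dr, dc), padding with `fill`.
shift_mat <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- max(1L, 1L + dr):min(nr, nr + dr)
  sc <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(sr) == 0L || length(sc) == 0L) return(out)
  out[sr, sc] <- m[sr - dr, sc - dc]
  out
}

NEIGH8 <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))

# Connected-component labelling by column runs + union-find.
# Returns an integer matrix with labels 1..k in first-seen order (0 = background).
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  if (!any(mask)) return(out)
  tol <- if (connectivity == 8L) 1L else 0L

  run_col <- integer(0); run_s <- integer(0); run_e <- integer(0)
  prev_idx <- integer(0)
  parent <- integer(0)
  uf_find <- function(x) {
    root <- x
    while (parent[root] != root) root <- parent[root]
    while (parent[x] != root) { nxt <- parent[x]; parent[x] <<- root; x <- nxt }
    root
  }
  for (j in seq_len(nc)) {
    col <- mask[, j]
    if (!any(col)) { prev_idx <- integer(0); next }
    r <- rle(as.logical(col))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    s <- starts[keep]; e <- ends[keep]
    n_new <- length(s)
    ids <- length(parent) + seq_len(n_new)
    parent <- c(parent, ids)
    run_col <- c(run_col, rep.int(j, n_new))
    run_s <- c(run_s, s); run_e <- c(run_e, e)
    # merge with previous column's runs (both sorted by start row)
    if (length(prev_idx)) {
      pi <- 1L
      for (k in seq_len(n_new)) {
        while (pi <= length(prev_idx) && run_e[prev_idx[pi]] + tol < s[k]) pi <- pi + 1L
        qi <- pi
        while (qi <= length(prev_idx) && run_s[prev_idx[qi]] <= e[k] + tol) {
          ra <- uf_find(ids[k]); rb <- uf_find(prev_idx[qi])
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
          qi <- qi + 1L
        }
      }
    }
    prev_idx <- ids
  }
  roots <- vapply(seq_along(parent), uf_find, integer(1))
  lab_of_root <- integer(length(parent))
  uroots <- unique(roots)
  lab_of_root[uroots] <- seq_along(uroots)
  labs <- lab_of_root[roots]
  for (i in seq_along(run_col)) {
    out[run_s[i]:run_e[i], run_col[i]] <- labs[i]
  }
  out
}

# Fill interior holes: background 4-components not touching the image border.
fill_holes <- function(mask) {
  bg <- !mask
  lab <- label_components(bg, connectivity = 4L)
  border_ids <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_ids <- border_ids[border_ids > 0L]
  hole <- bg & !(lab %in% border_ids)
  mask | hole
}

# Pixels of `mask` with at least one 4-neighbour outside the mask (or on the edge).
boundary_mask <- function(mask) {
  inner <- shift_mat(mask, 1L, 0L, FALSE) & shift_mat(mask, -1L, 0L, FALSE) &
    shift_mat(mask, 0L, 1L, FALSE) & shift_mat(mask, 0L, -1L, FALSE)
  mask & !inner
}

# Chamfer 3-4 distance (in pixels) from every foreground pixel to the nearest
# background pixel; pixels outside the image count as background.
dist_to_background <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  big <- 3 * (nr + nc + 2)
  d <- matrix(0, nr, nc)
  d[mask] <- big
  horiz <- function(v) {
    # running min of v[k] + 3*(j-k) over k <= j, vectorised via cummin
    j <- seq_along(v)
    fwd <- cummin(v - 3 * j) + 3 * j
    bwd <- rev(cummin(rev(v + 3 * j))) - 3 * j
    pmin(fwd, bwd)
  }
  pad <- rep(0, nc)  # outside the image counts as background
  for (i in seq_len(nr)) {        # forward pass
    up <- if (i > 1L) d[i - 1L, ] else pad
    diag1 <- c(big, up[-nc]); diag2 <- c(up[-1L], big)
    d[i, ] <- horiz(pmin(d[i, ], up + 3, diag1 + 4, diag2 + 4))
  }
  for (i in rev(seq_len(nr))) {   # backward pass
    dn <- if (i < nr) d[i + 1L, ] else pad
    diag1 <- c(big, dn[-nc]); diag2 <- c(dn[-1L], big)
    d[i, ] <- horiz(pmin(d[i, ], dn + 3, diag1 + 4, diag2 + 4))
  }
  d / 3
}

# Moore-neighbour contour tracing of the outer boundary of a single
# 8-connected component. Returns the number of axial and diagonal chain-code
# steps. A one-pixel region yields c(0, 0).
trace_outer_contour <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(c(axial = 0L, diagonal = 0L))
  if (nrow(idx) == 1L) return(c(axial = 0L, diagonal = 0L))
  # start: topmost pixel of leftmost column containing the component
  jmin <- min(idx[, 2])
  imin <- min(idx[idx[, 2] == jmin, 1])
  start <- c(imin, jmin)
  nr <- nrow(mask); nc <- ncol(mask)
  inm <- function(p) p[1] >= 1L && p[1] <= nr && p[2] >= 1L && p[2] <= nc && mask[p[1], p[2]]
  # clockwise Moore neighbourhood starting from W
  moore <- cbind(dr = c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L),
                 dc = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L))
  # lookup: offset (dr, dc) -> index in `moore`
  dir_index <- integer(9L)
  dir_index[(moore[, 1] + 1L) * 3L + (moore[, 2] + 1L) + 1L] <- seq_len(8L)
  cur <- start
  # backtrack pixel: we entered scanning from the W (col - 1 is background)
  bdir <- 1L  # index into moore of the backtrack (background) pixel
  n_ax <- 0L; n_di <- 0L
  first_dir <- NA_integer_
  max_steps <- 4L * (nr * nc)
  steps <- 0L
  repeat {
    found <- FALSE
    k <- bdir
    kprev <- bdir
    for (t in seq_len(8L)) {
      kprev <- k
      k <- (k %% 8L) + 1L  # next clockwise
      cand <- cur + c(moore[k, 1], moore[k, 2])
      if (inm(cand)) { found <- TRUE; break }
    }
    if (!found) break  # isolated pixel (should not happen for n > 1 connected)
    if (is.na(first_dir)) first_dir <- k
    else if (all(cur == start) && k == first_dir) break  # Jacob's criterion
    if (moore[k, 1] != 0L && moore[k, 2] != 0L) n_di <- n_di + 1L else n_ax <- n_ax + 1L
    # next search backtracks from the background pixel examined just before cand
    pb <- cur + c(moore[kprev, 1], moore[kprev, 2])
    off <- pb - cand
    bdir <- dir_index[(off[1] + 1L) * 3L + (off[2] + 1L) + 1L]
    cur <- cand
    steps <- steps + 1L
    if (steps > max_steps) stop("contour tracing failed to terminate")
  }
  c(axial = n_ax, diagonal = n_di)
}

# Perimeter of a single component in pixel units, including hole boundaries.
# Chain-code length estimator with Vossepoel-Smeulders style weights,
# calibrated so digital disks of radius >= 50 px give compactness 1.00 +/- 0.02.
PERIM_W_AXIAL <- 0.948
PERIM_W_DIAG <- 1.340

perimeter_px <- function(mask) {
  steps <- trace_outer_contour(mask)
  p <- PERIM_W_AXIAL * steps[["axial"]] + PERIM_W_DIAG * steps[["diagonal"]]
  if (p == 0) p <- 3.792  # single/degenerate pixel: unit-square model
  filled <- fill_holes(mask)
  holes <- filled & !mask
  if (any(holes)) {
    hlab <- label_components(holes, connectivity = 4L)
    for (h in seq_len(max(hlab))) {
      hs <- trace_outer_contour(hlab == h)
      hp <- PERIM_W_AXIAL * hs[["axial"]] + PERIM_W_DIAG * hs[["diagonal"]]
      p <- p + (if (hp == 0) 3.792 else hp)
    }
  }
  unname(p)
}

# Guo-Hall thinning to a 1-px, 8-connected topological skeleton (preserves
# diagonal stroke ends, which Zhang-Suen erodes), followed by a sequential
# unit-width cleanup.
skeletonize <- function(mask) {
  img <- mask
  sh <- function(m, dr, dc) shift_mat(m, dr, dc, FALSE)
  repeat {
    changed <- FALSE
    for (sub in 0:1) {
      p2 <- sh(img, 1L, 0L);  p3 <- sh(img, 1L, -1L)
      p4 <- sh(img, 0L, -1L); p5 <- sh(img, -1L, -1L)
      p6 <- sh(img, -1L, 0L); p7 <- sh(img, -1L, 1L)
      p8 <- sh(img, 0L, 1L);  p9 <- sh(img, 1L, 1L)
      cnum <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
        (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
      n1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      n2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      nmin <- pmin(n1, n2)
      m3 <- if (sub == 0L) ((p6 | p7 | !p9) & p8) else ((p2 | p3 | !p5) & p4)
      cond <- img & cnum == 1 & nmin >= 2 & nmin <= 3 & !m3
      if (any(cond)) { img[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  .thin_to_unit_width(img)
}

# Zhang-Suen leaves 2-px staircases on diagonal runs. Remove every pixel that
# is 8-simple (crossing number 1) and has >= 3 neighbours, sequentially in
# raster order, until stable: junction centres (crossing number >= 2) and
# endpoints (1 neighbour) are untouchable, so topology is preserved.
.thin_to_unit_width <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  ring <- cbind(dr = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
                dc = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L))
  repeat {
    nb <- neighbour_count(skel)
    cand <- which(skel & nb >= 3L, arr.ind = TRUE)
    if (nrow(cand) == 0L) break
    changed <- FALSE
    for (q in seq_len(nrow(cand))) {
      i <- cand[q, 1]; j <- cand[q, 2]
      if (!skel[i, j]) next
      v <- logical(8L); b <- 0L
      for (k in seq_len(8L)) {
        ii <- i + ring[k, 1]; jj <- j + ring[k, 2]
        if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc && skel[ii, jj]) {
          v[k] <- TRUE; b <- b + 1L
        }
      }
      if (b < 3L) next
      # Yokoi connectivity number for 8-connected foreground:
      # ring order N,NE,E,SE,S,SW,W,NW; sum over axial positions k
      xb <- 1L - as.integer(v)
      c8 <- 0L
      for (k in c(1L, 3L, 5L, 7L)) {
        k1 <- if (k == 7L) 8L else k + 1L
        k2 <- if (k >= 7L) k - 6L else k + 2L
        c8 <- c8 + xb[k] - xb[k] * xb[k1] * xb[k2]
      }
      if (c8 == 1L) { skel[i, j] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  skel
}

# Count of 8-neighbours on the skeleton for every skeleton pixel.
neighbour_count <- function(skel) {
  nb <- matrix(0L, nrow(skel), ncol(skel))
  for (k in seq_len(8L)) {
    nb <- nb + shift_mat(skel, NEIGH8[k, 1], NEIGH8[k, 2], FALSE)
  }
  nb[!skel] <- 0L
  nb
}

# Morphological opening with a disk of radius r_px, via two chamfer
# transforms: erosion keeps pixels deeper than r_px, dilation restores
# everything within r_px of the eroded core. Removes protrusions thinner
# than 2*r_px while leaving thicker convex bodies essentially unchanged.
morph_open <- function(mask, r_px) {
  er <- dist_to_background(mask) > r_px
  if (!any(er)) return(matrix(FALSE, nrow(mask), ncol(mask)))
  dist_to_background(!er) <= r_px
}

# Crop a logical mask to its bounding box with `pad` background pixels around.
# Returns list(mask, offset = c(row0, col0)) with 1-based offsets.
crop_mask <- function(mask, pad = 2L) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(nrow(mask), max(idx[, 1]) + pad)
  c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(ncol(mask), max(idx[, 2]) + pad)
  list(mask = mask[r0:r1, c0:c1, drop = FALSE], offset = c(r0, c0))
}
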