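# Shared in-code fixtures: tiny painted cells, random blob masks, small scene
# specs. Everything is generated at test time; no binary fixtures on disk.

# paint a filled disc into a matrix (1-based centre, inclusive radius)
fx_disc <- function(img, ctr, radius, value) {
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      if ((r - ctr[1])^2 + (c - ctr[2])^2 <= radius^2) img[r, c] <- value
    }
  }
  img
}

fx_annulus <- function(img, ctr, r_in, r_out, value) {
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      d2 <- (r - ctr[1])^2 + (c - ctr[2])^2
      if (d2 > r_in^2 && d2 <= r_out^2) img[r, c] <- value
    }
  }
  img
}

# bright field with one dark nucleolus disc, optionally ringed by a dark
# nuclear annulus -- the canonical procedure-(1) test scene
fx_cell_image <- function(shape = c(41L, 41L), ctr = c(21, 21), ring = TRUE,
                          disc_radius = 2.5, ring_in = 6, ring_out = 8.5) {
  img <- matrix(0.8, shape[1], shape[2])
  if (ring) img <- fx_annulus(img, ctr, ring_in, ring_out, 0.3)
  fx_disc(img, ctr, disc_radius, 0.15)
}

# random blob mask from a union of discs (reproducible)
fx_blob_mask <- function(shape = c(64L, 64L), n_discs = 6L, seed = 1L) {
  set.seed(seed)
  img <- matrix(0, shape[1], shape[2])
  margin <- max(3, min(10, min(shape) %/% 4))
  rmax <- max(3, min(8, min(shape) %/% 5))
  for (i in seq_len(n_discs)) {
    ctr <- c(stats::runif(1, margin, shape[1] - margin),
             stats::runif(1, margin, shape[2] - margin))
    img <- fx_disc(img, ctr, stats::runif(1, 2.5, rmax), 1)
  }
  img > 0
}

# independent crossing-number oracle: explicit loop over the printed cyclic sum
fx_cn_oracle <- function(neigh) {
  p <- c(neigh, neigh[1])
  s <- 0
  for (i in 1:8) s <- s + abs(p[i] - p[i + 1])
  s / 2
}

# embed an 8-neighborhood (cyclic order NW,N,NE,E,SE,S,SW,W) in a 3x3 skeleton
fx_embed_neigh <- function(neigh, center = TRUE) {
  m <- matrix(FALSE, 3L, 3L)
  pos <- rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 3), c(3, 3), c(3, 2), c(3, 1), c(2, 1))
  for (i in 1:8) m[pos[i, 1], pos[i, 2]] <- neigh[i] == 1
  m[2, 2] <- center
  m
}

fx_small_scene <- function(seed = 1L, motion = list(type = "zero"),
                           n_frames = 2L, shape = c(192L, 192L),
                           colony_radius = 70, n_cells = 14, n_feeder = 4,
                           n_decoys = 2, ...) {
  scene_spec(shape = shape, colony_radius = colony_radius, n_cells = n_cells,
             cell_spacing_px = 17, n_feeder = n_feeder, n_decoys = n_decoys,
             motion = motion, n_frames = n_frames, seed = seed, ...)
}

fx_mask_centroid <- function(mask) {
  idx <- which(mask)
  c(mean((idx - 1L) %% nrow(mask) + 1L), mean((idx - 1L) %/% nrow(mask) + 1L))
}
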