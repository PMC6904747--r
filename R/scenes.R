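#' Specification of a synthetic phase-contrast scene
#'
#' Describes a schematic co-culture field with known ground truth: a colony
#' polygon packed with cells whose appearance mimics what the pipeline
#' consumes in real phase contrast — a dark nucleolus spot (1-2 per cell)
#' inside a dark nuclear ring, a bright mesh of cell-cell boundaries (the
#' edges of the nearest-seed partition of the colony), and, outside the
#' polygon, sparse elongated dark feeder cells plus ring-less dark decoy
#' spots that a correct nucleolus detector must reject. A mild horizontal
#' illumination gradient is included so that only adaptive (not global)
#' thresholding works. Defaults emulate a full camera frame (1040 x 1388, a
#' 1.4-megapixel monochrome CCD) with a colony a few hundred pixels across.
#'
#' @param shape `(rows, cols)`; default `c(1040, 1388)`.
#' @param colony_polygon Two-column matrix of `(row, col)` vertices, or
#'   `NULL` for a seeded irregular blob of radius `colony_radius` at the
#'   image center.
#' @param colony_radius Mean radius (px) of the default polygon; default 280.
#' @param n_cells Cells to place inside the polygon; default 450.
#' @param cell_spacing_px Minimum seed spacing (px); default 24.
#' @param nucleolus_radius_px Nucleolus disc radius; default 3 (area ~29 px,
#'   inside the 12-72 px detection window).
#' @param ring_inner_px,ring_outer_px Nuclear ring radii; defaults 7 and 9.5.
#' @param boundary_brightness Mesh contrast above background; default 0.25.
#' @param nucleus_darkness Ring contrast below background; default 0.25
#'   (nucleoli are drawn 0.15 darker still).
#' @param n_feeder Feeder ellipses outside the colony; default 25.
#' @param n_decoys Ring-less dark spots outside the colony; default 8.
#' @param noise_sd Gaussian intensity noise SD, fresh per frame; default
#'   0.015.
#' @param texture_sd SD of the static pixel-scale texture field baked into
#'   the scene (cytoplasmic/optical granularity); it moves with the scene
#'   and is what optical flow locks onto. Default 0.02.
#' @param motion List: `list(type = "zero")`,
#'   `list(type = "translation", dv = , du = )` (px/frame) or
#'   `list(type = "radial", rate = )` (px/frame at the colony edge).
#' @param n_frames Frames to render (>= 1); default 3 (the short screening
#'   protocol: 2-3 serial images at 5 min intervals).
#' @param interval_min Frame interval metadata; default 5.
#' @param seed RNG seed; scenes are bit-reproducible given the spec.
#' @param label,condition Free-text identifiers used by screening suites.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(shape = c(1040L, 1388L), colony_polygon = NULL,
                       colony_radius = 280, n_cells = 170,
                       cell_spacing_px = 24, nucleolus_radius_px = 3,
                       ring_inner_px = 7, ring_outer_px = 9.5,
                       boundary_brightness = 0.25, nucleus_darkness = 0.25,
                       n_feeder = 25, n_decoys = 8, noise_sd = 0.015,
                       texture_sd = 0.02,
                       motion = list(type = "zero"), n_frames = 3L,
                       interval_min = 5, seed = 1L,
                       label = "scene", condition = NA_character_) {
  shape <- as.integer(shape)
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!motion$type %in% c("zero", "translation", "radial"))
    stop("motion$type must be 'zero', 'translation' or 'radial'")
  if (!is.null(colony_polygon)) {
    colony_polygon <- as.matrix(colony_polygon)
    if (any(colony_polygon[, 1L] < 1 | colony_polygon[, 1L] > shape[1L] |
            colony_polygon[, 2L] < 1 | colony_polygon[, 2L] > shape[2L]))
      stop("colony_polygon lies outside image bounds")
  }
  structure(as.list(environment()), class = "scene_spec")
}

default_polygon <- function(shape, radius) {
  th <- seq(0, 2 * pi, length.out = 13L)[-13L]
  rr <- radius * (1 + 0.18 * sin(3 * th) + 0.1 * cos(2 * th))
  cbind(shape[1L] / 2 + rr * sin(th), shape[2L] / 2 + rr * cos(th))
}

polygon_mask <- function(poly, shape) {
  cols <- rep(seq_len(shape[2L]), each = shape[1L])
  rows <- rep(seq_len(shape[1L]), times = shape[2L])
  inside <- sp::point.in.polygon(cols, rows, poly[, 2L], poly[, 1L]) > 0
  matrix(inside, shape[1L], shape[2L])
}

#' Apply a displacement field to an image
#'
#' Forward motion by `(v, u)` pixels: the output at `(r, c)` samples the
#' input at `(r - v, c - u)` with bilinear interpolation (edge values
#' replicated). The scene generator builds frame t+1 from frame t with this
#' exact operator, so warping a clean frame by the ground-truth field
#' reproduces the next clean frame bit-for-bit.
#'
#' @param img Numeric matrix.
#' @param u,v Column/row displacement fields (matrices or scalars),
#'   px/frame.
#' @return Numeric matrix.
#' @export
apply_displacement <- function(img, u, v) {
  if (length(u) == 1L) u <- matrix(u, nrow(img), ncol(img))
  if (length(v) == 1L) v <- matrix(v, nrow(img), ncol(img))
  .cf_bilinear_warp(img, -u, -v)
}

paint_disc <- function(img, ctr, radius, value) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- max(1L, floor(ctr[1L] - radius)); r1 <- min(nr, ceiling(ctr[1L] + radius))
  c0 <- max(1L, floor(ctr[2L] - radius)); c1 <- min(nc, ceiling(ctr[2L] + radius))
  if (r0 > r1 || c0 > c1) return(img)
  rs <- r0:r1; cs <- c0:c1
  d2 <- outer((rs - ctr[1L])^2, (cs - ctr[2L])^2, "+")
  sub <- img[rs, cs, drop = FALSE]
  sub[d2 <= radius^2] <- value
  img[rs, cs] <- sub
  img
}

paint_annulus <- function(img, ctr, r_in, r_out, value) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- max(1L, floor(ctr[1L] - r_out)); r1 <- min(nr, ceiling(ctr[1L] + r_out))
  c0 <- max(1L, floor(ctr[2L] - r_out)); c1 <- min(nc, ceiling(ctr[2L] + r_out))
  if (r0 > r1 || c0 > c1) return(img)
  rs <- r0:r1; cs <- c0:c1
  d2 <- outer((rs - ctr[1L])^2, (cs - ctr[2L])^2, "+")
  sub <- img[rs, cs, drop = FALSE]
  sub[d2 > r_in^2 & d2 <= r_out^2] <- value
  img[rs, cs] <- sub
  img
}

paint_ellipse <- function(img, ctr, a, b, theta, value) {
  nr <- nrow(img); nc <- ncol(img)
  ext <- max(a, b)
  r0 <- max(1L, floor(ctr[1L] - ext)); r1 <- min(nr, ceiling(ctr[1L] + ext))
  c0 <- max(1L, floor(ctr[2L] - ext)); c1 <- min(nc, ceiling(ctr[2L] + ext))
  if (r0 > r1 || c0 > c1) return(img)
  rs <- r0:r1; cs <- c0:c1
  dr <- matrix(rs - ctr[1L], length(rs), length(cs))
  dc <- matrix(rep(cs - ctr[2L], each = length(rs)), length(rs), length(cs))
  xr <- dc * cos(theta) + dr * sin(theta)
  yr <- -dc * sin(theta) + dr * cos(theta)
  sub <- img[rs, cs, drop = FALSE]
  sub[(xr / a)^2 + (yr / b)^2 <= 1] <- value
  img[rs, cs] <- sub
  img
}

# Poisson-disk style seed placement inside a mask
place_seeds <- function(inside_idx, shape, n, spacing) {
  rows <- (inside_idx - 1L) %% shape[1L] + 1L
  cols <- (inside_idx - 1L) %/% shape[1L] + 1L
  ord <- sample.int(length(inside_idx))
  acc_r <- numeric(0); acc_c <- numeric(0)
  s2 <- spacing^2
  for (i in ord) {
    r <- rows[i]; c <- cols[i]
    if (length(acc_r) == 0L || min((acc_r - r)^2 + (acc_c - c)^2) >= s2) {
      acc_r <- c(acc_r, r); acc_c <- c(acc_c, c)
      if (length(acc_r) == n) break
    }
  }
  cbind(acc_r, acc_c)
}

#' Render a synthetic scene with ground truth
#'
#' Builds the clean frame-0 raster from a [scene_spec()], propagates it
#' through time with the specified displacement field (bilinear resampling of
#' the pre-noise scene), and adds fresh Gaussian noise to every frame. Fully
#' reproducible from the spec's seed.
#'
#' @param spec A [scene_spec()].
#' @return List with `frames` (list of [gray_frame()]) and `truth`, a list
#'   holding `colony_masks` (logical matrix per frame), `nucleoli`
#'   ([point_set()] per frame), `flow` (per-pair list of `u`, `v` matrices),
#'   `clean_frames` (pre-noise rasters), `seeds`, `feeder_centroids` and
#'   `decoy_centroids`.
#' @export
generate_scene <- function(spec) {
  set.seed(spec$seed)
  shape <- spec$shape
  nr <- shape[1L]; nc <- shape[2L]
  poly <- if (is.null(spec$colony_polygon))
    default_polygon(shape, spec$colony_radius) else spec$colony_polygon
  inside <- polygon_mask(poly, shape)

  bg <- 0.55 + 0.05 * (matrix(rep(seq_len(nc), each = nr), nr, nc) / nc - 0.5)
  img <- bg

  seeds <- NULL
  if (spec$n_cells > 0L) {
    margin <- ceiling(spec$ring_outer_px) + 2L
    core <- .cf_morph3(inside, "erode", margin)
    core_idx <- which(core)
    if (length(core_idx) == 0L)
      stop("colony polygon too small for any cell")
    seeds <- place_seeds(core_idx, shape, spec$n_cells, spec$cell_spacing_px)
    if (nrow(seeds) < spec$n_cells)
      stop(sprintf("colony polygon too small for n_cells = %d (placed %d)",
                   spec$n_cells, nrow(seeds)))
    # bright cell-cell boundary mesh: pixels roughly equidistant from the two
    # nearest seeds (edges of the nearest-seed partition), colony interior only
    in_idx <- which(inside)
    q <- cbind((in_idx - 1L) %% nr + 1L, (in_idx - 1L) %/% nr + 1L)
    kn <- FNN::get.knnx(seeds, q, k = min(2L, nrow(seeds)))
    if (ncol(kn$nn.dist) >= 2L) {
      mesh <- kn$nn.dist[, 2L] - kn$nn.dist[, 1L] < 3
      img[in_idx[mesh]] <- bg[in_idx[mesh]] + spec$boundary_brightness
    }
    # nuclear ring + 1-2 nucleoli per cell
    two <- stats::runif(nrow(seeds)) < 0.3
    for (i in seq_len(nrow(seeds))) {
      ctr <- seeds[i, ]
      img <- paint_annulus(img, ctr, spec$ring_inner_px, spec$ring_outer_px,
                           bg[ctr[1L], ctr[2L]] - spec$nucleus_darkness)
      dark <- bg[ctr[1L], ctr[2L]] - spec$nucleus_darkness - 0.15
      img <- paint_disc(img, ctr, spec$nucleolus_radius_px, dark)
      if (two[i]) {
        th <- stats::runif(1, 0, 2 * pi)
        img <- paint_disc(img, ctr + 2 * c(sin(th), cos(th)),
                          spec$nucleolus_radius_px, dark)
      }
    }
  }

  # feeder cells and decoy spots live outside a safety band around the colony
  outer_ok <- !.cf_morph3(inside, "dilate", 20L)
  out_idx <- which(outer_ok)
  feeders <- decoys <- matrix(numeric(), 0L, 2L)
  if (spec$n_feeder > 0L && length(out_idx) > 0L) {
    pick <- sample(out_idx, min(spec$n_feeder, length(out_idx)))
    feeders <- cbind((pick - 1L) %% nr + 1L, (pick - 1L) %/% nr + 1L)
    for (i in seq_len(nrow(feeders)))
      img <- paint_ellipse(img, feeders[i, ], a = 14, b = 4,
                           theta = stats::runif(1, 0, pi),
                           value = bg[feeders[i, 1L], feeders[i, 2L]] - 0.12)
  }
  if (spec$n_decoys > 0L && length(out_idx) > 0L) {
    pick <- sample(out_idx, min(spec$n_decoys, length(out_idx)))
    decoys <- cbind((pick - 1L) %% nr + 1L, (pick - 1L) %/% nr + 1L)
    for (i in seq_len(nrow(decoys)))
      img <- paint_disc(img, decoys[i, ], spec$nucleolus_radius_px,
                        bg[decoys[i, 1L], decoys[i, 2L]] - 0.35)
  }
  if (spec$texture_sd > 0)
    img <- img + stats::rnorm(length(img), 0, spec$texture_sd)
  img <- pmin(pmax(img, 0), 1)

  # motion field for one frame step
  field <- motion_field(spec$motion, shape, poly)

  clean <- vector("list", spec$n_frames)
  clean[[1L]] <- img
  if (spec$n_frames > 1L)
    for (t in 2:spec$n_frames)
      clean[[t]] <- apply_displacement(clean[[t - 1L]], field$u, field$v)

  frames <- vector("list", spec$n_frames)
  truth_masks <- vector("list", spec$n_frames)
  truth_nuc <- vector("list", spec$n_frames)
  nuc0 <- if (is.null(seeds)) matrix(integer(), 0L, 2L) else round(seeds)
  for (t in seq_len(spec$n_frames)) {
    noisy <- clean[[t]]
    if (spec$noise_sd > 0)
      noisy <- pmin(pmax(noisy + stats::rnorm(length(noisy), 0, spec$noise_sd),
                         0), 1)
    frames[[t]] <- gray_frame(noisy, frame_index = t,
                              interval_min = spec$interval_min)
    shift <- motion_shift(spec$motion, t - 1L)
    poly_t <- sweep(poly, 2L, shift, "+")
    truth_masks[[t]] <- if (spec$motion$type == "zero" || t == 1L) inside
                        else polygon_mask(poly_t, shape)
    pts <- nuc0
    if (nrow(pts) > 0L) {
      pts <- round(sweep(pts, 2L, shift, "+"))
      keep <- pts[, 1L] >= 1L & pts[, 1L] <= nr & pts[, 2L] >= 1L & pts[, 2L] <= nc
      pts <- pts[keep, , drop = FALSE]
      pts <- pts[!duplicated(pts), , drop = FALSE]
    }
    truth_nuc[[t]] <- point_set(pts, "nucleolus", shape)
  }
  flow_truth <- if (spec$n_frames > 1L)
    lapply(seq_len(spec$n_frames - 1L), function(t) field) else list()

  list(frames = frames,
       truth = list(colony_masks = truth_masks, nucleoli = truth_nuc,
                    flow = flow_truth, clean_frames = clean, seeds = seeds,
                    feeder_centroids = feeders, decoy_centroids = decoys,
                    polygon = poly))
}

motion_field <- function(motion, shape, poly) {
  nr <- shape[1L]; nc <- shape[2L]
  if (motion$type == "zero")
    return(list(u = matrix(0, nr, nc), v = matrix(0, nr, nc)))
  if (motion$type == "translation")
    return(list(u = matrix(motion$du, nr, nc), v = matrix(motion$dv, nr, nc)))
  ctr <- colMeans(poly)
  rad <- mean(sqrt((poly[, 1L] - ctr[1L])^2 + (poly[, 2L] - ctr[2L])^2))
  rowm <- matrix(seq_len(nr), nr, nc)
  colm <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  list(u = motion$rate * (colm - ctr[2L]) / rad,
       v = motion$rate * (rowm - ctr[1L]) / rad)
}

# cumulative (row, col) shift of scene content after t frame steps
motion_shift <- function(motion, t) {
  if (motion$type == "translation") t * c(motion$dv, motion$du) else c(0, 0)
}

#' Pre-built scene suites for validation
#'
#' * `"segmentation"` — 10 full-field scenes varying cell spacing and feeder
#'   count, for pixel-level segmentation scoring.
#' * `"flow"` — 7 small textured scenes: integer translations `(0,0)`,
#'   `(0,3)`, `(-2,1)` plus diagonal motion amplitudes 0, 0.5, 1 and 2
#'   px/frame, for flow-recovery and monotonicity checks.
#' * `"screening"` — 5 "control" colonies moving at 2 px/frame vs 5
#'   "inhibited" colonies at 0.1 px/frame, 3 frames each at 5 min intervals
#'   (the short screening protocol; complete separation by construction).
#'
#' @param profile `"segmentation"`, `"flow"` or `"screening"`.
#' @param master_seed Integer; per-scene seeds derive from it.
#' @return List of [scene_spec()] objects.
#' @export
scene_suite <- function(profile = c("segmentation", "flow", "screening"),
                        master_seed = 1L) {
  profile <- tryCatch(match.arg(profile), error = function(e)
    stop("unknown profile; available: segmentation, flow, screening",
         call. = FALSE))
  master_seed <- as.integer(master_seed)
  if (profile == "segmentation") {
    spacing <- rep(c(22, 24, 26, 28, 30), 2L)
    feeders <- rep(c(12, 40), each = 5L)
    lapply(seq_len(10L), function(i)
      scene_spec(cell_spacing_px = spacing[i],
                 n_cells = round(100000 / spacing[i]^2),
                 n_feeder = feeders[i], n_frames = 1L,
                 seed = master_seed + i,
                 label = sprintf("seg%02d", i)))
  } else if (profile == "flow") {
    base <- function(motion, i, lab) scene_spec(
      shape = c(192L, 192L), colony_radius = 70, n_cells = 14,
      cell_spacing_px = 17, n_feeder = 4, n_decoys = 2,
      motion = motion, n_frames = 2L, seed = master_seed + 100L + i,
      label = lab)
    amp <- c(0, 0.5, 1, 2)
    c(list(base(list(type = "translation", dv = 0, du = 0), 1L, "trans_0_0"),
           base(list(type = "translation", dv = 0, du = 3), 2L, "trans_0_3"),
           base(list(type = "translation", dv = -2, du = 1), 3L, "trans_m2_1")),
      lapply(seq_along(amp), function(i)
        base(list(type = "translation", dv = amp[i] / sqrt(2),
                  du = amp[i] / sqrt(2)), 3L + i,
             sprintf("amp_%g", amp[i]))))
  } else {
    conds <- rep(c("control", "inhibited"), each = 5L)
    amps <- rep(c(2, 0.1), each = 5L)
    dirs <- seq(0, 2 * pi, length.out = 11L)[1:10]
    lapply(seq_len(10L), function(i)
      scene_spec(shape = c(512L, 512L), colony_radius = 160, n_cells = 50,
                 cell_spacing_px = 22, n_feeder = 8, n_decoys = 3,
                 motion = list(type = "translation",
                               dv = amps[i] * sin(dirs[i]),
                               du = amps[i] * cos(dirs[i])),
                 n_frames = 3L, seed = master_seed + 200L + i,
                 label = sprintf("%s%02d", conds[i], i),
                 condition = conds[i]))
  }
}
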