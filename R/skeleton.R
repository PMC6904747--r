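#' Extract the bright cell-cell boundary mesh
#'
#' Keratinocytes inside a colony are outlined by bright cell-cell boundaries
#' in phase contrast, while feeder fibroblasts lack this mesh. The frame is
#' adaptively binarized with bright polarity, cleaned by a 3x3 morphological
#' opening then closing (removing small spots and protrusions), and
#' connected regions of `boundary_min_region_px` pixels or fewer are removed.
#'
#' @param frame A [gray_frame()] or numeric matrix.
#' @param config A [pipeline_config()].
#' @return Logical matrix: the cleaned boundary mask.
#' @export
extract_boundary_mask <- function(frame, config = pipeline_config()) {
  px <- frame_pixels(frame)
  bw <- adaptive_binarize(px, window = config$binarize_window,
                          offset = config$binarize_offset, polarity = "bright",
                          weighting = config$binarize_weighting)
  bw <- .cf_morph3(.cf_morph3(bw, "erode", 1L), "dilate", 1L)   # opening
  bw <- .cf_morph3(.cf_morph3(bw, "dilate", 1L), "erode", 1L)   # closing
  remove_small_regions(bw, config$boundary_min_region_px, config$connectivity)
}

#' Zhang-Suen thinning
#'
#' Iterative two-subiteration thinning of a binary mask to a nominally
#' 1-pixel-wide skeleton, run until no pixel changes. A final pruning pass
#' removes the algorithm's known residual 2x2 staircase blocks (deleting only
#' topology-preserving pixels), so that crossing-number analysis downstream
#' sees clean junctions.
#'
#' @param mask Logical matrix.
#' @param prune Remove residual 2x2 foreground blocks (default `TRUE`).
#' @return Logical matrix of class `skeleton`.
#' @export
zhang_suen_thin <- function(mask, prune = TRUE) {
  if (!is.logical(mask)) stop("mask must be a logical matrix")
  out <- .cf_zhang_suen(mask, prune)
  class(out) <- c("skeleton", class(out))
  out
}

# 8-neighborhood of (r, c) in fixed cyclic order, clockwise from the top-left
# neighbor: NW, N, NE, E, SE, S, SW, W. Outside pixels count as background.
neighborhood8 <- function(mask, r, c) {
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- rbind(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, 1L),
                c(1L, 1L), c(1L, 0L), c(1L, -1L), c(0L, -1L))
  vapply(seq_len(8L), function(i) {
    rr <- r + offs[i, 1L]; cc <- c + offs[i, 2L]
    if (rr < 1L || rr > nr || cc < 1L || cc > nc) 0L else as.integer(mask[rr, cc])
  }, integer(1L))
}

#' Crossing number of a skeleton pixel
#'
#' Half the sum of absolute differences of the eight neighbor values taken in
#' cyclic order (the first neighbor repeated as the ninth):
#' `CN = 0.5 * sum_{i=1..8} |P_i - P_{i+1}|`, `P_9 = P_1`. CN is 1 at a line
#' endpoint, 2 in a line interior, 3 at a bifurcation and 4 at a crossing;
#' skeleton pixels with CN 3 are the branch points of the cell-boundary mesh.
#' Pixels on the image border are evaluated with zero padding.
#'
#' @param skeleton Logical matrix (nominally 1-px-wide curves).
#' @param pixel Integer `(row, col)` of a foreground pixel.
#' @return Integer in 0..4.
#' @export
crossing_number <- function(skeleton, pixel) {
  r <- as.integer(pixel[1L]); c <- as.integer(pixel[2L])
  if (!isTRUE(skeleton[r, c] == TRUE))
    stop("crossing_number is defined only for skeleton (foreground) pixels")
  p <- neighborhood8(skeleton, r, c)
  as.integer(0.5 * sum(abs(diff(c(p, p[1L])))))
}

# crossing number of every pixel at once (vectorized via shifted copies)
crossing_number_map <- function(skeleton) {
  nr <- nrow(skeleton); nc <- ncol(skeleton)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- as.integer(skeleton)
  sh <- function(dr, dc) pad[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  # cyclic order: NW, N, NE, E, SE, S, SW, W (clockwise from top-left)
  p <- list(sh(-1L, -1L), sh(-1L, 0L), sh(-1L, 1L), sh(0L, 1L),
            sh(1L, 1L), sh(1L, 0L), sh(1L, -1L), sh(0L, -1L))
  acc <- abs(p[[8L]] - p[[1L]])
  for (i in 1:7) acc <- acc + abs(p[[i]] - p[[i + 1L]])
  acc %/% 2L
}

#' Detect branch points of a skeleton
#'
#' Returns every skeleton pixel whose crossing number is exactly 3 (the
#' published bifurcation rule). Four-way crossings (CN 4) are included only
#' when `include_crossings` is `TRUE`.
#'
#' @param skeleton Logical matrix from [zhang_suen_thin()].
#' @param include_crossings Also report CN 4 pixels; default `FALSE`.
#' @return A [point_set()] of kind `"branch_point"`.
#' @export
detect_branch_points <- function(skeleton, include_crossings = FALSE) {
  cn <- crossing_number_map(skeleton)
  want <- skeleton & (cn == 3L | (include_crossings & cn == 4L))
  idx <- which(want)
  pts <- cbind((idx - 1L) %% nrow(skeleton) + 1L,
               (idx - 1L) %/% nrow(skeleton) + 1L)
  point_set(pts, "branch_point", dim(skeleton))
}
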