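#' Detect nucleoli as ring-enclosed dark spots
#'
#' Implements the cell-center landmark channel. In phase contrast the
#' nucleolus appears as a dark spot and the nucleus as a dark ring at the
#' cytoplasm boundary. The frame is adaptively binarized with dark polarity,
#' connected components are labeled, and components are kept when their area
#' lies in the configured `[nucleolus_min_px, nucleolus_max_px]` window.
#' A surviving region contributes a landmark only when both hold:
#'
#' * the rounded centroid pixel belongs to the region itself (rules out
#'   crescents and other concave fragments), and
#' * the region is enclosed by a second dark region, the nuclear ring: no
#'   background path from the region reaches the image border without
#'   crossing other foreground. Isolated dark specks (feeder debris, noise)
#'   fail this test.
#'
#' @param frame A [gray_frame()] or numeric matrix.
#' @param config A [pipeline_config()].
#' @return A [point_set()] of kind `"nucleolus"` (possibly empty) with
#'   integer-rounded centroid coordinates; ties in rounding go to the
#'   smaller index.
#' @export
detect_nucleoli <- function(frame, config = pipeline_config()) {
  px <- frame_pixels(frame)
  bw <- adaptive_binarize(px, window = config$binarize_window,
                          offset = config$binarize_offset, polarity = "dark",
                          weighting = config$binarize_weighting)
  regions <- label_components(bw, config$connectivity)
  cand <- filter_by_size(regions, config$nucleolus_min_px, config$nucleolus_max_px)
  tbl <- cand$region_table
  if (nrow(tbl) == 0L)
    return(point_set(matrix(integer(), 0L, 2L), "nucleolus", dim(px)))

  exposed <- exposed_labels(bw, cand$label_image)

  r <- round_half_down(tbl$centroid_row)
  c <- round_half_down(tbl$centroid_col)
  lab_at_centroid <- cand$label_image[cbind(r, c)]
  ok <- (lab_at_centroid == tbl$label) & !(tbl$label %in% exposed)
  point_set(cbind(r[ok], c[ok]), "nucleolus", dim(px))
}

# nearest-integer rounding with .5 ties toward the smaller index
round_half_down <- function(x) as.integer(ceiling(x - 0.5))

# Labels (of cand_label) that can reach the image border through background:
# label the background of the FULL dark mask with 4-connectivity, mark
# components touching the border as outer, and flag candidate regions that
# touch the border or are 4-adjacent to an outer background component.
exposed_labels <- function(full_mask, cand_label) {
  nr <- nrow(full_mask); nc <- ncol(full_mask)
  bg <- !full_mask
  bglab <- .cf_label_components(bg, 4L)
  border_idx <- c(bglab[1L, ], bglab[nr, ], bglab[, 1L], bglab[, nc])
  outer <- unique(border_idx[border_idx > 0L])
  outer_bg <- matrix(bglab %in% outer, nr, nc)
  # dilate outer background by one pixel in the 4 cardinal directions
  touch <- outer_bg
  touch[-1L, ] <- touch[-1L, ] | outer_bg[-nr, ]
  touch[-nr, ] <- touch[-nr, ] | outer_bg[-1L, ]
  touch[, -1L] <- touch[, -1L] | outer_bg[, -nc]
  touch[, -nc] <- touch[, -nc] | outer_bg[, -1L]
  # regions on the image border are exposed by definition
  on_border <- matrix(FALSE, nr, nc)
  on_border[c(1L, nr), ] <- TRUE
  on_border[, c(1L, nc)] <- TRUE
  hit <- cand_label[(touch | on_border) & cand_label > 0L]
  unique(hit)
}
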