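#' Adaptive binarization against a local weighted mean
#'
#' Thresholds each pixel against the weighted average intensity of its
#' neighborhood, which makes the segmentation robust to the uneven
#' illumination typical of phase-contrast fields. With `polarity = "dark"` a
#' pixel becomes foreground iff its intensity is below the local mean minus
#' `offset` (nucleoli, nuclear rings); with `"bright"` iff above the local
#' mean plus `offset` (cell-cell boundaries). Borders are handled by
#' mirror-reflected padding.
#'
#' @param frame A [gray_frame()] or numeric matrix in `[0, 1]`.
#' @param window Odd neighborhood width in pixels, >= 3 and smaller than both
#'   image dimensions.
#' @param offset Required deviation from the local mean, on the `[0, 1]`
#'   intensity scale.
#' @param polarity `"dark"` or `"bright"`.
#' @param weighting `"gaussian"` (sigma = window/6) or `"box"`.
#' @return Logical matrix, `TRUE` = foreground.
#' @export
adaptive_binarize <- function(frame, window = 41L, offset = 0.03,
                              polarity = c("dark", "bright"),
                              weighting = c("gaussian", "box")) {
  polarity <- match.arg(polarity)
  weighting <- match.arg(weighting)
  px <- frame_pixels(frame)
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 3L)
    stop("window must be an odd integer >= 3")
  if (window >= nrow(px) || window >= ncol(px))
    stop("window must be smaller than both image dimensions")
  k <- local_mean_kernel(window, weighting)
  mu <- .cf_sep_conv2(px, k, "reflect")
  if (polarity == "dark") px < mu - offset else px > mu + offset
}

local_mean_kernel <- function(window, weighting) {
  if (weighting == "box") {
    rep(1 / window, window)
  } else {
    s <- window / 6
    t <- seq.int(-(window %/% 2L), window %/% 2L)
    k <- exp(-t^2 / (2 * s^2))
    k / sum(k)
  }
}

#' Label connected components of a binary mask
#'
#' Maximal connected components under 4- or 8-connectivity, labeled 1..K in
#' raster order of each component's first-encountered pixel, with a per-label
#' table of pixel area and centroid.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8.
#' @return An object of class `labeled_regions`: list with `label_image`
#'   (integer matrix, 0 = background), `region_table` (data frame with
#'   columns `label`, `area`, `centroid_row`, `centroid_col`) and
#'   `connectivity`.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!is.logical(mask)) stop("mask must be a logical matrix")
  lab <- .cf_label_components(mask, as.integer(connectivity))
  labeled_regions(lab, as.integer(connectivity))
}

labeled_regions <- function(label_image, connectivity) {
  k <- max(label_image)
  if (k > 0L) {
    idx <- which(label_image > 0L)
    lv <- label_image[idx]
    rows <- (idx - 1L) %% nrow(label_image) + 1L
    cols <- (idx - 1L) %/% nrow(label_image) + 1L
    area <- tabulate(lv, nbins = k)
    tbl <- data.frame(
      label = seq_len(k),
      area = area,
      centroid_row = as.numeric(rowsum(as.numeric(rows), lv)) / area,
      centroid_col = as.numeric(rowsum(as.numeric(cols), lv)) / area
    )
  } else {
    tbl <- data.frame(label = integer(), area = integer(),
                      centroid_row = numeric(), centroid_col = numeric())
  }
  structure(list(label_image = label_image, region_table = tbl,
                 connectivity = connectivity),
            class = "labeled_regions")
}

#' @export
print.labeled_regions <- function(x, ...) {
  cat(sprintf("<labeled_regions: %d regions, %d-connectivity>\n",
              nrow(x$region_table), x$connectivity))
  invisible(x)
}

#' Keep regions within an inclusive area range
#'
#' Retains exactly the regions with `min_px <= area <= max_px` and relabels
#' the survivors consecutively (raster order preserved). The published
#' nucleolus filter keeps dark regions of 12 to 72 pixels, read as the
#' inclusive range (the literal "or" reading of the rule would keep
#' everything).
#'
#' @param regions A [label_components()] result.
#' @param min_px,max_px Inclusive area bounds in pixels.
#' @return A relabeled `labeled_regions`.
#' @export
filter_by_size <- function(regions, min_px, max_px) {
  if (min_px > max_px) stop("min_px must be <= max_px")
  keep <- regions$region_table$label[
    regions$region_table$area >= min_px & regions$region_table$area <= max_px]
  remap <- integer(max(1L, max(regions$label_image)))
  remap[keep] <- seq_along(keep)
  lab <- regions$label_image
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  labeled_regions(lab, regions$connectivity)
}

#' Remove regions of at most a given size
#'
#' Companion of [filter_by_size()] used by the boundary channel: drops every
#' connected region whose area is `max_px` pixels or less and returns the
#' cleaned mask.
#'
#' @param mask Logical matrix.
#' @param max_px Regions of this area or smaller are removed.
#' @param connectivity 4 or 8.
#' @return Logical matrix.
#' @export
remove_small_regions <- function(mask, max_px, connectivity = 8L) {
  regions <- label_components(mask, connectivity)
  drop <- regions$region_table$label[regions$region_table$area <= max_px]
  out <- mask
  out[regions$label_image %in% drop] <- FALSE
  out
}
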