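#' Construct a grayscale frame
#'
#' A `gray_frame` holds one 2-D phase-contrast image together with its
#' acquisition metadata. Pixel intensities are stored as doubles in `[0, 1]`
#' (8-bit inputs are divided by 255 at the I/O boundary), so every
#' thresholding step works on a single intensity scale.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]`, at least 2x2,
#'   with no missing values.
#' @param frame_index Integer position of the frame in its time series
#'   (1-based, consistent with R indexing).
#' @param interval_min Minutes between consecutive frames (> 0). Time-lapse
#'   acquisitions in feeder co-culture are typically recorded at 5 min
#'   intervals.
#' @param pixel_size_um Micrometers per pixel (> 0), or `NA` when unknown;
#'   speeds are then reported in px/frame only.
#' @return An object of class `gray_frame`.
#' @export
gray_frame <- function(pixels, frame_index = 1L, interval_min = 5,
                       pixel_size_um = NA_real_) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("frame must have at least 2 rows and 2 columns")
  if (anyNA(pixels)) stop("frame contains missing values")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("pixel intensities must lie in [0, 1]")
  if (!is.na(interval_min) && interval_min <= 0) stop("interval_min must be > 0")
  if (!is.na(pixel_size_um) && pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  structure(
    list(pixels = pixels, frame_index = as.integer(frame_index),
         interval_min = interval_min, pixel_size_um = pixel_size_um),
    class = "gray_frame"
  )
}

#' @export
print.gray_frame <- function(x, ...) {
  cat(sprintf("<gray_frame %d x %d, frame %d, interval %s min, pixel %s um>\n",
              nrow(x$pixels), ncol(x$pixels), x$frame_index,
              format(x$interval_min), format(x$pixel_size_um)))
  invisible(x)
}

frame_pixels <- function(frame) {
  if (inherits(frame, "gray_frame")) frame$pixels else as.matrix(frame)
}

#' Construct a point set of image landmarks
#'
#' Landmarks are either nucleolus centroids (dark intranuclear spots) or
#' cell-cell boundary branch points; both serve as kernel-density sample
#' points for colony extraction. Coordinates are 1-based `(row, col)` with
#' row 1 the top image row.
#'
#' @param points Two-column integer matrix (or data frame) of `(row, col)`
#'   coordinates; may have zero rows.
#' @param kind Character vector, `"nucleolus"` or `"branch_point"`; length 1
#'   (recycled) or one entry per point. Pooled sets carry both kinds.
#' @param shape Integer `(rows, cols)` of the source frame, used to assert
#'   that every point lies in bounds.
#' @return An object of class `point_set` with elements `points` (n x 2
#'   integer matrix, columns `row`, `col`), `kind` (character vector of n)
#'   and `shape`.
#' @export
point_set <- function(points, kind, shape) {
  points <- as.matrix(points)
  if (length(points) == 0L) points <- matrix(integer(), 0L, 2L)
  if (ncol(points) != 2L) stop("points must have two columns (row, col)")
  storage.mode(points) <- "integer"
  colnames(points) <- c("row", "col")
  shape <- as.integer(shape)
  n <- nrow(points)
  kind <- as.character(kind)
  if (!all(kind %in% c("nucleolus", "branch_point")))
    stop("kind must be 'nucleolus' or 'branch_point'")
  kind <- if (length(kind) == 1L) rep(kind, n) else kind
  if (length(kind) != n) stop("kind must have one entry per point")
  if (n > 0L) {
    if (any(points[, 1L] < 1L | points[, 1L] > shape[1L] |
            points[, 2L] < 1L | points[, 2L] > shape[2L]))
      stop("point outside source image bounds")
    key <- paste(points[, 1L], points[, 2L], kind)
    if (anyDuplicated(key)) stop("duplicate coordinates within one landmark kind")
  }
  structure(list(points = points, kind = kind, shape = shape),
            class = "point_set")
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set of %d points (%s) on %d x %d frame>\n",
              nrow(x$points), paste(unique(x$kind), collapse = "+"),
              x$shape[1L], x$shape[2L]))
  invisible(x)
}

n_points <- function(ps) nrow(ps$points)

#' Pipeline configuration
#'
#' One record holding every tunable threshold of the colony-extraction and
#' motion-analysis pipeline, so no stage carries hidden magic numbers. The
#' defaults are the published operating point of the method: a 41 x 41
#' adaptive-threshold neighborhood, a nucleolus size window of 12-72 px,
#' removal of boundary fragments of 250 px or less, and a Gaussian KDE
#' bandwidth of h = 151 px.
#'
#' @param binarize_window Odd neighborhood width (px) for adaptive
#'   binarization; default 41.
#' @param binarize_offset Threshold offset as a fraction of the intensity
#'   range; a pixel must deviate from its local weighted mean by more than
#'   this to become foreground. Default 0.03.
#' @param binarize_weighting `"gaussian"` (sigma = window/6) or `"box"`
#'   local-mean weighting.
#' @param nucleolus_min_px,nucleolus_max_px Inclusive area range (px) a dark
#'   region must fall in to be a nucleolus candidate; defaults 12 and 72.
#' @param boundary_min_region_px Boundary-mask regions of this many pixels or
#'   fewer are removed; default 250.
#' @param kde_bandwidth Gaussian KDE bandwidth h in pixels; default 151.
#' @param kde_threshold_frac Fraction of the density maximum at which the
#'   density surface is binarized; default 0.5 (the half-maximum level set of
#'   a Gaussian-smoothed indicator tracks the indicator's boundary).
#' @param kde_truncate Kernel truncation radius in bandwidths for the
#'   convolution evaluation; default 6 (truncation error ~ exp(-18)).
#' @param flow_backend `"lk"` (pyramidal Lucas-Kanade dense flow, default) or
#'   `"block"` (exhaustive integer block matching, the testing oracle).
#' @param include_crossings If `TRUE`, skeleton pixels with crossing number 4
#'   also count as branch points; default `FALSE` (crossing number exactly 3).
#' @param connectivity Pixel connectivity for component labeling, 4 or 8;
#'   default 8.
#' @param pixel_size_um,interval_min Acquisition metadata defaults applied by
#'   [read_frames()]; `pixel_size_um` has no universal default because it
#'   depends on the objective used.
#' @param random_seed Optional integer seed recorded in run manifests.
#' @return An object of class `pipeline_config` (a validated named list).
#' @export
pipeline_config <- function(binarize_window = 41L,
                            binarize_offset = 0.03,
                            binarize_weighting = c("gaussian", "box"),
                            nucleolus_min_px = 12L,
                            nucleolus_max_px = 72L,
                            boundary_min_region_px = 250L,
                            kde_bandwidth = 151,
                            kde_threshold_frac = 0.5,
                            kde_truncate = 6,
                            flow_backend = c("lk", "block"),
                            include_crossings = FALSE,
                            connectivity = 8L,
                            pixel_size_um = NA_real_,
                            interval_min = 5,
                            random_seed = NULL) {
  binarize_weighting <- match.arg(binarize_weighting)
  flow_backend <- match.arg(flow_backend)
  binarize_window <- as.integer(binarize_window)
  if (binarize_window < 3L || binarize_window %% 2L == 0L)
    stop("binarize_window must be an odd integer >= 3")
  if (nucleolus_min_px > nucleolus_max_px)
    stop("nucleolus_min_px must be <= nucleolus_max_px")
  if (kde_bandwidth <= 0) stop("kde_bandwidth must be > 0")
  if (kde_threshold_frac <= 0 || kde_threshold_frac >= 1)
    stop("kde_threshold_frac must lie in (0, 1)")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  structure(
    list(binarize_window = binarize_window,
         binarize_offset = binarize_offset,
         binarize_weighting = binarize_weighting,
         nucleolus_min_px = as.integer(nucleolus_min_px),
         nucleolus_max_px = as.integer(nucleolus_max_px),
         boundary_min_region_px = as.integer(boundary_min_region_px),
         kde_bandwidth = kde_bandwidth,
         kde_threshold_frac = kde_threshold_frac,
         kde_truncate = kde_truncate,
         flow_backend = flow_backend,
         include_crossings = isTRUE(include_crossings),
         connectivity = as.integer(connectivity),
         pixel_size_um = pixel_size_um,
         interval_min = interval_min,
         random_seed = random_seed),
    class = "pipeline_config"
  )
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path File path.
#' @return `read_config()` returns a [pipeline_config()]; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals[names(vals) %in% names(formals(pipeline_config))])
}

#' @rdname read_config
#' @param config A [pipeline_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

read_one_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- tryCatch({
    if (ext == "png") {
      png::readPNG(path)
    } else if (ext %in% c("pgm", "ppm", "pnm")) {
      pm <- pixmap::read.pnm(path)
      if (inherits(pm, "pixmapRGB"))
        (pm@red + pm@green + pm@blue) / 3
      else
        pm@grey
    } else if (ext %in% c("csv", "txt")) {
      as.matrix(utils::read.csv(path, header = FALSE))
    } else {
      stop("unsupported image format '", ext, "' (PNG, PGM/PPM or CSV expected)")
    }
  }, error = function(e) {
    stop("failed to read image file '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (length(dim(px)) == 3L) px <- apply(px, c(1L, 2L), mean)  # luminance average
  px <- as.matrix(px)
  storage.mode(px) <- "double"
  if (max(px) > 1) px <- px / 255
  px
}

#' Read an ordered image time series
#'
#' Accepts a directory of numbered single-frame files or an explicit vector
#' of file paths (PNG, PGM/PPM or CSV matrices); files are sorted by name and
#' become frames 1, 2, .... All frames must share one shape.
#'
#' @param path_or_list Directory, or character vector of image files.
#' @param interval_min Minutes between consecutive frames.
#' @param pixel_size_um Micrometers per pixel (`NA` if unknown).
#' @return List of [gray_frame()] objects ordered by `frame_index`.
#' @export
read_frames <- function(path_or_list, interval_min = 5, pixel_size_um = NA_real_) {
  files <- path_or_list
  if (length(files) == 1L && dir.exists(files)) {
    files <- list.files(files, pattern = "\\.(png|pgm|ppm|pnm|csv)$",
                        ignore.case = TRUE, full.names = TRUE)
    files <- sort(files)
  }
  if (length(files) == 0L) stop("no image files found")
  frames <- vector("list", length(files))
  shp <- NULL
  for (i in seq_along(files)) {
    px <- read_one_image(files[[i]])
    if (is.null(shp)) shp <- dim(px)
    if (!identical(dim(px), shp))
      stop(sprintf("frame shape mismatch: '%s' is %d x %d, expected %d x %d",
                   files[[i]], nrow(px), ncol(px), shp[1L], shp[2L]))
    frames[[i]] <- gray_frame(px, frame_index = i, interval_min = interval_min,
                              pixel_size_um = pixel_size_um)
  }
  frames
}

#' Write and read binary masks and landmark point sets
#'
#' Masks are written as 8-bit PNG (background 0, foreground 255); point sets
#' as CSV with header `row,col,kind`. Both round-trip exactly.
#'
#' @param mask Logical matrix (or `colony_mask`).
#' @param path Output file path.
#' @return The path, invisibly (`write_*`); a logical matrix or
#'   [point_set()] (`read_*`).
#' @export
write_mask <- function(mask, path) {
  if (inherits(mask, "colony_mask")) mask <- mask$pixels
  if (!is.logical(mask)) stop("mask must be a logical matrix")
  ok <- tryCatch(png::writePNG(mask * 1, path), error = function(e)
    stop("cannot write mask to '", path, "': ", conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  px <- read_one_image(path)
  px > 0.5
}

#' @rdname write_mask
#' @param points A [point_set()].
#' @export
write_points <- function(points, path) {
  df <- data.frame(row = points$points[, 1L], col = points$points[, 2L],
                   kind = points$kind)
  tryCatch(utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
           error = function(e)
    stop("cannot write points to '", path, "': ", conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' @rdname write_mask
#' @param shape Frame shape `(rows, cols)` the points belong to.
#' @export
read_points <- function(path, shape) {
  df <- utils::read.csv(path)
  point_set(cbind(df$row, df$col), kind = as.character(df$kind), shape = shape)
}
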