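#' Pool nucleolus and branch-point landmarks
#'
#' The two landmark channels are combined into one sample-point set for
#' kernel density estimation. A coordinate present in both channels counts
#' twice: each landmark contributes its own kernel mass.
#'
#' @param nucleoli,branch_points [point_set()] objects from the same frame.
#' @return A [point_set()] carrying both kinds.
#' @export
pool_landmarks <- function(nucleoli, branch_points) {
  if (!identical(nucleoli$shape, branch_points$shape))
    stop("landmark sets come from frames of different shapes")
  point_set(rbind(nucleoli$points, branch_points$points),
            kind = c(nucleoli$kind, branch_points$kind),
            shape = nucleoli$shape)
}

#' Gaussian kernel density surface over landmark points
#'
#' Evaluates an isotropic 2-D Gaussian kernel density estimate at every
#' pixel:
#' `f(x) = 1/(n * 2*pi*h^2) * sum_i exp(-||x - x_i||^2 / (2 h^2))`,
#' the 2-D generalization of the classic `f(x) = (1/nh) sum_i K((x - x_i)/h)`
#' with the proper bivariate normalizer. Colony interiors contain many
#' nucleoli and boundary branch points, so `f` is the per-pixel likelihood of
#' colony membership. The surface is computed by separable convolution of a
#' landmark impulse image with a truncated Gaussian (zero-padded borders, so
#' the result equals the direct sum over landmarks up to the truncation
#' error); `method = "direct"` evaluates the sum explicitly and serves as the
#' reference implementation.
#'
#' @param points A [point_set()] (typically from [pool_landmarks()]).
#' @param shape `(rows, cols)` of the target surface; defaults to the point
#'   set's source shape.
#' @param bandwidth Gaussian bandwidth h in pixels (> 0); the published
#'   operating point is h = 151.
#' @param method `"convolution"` (default) or `"direct"`.
#' @param truncate Kernel truncation radius in bandwidths (convolution
#'   method); default 6.
#' @return An object of class `density_map`: list with `values` (matrix),
#'   `bandwidth` and `n_points`. An empty point set yields an all-zero map
#'   with attribute `empty = TRUE`.
#' @export
kde_density <- function(points, shape = points$shape, bandwidth = 151,
                        method = c("convolution", "direct"), truncate = 6) {
  method <- match.arg(method)
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  shape <- as.integer(shape)
  n <- n_points(points)
  if (n == 0L) {
    out <- structure(list(values = matrix(0, shape[1L], shape[2L]),
                          bandwidth = bandwidth, n_points = 0L),
                     class = "density_map")
    attr(out, "empty") <- TRUE
    return(out)
  }
  h <- bandwidth
  norm <- n * 2 * pi * h^2
  if (method == "direct") {
    vals <- matrix(0, shape[1L], shape[2L])
    rows <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
    cols <- matrix(rep(seq_len(shape[2L]), each = shape[1L]), shape[1L], shape[2L])
    for (i in seq_len(n)) {
      d2 <- (rows - points$points[i, 1L])^2 + (cols - points$points[i, 2L])^2
      vals <- vals + exp(-d2 / (2 * h^2))
    }
    vals <- vals / norm
  } else {
    imp <- matrix(0, shape[1L], shape[2L])
    idx <- cbind(points$points[, 1L], points$points[, 2L])
    for (i in seq_len(n)) imp[idx[i, 1L], idx[i, 2L]] <- imp[idx[i, 1L], idx[i, 2L]] + 1
    r <- ceiling(truncate * h)
    t <- seq.int(-r, r)
    k <- exp(-t^2 / (2 * h^2))
    vals <- .cf_sep_conv2(imp, k, "zero") / norm
  }
  structure(list(values = vals, bandwidth = bandwidth, n_points = n),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map %d x %d, h = %s, n = %d, max = %.3g>\n",
              nrow(x$values), ncol(x$values), format(x$bandwidth), x$n_points,
              max(x$values)))
  invisible(x)
}

#' Threshold a density surface and keep the largest region
#'
#' Binarizes the density at `threshold_frac` times its maximum (relative
#' thresholding, so the KDE normalizing constant cancels) and keeps the
#' largest 8-connected super-threshold region as the colony; ties go to the
#' region whose first pixel comes earliest in raster order. Use
#' `absolute = TRUE` to threshold at a fixed density value instead.
#'
#' @param density A [kde_density()] result.
#' @param threshold_frac Fraction of the density maximum in (0, 1), or an
#'   absolute density when `absolute = TRUE`.
#' @param frame_index Frame index recorded in the mask.
#' @param absolute Interpret `threshold_frac` as an absolute density value.
#' @return An object of class `colony_mask`: list with `pixels` (logical
#'   matrix, one 8-connected component or empty), `area_px` and
#'   `frame_index`. An all-zero density yields an empty mask with attribute
#'   `empty = TRUE`.
#' @export
extract_colony <- function(density, threshold_frac = 0.5, frame_index = 1L,
                           absolute = FALSE) {
  vals <- density$values
  if (!absolute && (threshold_frac <= 0 || threshold_frac >= 1))
    stop("threshold_frac must lie in (0, 1)")
  mx <- max(vals)
  if (mx <= 0) {
    warning("all-zero density: no colony extracted")
    return(colony_mask(matrix(FALSE, nrow(vals), ncol(vals)), frame_index,
                       empty = TRUE))
  }
  thr <- if (absolute) threshold_frac else threshold_frac * mx
  bw <- vals >= thr
  regions <- label_components(bw, 8L)
  tbl <- regions$region_table
  if (nrow(tbl) == 0L)
    return(colony_mask(matrix(FALSE, nrow(vals), ncol(vals)), frame_index,
                       empty = TRUE))
  best <- tbl$label[which.max(tbl$area)]  # labels are raster-ordered: first max wins ties
  colony_mask(regions$label_image == best, frame_index)
}

colony_mask <- function(pixels, frame_index = 1L, empty = FALSE) {
  out <- structure(list(pixels = pixels, area_px = sum(pixels),
                        frame_index = as.integer(frame_index)),
                   class = "colony_mask")
  if (empty) attr(out, "empty") <- TRUE
  out
}

#' @export
print.colony_mask <- function(x, ...) {
  cat(sprintf("<colony_mask frame %d: %d px>\n", x$frame_index, x$area_px))
  invisible(x)
}

#' Run colony extraction on every frame of a time series
#'
#' Per frame: nucleolus detection, boundary skeletonization with branch-point
#' detection, landmark pooling, kernel density estimation and largest-region
#' thresholding. A frame with no landmarks yields an empty mask and a
#' warning; downstream speed statistics skip such frames.
#'
#' @param frames List of [gray_frame()] objects.
#' @param config A [pipeline_config()].
#' @return List of `colony_mask` objects, one per frame, each carrying a
#'   `n_landmarks` attribute.
#' @export
extract_colony_timeseries <- function(frames, config = pipeline_config()) {
  if (length(frames) < 1L) stop("at least one frame required")
  lapply(frames, function(fr) {
    nuc <- detect_nucleoli(fr, config)
    bmask <- extract_boundary_mask(fr, config)
    skel <- zhang_suen_thin(bmask)
    bp <- detect_branch_points(skel, config$include_crossings)
    landmarks <- pool_landmarks(nuc, bp)
    if (n_points(landmarks) == 0L) {
      warning(sprintf("frame %d: no landmarks detected; empty colony mask",
                      fr$frame_index))
      m <- colony_mask(matrix(FALSE, nrow(fr$pixels), ncol(fr$pixels)),
                       fr$frame_index, empty = TRUE)
    } else {
      dens <- kde_density(landmarks, bandwidth = config$kde_bandwidth,
                          truncate = config$kde_truncate)
      m <- extract_colony(dens, config$kde_threshold_frac, fr$frame_index)
    }
    attr(m, "n_landmarks") <- n_points(landmarks)
    m
  })
}
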