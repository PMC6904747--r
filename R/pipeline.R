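#' Run the full extraction + motion pipeline on one time series
#'
#' Orchestrates the whole workflow for one recorded field: per-frame colony
#' extraction (nucleoli + branch points + KDE), per-pair dense optical flow,
#' speed summaries, and file outputs — colony mask PNGs, a per-frame colony
#' CSV (`frame_index`, `n_landmarks`, `colony_area_px`), a per-pair speed
#' CSV, and a JSON run manifest recording the config snapshot, input
#' checksums, package version, seed, per-stage timings and every warning
#' emitted. A run whose frames yield no colony at all exits with a
#' dataset-level diagnostic rather than a crash.
#'
#' @param frames_path Directory or file vector accepted by [read_frames()],
#'   or a pre-read list of [gray_frame()] objects.
#' @param config A [pipeline_config()], or a path to a YAML config.
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   all file output.
#' @param extraction_only Skip the flow/speed stage (valid for single-frame
#'   input).
#' @return The run manifest (list), invisibly; its `$results` element holds
#'   the in-memory masks and `speed_summary`.
#' @export
run_pipeline <- function(frames_path, config = pipeline_config(),
                         out_dir = NULL, extraction_only = FALSE) {
  if (is.character(config)) config <- read_config(config)
  input_files <- NULL
  if (is.character(frames_path)) {
    input_files <- if (length(frames_path) == 1L && dir.exists(frames_path))
      sort(list.files(frames_path, pattern = "\\.(png|pgm|ppm|pnm|csv)$",
                      ignore.case = TRUE, full.names = TRUE)) else frames_path
    frames <- read_frames(frames_path, config$interval_min, config$pixel_size_um)
  } else {
    frames <- frames_path
  }
  if (!extraction_only && length(frames) < 2L)
    stop("motion analysis needs >= 2 frames; pass extraction_only = TRUE for one")
  if (!is.null(config$random_seed)) set.seed(config$random_seed)

  warnings_seen <- character(0)
  catch_warn <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  timings <- c()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- expr
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }

  masks <- tick("extract", catch_warn(extract_colony_timeseries(frames, config)))
  if (all(vapply(masks, function(m) m$area_px == 0L, logical(1L))))
    stop("no valid colony mask in any frame: check focus, contrast and config ",
         "thresholds (dataset-level failure, not a crash)")

  speed <- NULL
  if (!extraction_only)
    speed <- tick("flow", catch_warn(speed_timecourse(frames, masks, config)))

  outputs <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(masks)) {
      f <- file.path(out_dir, sprintf("mask_%03d.png", i))
      write_mask(masks[[i]], f)
      outputs <- c(outputs, f)
    }
    colony_csv <- file.path(out_dir, "colony_area.csv")
    utils::write.csv(data.frame(
      frame_index = vapply(masks, function(m) m$frame_index, integer(1L)),
      n_landmarks = vapply(masks, function(m) attr(m, "n_landmarks") %||% NA_integer_,
                           integer(1L)),
      colony_area_px = vapply(masks, function(m) m$area_px, integer(1L))
    ), colony_csv, row.names = FALSE)
    outputs <- c(outputs, colony_csv)
    if (!is.null(speed)) {
      pair_ids <- setdiff(seq_len(length(frames) - 1L), speed$skipped_pairs)
      speed_csv <- file.path(out_dir, "speeds.csv")
      utils::write.csv(data.frame(
        frame_pair = sprintf("%d-%d", pair_ids, pair_ids + 1L),
        mean_speed = speed$per_pair_means,
        unit = speed$unit,
        n_pixels = speed$n_pixels
      ), speed_csv, row.names = FALSE)
      outputs <- c(outputs, speed_csv)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("colonyflow")),
    config = unclass(config),
    seed = config$random_seed,
    inputs = if (!is.null(input_files))
      data.frame(file = input_files,
                 md5 = unname(tools::md5sum(input_files))) else NULL,
    outputs = outputs,
    timings_sec = as.list(timings),
    warnings = warnings_seen,
    results = list(masks = masks, speed = speed)
  )
  if (!is.null(out_dir)) {
    keep <- manifest[setdiff(names(manifest), "results")]
    jsonlite::write_json(keep, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                         null = "null")
  }
  invisible(manifest)
}

#' Screen conditions by collective motion
#'
#' The short-protocol screening readout: per condition (e.g. control vs
#' metabolic or cytoskeletal inhibitor), each colony's time series is run
#' through colony extraction and optical flow, its per-pair speeds averaged
#' into one per-colony mean — the statistical unit. Two conditions are
#' compared with the unpaired two-tailed Mann-Whitney U test; three or more
#' with Kruskal-Wallis plus Dunn's post-hoc versus the designated control.
#' Colonies with fewer than 2 usable frames are excluded with a warning.
#' 2-3 serial frames at 5 min intervals per colony suffice.
#'
#' @param conditions Named list; each element is a list of colony recordings,
#'   each recording either a list of [gray_frame()] objects or a
#'   directory/file-vector accepted by [read_frames()].
#' @param config A [pipeline_config()].
#' @param control Name of the control condition (default: first).
#' @param out_dir Optional output directory for a long-format violin-ready
#'   CSV (`condition`, `colony_id`, `frame_pair`, `mean_speed`, `n_pixels`)
#'   and a stats JSON report.
#' @return List with `per_colony` (data frame of per-colony mean speeds),
#'   `stats` (a `group_comparison`), and `unit`.
#' @export
run_screen <- function(conditions, config = pipeline_config(),
                       control = names(conditions)[1L], out_dir = NULL) {
  if (length(conditions) < 2L) stop("need >= 2 conditions")
  if (is.null(names(conditions)) || any(names(conditions) == ""))
    stop("conditions must be named")
  long <- NULL
  per_colony <- NULL
  unit <- NULL
  for (cond in names(conditions)) {
    colonies <- conditions[[cond]]
    for (k in seq_along(colonies)) {
      frames <- colonies[[k]]
      if (is.character(frames))
        frames <- read_frames(frames, config$interval_min, config$pixel_size_um)
      if (length(frames) < 2L) {
        warning(sprintf("condition '%s' colony %d: <2 frames, excluded", cond, k))
        next
      }
      masks <- suppressWarnings(extract_colony_timeseries(frames, config))
      sp <- tryCatch(suppressWarnings(speed_timecourse(frames, masks, config)),
                     error = function(e) NULL)
      if (is.null(sp) || length(sp$per_pair_means) == 0L) {
        warning(sprintf("condition '%s' colony %d: no usable frame pair, excluded",
                        cond, k))
        next
      }
      unit <- sp$unit
      pair_ids <- setdiff(seq_len(length(frames) - 1L), sp$skipped_pairs)
      long <- rbind(long, data.frame(
        condition = cond, colony_id = k,
        frame_pair = sprintf("%d-%d", pair_ids, pair_ids + 1L),
        mean_speed = sp$per_pair_means, n_pixels = sp$n_pixels))
      per_colony <- rbind(per_colony, data.frame(
        condition = cond, colony_id = k, mean_speed = sp$mean_speed))
    }
  }
  if (is.null(per_colony)) stop("no usable colonies in any condition")
  grp <- split(per_colony$mean_speed, per_colony$condition)
  grp <- grp[intersect(names(conditions), names(grp))]  # preserve input order
  stats_out <- if (length(grp) == 2L) {
    ord <- c(control, setdiff(names(grp), control))
    compare_two_groups(grp[[ord[1L]]], grp[[ord[2L]]], labels = ord)
  } else {
    compare_multi_groups(grp, control = control)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(long, file.path(out_dir, "speeds_long.csv"),
                     row.names = FALSE)
    report <- list(test = stats_out$test_name, statistic = stats_out$statistic,
                   p_value = stats_out$p_value,
                   n = as.list(stats_out$n), control = control,
                   unit = unit, note = stats_out$note,
                   posthoc = stats_out$posthoc_table)
    jsonlite::write_json(report, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                         null = "null", na = "null")
  }
  list(per_colony = per_colony, long = long, stats = stats_out, unit = unit)
}
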