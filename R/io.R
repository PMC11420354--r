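stack_meta_path <- function(path) paste0(path, ".json")

#' Write a calibrated stack to a multi-page TIFF
#'
#' Pages are written frame-major with channels interleaved
#' (`t1c1, t1c2, t2c1, ...`) as 16-bit unsigned integers (intensities
#' clipped to `[0, 65535]` and rounded). Calibration, channel labels and
#' page layout are stored in a JSON sidecar (`<path>.json`) that
#' [read_stack()] treats as the file's metadata.
#'
#' @param stack a [calibrated_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "calibrated_stack"))
  d <- dim(stack$data)
  scale <- 65535
  pages <- vector("list", d[3L] * d[4L])
  k <- 0L
  for (f in seq_len(d[4L])) for (c in seq_len(d[3L])) {
    k <- k + 1L
    m <- stack$data[, , c, f]
    m <- round(pmin(pmax(m, 0), scale)) / scale
    pages[[k]] <- m
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "deflate")
  meta <- list(pixel_size_um = stack$pixel_size,
               frame_interval_s = stack$frame_interval,
               channels = as.list(stack$channels),
               n_frames = d[4L], n_channels = d[3L],
               intensity_scale = scale,
               page_order = "frame-major, channel-interleaved")
  jsonlite::write_json(meta, stack_meta_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a calibrated stack from a multi-page TIFF
#'
#' Calibration is taken from the JSON sidecar written by [write_stack()]
#' when present; otherwise the `pixel_size` / `frame_interval` overrides
#' are used. If a calibration value is available from neither source the
#' read fails. Without a sidecar, pages are interpreted as a
#' single-channel time series.
#'
#' @param path TIFF path.
#' @param pixel_size,frame_interval calibration overrides (um/px, s);
#'   an override, when given, wins over the sidecar.
#' @return a [calibrated_stack()].
#' @export
read_stack <- function(path, pixel_size = NULL, frame_interval = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- NULL
  mp <- stack_meta_path(path)
  if (file.exists(mp)) meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  px <- if (!is.null(pixel_size)) pixel_size else meta$pixel_size_um
  dt <- if (!is.null(frame_interval)) frame_interval else
    meta$frame_interval_s
  if (is.null(px) || is.null(dt))
    stop("no calibration: supply `pixel_size` and `frame_interval` ",
         "or provide the metadata sidecar")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 65535
  nc <- if (!is.null(meta$n_channels)) meta$n_channels else 1L
  nf <- length(pages) / nc
  if (nf != round(nf)) stop("page count not divisible by channel count")
  H <- nrow(pages[[1L]]); W <- ncol(pages[[1L]])
  data <- array(NA_real_, c(H, W, nc, nf))
  k <- 0L
  for (f in seq_len(nf)) for (c in seq_len(nc)) {
    k <- k + 1L
    data[, , c, f] <- pages[[k]] * scale
  }
  channels <- if (!is.null(meta$channels)) unlist(meta$channels) else NULL
  calibrated_stack(data, px, dt, channels)
}

#' Pipeline configuration with validated defaults
#'
#' Collects every tunable of the analysis pipeline with its default and
#' valid range: spot diameter for chloroplast tracking, linking gap,
#' velocity smoothing window, gliding-window thresholds, batch ROI
#' duration bounds, stripe-notch width, orientation bins and fit
#' threshold, and the population trace filters.
#'
#' @param ... named overrides of the defaults.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    spot_diameter_um = 5.6,      # bounding circle of the larger chloroplast
    max_gap = 5L,
    smoothing_window = 20L,
    gliding_v_min_um_s = 0.5,
    gliding_t_min_s = 5,
    roi_min_s = 5,
    roi_max_s = 15,
    stripe_mask_width = 2L,
    n_orientation_bins = 90L,
    r2_threshold = 0.5,
    trace_min_duration_s = 30,
    trace_min_distance_um = 50,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  with(cfg, {
    if (spot_diameter_um < 4 || spot_diameter_um > 8)
      stop("spot_diameter_um must be in [4, 8]")
    if (smoothing_window < 1) stop("smoothing_window must be >= 1")
    if (roi_min_s >= roi_max_s) stop("roi_min_s must be < roi_max_s")
    if (stripe_mask_width < 1) stop("stripe_mask_width must be >= 1")
    if (n_orientation_bins < 8) stop("n_orientation_bins must be >= 8")
    if (r2_threshold < 0 || r2_threshold > 1)
      stop("r2_threshold must be in [0, 1]")
  })
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg <- cfg[order(names(cfg))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = 15)
  unname(tools::md5sum(tmp))
}

#' Write pipeline results with a reproducibility manifest
#'
#' Data frames are written as tidy CSV (units in column names),
#' kymographs and stacks as TIFF, and a JSON manifest records the
#' configuration, its hash, the seed and the MD5 of every written file
#' so a run can be reproduced bit-identically from config + seed.
#'
#' @param results named list whose elements are data frames,
#'   [kymograph()] objects or [calibrated_stack()] objects.
#' @param out_dir output directory (created if missing).
#' @param config a [pipeline_config()].
#' @param seed the seed the run used.
#' @return the manifest (also written to `manifest.json`), invisibly.
#' @export
write_results <- function(results, out_dir, config = pipeline_config(),
                          seed = config$seed) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stopifnot(is.list(results), !is.null(names(results)),
            all(nzchar(names(results))))
  files <- character(0)
  for (nm in names(results)) {
    obj <- results[[nm]]
    if (inherits(obj, "kymograph")) {
      fp <- file.path(out_dir, paste0(nm, ".tif"))
      st <- calibrated_stack(array(unclass(obj), c(dim(obj), 1L, 1L)),
                             attr(obj, "pixel_size"),
                             attr(obj, "frame_interval"), nm)
      write_stack(st, fp)
      files <- c(files, fp, stack_meta_path(fp))
    } else if (inherits(obj, "calibrated_stack")) {
      fp <- file.path(out_dir, paste0(nm, ".tif"))
      write_stack(obj, fp)
      files <- c(files, fp, stack_meta_path(fp))
    } else if (is.data.frame(obj)) {
      fp <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(obj, fp, row.names = FALSE)
      files <- c(files, fp)
    } else {
      stop("cannot serialise result `", nm, "` of class ",
           paste(class(obj), collapse = "/"))
    }
  }
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = unclass(config),
    config_hash = config_hash(config),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
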