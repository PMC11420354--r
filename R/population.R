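#' Construct a population motility trace
#'
#' One cell's position-vs-time record in the population assay. Duration
#' is `(n_frames - 1) * frame_interval`, path length is the cumulative
#' frame-to-frame displacement, and the mean velocity is path length over
#' duration.
#'
#' @param t_s frame times, seconds (strictly increasing).
#' @param x_um,y_um positions, micrometres.
#' @param cell cell identifier.
#' @return list of class `motility_trace` with fields `cell`, `t_s`,
#'   `x_um`, `y_um`, `duration_s`, `path_um`, `mean_v_um_s`.
#' @export
motility_trace <- function(t_s, x_um, y_um, cell = 1L) {
  stopifnot(length(t_s) == length(x_um), length(t_s) == length(y_um),
            length(t_s) >= 1L)
  if (is.unsorted(t_s, strictly = TRUE)) stop("`t_s` must be increasing")
  path <- if (length(t_s) > 1L) sum(sqrt(diff(x_um)^2 + diff(y_um)^2)) else 0
  dur <- t_s[length(t_s)] - t_s[1L]
  structure(list(cell = cell, t_s = t_s, x_um = x_um, y_um = y_um,
                 duration_s = dur, path_um = path,
                 mean_v_um_s = if (dur > 0) path / dur else 0),
            class = "motility_trace")
}

#' @export
print.motility_trace <- function(x, ...) {
  cat(sprintf("<motility_trace> cell %s: %.1f s, %.1f um, %.3f um/s\n",
              format(x$cell), x$duration_s, x$path_um, x$mean_v_um_s))
  invisible(x)
}

#' Track every cell in a low-magnification population movie
#'
#' Cells appear as dark elongated bodies on a bright background. Each
#' frame is inverted, lightly Gaussian-smoothed (sigma 1 px) and
#' segmented by Otsu thresholding; connected components above
#' `min_area_um2` are reduced to centroids weighted by the
#' above-threshold intensity excess (which suppresses boundary-noise
#' jitter), and centroids are linked across frames by nearest-neighbour
#' assignment within `search_radius_um`, tolerating up to `max_gap`
#' missed frames per track.
#'
#' @param stack single-channel [calibrated_stack()].
#' @param min_area_um2 minimum segmented area of a cell (square
#'   micrometres).
#' @param search_radius_um maximum frame-to-frame displacement for
#'   linking (micrometres).
#' @param max_gap maximum number of consecutive frames a track may go
#'   undetected before it is closed.
#' @param min_points minimum number of points for a track to be reported.
#' @return list of [motility_trace()] objects (possibly empty).
#' @export
track_population <- function(stack, min_area_um2 = 100,
                             search_radius_um = 30, max_gap = 2L,
                             min_points = 3L) {
  stopifnot(inherits(stack, "calibrated_stack"))
  if (n_channels(stack) != 1L) stop("expected a single-channel movie")
  px <- stack$pixel_size
  dt <- stack$frame_interval
  nf <- n_frames(stack)
  min_area_px <- min_area_um2 / px^2

  smooth_kernel <- {
    r <- 3L
    g <- exp(-(-r:r)^2 / 2)          # sigma = 1 px: damps centroid jitter
    k <- outer(g, g)
    k / sum(k)
  }
  centroids <- vector("list", nf)
  for (f in seq_len(nf)) {
    img <- get_frame(stack, f, 1L)
    rng <- range(img)
    if (diff(rng) == 0) next
    inv <- (rng[2L] - img) / diff(rng)          # dark cells -> bright, [0,1]
    inv <- fft_convolve_same(inv, smooth_kernel)
    thr <- EBImage::otsu(EBImage::Image(pmin(pmax(inv, 0), 1)),
                         range = c(0, 1))
    mask <- inv > thr
    if (!any(mask)) next
    lab <- EBImage::bwlabel(EBImage::Image(mask))
    lab <- as.integer(lab)
    keep <- which(tabulate(lab) >= min_area_px)
    if (!length(keep)) next
    idx <- which(lab %in% keep)
    ri <- (idx - 1L) %% nrow(img)               # 0-based row
    ci <- (idx - 1L) %/% nrow(img)              # 0-based col
    wgt <- pmax(inv[idx] - thr, 0)   # above-threshold excess: suppresses
                                     # centroid jitter from boundary noise
    li <- lab[idx]
    sw <- tapply(wgt, li, sum)
    cx <- tapply(wgt * ci, li, sum) / sw
    cy <- tapply(wgt * ri, li, sum) / sw
    centroids[[f]] <- data.frame(x_um = as.numeric(cx) * px,
                                 y_um = as.numeric(cy) * px)
  }

  # greedy nearest-neighbour linking with gap tolerance
  tracks <- list()     # each: list(t, x, y, last_frame, open)
  for (f in seq_len(nf)) {
    det <- centroids[[f]]
    open <- which(vapply(tracks, function(tr) tr$open, logical(1)))
    # close stale tracks
    for (i in open) if (f - tracks[[i]]$last_frame > max_gap + 1L)
      tracks[[i]]$open <- FALSE
    open <- which(vapply(tracks, function(tr) tr$open, logical(1)))
    if (is.null(det) || nrow(det) == 0L) next
    used_det <- rep(FALSE, nrow(det))
    if (length(open)) {
      lx <- vapply(tracks[open], function(tr) tr$x[length(tr$x)], numeric(1))
      ly <- vapply(tracks[open], function(tr) tr$y[length(tr$y)], numeric(1))
      D <- sqrt(outer(lx, det$x_um, "-")^2 + outer(ly, det$y_um, "-")^2)
      repeat {
        if (all(is.infinite(D)) || min(D) > search_radius_um) break
        w <- arrayInd(which.min(D), dim(D))
        ti <- open[w[1L]]; di <- w[2L]
        tracks[[ti]]$t <- c(tracks[[ti]]$t, (f - 1L) * dt)
        tracks[[ti]]$x <- c(tracks[[ti]]$x, det$x_um[di])
        tracks[[ti]]$y <- c(tracks[[ti]]$y, det$y_um[di])
        tracks[[ti]]$last_frame <- f
        used_det[di] <- TRUE
        D[w[1L], ] <- Inf
        D[, w[2L]] <- Inf
      }
    }
    for (di in which(!used_det)) {
      tracks[[length(tracks) + 1L]] <- list(
        t = (f - 1L) * dt, x = det$x_um[di], y = det$y_um[di],
        last_frame = f, open = TRUE)
    }
  }

  out <- list()
  cell_id <- 0L
  for (tr in tracks) {
    if (length(tr$t) < min_points) next
    cell_id <- cell_id + 1L
    out[[cell_id]] <- motility_trace(tr$t, tr$x, tr$y, cell = cell_id)
  }
  out
}

#' Filter motility traces by duration and distance moved
#'
#' Keeps only traces strictly longer than `min_duration` seconds in which
#' the cell moved strictly more than `min_distance` micrometres
#' (cumulative path length; about one cell length by default).
#'
#' @param traces list of [motility_trace()] objects.
#' @param min_duration seconds.
#' @param min_distance micrometres.
#' @return the filtered list.
#' @export
filter_traces <- function(traces, min_duration = 30, min_distance = 50) {
  keep <- vapply(traces, function(tr) {
    stopifnot(inherits(tr, "motility_trace"))
    tr$duration_s > min_duration && tr$path_um > min_distance
  }, logical(1))
  traces[keep]
}

#' Summarise the distribution of per-cell mean velocities
#'
#' Median and interquartile range (linear-interpolation percentile rule,
#' i.e. R quantile type 7) of the mean velocities of a set of traces, as
#' shown in the population motility boxplots.
#'
#' @param traces non-empty list of [motility_trace()] objects.
#' @return data frame with one row: `n`, `median_um_s`, `q25_um_s`,
#'   `q75_um_s`, `iqr_um_s`, `mean_um_s`, `sd_um_s`.
#' @export
summarize_velocities <- function(traces) {
  if (length(traces) == 0L) stop("no traces to summarise")
  v <- vapply(traces, function(tr) tr$mean_v_um_s, numeric(1))
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(n = length(v), median_um_s = q[2L], q25_um_s = q[1L],
             q75_um_s = q[3L], iqr_um_s = q[3L] - q[1L],
             mean_um_s = mean(v), sd_um_s = stats::sd(v))
}
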