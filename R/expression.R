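#' Otsu threshold by exhaustive between-class-variance maximization
#'
#' Computes the Otsu threshold of a set of intensities exactly: every
#' midpoint between consecutive distinct values is a candidate threshold,
#' and the one maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` is returned (ties broken towards the lowest
#' threshold). Working on the exact value set rather than a binned histogram
#' keeps the result exact for float images.
#'
#' @param x Numeric vector (or matrix) of intensities.
#' @return The threshold; pixels strictly above it form the foreground mask.
#' @export
otsu_threshold <- function(x) {
  v <- sort(as.numeric(x))
  u <- unique(v)
  if (length(u) < 2) abort("no contrast for segmentation")
  n <- length(v)
  # cumulative counts and sums at each distinct value
  cnt <- cumsum(tabulate(match(v, u), nbins = length(u)))
  csum <- cumsum(v)[cnt]
  k <- seq_len(length(u) - 1L)
  w0 <- cnt[k] / n
  w1 <- 1 - w0
  mu0 <- csum[k] / cnt[k]
  mu1 <- (csum[length(u)] - csum[k]) / (n - cnt[k])
  score <- w0 * w1 * (mu0 - mu1)^2
  best <- which.max(score) # which.max returns the first (lowest) maximizer
  (u[best] + u[best + 1L]) / 2
}

#' Otsu-masked nuclear mean intensity
#'
#' Segments one nucleus inside a square region of interest (5 um x 5 um by
#' default) centred on its annotated position, using Otsu's method on the
#' ROI intensities, and returns the mean fluorescence over the mask. Nucleus
#' size and shape change over development, which the per-timepoint mask
#' absorbs.
#'
#' @param image Numeric matrix; pixel `image[i, j]` centred at
#'   `((j - 1) * pixel_size, (i - 1) * pixel_size)` micrometres.
#' @param centre_um Nucleus centre `c(x, y)` in micrometres (camera frame).
#' @param pixel_size Micrometres per pixel.
#' @param roi_size_um ROI side length in micrometres (default 5).
#' @return A `nuclear_roi` object: `mean_intensity`, `threshold`, `mask`
#'   (logical matrix), `roi` (intensity matrix), `centre_um`, and the pixel
#'   index ranges. Errors if the ROI leaves the image or has no contrast.
#' @export
nuclear_mean_intensity <- function(image, centre_um, pixel_size, roi_size_um = 5) {
  stopifnot(is.matrix(image), pixel_size > 0, roi_size_um > 0)
  centre_um <- drop(as_point_matrix(centre_um, "centre_um"))
  half_px <- roi_size_um / (2 * pixel_size)
  cx <- centre_um[1] / pixel_size # 0-based pixel coords
  cy <- centre_um[2] / pixel_size
  jr <- (round(cx - half_px):round(cx + half_px)) + 1L # 1-based columns
  ir <- (round(cy - half_px):round(cy + half_px)) + 1L
  if (min(ir) < 1 || min(jr) < 1 || max(ir) > nrow(image) || max(jr) > ncol(image)) {
    abort("nuclear ROI extends outside the image")
  }
  roi <- image[ir, jr, drop = FALSE]
  thr <- otsu_threshold(roi) # errors on degenerate (constant) ROI
  mask <- roi > thr
  structure(
    list(
      mean_intensity = mean(roi[mask]),
      threshold = thr,
      mask = mask,
      roi = roi,
      centre_um = centre_um,
      rows = range(ir), cols = range(jr)
    ),
    class = "nuclear_roi"
  )
}

#' @export
print.nuclear_roi <- function(x, ...) {
  cat(sprintf(
    "<nuclear_roi> %dx%d px, threshold %.3g, mask %d px, mean intensity %.3g\n",
    nrow(x$roi), ncol(x$roi), x$threshold, sum(x$mask), x$mean_intensity
  ))
  invisible(x)
}

#' Kymograph of expression along the A--P axis
#'
#' For each time point, the mean fluorescence intensity as a function of
#' A--P position, averaging over a dorsoventral window `|t| < dv_window`
#' (60 um by default) and binning positions as a percentage of body length
#' so that animals (or frames) of different lengths align.
#'
#' @param frames List of fluorescence image matrices, one per time point.
#' @param axes List of `body_axis` objects, one per frame.
#' @param pixel_size Micrometres per pixel.
#' @param times_h Acquisition times (hours), one per frame.
#' @param dv_window D--V averaging half-window in micrometres (default 60).
#' @param n_bins Number of A--P position bins over 0--100% body length
#'   (default 100, i.e. 1% bins).
#' @return A `kymograph` object: `intensity` (time x position matrix),
#'   `times_h`, `position_pct` (bin centres), `dv_window`, and per-frame
#'   body lengths.
#' @export
build_kymograph <- function(frames, axes, pixel_size, times_h = seq_along(frames),
                            dv_window = 60, n_bins = 100L) {
  if (length(frames) != length(axes) || length(frames) != length(times_h)) {
    abort("`frames`, `axes` and `times_h` must have the same length")
  }
  if (dv_window <= 0) abort("empty D-V window")
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  rows <- lapply(seq_along(frames), function(i) {
    st <- straighten_image(frames[[i]], axes[[i]], half_width = dv_window,
      pixel_size = pixel_size)
    s_frac <- straightened_s_axis(st) / axes[[i]]$length
    keep <- abs(straightened_t_axis(st)) < dv_window
    bin <- pmin(findInterval(s_frac, breaks, rightmost.closed = TRUE), n_bins)
    col_mean <- colMeans(st[keep, , drop = FALSE])
    vapply(seq_len(n_bins), function(b) {
      if (any(bin == b)) mean(col_mean[bin == b]) else NA_real_
    }, 0)
  })
  structure(
    list(
      intensity = do.call(rbind, rows),
      times_h = times_h,
      position_pct = (breaks[-1] + breaks[-length(breaks)]) / 2 * 100,
      dv_window = dv_window,
      body_length_um = vapply(axes, body_length, 0)
    ),
    class = "kymograph"
  )
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf(
    "<kymograph> %d time points x %d position bins, |t| < %g um window\n",
    nrow(x$intensity), ncol(x$intensity), x$dv_window
  ))
  invisible(x)
}

#' Tidy a kymograph into long form
#'
#' @param x A `kymograph`.
#' @param ... Unused.
#' @return A tibble with columns `time_h`, `position_pct`, `intensity`.
#' @export
tidy.kymograph <- function(x, ...) {
  tibble(
    time_h = rep(x$times_h, times = ncol(x$intensity)),
    position_pct = rep(x$position_pct, each = nrow(x$intensity)),
    intensity = as.vector(x$intensity)
  )
}

#' Plot a kymograph
#'
#' @param object A `kymograph`.
#' @param ... Unused.
#' @return A ggplot raster of intensity over (A--P position, time).
#' @export
autoplot.kymograph <- function(object, ...) {
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(x = .data$position_pct, y = .data$time_h, fill = .data$intensity)
  ) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = "A–P position (% body length)", y = "time (h)",
      fill = "intensity"
    )
}

#' Regional expression trace from a kymograph
#'
#' Integrates fluorescence over a region of the body (5% of body length by
#' default) centred at a chosen fractional position (25, 50 or 75% in the
#' standard analysis), per time point.
#'
#' @param kymo A `kymograph`.
#' @param centre_pct Region centre, percent of body length.
#' @param width_pct Region width, percent of body length (default 5; must be
#'   > 0 and the region must lie within 0--100%).
#' @return An expression-trace tibble: `time_h`, `intensity`, `region`.
#' @export
regional_trace <- function(kymo, centre_pct, width_pct = 5) {
  stopifnot(inherits(kymo, "kymograph"))
  if (width_pct <= 0) abort("`width_pct` must be > 0")
  lo <- centre_pct - width_pct / 2
  hi <- centre_pct + width_pct / 2
  if (lo < 0 || hi > 100) abort("region extends outside the body (0-100% body length)")
  cols <- which(kymo$position_pct >= lo & kymo$position_pct <= hi)
  if (length(cols) == 0) abort("region narrower than one position bin")
  tibble(
    time_h = kymo$times_h,
    intensity = rowSums(kymo$intensity[, cols, drop = FALSE], na.rm = TRUE),
    region = sprintf("%g%%", centre_pct)
  )
}

#' Whole-animal integrated fluorescence
#'
#' Sum of fluorescence over the body band (`|t| < half_width`), with the
#' frame background -- the median intensity of pixels outside the band --
#' subtracted, making the measure invariant to a constant background offset.
#'
#' @param frame Fluorescence image matrix.
#' @param axis The frame's `body_axis`.
#' @param pixel_size Micrometres per pixel.
#' @param half_width Body band half-width in micrometres (default 60).
#' @return Background-subtracted integrated intensity (scalar).
#' @export
total_intensity <- function(frame, axis, pixel_size, half_width = 60) {
  mask <- body_mask(dim(frame), axis, half_width, pixel_size)
  if (!any(mask)) return(0)
  bg <- if (all(mask)) 0 else median(frame[!mask])
  sum(frame[mask]) - bg * sum(mask)
}

# Gaussian smoothing of a (possibly non-uniform) time series: kernel
# truncated at +/- 3 sigma and renormalized, so edges keep unit weight
gaussian_smooth <- function(time_h, x, sigma_h) {
  vapply(seq_along(time_h), function(i) {
    dt <- time_h - time_h[i]
    w <- exp(-dt^2 / (2 * sigma_h^2))
    w[abs(dt) > 3 * sigma_h] <- 0
    sum(w * x) / sum(w)
  }, 0)
}

#' Per-stage expression peak times
#'
#' Molting-cycle reporters pulse once per larval stage. The trace is
#' smoothed with a Gaussian filter (width `sigma = filter_width_h`,
#' truncated at three sigma with renormalized edge kernels) and, within each
#' larval stage `[start, end)`, the time of the maximum of the smoothed
#' series is reported. A peak falling on the first or last sample covered by
#' the stage is flagged as a boundary maximum (the pulse may be truncated).
#'
#' @param trace A data frame with columns `time_h`, `intensity`.
#' @param tl The animal's [developmental_timeline()].
#' @param filter_width_h Gaussian filter width sigma in hours (default 1).
#' @return A tibble with one row per covered stage: `stage`, `peak_time_h`,
#'   `peak_intensity`, `boundary` (logical). Stages with no samples are
#'   omitted.
#' @export
detect_stage_peak <- function(trace, tl, filter_width_h = 1) {
  stopifnot(inherits(tl, "developmental_timeline"))
  if (!all(c("time_h", "intensity") %in% names(trace))) {
    abort("trace needs `time_h` and `intensity` columns")
  }
  ord <- order(trace$time_h)
  time_h <- trace$time_h[ord]
  smoothed <- gaussian_smooth(time_h, trace$intensity[ord], filter_width_h)
  purrr::map_dfr(larval_stages, function(stg) {
    iv <- stage_interval(tl, stg)
    in_stage <- which(time_h >= iv[1] & time_h < iv[2])
    if (length(in_stage) == 0) {
      return(tibble(
        stage = factor(character(), levels = larval_stages),
        peak_time_h = numeric(), peak_intensity = numeric(), boundary = logical()
      ))
    }
    k <- in_stage[which.max(smoothed[in_stage])]
    tibble(
      stage = factor(stg, levels = larval_stages),
      peak_time_h = time_h[k],
      peak_intensity = smoothed[k],
      boundary = k == in_stage[1] || k == in_stage[length(in_stage)]
    )
  })
}

#' Peak timing relative to ecdysis
#'
#' Expresses per-stage expression peaks as hours before the ecdysis ending
#' the same stage (positive values: the peak precedes the molt). Molting
#' cycle genes typically peak about an hour before ecdysis, much more
#' reproducibly than in absolute time.
#'
#' @param peaks Output of [detect_stage_peak()] (columns `stage`,
#'   `peak_time_h`).
#' @param tl The animal's [developmental_timeline()].
#' @return `peaks` with a `lead_h` column appended: ecdysis time minus peak
#'   time.
#' @export
peak_relative_to_event <- function(peaks, tl) {
  stopifnot(inherits(tl, "developmental_timeline"))
  idx <- match(as.character(peaks$stage), larval_stages)
  dplyr::mutate(as_tibble(peaks), lead_h = tl$ecdysis_h[idx] - .data$peak_time_h)
}

#' Correlation between two expression traces
#'
#' Pearson correlation of intensities over shared time points. With cohort
#' input (an `animal` column) pairs are matched within animal and pooled
#' before computing a single R, as when correlating expression between seam
#' cells across a cohort.
#'
#' @param a,b Expression-trace data frames with columns `time_h`,
#'   `intensity` and optionally `animal`.
#' @return Pearson R. At least 3 shared time points are required; if either
#'   trace has zero variance the correlation is undefined and `NA` is
#'   returned with a warning.
#' @export
trace_correlation <- function(a, b) {
  keys <- intersect(intersect(names(a), names(b)), c("animal", "time_h"))
  if (!"time_h" %in% keys) abort("traces need a `time_h` column")
  paired <- dplyr::inner_join(
    dplyr::select(as_tibble(a), dplyr::all_of(keys), ia = "intensity"),
    dplyr::select(as_tibble(b), dplyr::all_of(keys), ib = "intensity"),
    by = keys
  )
  if (nrow(paired) < 3) abort("need at least 3 overlapping time points")
  if (sd(paired$ia) == 0 || sd(paired$ib) == 0) {
    warn("zero-variance trace: correlation undefined")
    return(NA_real_)
  }
  cor(paired$ia, paired$ib)
}

#' Plot expression traces with detected peaks
#'
#' @param trace A trace tibble (`time_h`, `intensity`, optional `region`).
#' @param peaks Optional output of [detect_stage_peak()] to mark.
#' @param tl Optional [developmental_timeline()]; ecdyses drawn as dashed
#'   lines.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, peaks = NULL, tl = NULL) {
  trace <- as_tibble(trace)
  if (!"region" %in% names(trace)) trace$region <- "trace"
  p <- ggplot2::ggplot(trace, ggplot2::aes(
    x = .data$time_h, y = .data$intensity, colour = .data$region
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "intensity (a.u.)", colour = NULL)
  if (!is.null(tl)) {
    p <- p + ggplot2::geom_vline(
      xintercept = tl$ecdysis_h, linetype = "dashed", colour = "grey50"
    )
  }
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_point(
      data = peaks,
      ggplot2::aes(x = .data$peak_time_h, y = .data$peak_intensity),
      inherit.aes = FALSE, colour = "red", shape = 4, size = 3
    )
  }
  p
}
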