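#' Validate a cell trajectory
#'
#' A trajectory is a tibble of body-coordinate samples for one cell: time in
#' hours and position (`s_um` along the A--P axis, relative to the
#' stage-appropriate origin, and signed `t_um` along the D--V axis, negative
#' ventral). Sampling is nominally every 20 min; gaps are allowed but times
#' must be strictly increasing.
#'
#' @param traj A data frame with columns `time_h`, `s_um` and/or `t_um`.
#' @return The trajectory as a tibble, ordered and validated.
#' @export
as_trajectory <- function(traj) {
  if (!"time_h" %in% names(traj)) abort("trajectory needs a `time_h` column")
  if (!any(c("s_um", "t_um") %in% names(traj))) {
    abort("trajectory needs an `s_um` and/or `t_um` column")
  }
  if (nrow(traj) == 0) abort("empty trajectory")
  out <- dplyr::arrange(as_tibble(traj), .data$time_h)
  if (any(diff(out$time_h) <= 0)) abort("trajectory times must be strictly increasing")
  out
}

#' Correct A--P positions for inter-slice body movement
#'
#' The animal can move along its A--P axis between the acquisition of the
#' Z-slices containing a tracked cell and a reference slice. The displacement
#' `Delta s` is measured on anatomical markers (pharyngeal bulbs, vulva,
#' anus) visible in both slices, averaged over markers, and subtracted from
#' the raw cell position.
#'
#' @param raw_s_um Raw A--P position(s) of the cell, micrometres.
#' @param marker_shift_um Per-marker A--P displacements between the two
#'   slices (micrometres), i.e. position in the cell's slice minus position
#'   in the reference slice.
#' @return `raw_s_um - mean(marker_shift_um)`. With no usable marker the
#'   correction is skipped with a warning and `raw_s_um` returned unchanged.
#' @examples
#' correct_ap_offset(120, marker_shift_um = c(4, 6)) # 115
#' @export
correct_ap_offset <- function(raw_s_um, marker_shift_um) {
  marker_shift_um <- marker_shift_um[is.finite(marker_shift_um)]
  if (length(marker_shift_um) == 0) {
    warn("no shared anatomical marker between slices; A-P offset correction skipped")
    return(raw_s_um)
  }
  raw_s_um - mean(marker_shift_um)
}

#' Stage-appropriate A--P origin
#'
#' The origin `s = 0` for migration trajectories is the midbody in L1--L3 --
#' the point exactly between the posterior pharyngeal bulb and the anus --
#' and the vulval invagination from the L3--L4 transition onwards. In most
#' animals the two definitions coincide.
#'
#' @param markers A data frame with columns `marker` and `s_um` containing
#'   (as available) `"posterior_bulb"`, `"anus"`, `"vulva"` positions along
#'   the axis in micrometres.
#' @param stage Larval stage ("L1".."L4", or "adult").
#' @param use Force a definition: `"auto"` (midbody for L1--L3, vulva for
#'   L4+), `"midbody"`, or `"vulva"`.
#' @return Origin position (micrometres along the axis).
#' @export
reference_origin <- function(markers, stage, use = c("auto", "midbody", "vulva")) {
  use <- match.arg(use)
  stage <- match.arg(stage, c(larval_stages, "adult"))
  if (use == "auto") {
    use <- if (stage %in% c("L1", "L2", "L3")) "midbody" else "vulva"
  }
  get_marker <- function(name) {
    v <- markers$s_um[markers$marker == name]
    if (length(v) == 0 || !is.finite(v[1])) {
      abort(sprintf("missing anatomical marker: %s", name))
    }
    v[1]
  }
  if (use == "midbody") {
    (get_marker("posterior_bulb") + get_marker("anus")) / 2
  } else {
    get_marker("vulva")
  }
}

# centred moving average over samples within +/- window/2, truncated at the
# series ends; uniform weights over in-window samples
sliding_average <- function(time_h, x, window_h) {
  half <- window_h / 2 + 1e-12
  vapply(seq_along(time_h), function(i) {
    mean(x[abs(time_h - time_h[i]) <= half], na.rm = TRUE)
  }, 0)
}

#' Smooth a trajectory with a sliding average
#'
#' Applies a centred 1 h (by default) sliding average to the `s_um` and
#' `t_um` series of a trajectory, the preprocessing step before velocity
#' estimation. The window is truncated at the trajectory ends; samples in
#' the window are weighted uniformly.
#'
#' @param traj A trajectory (see [as_trajectory()]).
#' @param window_h Window size in hours (> 0); default 1 h.
#' @return The trajectory with `s_um`/`t_um` replaced by their smoothed
#'   values.
#' @export
smooth_trajectory <- function(traj, window_h = 1) {
  if (!is.numeric(window_h) || window_h <= 0) abort("`window_h` must be > 0")
  traj <- as_trajectory(traj)
  for (col in intersect(c("s_um", "t_um"), names(traj))) {
    traj[[col]] <- sliding_average(traj$time_h, traj[[col]], window_h)
  }
  traj
}

# central finite differences on the actual (possibly non-uniform) time grid,
# one-sided at the ends
finite_diff <- function(time_h, x) {
  n <- length(x)
  if (n < 2) abort("need at least 2 samples to differentiate")
  v <- numeric(n)
  v[1] <- (x[2] - x[1]) / (time_h[2] - time_h[1])
  v[n] <- (x[n] - x[n - 1]) / (time_h[n] - time_h[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    v[i] <- (x[i + 1] - x[i - 1]) / (time_h[i + 1] - time_h[i - 1])
  }
  v
}

#' Migration velocities from a (smoothed) trajectory
#'
#' Time derivatives of the `s` and `t` series by central finite differences
#' on the actual timestamps (one-sided at the ends). The A--P velocity uses
#' the outward-positive convention: `v_ap = sign(s) * ds/dt`, so both the
#' anterior and the posterior distal tip cell read positive while moving
#' away from the origin and negative while moving back. The D--V velocity is
#' `dt/dt`, positive when moving dorsally.
#'
#' @param traj A trajectory, normally smoothed first with
#'   [smooth_trajectory()].
#' @param outward_positive If `FALSE`, return the raw derivative `ds/dt`
#'   instead of the outward-signed A--P velocity.
#' @return The trajectory with velocity columns appended (`v_ap_um_h` and/or
#'   `v_dv_um_h`, micrometres per hour).
#' @export
trajectory_velocity <- function(traj, outward_positive = TRUE) {
  traj <- as_trajectory(traj)
  if (nrow(traj) < 2) abort("need at least 2 samples to estimate velocity")
  if ("s_um" %in% names(traj)) {
    dsdt <- finite_diff(traj$time_h, traj$s_um)
    traj$v_ap_um_h <- if (outward_positive) {
      ifelse(traj$s_um >= 0, 1, -1) * dsdt
    } else {
      dsdt
    }
  }
  if ("t_um" %in% names(traj)) {
    traj$v_dv_um_h <- finite_diff(traj$time_h, traj$t_um)
  }
  traj
}

#' Re-time a series relative to a developmental event
#'
#' Shifts the time axis of a per-animal series so that a chosen timeline
#' event (hatch or one of the four ecdyses) is at time zero. Aligning on the
#' animal's own L3 ecdysis, for example, lets trajectories be averaged
#' across animals despite animal-to-animal variability in absolute molt
#' times.
#'
#' @param df A data frame with a `time_h` column.
#' @param tl The animal's [developmental_timeline()].
#' @param event One of `"hatch"`, `"L1_ecdysis"` .. `"L4_ecdysis"`.
#' @return `df` with a `time_rel_h` column appended (`time_h` minus the
#'   event time).
#' @export
align_to_event <- function(df, tl, event = "L3_ecdysis") {
  stopifnot(inherits(tl, "developmental_timeline"))
  event <- match.arg(event, c("hatch", paste0(larval_stages, "_ecdysis")))
  t0 <- if (event == "hatch") tl$hatch_h else tl$ecdysis_h[match(event, paste0(larval_stages, "_ecdysis"))]
  dplyr::mutate(as_tibble(df), time_rel_h = .data$time_h - t0)
}

#' Average event-aligned series across animals
#'
#' Bins event-aligned samples (from [align_to_event()]) and returns the
#' per-bin mean, standard error of the mean and sample count, for
#' cross-animal averages such as mean migration velocity versus time after
#' the L3 ecdysis.
#'
#' @param df A data frame with columns `time_rel_h` and the value column.
#' @param value Name of the value column (string).
#' @param bin_width Bin width in hours (default 20 min).
#' @return A tibble with `time_rel_h` (bin centre), `mean`, `sem`, `n`.
#' @export
average_aligned <- function(df, value, bin_width = 1 / 3) {
  if (!value %in% names(df)) abort(sprintf("no column `%s`", value))
  bins <- round(df$time_rel_h / bin_width)
  out <- dplyr::summarise(
    dplyr::group_by(tibble(bin = bins, v = df[[value]]), .data$bin),
    mean = mean(.data$v, na.rm = TRUE),
    sem = sd(.data$v, na.rm = TRUE) / sqrt(sum(is.finite(.data$v))),
    n = sum(is.finite(.data$v)),
    .groups = "drop"
  )
  dplyr::select(
    dplyr::mutate(out, time_rel_h = .data$bin * bin_width),
    "time_rel_h", "mean", "sem", "n"
  )
}

#' Detect the ventral-to-dorsal midline crossing
#'
#' First time at which the (smoothed) D--V series changes sign from negative
#' (ventral) to positive (dorsal), linearly interpolated between the two
#' bracketing samples. During its dorsal turn a distal tip cell crosses the
#' body midline once; the anterior DTC typically crosses first.
#'
#' @param traj A trajectory with a `t_um` column.
#' @param smooth_window_h Sliding-average window applied to `t_um` before
#'   crossing detection; `NULL` to skip smoothing.
#' @return Crossing time in hours, or `NA_real_` if `t` never crosses from
#'   negative to positive.
#' @export
detect_midline_crossing <- function(traj, smooth_window_h = 1) {
  traj <- as_trajectory(traj)
  if (!"t_um" %in% names(traj)) abort("trajectory needs a `t_um` column")
  t_series <- if (is.null(smooth_window_h)) {
    traj$t_um
  } else {
    sliding_average(traj$time_h, traj$t_um, smooth_window_h)
  }
  n <- length(t_series)
  if (n < 2) return(NA_real_)
  for (i in seq_len(n - 1)) {
    if (t_series[i] < 0 && t_series[i + 1] >= 0) {
      # linear interpolation of the zero crossing
      frac <- -t_series[i] / (t_series[i + 1] - t_series[i])
      return(traj$time_h[i] + frac * (traj$time_h[i + 1] - traj$time_h[i]))
    }
  }
  NA_real_
}

#' Plot a migration trajectory
#'
#' A--P and D--V position versus time for one or more cells.
#'
#' @param traj A trajectory tibble, optionally with a `cell` column.
#' @return A ggplot object (faceted s and t panels).
#' @export
plot_trajectory <- function(traj) {
  traj <- as_tibble(traj)
  if (!"cell" %in% names(traj)) traj$cell <- "cell"
  long <- tidyr::pivot_longer(traj,
    cols = dplyr::any_of(c("s_um", "t_um")),
    names_to = "axis", values_to = "position_um"
  )
  long$axis <- dplyr::recode(long$axis, s_um = "A–P (s)", t_um = "D–V (t)")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$time_h, y = .data$position_um, colour = .data$cell
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(~axis, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "position (µm)", colour = NULL)
}
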