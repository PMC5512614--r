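#' Configuration of the synthetic worm-movie generator
#'
#' Builds the parameter set for [generate_movie()] and [generate_cohort()].
#' Defaults mirror the biology of post-embryonic *C. elegans* development as
#' quantified in long-term microchamber recordings: mean larval stage
#' durations of 11.1, 7.3, 7.1 and 10.2 h (L1--L4) with sub-hour
#' animal-to-animal jitter; seam-cell divisions whose relative timing is
#' centre-early/ends-late (V3 early by 0.4 h, T late by 0.5 h, V5 first);
#' distal tip cells that migrate outward ventrally, cross to the dorsal side
#' over about 3 h starting about 3 h before the L3 ecdysis, and return
#' inward; and a molting-cycle reporter pulsing once per stage, peaking
#' 1.1 h before each ecdysis. All stochastic draws are fixed by `seed`.
#'
#' @param seed Integer seed fixing every random draw.
#' @param ... Overrides for any default parameter (see the source for the
#'   full list: pixel size, image size, body geometry, stage timing, seam
#'   roster and offsets, DTC path, expression pulse and noise model).
#' @return A `worm_config` list.
#' @export
worm_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # imaging geometry
    pixel_size_um = 1,
    image_size_px = c(160L, 300L), # rows, cols
    body_half_width_um = 12,
    frame_interval_h = 1 / 3,
    # developmental timing
    hatch_time_h = 1,
    stage_duration_mean_h = c(11.1, 7.3, 7.1, 10.2),
    stage_duration_sd_h = c(0.2, 0.2, 0.3, 0.4),
    # body length growth (um/h per stage) and midline shape
    length_start_um = 140,
    growth_rate_um_h = c(2, 2.5, 3, 3.5),
    midline_amplitude_um = 22,
    midline_amplitude_jitter_um = 3,
    midline_wavelength_um = 170,
    rigid_jitter_um = 4,
    n_centerline_points = 12L,
    # seam cell roster: A-P anchor as fraction of body length
    seam_anchor_frac = c(
      H1 = 0.12, H2 = 0.18, V1 = 0.28, V2 = 0.38, V3 = 0.48,
      V4 = 0.58, V5 = 0.68, V6 = 0.78, T = 0.90
    ),
    nucleus_t_um = 6,
    sibling_spacing_um = 5,
    # division timing: fraction of the stage, per-round, plus per-lineage
    # offsets (h) and cell-level noise (h)
    division_frac_asym = 0.55,
    division_frac_l2 = c(0.30, 0.65),
    lineage_offset_h = c(
      H1 = 0.3, H2 = 0.2, V1 = 0.1, V2 = -0.2, V3 = -0.4,
      V4 = -0.2, V5 = -0.6, V6 = 0.2, T = 0.5
    ),
    division_time_sd_h = 0.3,
    # anatomical marker anchors (fraction of body length)
    marker_frac = c(posterior_bulb = 0.17, anus = 0.95, vulva = 0.56),
    # distal tip cells
    dtc_outward_rate_um_h = 5.5,
    dtc_inward_rate_um_h = 7,
    dtc_turn_lead_h = 3, # turn onset before L3 ecdysis
    dtc_cross_duration_h = 3, # ventral-to-dorsal crossing time
    dtc_anterior_lead_h = 0.4, # anterior DTC turns this much earlier
    dtc_ventral_t_um = -8,
    dtc_dorsal_t_um = 8,
    dtc_slice_shift_sd_um = 2, # planted inter-Z-slice A-P shift
    # oscillatory reporter expression
    expression_baseline = 8,
    expression_pulse_amplitude = c(60, 80, 100, 120),
    expression_pulse_sd_h = 0.8,
    expression_peak_lead_h = 1.1, # peak precedes ecdysis by this much
    expression_noise_sd = 0,
    # rendering
    background_level = 10,
    read_noise_sd = 2,
    spot_sigma_um = 1.5,
    dtc_spot_amplitude = 150,
    trans_base = 200,
    trans_body = 80
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(sprintf("unknown worm_config parameter(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  stopifnot(
    cfg$pixel_size_um > 0, cfg$body_half_width_um > 0,
    all(cfg$stage_duration_mean_h > 0), all(cfg$stage_duration_sd_h >= 0),
    all(cfg$growth_rate_um_h > 0), cfg$frame_interval_h > 0
  )
  if (abs(cfg$nucleus_t_um) > cfg$body_half_width_um ||
    max(abs(c(cfg$dtc_ventral_t_um, cfg$dtc_dorsal_t_um))) > cfg$body_half_width_um) {
    abort("nuclei must lie inside the body: |t| must not exceed body_half_width_um")
  }
  structure(cfg, class = "worm_config")
}

#' Draw a developmental timeline from a configuration
#'
#' Hatch time plus four stage durations drawn from the configured means and
#' standard deviations (draws come from the current RNG state).
#'
#' @param cfg A [worm_config()].
#' @return A [developmental_timeline()].
#' @export
generate_timeline <- function(cfg) {
  d <- pmax(cfg$stage_duration_mean_h +
    rnorm(4, 0, cfg$stage_duration_sd_h), 1)
  developmental_timeline(cfg$hatch_time_h, cfg$hatch_time_h + cumsum(d))
}

# nominal body length at a time: piecewise-linear growth per stage
nominal_length <- function(cfg, tl, time_h) {
  bounds <- c(tl$hatch_h, tl$ecdysis_h)
  elapsed <- vapply(seq_len(4), function(i) {
    pmin(pmax(time_h - bounds[i], 0), bounds[i + 1] - bounds[i])
  }, numeric(length(time_h)))
  if (is.null(dim(elapsed))) elapsed <- matrix(elapsed, nrow = 1)
  cfg$length_start_um + as.numeric(elapsed %*% cfg$growth_rate_um_h)
}

# One frame's midline: a sine-shaped curve of total arc length L, centred in
# the image, with per-frame phase/amplitude/rigid jitter already drawn.
# Returns control points and the ventral-marker point used to fit the axis.
frame_midline <- function(cfg, L, amplitude, phase, offset) {
  lambda <- cfg$midline_wavelength_um
  xg <- seq(0, 4 * L, by = 0.25)
  yg <- amplitude * sin(2 * pi * xg / lambda + phase)
  arc <- c(0, cumsum(sqrt(diff(xg)^2 + diff(yg)^2)))
  x_of_s <- approxfun(arc, xg)
  s_ctrl <- seq(0, L, length.out = cfg$n_centerline_points)
  xs <- x_of_s(s_ctrl)
  ys <- amplitude * sin(2 * pi * xs / lambda + phase)
  # centre in the image plus rigid jitter
  ctr <- c(
    (cfg$image_size_px[2] - 1) * cfg$pixel_size_um / 2,
    (cfg$image_size_px[1] - 1) * cfg$pixel_size_um / 2
  )
  shift <- ctr - c(mean(range(xs)), mean(range(ys))) + offset
  cbind(xs + shift[1], ys + shift[2])
}

# wild-type seam division plan for one stage and lineage: list of rounds,
# each round a (class, stage fraction) pair. In L2, H1/V1-V4/V6 double with
# a symmetric division before the asymmetric round.
seam_division_plan <- function(cfg, stage, lineage) {
  sym_set <- c("H1", "V1", "V2", "V3", "V4", "V6")
  if (stage == "L2" && lineage %in% sym_set) {
    list(
      list(class = 1L, frac = cfg$division_frac_l2[1]),
      list(class = 2L, frac = cfg$division_frac_l2[2])
    )
  } else {
    list(list(class = 2L, frac = cfg$division_frac_asym))
  }
}

#' Generate a seam-cell lineage table
#'
#' Walks the stylized wild-type seam division program (asymmetric divisions
#' every stage; a symmetric doubling round in L2 for H1, V1--V4 and V6) and
#' emits one record per seam cell with its division class and time. With
#' positive error probabilities the walk emulates a lineage mutant:
#' asymmetric divisions convert to symmetric with probability `p_symmetric`
#' (the extra seam daughter then continues dividing, but only outside the
#' wild-type name space), and divisions fail (class 0) with probability
#' `p_nodivision`, ending that sublineage.
#'
#' Draws come from the current RNG state; callers seed via
#' [generate_cohort()] or `set.seed()`.
#'
#' @param cfg A [worm_config()].
#' @param tl The animal's [developmental_timeline()].
#' @param animal Animal identifier for the `animal` column.
#' @param p_symmetric,p_nodivision Error probabilities (0 for wild type).
#' @return A seam-cell record tibble (see [seam_cell_records()]).
#' @export
generate_lineage <- function(cfg, tl, animal = "wt", p_symmetric = 0, p_nodivision = 0) {
  bounds <- c(tl$hatch_h, tl$ecdysis_h)
  rec <- list()
  current <- unlist(lapply(c("L", "R"), function(sd) paste0(seam_lineages, sd)))
  for (si in seq_along(larval_stages)) {
    stage <- larval_stages[si]
    start <- bounds[si]
    dur <- bounds[si + 1] - bounds[si]
    info <- parse_seam_cell(current)
    next_cells <- character()
    for (lin in seam_lineages) {
      for (side in c("L", "R")) {
        cells <- current[info$lineage == lin & info$side == side]
        if (length(cells) == 0) next
        plan <- seam_division_plan(cfg, stage, lin)
        last_time <- rep(-Inf, length(cells))
        for (round in plan) {
          t_base <- start + round$frac * dur + cfg$lineage_offset_h[[lin]]
          daughters <- character()
          d_times <- numeric()
          for (ci in seq_along(cells)) {
            cls <- round$class
            if (p_nodivision > 0 && runif(1) < p_nodivision) {
              cls <- 0L
            } else if (cls == 2L && p_symmetric > 0 && runif(1) < p_symmetric) {
              cls <- 1L
            }
            tm <- if (cls == 0L) NA_real_ else {
              max(t_base + rnorm(1, 0, cfg$division_time_sd_h), last_time[ci] + 0.1)
            }
            rec[[length(rec) + 1L]] <- list(
              animal = animal, cell = cells[ci], stage = stage,
              division_class = cls, division_time_h = tm
            )
            if (cls > 0L) {
              base <- if (grepl("\\.", cells[ci])) cells[ci] else paste0(cells[ci], ".")
              ds <- if (cls == 1L) paste0(base, c("a", "p")) else paste0(base, "p")
              daughters <- c(daughters, ds)
              d_times <- c(d_times, rep(tm, length(ds)))
            }
          }
          cells <- daughters
          last_time <- d_times
          if (length(cells) == 0) break
        }
        next_cells <- c(next_cells, cells)
      }
    }
    current <- next_cells
    if (length(current) == 0) break
  }
  seam_cell_records(dplyr::bind_rows(lapply(rec, as_tibble)))
}

#' Ground-truth distal-tip-cell path
#'
#' The noiseless DTC path in origin-relative body coordinates: born at the
#' L1 ecdysis at the origin, outward on the ventral side, A--P movement
#' frozen during the ventral-to-dorsal crossing (starting
#' `dtc_turn_lead_h` before the L3 ecdysis, lasting
#' `dtc_cross_duration_h`), inward on the dorsal side from the L3 ecdysis.
#'
#' @param cfg A [worm_config()].
#' @param tl The animal's [developmental_timeline()].
#' @param time_h Times (h) at which to evaluate the path.
#' @param cell `"anterior"` or `"posterior"`.
#' @return A tibble `time_h`, `s_rel_um`, `t_um` (`NA` before birth).
#' @export
dtc_path <- function(cfg, tl, time_h, cell = c("anterior", "posterior")) {
  cell <- match.arg(cell)
  sgn <- if (cell == "anterior") -1 else 1
  birth <- tl$ecdysis_h[1]
  onset <- tl$ecdysis_h[3] - cfg$dtc_turn_lead_h -
    if (cell == "anterior") cfg$dtc_anterior_lead_h else 0
  cross_end <- onset + cfg$dtc_cross_duration_h
  resume <- tl$ecdysis_h[3] # inward A-P movement resumes at L3 ecdysis
  out_max <- cfg$dtc_outward_rate_um_h * (onset - birth)
  s_rel <- t_dv <- rep(NA_real_, length(time_h))
  alive <- time_h >= birth
  tt <- time_h[alive]
  s_out <- pmin(cfg$dtc_outward_rate_um_h * (tt - birth), out_max)
  s_in <- pmax(out_max - cfg$dtc_inward_rate_um_h * pmax(tt - resume, 0), 0)
  s_rel[alive] <- sgn * ifelse(tt < resume, s_out, s_in)
  frac <- pmin(pmax((tt - onset) / cfg$dtc_cross_duration_h, 0), 1)
  t_dv[alive] <- cfg$dtc_ventral_t_um +
    frac * (cfg$dtc_dorsal_t_um - cfg$dtc_ventral_t_um)
  tibble(time_h = time_h, s_rel_um = s_rel, t_um = t_dv)
}

#' Ground-truth reporter expression signal
#'
#' Noiseless per-cell reporter intensity: a baseline plus one Gaussian
#' pulse per larval stage, each peaking `expression_peak_lead_h` before
#' that stage's ecdysis.
#'
#' @param cfg A [worm_config()].
#' @param tl The animal's [developmental_timeline()].
#' @param time_h Times (h) at which to evaluate the signal.
#' @return Numeric vector of intensities (arbitrary units).
#' @export
expression_signal <- function(cfg, tl, time_h) {
  v <- rep(cfg$expression_baseline, length(time_h))
  for (i in seq_len(4)) {
    peak <- tl$ecdysis_h[i] - cfg$expression_peak_lead_h
    v <- v + cfg$expression_pulse_amplitude[i] *
      exp(-(time_h - peak)^2 / (2 * cfg$expression_pulse_sd_h^2))
  }
  v
}

# add a Gaussian spot to an image (in place value-wise); px coords 0-based
add_spot <- function(img, x_um, y_um, amplitude, sigma_um, pixel_size) {
  sx <- x_um / pixel_size
  sy <- y_um / pixel_size
  sg <- sigma_um / pixel_size
  r <- ceiling(4 * sg)
  j_lo <- max(1, round(sx) + 1 - r); j_hi <- min(ncol(img), round(sx) + 1 + r)
  i_lo <- max(1, round(sy) + 1 - r); i_hi <- min(nrow(img), round(sy) + 1 + r)
  if (i_lo > i_hi || j_lo > j_hi) return(img)
  jj <- j_lo:j_hi
  ii <- i_lo:i_hi
  gx <- exp(-((jj - 1) - sx)^2 / (2 * sg^2))
  gy <- exp(-((ii - 1) - sy)^2 / (2 * sg^2))
  img[ii, jj] <- img[ii, jj] + amplitude * outer(gy, gx)
  img
}

# rasterize the body band (union of disks along the centre line)
render_body_band <- function(cfg, axis) {
  nr <- cfg$image_size_px[1]
  nc <- cfg$image_size_px[2]
  px <- cfg$pixel_size_um
  mask <- matrix(FALSE, nr, nc)
  hw_px <- cfg$body_half_width_um / px
  s_grid <- seq(0, axis$length, by = px / 2)
  q <- axis_curve(axis, s_grid) / px
  r <- ceiling(hw_px)
  for (k in seq_len(nrow(q))) {
    j_lo <- max(1, round(q[k, 1]) + 1 - r); j_hi <- min(nc, round(q[k, 1]) + 1 + r)
    i_lo <- max(1, round(q[k, 2]) + 1 - r); i_hi <- min(nr, round(q[k, 2]) + 1 + r)
    if (i_lo > i_hi || j_lo > j_hi) next
    jj <- j_lo:j_hi
    ii <- i_lo:i_hi
    d2 <- outer(((ii - 1) - q[k, 2])^2, ((jj - 1) - q[k, 1])^2, `+`)
    mask[ii, jj] <- mask[ii, jj] | d2 <= hw_px^2
  }
  mask
}

#' Generate a ground-truthed synthetic worm movie
#'
#' Renders a two-channel time-lapse of a bent, growing larva: a fluorescence
#' channel with Gaussian nuclear spots (seam cells of the side closest to
#' the objective, both distal tip cells) over a uniform background with read
#' noise, and a transmitted-light channel with the body as a dark band. The
#' animal's midline is a sine-shaped curve whose arc length follows the
#' stage-dependent growth law; bending phase, amplitude and rigid position
#' re-draw every frame, emulating movement between acquisitions. Everything
#' rendered is also exported as ground truth (per-frame axis, per-cell body
#' and camera coordinates, expression values, division and timeline events,
#' DTC turn parameters, planted inter-slice A--P shifts), together with an
#' annotation structure consumable by [load_annotations()] /
#' [save_annotations()] unchanged.
#'
#' @param cfg A [worm_config()]; `cfg$seed` fixes all draws (same seed, same
#'   movie, bit for bit).
#' @param t_range_h Optional `c(min, max)` restricting rendered frames to a
#'   time window (events and ground truth still cover the whole timeline).
#' @param channels Which channels to render: subset of
#'   `c("fluorescence", "transmitted")`.
#' @return A `worm_movie` list: `config`, `timeline`, `times_h`,
#'   `frames_fluor`, `frames_trans`, `truth` (axes, lengths, cells, dtc,
#'   divisions, markers, slice shifts, turn parameters) and `annotations`.
#' @export
generate_movie <- function(cfg, t_range_h = NULL,
                           channels = c("fluorescence", "transmitted")) {
  stopifnot(inherits(cfg, "worm_config"))
  channels <- match.arg(channels, several.ok = TRUE)
  with_seed(cfg$seed, {
    tl <- generate_timeline(cfg)
    lineage <- generate_lineage(cfg, tl, animal = "sim")
    times <- seq(tl$hatch_h, tl$ecdysis_h[4] + 0.5, by = cfg$frame_interval_h)
    if (!is.null(t_range_h)) {
      times <- times[times >= t_range_h[1] & times <= t_range_h[2]]
    }
    n_frames <- length(times)
    px <- cfg$pixel_size_um

    # per-frame stochastic pose
    phases <- runif(n_frames, 0, 2 * pi)
    amps <- cfg$midline_amplitude_um +
      rnorm(n_frames, 0, cfg$midline_amplitude_jitter_um)
    offsets <- matrix(rnorm(2 * n_frames, 0, cfg$rigid_jitter_um), ncol = 2)
    slice_shifts <- rnorm(n_frames, 0, cfg$dtc_slice_shift_sd_um)

    # seam cell occupancy: which cells exist at each time, and their s offset
    occupancy <- seam_occupancy(lineage, tl, cfg)

    axes <- vector("list", n_frames)
    frames_fluor <- if ("fluorescence" %in% channels) vector("list", n_frames) else NULL
    frames_trans <- if ("transmitted" %in% channels) vector("list", n_frames) else NULL
    lengths <- numeric(n_frames)
    cells_truth <- vector("list", n_frames)
    dtc_truth <- vector("list", n_frames)
    markers_truth <- vector("list", n_frames)
    ann_frames <- vector("list", n_frames)

    for (f in seq_len(n_frames)) {
      L <- nominal_length(cfg, tl, times[f])
      ctrl <- frame_midline(cfg, L, amps[f], phases[f], offsets[f, ])
      # provisional ventral reference below the mid control point, then the
      # definitive gonad/vulva marker at (0.56 L, t = -10)
      mid <- ctrl[ceiling(nrow(ctrl) / 2), ]
      axis0 <- fit_body_axis(ctrl, ventral_marker = mid + c(0, -15))
      vm <- unlist(from_body_coords(
        tibble(s_um = cfg$marker_frac[["vulva"]] * axis0$length, t_um = -10), axis0
      ), use.names = FALSE)
      axis <- fit_body_axis(ctrl, ventral_marker = vm)
      axes[[f]] <- axis
      lengths[f] <- axis$length

      # anatomical markers (s anchored as fractions of the fitted length)
      mk <- tibble(
        marker = names(cfg$marker_frac),
        s_um = as.numeric(cfg$marker_frac) * axis$length,
        t_um = c(0, 0, -8)[match(names(cfg$marker_frac), c("posterior_bulb", "anus", "vulva"))]
      )
      mk_xy <- from_body_coords(tibble(s_um = mk$s_um, t_um = mk$t_um), axis)
      markers_truth[[f]] <- dplyr::bind_cols(
        tibble(frame = f, time_h = times[f]), mk, mk_xy
      )

      # seam cells present now (rendered side: L, closest to the objective)
      occ <- occupancy[occupancy$t_birth_h <= times[f] &
        times[f] < occupancy$t_end_h, , drop = FALSE]
      expr_sig <- expression_signal(cfg, tl, times[f])
      if (nrow(occ) > 0) {
        s_um <- pmin(pmax(occ$anchor_frac * axis$length + occ$s_offset_um, 1), axis$length - 1)
        t_um <- ifelse(occ$side == "L", 1, -1) * cfg$nucleus_t_um
        noise <- if (cfg$expression_noise_sd > 0) {
          rnorm(nrow(occ), 0, cfg$expression_noise_sd)
        } else {
          rep(0, nrow(occ))
        }
        xy <- from_body_coords(tibble(s_um = s_um, t_um = t_um), axis)
        cells_truth[[f]] <- tibble(
          frame = f, time_h = times[f], name = occ$cell, side = occ$side,
          s_um = s_um, t_um = t_um, x_um = xy$x_um, y_um = xy$y_um,
          expression = expr_sig, expression_noisy = expr_sig + noise,
          rendered = occ$side == "L"
        )
      } else {
        cells_truth[f] <- list(NULL)
      }

      # distal tip cells (exist from the L1 ecdysis onwards)
      origin_s <- cfg$marker_frac[["vulva"]] * axis$length
      dtc <- dplyr::bind_rows(lapply(c("anterior", "posterior"), function(cc) {
        p <- dtc_path(cfg, tl, times[f], cc)
        dplyr::mutate(p, cell = cc)
      }))
      dtc <- dtc[is.finite(dtc$s_rel_um), , drop = FALSE]
      if (nrow(dtc) > 0) {
        dtc$s_abs_um <- origin_s + dtc$s_rel_um
        xy <- from_body_coords(tibble(s_um = dtc$s_abs_um, t_um = dtc$t_um), axis)
        dtc_truth[[f]] <- dplyr::bind_cols(
          tibble(frame = f), dtc[, c("time_h", "cell", "s_rel_um", "t_um", "s_abs_um")],
          xy, tibble(slice_shift_um = slice_shifts[f])
        )
      } else {
        dtc_truth[f] <- list(NULL)
      }

      # render channels
      if (!is.null(frames_fluor)) {
        img <- matrix(cfg$background_level, cfg$image_size_px[1], cfg$image_size_px[2])
        ct <- cells_truth[[f]]
        if (!is.null(ct)) {
          for (k in which(ct$rendered)) {
            img <- add_spot(img, ct$x_um[k], ct$y_um[k], ct$expression_noisy[k],
              cfg$spot_sigma_um, px)
          }
        }
        dt <- dtc_truth[[f]]
        if (!is.null(dt)) {
          for (k in seq_len(nrow(dt))) {
            img <- add_spot(img, dt$x_um[k], dt$y_um[k], cfg$dtc_spot_amplitude,
              cfg$spot_sigma_um, px)
          }
        }
        if (cfg$read_noise_sd > 0) {
          img <- img + matrix(rnorm(length(img), 0, cfg$read_noise_sd), nrow(img))
        }
        frames_fluor[[f]] <- img
      }
      if (!is.null(frames_trans)) {
        band <- render_body_band(cfg, axis)
        img <- matrix(cfg$trans_base, cfg$image_size_px[1], cfg$image_size_px[2])
        img[band] <- cfg$trans_body
        if (cfg$read_noise_sd > 0) {
          img <- img + matrix(rnorm(length(img), 0, cfg$read_noise_sd), nrow(img))
        }
        frames_trans[[f]] <- img
      }

      # annotation entry (pixel coordinates; DTC records sit on a different
      # Z-slice, displaced by the planted inter-slice shift)
      ann_cells <- list()
      ct <- cells_truth[[f]]
      if (!is.null(ct)) {
        for (k in seq_len(nrow(ct))) {
          ann_cells[[length(ann_cells) + 1L]] <- list(
            name = ct$name[k], x_px = ct$x_um[k] / px, y_px = ct$y_um[k] / px,
            z = 10L, side = ct$side[k]
          )
        }
      }
      dt <- dtc_truth[[f]]
      markers_dtc <- NULL
      if (!is.null(dt)) {
        shifted <- from_body_coords(
          tibble(s_um = pmin(dt$s_abs_um + slice_shifts[f], axis$length), t_um = dt$t_um),
          axis
        )
        for (k in seq_len(nrow(dt))) {
          ann_cells[[length(ann_cells) + 1L]] <- list(
            name = ifelse(dt$cell[k] == "anterior", "DTC_A", "DTC_P"),
            x_px = shifted$x_um[k] / px, y_px = shifted$y_um[k] / px,
            z = 14L, side = "L"
          )
        }
        mk_sh <- from_body_coords(
          tibble(s_um = pmin(mk$s_um + slice_shifts[f], axis$length), t_um = mk$t_um),
          axis
        )
        markers_dtc <- purrr::map(seq_len(nrow(mk)), function(i) {
          list(marker = mk$marker[i], x_px = mk_sh$x_um[i] / px, y_px = mk_sh$y_um[i] / px)
        })
      }
      ann_frames[[f]] <- list(
        index = f, time_h = times[f],
        centerline_px = lapply(seq_len(nrow(ctrl)), function(i) as.numeric(ctrl[i, ] / px)),
        ventral_px = as.numeric(vm / px),
        markers = purrr::map(seq_len(nrow(mk)), function(i) {
          list(marker = mk$marker[i], x_px = mk_xy$x_um[i] / px, y_px = mk_xy$y_um[i] / px)
        }),
        markers_dtc_slice = markers_dtc,
        cells = ann_cells
      )
    }

    # annotated division times snap to the first frame at/after the event
    # (first appearance of the two daughter nuclei)
    all_times <- seq(tl$hatch_h, tl$ecdysis_h[4] + 0.5, by = cfg$frame_interval_h)
    div <- dplyr::filter(lineage, .data$division_class > 0)
    div$time_frame_h <- vapply(div$division_time_h, function(tm) {
      all_times[which(all_times >= tm)[1]]
    }, 0)

    annotations <- list(
      schema_version = 1L,
      animal = "sim",
      pixel_size_um = px,
      events = list(hatch_h = tl$hatch_h, ecdysis_h = tl$ecdysis_h),
      frames = ann_frames,
      divisions = purrr::map(seq_len(nrow(div)), function(i) {
        list(
          cell = div$cell[i], stage = as.character(div$stage[i]),
          division_class = div$division_class[i],
          division_time_h = div$time_frame_h[i]
        )
      })
    )

    onset <- tl$ecdysis_h[3] - cfg$dtc_turn_lead_h - c(anterior = cfg$dtc_anterior_lead_h, posterior = 0)
    structure(
      list(
        config = cfg,
        timeline = tl,
        times_h = times,
        frames_fluor = frames_fluor,
        frames_trans = frames_trans,
        truth = list(
          axes = axes,
          lengths = tibble(frame = seq_len(n_frames), time_h = times, length_um = lengths),
          cells = dplyr::bind_rows(cells_truth),
          dtc = dplyr::bind_rows(dtc_truth),
          markers = dplyr::bind_rows(markers_truth),
          divisions = div,
          lineage = lineage,
          dtc_turn_onset_h = onset,
          dtc_midline_crossing_h = onset + cfg$dtc_cross_duration_h *
            (-cfg$dtc_ventral_t_um) / (cfg$dtc_dorsal_t_um - cfg$dtc_ventral_t_um),
          slice_shifts_um = slice_shifts
        ),
        annotations = annotations
      ),
      class = "worm_movie"
    )
  })
}

# lifetime table of seam cells: birth (parent division or hatch), end
# (own division or end of recording), anchor fraction and within-lineage
# s offset from the sibling naming
seam_occupancy <- function(lineage, tl, cfg) {
  cfgoff <- function(sub, spacing) {
    if (nchar(sub) == 0) return(0)
    ch <- strsplit(sub, "")[[1]]
    sum(ifelse(ch == "a", -1, 1) * spacing / seq_along(ch))
  }
  anchor <- cfg$seam_anchor_frac
  rec <- lineage
  parent_of <- function(cell) {
    p <- parse_seam_cell(cell)
    if (p$generation == 0) return(NA_character_)
    sub <- substr(p$sublineage, 1, p$generation - 1)
    paste0(p$lineage, p$side, if (nchar(sub)) paste0(".", sub) else "")
  }
  birth <- vapply(rec$cell, function(cl) {
    par <- parent_of(cl)
    if (is.na(par)) return(tl$hatch_h)
    tm <- rec$division_time_h[rec$cell == par]
    if (length(tm) == 0 || !is.finite(tm[1])) tl$hatch_h else tm[1]
  }, 0)
  end <- ifelse(is.finite(rec$division_time_h), rec$division_time_h,
    tl$ecdysis_h[4] + 1
  )
  # terminal daughters (never divide) still occupy the body until the end
  terminal <- dplyr::filter(rec, .data$division_class > 0)
  term_rows <- purrr::map_dfr(seq_len(nrow(terminal)), function(i) {
    base <- if (grepl("\\.", terminal$cell[i])) terminal$cell[i] else paste0(terminal$cell[i], ".")
    ds <- if (terminal$division_class[i] == 1L) paste0(base, c("a", "p")) else paste0(base, "p")
    ds <- setdiff(ds, rec$cell)
    if (length(ds) == 0) return(NULL)
    tibble(cell = ds, t_birth_h = terminal$division_time_h[i], t_end_h = tl$ecdysis_h[4] + 1)
  })
  occ <- dplyr::bind_rows(
    tibble(cell = rec$cell, t_birth_h = birth, t_end_h = end),
    term_rows
  )
  p <- parse_seam_cell(occ$cell)
  occ$side <- p$side
  occ$anchor_frac <- unname(anchor[as.character(p$lineage)])
  occ$s_offset_um <- unname(vapply(p$sublineage, cfgoff, 0, spacing = cfg$sibling_spacing_um))
  occ
}

#' Generate a synthetic cohort
#'
#' Draws `n_animals` independent animals from one configuration: each gets
#' its own developmental timeline (stage durations jittered around the
#' configured means), seam-cell lineage and, optionally, per-cell expression
#' traces whose pulses track the animal's own ecdyses at the configured
#' fixed lead. Frames are not rendered unless requested; cohort-level
#' statistics need only the event tables.
#'
#' @param cfg A [worm_config()]; animal `i` uses a seed derived from
#'   `cfg$seed` and `i`.
#' @param n_animals Number of animals (>= 1).
#' @param p_symmetric,p_nodivision Lineage error probabilities passed to
#'   [generate_lineage()].
#' @param trace_cells Seam-cell names for which expression traces are
#'   generated (default V1L, V2L, V5L).
#' @param render_frames If `TRUE`, each animal also carries a full
#'   [generate_movie()] result.
#' @return A `worm_cohort` list of per-animal lists with elements `animal`,
#'   `timeline`, `lineage`, `traces` (tibble: cell, time_h, intensity,
#'   signal) and optionally `movie`.
#' @export
generate_cohort <- function(cfg, n_animals, p_symmetric = 0, p_nodivision = 0,
                            trace_cells = c("V1L", "V2L", "V5L"),
                            render_frames = FALSE) {
  stopifnot(inherits(cfg, "worm_config"))
  if (!is.numeric(n_animals) || n_animals < 1) abort("`n_animals` must be >= 1")
  animals <- lapply(seq_len(n_animals), function(i) {
    seed_i <- (abs(cfg$seed) + 7919L * i) %% 2147483647L
    cfg_i <- cfg
    cfg_i$seed <- seed_i
    res <- with_seed(seed_i, {
      tl <- generate_timeline(cfg)
      lin <- generate_lineage(cfg, tl,
        animal = sprintf("animal%02d", i),
        p_symmetric = p_symmetric, p_nodivision = p_nodivision
      )
      traces <- purrr::map_dfr(trace_cells, function(cl) {
        # recording continues ~2 h past the final molt, as in practice, so
        # the L4 expression pulse is fully covered
        times <- seq(tl$hatch_h, tl$ecdysis_h[4] + 2, by = cfg$frame_interval_h)
        sig <- expression_signal(cfg, tl, times)
        noise <- if (cfg$expression_noise_sd > 0) {
          rnorm(length(times), 0, cfg$expression_noise_sd)
        } else {
          rep(0, length(times))
        }
        tibble(
          animal = sprintf("animal%02d", i), cell = cl, time_h = times,
          intensity = sig + noise, signal = sig
        )
      })
      list(timeline = tl, lineage = lin, traces = traces)
    })
    res$animal <- sprintf("animal%02d", i)
    if (render_frames) res$movie <- generate_movie(cfg_i)
    res
  })
  structure(list(animals = animals, config = cfg), class = "worm_cohort")
}

#' @export
print.worm_movie <- function(x, ...) {
  cat(sprintf(
    "<worm_movie> %d frames (%.1f-%.1f h), %dx%d px, seed %d\n",
    length(x$times_h), min(x$times_h), max(x$times_h),
    x$config$image_size_px[1], x$config$image_size_px[2], x$config$seed
  ))
  invisible(x)
}

#' @export
print.worm_cohort <- function(x, ...) {
  cat(sprintf("<worm_cohort> %d animals, seed %d\n", length(x$animals), x$config$seed))
  invisible(x)
}
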