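test_that("A-P offset correction subtracts the mean marker displacement", {
  expect_equal(correct_ap_offset(120, 0), 120)
  expect_equal(correct_ap_offset(120, c(4, 6)), 115)
  expect_warning(out <- correct_ap_offset(120, numeric(0)), "skipped")
  expect_equal(out, 120)
  # rigid-shift invariance: shifting markers and cell together cancels
  expect_equal(correct_ap_offset(120 + 5, c(4, 6) + 0), correct_ap_offset(120, c(-1, 1)) + 0 + 5 - 5)
  expect_equal(correct_ap_offset(130, c(10, 10)), correct_ap_offset(120, c(0, 0)))
})

test_that("the migration origin is the midbody in L1-L3 and the vulva in L4", {
  mk <- tibble::tibble(
    marker = c("posterior_bulb", "anus", "vulva"),
    s_um = c(40, 160, 105)
  )
  expect_equal(reference_origin(mk, "L2"), 100)
  expect_equal(reference_origin(mk, "L4"), 105)
  expect_equal(reference_origin(mk, "L3", use = "vulva"), 105)
  expect_error(reference_origin(mk[1, ], "L1"), "anus")
  expect_error(reference_origin(mk[1:2, ], "L4"), "vulva")
})

test_that("the two origin definitions coincide on the synthetic animal", {
  cfg <- worm_config(seed = 8)
  mv <- generate_movie(cfg, t_range_h = c(20, 21), channels = "fluorescence")
  mk <- mv$truth$markers[mv$truth$markers$frame == 1, ]
  mid <- reference_origin(mk, "L3")
  vul <- reference_origin(mk, "L4")
  expect_lt(abs(mid - vul), 2)
})

test_that("sliding-average smoothing has the boxcar's exact fixed points", {
  const <- tibble::tibble(time_h = seq(0, 10, by = 1 / 3), s_um = 50)
  expect_equal(smooth_trajectory(const)$s_um, rep(50, nrow(const)))
  # linear series unchanged at interior points (symmetric window on a line)
  lin <- tibble::tibble(time_h = seq(0, 10, by = 1 / 3), s_um = 10 * seq(0, 10, by = 1 / 3))
  sm <- smooth_trajectory(lin)
  interior <- lin$time_h >= 0.5 & lin$time_h <= 9.5
  expect_equal(sm$s_um[interior], lin$s_um[interior], tolerance = 1e-12)
  expect_error(smooth_trajectory(const, window_h = 0), "window")
  expect_error(smooth_trajectory(const[0, ]), "empty")
})

test_that("a smoothed sinusoid matches the analytic boxcar attenuation", {
  tt <- seq(0, 16, by = 0.01)
  traj <- tibble::tibble(time_h = tt, s_um = sin(2 * pi * tt / 8))
  sm <- smooth_trajectory(traj, window_h = 1)
  att <- sin(pi / 8) / (pi / 8) # sinc(T/P) for T = 1 h window, P = 8 h
  interior <- tt >= 1 & tt <= 15
  expect_lt(max(abs(sm$s_um[interior] - att * sin(2 * pi * tt[interior] / 8))), 1e-3)
  # derivative of the smoothed series matches the attenuated cosine too
  vel <- trajectory_velocity(sm, outward_positive = FALSE)
  want <- att * (2 * pi / 8) * cos(2 * pi * tt / 8)
  expect_lt(max(abs(vel$v_ap_um_h[interior] - want[interior])), 1e-3)
})

test_that("velocities are exact on constant and linear trajectories", {
  tt <- seq(0, 6, by = 1 / 3)
  const <- tibble::tibble(time_h = tt, s_um = 80, t_um = -8)
  v <- trajectory_velocity(const)
  expect_equal(v$v_ap_um_h, rep(0, length(tt)))
  expect_equal(v$v_dv_um_h, rep(0, length(tt)))

  ramp <- tibble::tibble(time_h = tt, s_um = 10 * tt + 3)
  v2 <- trajectory_velocity(smooth_trajectory(ramp), outward_positive = FALSE)
  interior <- tt >= 0.5 & tt <= 5.5
  expect_equal(v2$v_ap_um_h[interior], rep(10, sum(interior)), tolerance = 1e-9)
  # outward convention: negative-s cells moving toward the head read positive
  ramp_neg <- tibble::tibble(time_h = tt, s_um = -10 * tt - 3)
  v3 <- trajectory_velocity(ramp_neg)
  expect_equal(v3$v_ap_um_h[2], 10, tolerance = 1e-9)
  expect_error(trajectory_velocity(ramp[1, , drop = FALSE]), "at least 2")
})

test_that("smoothing and differentiation commute on interior points", {
  tt <- seq(0, 12, by = 1 / 3)
  x <- sin(tt) + 0.3 * tt
  traj <- tibble::tibble(time_h = tt, s_um = x)
  a <- trajectory_velocity(smooth_trajectory(traj), outward_positive = FALSE)$v_ap_um_h
  d <- trajectory_velocity(traj, outward_positive = FALSE)
  b <- smooth_trajectory(
    tibble::tibble(time_h = tt, s_um = d$v_ap_um_h)
  )$s_um
  interior <- tt >= 1.5 & tt <= 10.5
  expect_lt(max(abs(a[interior] - b[interior])), 1e-9)
})

test_that("the planted dorsal-turn onset is recovered within one sample", {
  cfg <- worm_config(seed = 13)
  tl <- withr::with_seed(13, generate_timeline(cfg))
  tt <- seq(tl$ecdysis_h[1], tl$ecdysis_h[4], by = cfg$frame_interval_h)
  for (cell in c("anterior", "posterior")) {
    path <- dtc_path(cfg, tl, tt, cell)
    traj <- tibble::tibble(time_h = tt, s_um = path$s_rel_um, t_um = path$t_um)
    vel <- trajectory_velocity(smooth_trajectory(traj))
    vdv <- abs(vel$v_dv_um_h)
    above <- tt[vdv > max(vdv) / 2]
    onset_true <- tl$ecdysis_h[3] - cfg$dtc_turn_lead_h -
      if (cell == "anterior") cfg$dtc_anterior_lead_h else 0
    expect_lt(abs(min(above) - onset_true), cfg$frame_interval_h + 1e-9)
    # and the turn ends ~3 h later
    expect_lt(abs(max(above) - (onset_true + cfg$dtc_cross_duration_h)), cfg$frame_interval_h + 1e-9)
  }
})

test_that("event alignment re-times series and supports cohort averaging", {
  tl <- developmental_timeline(0, c(11, 18, 25, 35))
  df <- tibble::tibble(time_h = c(27, 30), v = c(1, 2))
  al <- align_to_event(df, tl, "L3_ecdysis")
  expect_equal(al$time_rel_h, c(2, 5))
  # averaging two constant aligned series: mean 4, s.e.m. 1
  two <- tibble::tibble(
    time_rel_h = c(0, 1, 0, 1),
    v = c(3, 3, 5, 5)
  )
  avg <- average_aligned(two, "v", bin_width = 1)
  expect_equal(avg$mean, c(4, 4))
  expect_equal(avg$sem, c(1, 1))
  expect_equal(avg$n, c(2L, 2L))
})

test_that("aligned mean A-P velocity crosses zero at the planted lag", {
  # inward resumption is planted exactly at the L3 ecdysis; aligning each
  # animal on its own molt pins the sign change to lag 0 despite jitter
  cfg <- worm_config(seed = 17)
  aligned <- dplyr::bind_rows(lapply(1:6, function(i) {
    tl <- withr::with_seed(300 + i, generate_timeline(cfg))
    tt <- seq(tl$ecdysis_h[1], tl$ecdysis_h[4] - 0.5, by = cfg$frame_interval_h)
    path <- dtc_path(cfg, tl, tt, "posterior")
    traj <- tibble::tibble(time_h = tt, s_um = path$s_rel_um, t_um = path$t_um)
    vel <- trajectory_velocity(smooth_trajectory(traj))
    dplyr::mutate(align_to_event(vel, tl, "L3_ecdysis"), animal = i)
  }))
  avg <- average_aligned(aligned, "v_ap_um_h", bin_width = 1 / 3)
  # v_AP > 0 (outward) well before, < 0 (inward) after the molt
  expect_gt(avg$mean[which.min(abs(avg$time_rel_h + 5))], 0)
  expect_lt(avg$mean[which.min(abs(avg$time_rel_h - 2))], 0)
  # inward migration (clearly negative v) starts at the molt, within the
  # 1 h smoothing window, despite per-animal jitter in absolute molt times
  inward_start <- min(avg$time_rel_h[avg$mean <= -1])
  expect_lt(abs(inward_start), 1)
})

test_that("midline crossings interpolate the first ventral-to-dorsal sign change", {
  tt <- seq(29, 32, by = 1 / 3)
  stay <- tibble::tibble(time_h = tt, t_um = -5 + 0 * tt)
  expect_true(is.na(detect_midline_crossing(stay, smooth_window_h = NULL)))
  cross <- tibble::tibble(time_h = c(30, 30.33), t_um = c(-2, 2))
  expect_equal(detect_midline_crossing(cross, smooth_window_h = NULL), 30.165)

  # synthetic pair: anterior crosses first by the planted lead
  cfg <- worm_config(seed = 19)
  tl <- withr::with_seed(19, generate_timeline(cfg))
  tt <- seq(tl$ecdysis_h[1], tl$ecdysis_h[4], by = cfg$frame_interval_h)
  crossings <- vapply(c("anterior", "posterior"), function(cell) {
    p <- dtc_path(cfg, tl, tt, cell)
    detect_midline_crossing(tibble::tibble(time_h = tt, t_um = p$t_um))
  }, 0)
  expect_lt(crossings["anterior"], crossings["posterior"])
  expect_lt(
    abs((crossings["posterior"] - crossings["anterior"]) - cfg$dtc_anterior_lead_h),
    cfg$frame_interval_h
  )
  expect_s3_class(
    plot_trajectory(tibble::tibble(time_h = tt, t_um = dtc_path(cfg, tl, tt)$t_um)),
    "ggplot"
  )
})
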