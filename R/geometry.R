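#' Fit the body axis from annotated centre-line points
#'
#' Fits an interpolating cubic spline through manually annotated centre-line
#' points (anterior first) and reparameterizes it by arc length, yielding the
#' body-coordinate system used throughout the package: position `s` in
#' micrometres along the anteroposterior (A--P) axis and signed distance `t`
#' along the dorsoventral (D--V) axis, with `t < 0` on the ventral side. The
#' ventral side is identified from a marker point (position of the gonad in
#' L2--L3 animals, of the vulva in L3--L4 animals).
#'
#' The spline interpolates the points exactly (no smoothing), honouring the
#' manual annotation. Arc-length reparameterization is numerical, through a
#' dense polyline with `dense_per_segment` samples per control-point segment,
#' so that equal steps in `s` traverse equal curve lengths to within 0.1%.
#'
#' @param points Centre-line points, anterior first: an n x 2 matrix or a
#'   data frame with columns `x_um`, `y_um` (or `x`, `y`), in micrometres in
#'   the camera frame. At least 4 points; consecutive points must be distinct.
#' @param ventral_marker A single 2D point (micrometres) on the ventral side
#'   of the animal.
#' @param dense_per_segment Number of dense samples per control segment used
#'   for arc-length integration (default 400; the arc-length map is
#'   piecewise linear on this grid, so its resolution bounds the
#'   round-trip precision of the coordinate transforms).
#' @return A `body_axis` object with elements `length` (body length L in
#'   micrometres), `control_points`, `ventral_marker`, and internal
#'   interpolants used by [to_body_coords()], [from_body_coords()] and
#'   [straighten_image()].
#' @seealso [body_length()], [to_body_coords()], [straighten_image()]
#' @examples
#' pts <- cbind(seq(0, 90, length.out = 10), 0)
#' ax <- fit_body_axis(pts, ventral_marker = c(45, -20))
#' body_length(ax) # 90
#' @export
fit_body_axis <- function(points, ventral_marker, dense_per_segment = 400L) {
  pts <- as_point_matrix(points)
  if (nrow(pts) < 4) {
    abort("insufficient centre-line points: need at least 4")
  }
  seg <- diff(pts)
  seg_len <- sqrt(rowSums(seg^2))
  if (any(seg_len == 0)) {
    abort("duplicate consecutive centre-line points")
  }
  vm <- drop(as_point_matrix(ventral_marker, "ventral_marker"))

  # chord-length parameterization, then natural interpolating cubic splines
  u <- c(0, cumsum(seg_len))
  fx <- splinefun(u, pts[, 1], method = "natural")
  fy <- splinefun(u, pts[, 2], method = "natural")

  # dense polyline for numerical arc length and the s -> u map
  n_seg <- nrow(pts) - 1L
  u_dense <- unique(unlist(lapply(seq_len(n_seg), function(i) {
    seq(u[i], u[i + 1], length.out = dense_per_segment + 1L)
  })))
  xd <- fx(u_dense)
  yd <- fy(u_dense)
  s_dense <- c(0, cumsum(sqrt(diff(xd)^2 + diff(yd)^2)))
  L <- s_dense[length(s_dense)]
  s_to_u <- approxfun(s_dense, u_dense, rule = 2)

  axis <- structure(
    list(
      control_points = pts,
      ventral_marker = vm,
      length = L,
      fx = fx, fy = fy,
      s_to_u = s_to_u,
      s_dense = s_dense,
      xy_dense = cbind(xd, yd),
      ventral_sign = 1
    ),
    class = "body_axis"
  )
  # orient the normal so the ventral marker lands at t < 0
  bp <- project_point(vm, axis)
  if (bp$t > 0) axis$ventral_sign <- -1
  axis
}

#' @export
print.body_axis <- function(x, ...) {
  cat(sprintf(
    "<body_axis> L = %.2f um, %d control points, ventral marker (%.1f, %.1f)\n",
    x$length, nrow(x$control_points), x$ventral_marker[1], x$ventral_marker[2]
  ))
  invisible(x)
}

#' Body length
#'
#' The length of the fitted body-axis curve in micrometres.
#'
#' @param axis A `body_axis` from [fit_body_axis()].
#' @return Body length L in micrometres.
#' @export
body_length <- function(axis) {
  stopifnot(inherits(axis, "body_axis"))
  axis$length
}

#' Evaluate the body-axis curve, tangent and normal
#'
#' `axis_curve()` returns camera-frame positions of the centre line at arc
#' lengths `s`; `axis_normal()` returns the unit normal oriented so that the
#' ventral side corresponds to negative `t`.
#'
#' @param axis A `body_axis`.
#' @param s Arc-length positions in micrometres, in `[0, L]`.
#' @return An `length(s)` x 2 matrix of (x, y) in micrometres (curve) or unit
#'   vectors (normal).
#' @export
axis_curve <- function(axis, s) {
  u <- axis$s_to_u(s)
  cbind(axis$fx(u), axis$fy(u))
}

#' @rdname axis_curve
#' @export
axis_normal <- function(axis, s) {
  u <- axis$s_to_u(s)
  tx <- axis$fx(u, deriv = 1)
  ty <- axis$fy(u, deriv = 1)
  nrm <- sqrt(tx^2 + ty^2)
  # +90 degree rotation of the unit tangent, globally flipped at fit time so
  # the ventral marker projects to t < 0
  cbind(-ty / nrm, tx / nrm) * axis$ventral_sign
}

# Single-point projection onto the axis: dense bracketing then golden-section
# refinement. Points beyond the head or tail clamp to s = 0 or s = L.
project_point <- function(p, axis, tie_tol = 1e-6) {
  xy <- axis$xy_dense
  d2 <- (xy[, 1] - p[1])^2 + (xy[, 2] - p[2])^2
  i <- which.min(d2)
  # flag ambiguous projections (e.g. points on the medial axis of a bend):
  # other dense samples essentially as close but far away in s
  near <- which(d2 <= d2[i] * (1 + 1e-9) + tie_tol)
  if (any(abs(axis$s_dense[near] - axis$s_dense[i]) > axis$length * 0.02)) {
    warn("ambiguous projection: multiple arc-length positions minimize distance; returning the smallest s")
    i <- min(near)
  }
  s_lo <- axis$s_dense[max(1L, i - 1L)]
  s_hi <- axis$s_dense[min(length(axis$s_dense), i + 1L)]
  f <- function(s) {
    q <- axis_curve(axis, s)
    (q[1] - p[1])^2 + (q[2] - p[2])^2
  }
  if (s_hi > s_lo) {
    opt <- optimize(f, lower = s_lo, upper = s_hi, tol = 1e-8)
    s_best <- opt$minimum
    # endpoints of the bracket can beat optimize()'s interior minimum
    cand <- c(s_lo, s_best, s_hi)
    s_best <- cand[which.min(vapply(cand, f, 0))]
  } else {
    s_best <- s_lo
  }
  s_best <- min(max(s_best, 0), axis$length)
  # Brent stops near sqrt(eps) * |s|; polish with the stationarity condition
  # (p - c(s)) . T(s) = 0, a contraction whenever |t| is below the local
  # curvature radius. Clamped endpoints stay clamped.
  s_bracket <- s_best
  if (s_best > 0 && s_best < axis$length) {
    for (it in 1:50) {
      u <- axis$s_to_u(s_best)
      tx <- axis$fx(u, deriv = 1)
      ty <- axis$fy(u, deriv = 1)
      nrm <- sqrt(tx^2 + ty^2)
      q0 <- drop(axis_curve(axis, s_best))
      step <- ((p[1] - q0[1]) * tx + (p[2] - q0[2]) * ty) / nrm
      s_new <- min(max(s_best + step, 0), axis$length)
      done <- abs(s_new - s_best) < 1e-10
      s_best <- s_new
      if (done || s_best == 0 || s_best == axis$length) break
    }
    # beyond the curvature centre the iteration is not a contraction;
    # fall back to the bracketed minimum if polishing went uphill
    if (f(s_best) > f(s_bracket)) s_best <- s_bracket
  }
  q <- drop(axis_curve(axis, s_best))
  v <- p - q
  dist <- sqrt(sum(v^2))
  n <- drop(axis_normal(axis, s_best))
  t_signed <- if (dist == 0) 0 else dist * sign(sum(v * n))
  if (t_signed == 0 && dist > 0) t_signed <- dist # degenerate tangent-aligned residual
  list(s = s_best, t = t_signed)
}

#' Convert camera coordinates to body coordinates
#'
#' For each camera-frame point, finds the arc length `s` minimizing the
#' distance to the body-axis curve; `|t|` is that minimal distance and the
#' sign of `t` is negative on the ventral side. Points beyond the head or
#' tail clamp to `s = 0` or `s = L` with `|t|` the distance to the endpoint.
#' When several arc-length positions minimize the distance (a point on the
#' medial axis of a bend) the smallest `s` is returned with a warning.
#'
#' @param points Camera-frame points (micrometres): n x 2 matrix, data frame
#'   with `x_um`/`y_um`, or a single length-2 vector.
#' @param axis A `body_axis`.
#' @return A tibble with columns `s_um`, `t_um`.
#' @export
to_body_coords <- function(points, axis) {
  stopifnot(inherits(axis, "body_axis"))
  pts <- as_point_matrix(points)
  res <- lapply(seq_len(nrow(pts)), function(i) project_point(pts[i, ], axis))
  tibble(
    s_um = vapply(res, `[[`, 0, "s"),
    t_um = vapply(res, `[[`, 0, "t")
  )
}

#' Convert body coordinates to camera coordinates
#'
#' Inverse of [to_body_coords()]: returns `curve(s) + t * n(s)` where `n(s)`
#' is the unit normal oriented so the ventral side has `t < 0`. The round
#' trip with [to_body_coords()] is the identity (to numerical precision) for
#' `|t|` smaller than the local radius of curvature.
#'
#' @param body_points A data frame with columns `s_um`, `t_um` (as returned
#'   by [to_body_coords()]), or an n x 2 matrix of (s, t).
#' @param axis A `body_axis`.
#' @return A tibble with columns `x_um`, `y_um`.
#' @export
from_body_coords <- function(body_points, axis) {
  stopifnot(inherits(axis, "body_axis"))
  if (is.data.frame(body_points)) {
    s <- body_points$s_um
    t <- body_points$t_um
  } else {
    m <- as_point_matrix(body_points, "body_points")
    s <- m[, 1]
    t <- m[, 2]
  }
  eps <- 1e-9 * max(1, axis$length)
  if (any(s < -eps | s > axis$length + eps)) {
    abort(sprintf("s outside [0, L = %.3f]", axis$length))
  }
  s <- pmin(pmax(s, 0), axis$length)
  q <- axis_curve(axis, s)
  n <- axis_normal(axis, s)
  tibble(x_um = q[, 1] + t * n[, 1], y_um = q[, 2] + t * n[, 2])
}

#' Computationally straighten an image onto the body grid
#'
#' Resamples a camera-frame image onto the body-coordinate (s, t) grid so the
#' animal appears straight. Output column `c` (0-based) corresponds to
#' `s = c * pixel_size`; output row `r` to `t = (r - r0) * pixel_size`, where
#' `r0` is the row of the body axis, so ventral (`t < 0`) is at the top of
#' the matrix. Sampling is bilinear; positions outside the input image fill
#' with 0.
#'
#' @param image A numeric matrix (single channel, single Z-slice). Pixel
#'   `image[i, j]` is centred at camera position
#'   `((j - 1) * pixel_size, (i - 1) * pixel_size)` micrometres.
#' @param axis A `body_axis` fitted in the same frame.
#' @param half_width Half-width of the straightened band in micrometres
#'   (rows cover `|t| <= half_width`).
#' @param pixel_size Micrometres per pixel (isotropic, > 0).
#' @return A numeric matrix of size
#'   `ceiling(2 * half_width / pixel_size)` x `ceiling(L / pixel_size)` with
#'   attributes `s_um` (column positions), `t_um` (row positions) and
#'   `pixel_size`, class `straightened_image`.
#' @export
straighten_image <- function(image, axis, half_width, pixel_size) {
  stopifnot(inherits(axis, "body_axis"), is.matrix(image))
  if (!is.numeric(half_width) || length(half_width) != 1 || half_width <= 0) {
    abort("`half_width` must be a positive number (micrometres)")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    abort("`pixel_size` must be a positive number (micrometres per pixel)")
  }
  W <- as.integer(ceiling(axis$length / pixel_size))
  H <- as.integer(ceiling(2 * half_width / pixel_size))
  r0 <- floor(H / 2)
  s_vals <- (seq_len(W) - 1) * pixel_size
  t_vals <- ((seq_len(H) - 1) - r0) * pixel_size

  q <- axis_curve(axis, s_vals) # W x 2
  n <- axis_normal(axis, s_vals) # W x 2
  # camera positions of the full (t, s) grid, H x W each
  X <- outer(t_vals, n[, 1]) + matrix(q[, 1], H, W, byrow = TRUE)
  Y <- outer(t_vals, n[, 2]) + matrix(q[, 2], H, W, byrow = TRUE)
  vals <- bilinear_sample(image, X / pixel_size, Y / pixel_size)
  out <- matrix(vals, H, W)
  structure(out,
    s_um = s_vals, t_um = t_vals, pixel_size = pixel_size,
    class = c("straightened_image", "matrix", "array")
  )
}

#' Axis coordinates of a straightened image
#'
#' Column-wise `s` and row-wise `t` positions (micrometres) of a matrix
#' produced by [straighten_image()], so downstream code never re-derives the
#' row-to-t convention.
#'
#' @param x A `straightened_image`.
#' @return Numeric vector of positions in micrometres.
#' @export
straightened_s_axis <- function(x) attr(x, "s_um")

#' @rdname straightened_s_axis
#' @export
straightened_t_axis <- function(x) attr(x, "t_um")

#' Mask of pixels within the body band
#'
#' Logical matrix marking image pixels whose distance to the body-axis curve
#' is at most `half_width` micrometres. Used for whole-animal intensity
#' integration and background estimation.
#'
#' @param dim_px Image dimensions `c(rows, cols)`.
#' @param axis A `body_axis`.
#' @param half_width Band half-width in micrometres.
#' @param pixel_size Micrometres per pixel.
#' @return A logical matrix of size `dim_px`.
#' @export
body_mask <- function(dim_px, axis, half_width, pixel_size) {
  stopifnot(inherits(axis, "body_axis"), half_width > 0, pixel_size > 0)
  nr <- dim_px[1]
  nc <- dim_px[2]
  # curve samples every ~0.5 um: distance-to-polyline error << pixel scale
  s_grid <- seq(0, axis$length, by = 0.5)
  q <- axis_curve(axis, s_grid)
  px <- (seq_len(nc) - 1) * pixel_size
  py <- (seq_len(nr) - 1) * pixel_size
  P <- cbind(rep(px, each = nr), rep(py, times = nc)) # pixel centres, row-major in columns
  hw2 <- half_width^2
  ok <- logical(nrow(P))
  chunk <- 4000L
  for (start in seq(1L, nrow(P), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(P))
    dx <- outer(P[idx, 1], q[, 1], `-`)
    dy <- outer(P[idx, 2], q[, 2], `-`)
    d2 <- dx * dx + dy * dy
    ok[idx] <- matrixStats_rowMins(d2) <= hw2
  }
  matrix(ok, nr, nc)
}

# row minima without a matrixStats dependency
matrixStats_rowMins <- function(m) {
  do.call(pmin, c(as.data.frame(m), list(na.rm = TRUE)))
}

#' Plot a body axis over its control points
#'
#' @param object A `body_axis`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.body_axis <- function(object, ...) {
  s <- seq(0, object$length, length.out = 400)
  curve_df <- as_tibble(as.data.frame(axis_curve(object, s)))
  names(curve_df) <- c("x_um", "y_um")
  ctrl_df <- tibble(
    x_um = object$control_points[, 1],
    y_um = object$control_points[, 2]
  )
  ggplot2::ggplot(curve_df, ggplot2::aes(x = .data$x_um, y = .data$y_um)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = ctrl_df, shape = 1) +
    ggplot2::annotate("point",
      x = object$ventral_marker[1], y = object$ventral_marker[2],
      colour = "red", shape = 17
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (µm)", y = "y (µm)",
      title = sprintf("Body axis, L = %.1f µm (red: ventral marker)", object$length)
    )
}
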