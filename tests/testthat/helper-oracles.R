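# Independent oracles used by the test-suite. These are deliberately written
# as naive brute-force/enumeration code, sharing no logic with the package
# implementation they check.

# Brute-force nearest-point projection: minimize distance over n uniformly
# spaced arc-length samples of the fitted curve.
oracle_project <- function(p, axis, n = 1e5) {
  s_grid <- seq(0, body_length(axis), length.out = n)
  q <- axis_curve(axis, s_grid)
  d2 <- (q[, 1] - p[1])^2 + (q[, 2] - p[2])^2
  i <- which.min(d2)
  s <- s_grid[i]
  nrm <- axis_normal(axis, s)
  v <- p - q[i, ]
  t_abs <- sqrt(d2[i])
  t_sgn <- if (t_abs == 0) 0 else sign(sum(v * nrm))
  list(s = s, t = ifelse(t_sgn == 0 & t_abs > 0, t_abs, t_sgn * t_abs))
}

# Exhaustive Otsu: try every distinct value as a class boundary (foreground
# strictly above), score by between-class variance computed from first
# principles, return the winning boundary's midpoint threshold.
oracle_otsu <- function(x) {
  v <- as.numeric(x)
  u <- sort(unique(v))
  best_score <- -Inf
  best_thr <- NA_real_
  for (k in seq_len(length(u) - 1)) {
    thr <- (u[k] + u[k + 1]) / 2
    lo <- v[v <= thr]
    hi <- v[v > thr]
    w0 <- length(lo) / length(v)
    w1 <- 1 - w0
    score <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (score > best_score + 1e-12) {
      best_score <- score
      best_thr <- thr
    }
  }
  best_thr
}

# Enumeration oracle for the lineage-error probability: walk every mutant
# animal cell by cell, look the cell up in the wild-type table, and count
# mismatches per (lineage, stage) with explicit loops.
oracle_error_probability <- function(wt, mutants) {
  lineages <- c("H1", "H2", "V1", "V2", "V3", "V4", "V5", "V6", "T")
  stages <- c("L1", "L2", "L3", "L4")
  n <- matrix(0L, 9, 4, dimnames = list(lineages, stages))
  m <- matrix(0L, 9, 4, dimnames = list(lineages, stages))
  wt_class <- setNames(wt$division_class, wt$cell)
  wt_stage <- setNames(as.character(wt$stage), wt$cell)
  for (w in unique(mutants$animal)) {
    sub <- mutants[mutants$animal == w, ]
    for (i in seq_len(nrow(sub))) {
      cell <- sub$cell[i]
      if (!cell %in% names(wt_class)) next # created by an upstream error
      lin <- sub("^((H1|H2|V[1-6]|T)).*$", "\\1", cell)
      stg <- wt_stage[[cell]]
      n[lin, stg] <- n[lin, stg] + 1L
      if (wt_class[[cell]] != sub$division_class[i]) {
        m[lin, stg] <- m[lin, stg] + 1L
      }
    }
  }
  P <- m / n # NaN where n == 0
  P[n == 0] <- NA_real_
  P
}

# Random toy lineage pair (wild type + mutants) for oracle equivalence
# tests: a stylized tree of <= `max_gen` generations where every division
# class is drawn at random, and mutants re-draw classes with error
# probability `p_err`. Daughters follow the *local* class, so mutant-only
# cells arise naturally.
random_toy_lineages <- function(n_mutants = 3, max_gen = 3, p_err = 0.3) {
  lineages <- c("H1", "H2", "V1", "V2", "V3", "V4", "V5", "V6", "T")
  stages <- c("L1", "L2", "L3", "L4")
  grow <- function(perturb_of = NULL) {
    rec <- list()
    for (lin in sample(lineages, 4)) {
      side <- sample(c("L", "R"), 1)
      cells <- paste0(lin, side)
      for (g in seq_len(sample(1:max_gen, 1))) {
        stage <- stages[min(g, 4)]
        daughters <- character()
        for (cl in cells) {
          if (!is.null(perturb_of) && cl %in% names(perturb_of) && runif(1) < p_err) {
            d <- sample(setdiff(0:2, perturb_of[[cl]]), 1)
          } else if (!is.null(perturb_of) && cl %in% names(perturb_of)) {
            d <- perturb_of[[cl]]
          } else {
            d <- sample(0:2, 1, prob = c(0.15, 0.35, 0.5))
          }
          rec[[length(rec) + 1]] <- data.frame(
            cell = cl, stage = stage, division_class = d,
            division_time_h = if (d > 0) g * 10 + runif(1) else NA_real_
          )
          if (d > 0) {
            base <- if (grepl("\\.", cl)) cl else paste0(cl, ".")
            daughters <- c(daughters, paste0(base, if (d == 1) c("a", "p") else "p"))
          }
        }
        cells <- daughters
        if (length(cells) == 0) break
      }
    }
    do.call(rbind, rec)
  }
  wt <- grow()
  wt$animal <- "wt"
  wt_classes <- setNames(as.list(wt$division_class), wt$cell)
  muts <- do.call(rbind, lapply(seq_len(n_mutants), function(i) {
    m <- grow(perturb_of = wt_classes)
    m$animal <- paste0("mut", i)
    m
  }))
  list(wt = wt, mutants = muts)
}

# A smooth random test axis: low-order random Fourier midline, fitted from
# a handful of points like a manual annotation would be.
random_smooth_axis <- function(n_ctrl = 10, span_um = 200) {
  a <- runif(2, 5, 20)
  ph <- runif(2, 0, 2 * pi)
  x <- seq(0, span_um, length.out = n_ctrl)
  y <- a[1] * sin(2 * pi * x / span_um + ph[1]) +
    a[2] * sin(4 * pi * x / span_um + ph[2])
  fit_body_axis(cbind(x, y), ventral_marker = c(span_um / 2, min(y) - 30))
}

# Render a single Gaussian spot image (zero background) at given camera
# position; closed-form truth for centroid/integral oracles.
render_spot_image <- function(dim_px, x_um, y_um, amplitude, sigma_um, pixel_size = 1) {
  xg <- (seq_len(dim_px[2]) - 1) * pixel_size
  yg <- (seq_len(dim_px[1]) - 1) * pixel_size
  outer(
    exp(-(yg - y_um)^2 / (2 * sigma_um^2)),
    exp(-(xg - x_um)^2 / (2 * sigma_um^2))
  ) * amplitude
}

# intensity-weighted centroid of a straightened image in (s, t) coordinates
straightened_centroid <- function(st) {
  s <- straightened_s_axis(st)
  t <- straightened_t_axis(st)
  w <- pmax(unclass(st), 0)
  tot <- sum(w)
  list(
    s = sum(sweep(w, 2, s, `*`)) / tot,
    t = sum(sweep(w, 1, t, `*`)) / tot,
    mass = tot
  )
}
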