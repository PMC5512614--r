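#' Developmental timeline of one animal
#'
#' Records the hatch time and the four ecdysis times (end of L1--L4) of a
#' single animal, in hours. Ecdysis is an instantaneous annotated event,
#' defined by the appearance of a newly shed cuticle in the microchamber.
#'
#' @param hatch_h Hatch time (h).
#' @param ecdysis_h Four strictly increasing ecdysis times (h), all after
#'   `hatch_h`, for the L1--L4 molts.
#' @return A `developmental_timeline` object.
#' @examples
#' tl <- developmental_timeline(0, c(11, 18, 25, 35))
#' assign_stage(c(5, 20), tl)
#' @export
developmental_timeline <- function(hatch_h, ecdysis_h) {
  if (length(hatch_h) != 1 || length(ecdysis_h) != 4) {
    abort("need one hatch time and four ecdysis times")
  }
  times <- c(hatch_h, ecdysis_h)
  if (any(diff(times) <= 0)) {
    abort("timeline must be strictly increasing: hatch < L1 < L2 < L3 < L4 ecdysis")
  }
  structure(
    list(hatch_h = as.numeric(hatch_h), ecdysis_h = as.numeric(ecdysis_h)),
    class = "developmental_timeline"
  )
}

#' @export
print.developmental_timeline <- function(x, ...) {
  cat(sprintf(
    "<developmental_timeline> hatch %.2f h; ecdyses %s h\n",
    x$hatch_h, paste(sprintf("%.2f", x$ecdysis_h), collapse = ", ")
  ))
  invisible(x)
}

#' Map absolute time to larval stage
#'
#' Stages are half-open intervals: `[hatch, ecdysis1)` is L1, ...,
#' `[ecdysis4, Inf)` is adult; times before hatching are embryo. An ecdysis
#' time itself therefore belongs to the following stage.
#'
#' @param time_h Times in hours (vectorized).
#' @param tl A [developmental_timeline()].
#' @return A factor with levels embryo, L1--L4, adult.
#' @export
assign_stage <- function(time_h, tl) {
  stopifnot(inherits(tl, "developmental_timeline"))
  idx <- findInterval(time_h, c(tl$hatch_h, tl$ecdysis_h))
  factor(stage_levels[idx + 1L], levels = stage_levels)
}

#' Start and end of a larval stage
#'
#' @param tl A [developmental_timeline()].
#' @param stage One of "L1", "L2", "L3", "L4".
#' @return `c(start_h, end_h)` of the half-open stage interval.
#' @export
stage_interval <- function(tl, stage) {
  stopifnot(inherits(tl, "developmental_timeline"))
  i <- match(match.arg(stage, larval_stages), larval_stages)
  bounds <- c(tl$hatch_h, tl$ecdysis_h)
  c(start_h = bounds[i], end_h = bounds[i + 1])
}

#' Larval stage durations
#'
#' Successive differences of the timeline starting at hatch. Under standard
#' culture conditions these average about 11.1, 7.3, 7.1 and 10.2 h for
#' L1--L4.
#'
#' @param tl A [developmental_timeline()].
#' @return A tibble with columns `stage` and `duration_h`. The durations sum
#'   exactly to `ecdysis_h[4] - hatch_h`.
#' @export
stage_durations <- function(tl) {
  stopifnot(inherits(tl, "developmental_timeline"))
  d <- diff(c(tl$hatch_h, tl$ecdysis_h))
  if (any(d <= 0)) abort("timeline must be strictly increasing")
  tibble(stage = factor(larval_stages, levels = stage_levels), duration_h = d)
}

#' Fraction of animals in ecdysis per time bin
#'
#' Histogram of ecdysis events over a cohort: for each time bin, the number
#' of ecdysis events in the bin divided by the number of animals. With bins
#' narrower than any larval stage each value lies in [0, 1], and
#' `sum(fraction) * N` equals the total number of events inside the binned
#' range.
#'
#' @param timelines A list of [developmental_timeline()] objects.
#' @param bin_width Bin width in hours (> 0).
#' @param range_h Optional `c(min, max)` time range; defaults to spanning all
#'   events.
#' @return A tibble with columns `bin_start_h`, `bin_mid_h`, `n_events`,
#'   `fraction`.
#' @export
ecdysis_fraction <- function(timelines, bin_width, range_h = NULL) {
  if (length(timelines) < 1) abort("need at least one timeline")
  if (!is.numeric(bin_width) || bin_width <= 0) abort("`bin_width` must be > 0")
  events <- unlist(lapply(timelines, function(tl) {
    stopifnot(inherits(tl, "developmental_timeline"))
    tl$ecdysis_h
  }))
  if (is.null(range_h)) {
    range_h <- c(floor(min(events) / bin_width) * bin_width, max(events) + bin_width)
  }
  breaks <- seq(range_h[1], range_h[2] + bin_width, by = bin_width)
  counts <- tabulate(findInterval(events, breaks, rightmost.closed = FALSE),
    nbins = length(breaks) - 1L
  )
  tibble(
    bin_start_h = breaks[-length(breaks)],
    bin_mid_h = breaks[-length(breaks)] + bin_width / 2,
    n_events = counts,
    fraction = counts / length(timelines)
  )
}

#' Cohort stage-duration summary
#'
#' Per-stage mean, standard deviation and n of larval stage durations across
#' a cohort of timelines.
#'
#' @param timelines A list of [developmental_timeline()] objects.
#' @return A tibble with columns `stage`, `mean_h`, `sd_h`, `n`.
#' @export
cohort_stage_durations <- function(timelines) {
  if (length(timelines) < 1) abort("need at least one timeline")
  df <- purrr::map_dfr(seq_along(timelines), function(i) {
    dplyr::mutate(stage_durations(timelines[[i]]), animal = i)
  })
  dplyr::summarise(
    dplyr::group_by(df, .data$stage),
    mean_h = mean(.data$duration_h),
    sd_h = sd(.data$duration_h),
    n = dplyr::n(),
    .groups = "drop"
  )
}
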