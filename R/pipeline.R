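#' Fit body axes for every annotated frame
#'
#' @param ann A loaded annotation structure (see [load_annotations()]).
#' @return A list of `body_axis` objects, one per frame.
#' @export
annotation_body_axes <- function(ann) {
  lapply(ann$frames, function(fr) {
    fit_body_axis(fr$centerline_um, fr$ventral_um)
  })
}

#' Per-frame body lengths from an annotation
#'
#' @param ann A loaded annotation structure.
#' @param axes Optional precomputed axes from [annotation_body_axes()].
#' @return A tibble with `frame`, `time_h`, `length_um`.
#' @export
annotation_body_lengths <- function(ann, axes = NULL) {
  if (is.null(axes)) axes <- annotation_body_axes(ann)
  tibble(
    frame = seq_along(ann$frames),
    time_h = vapply(ann$frames, `[[`, 0, "time_h"),
    length_um = vapply(axes, body_length, 0)
  )
}

#' Body coordinates of all annotated cells
#'
#' Projects every annotated cell position onto the frame's body axis.
#'
#' @param ann A loaded annotation structure.
#' @param axes Optional precomputed axes.
#' @return A tibble: `frame`, `time_h`, `name`, `side`, `z`, `s_um`, `t_um`.
#' @export
annotation_cell_coords <- function(ann, axes = NULL) {
  if (is.null(axes)) axes <- annotation_body_axes(ann)
  purrr::map_dfr(seq_along(ann$frames), function(f) {
    fr <- ann$frames[[f]]
    if (is.null(fr$cells) || nrow(fr$cells) == 0) return(NULL)
    bc <- to_body_coords(cbind(fr$cells$x_um, fr$cells$y_um), axes[[f]])
    tibble(
      frame = f, time_h = fr$time_h,
      name = fr$cells$name, side = fr$cells$side, z = fr$cells$z,
      s_um = bc$s_um, t_um = bc$t_um
    )
  })
}

#' Distal-tip-cell trajectories from an annotation
#'
#' Assembles (s, t) trajectories of the two DTCs: projects the annotated
#' DTC positions onto each frame's axis, corrects the A--P position for the
#' body displacement between the DTC Z-slice and the reference slice
#' (measured on anatomical markers present in both, see
#' [correct_ap_offset()]), and re-references `s` to the stage-appropriate
#' origin (midbody in L1--L3, vulva in L3--L4, see [reference_origin()]).
#'
#' @param ann A loaded annotation structure.
#' @param axes Optional precomputed axes.
#' @param correct_slices Apply the inter-slice marker correction (default
#'   TRUE; skipped per frame with a warning when no marker is shared).
#' @return A tibble: `cell` ("anterior"/"posterior"), `time_h`, `s_um`
#'   (origin-relative), `t_um`.
#' @export
annotation_dtc_trajectories <- function(ann, axes = NULL, correct_slices = TRUE) {
  if (is.null(axes)) axes <- annotation_body_axes(ann)
  purrr::map_dfr(seq_along(ann$frames), function(f) {
    fr <- ann$frames[[f]]
    if (is.null(fr$cells)) return(NULL)
    dtc <- fr$cells[fr$cells$name %in% c("DTC_A", "DTC_P"), , drop = FALSE]
    if (nrow(dtc) == 0) return(NULL)
    ax <- axes[[f]]
    bc <- to_body_coords(cbind(dtc$x_um, dtc$y_um), ax)
    s_raw <- bc$s_um
    if (correct_slices && !is.null(fr$markers) && !is.null(fr$markers_dtc)) {
      shared <- dplyr::inner_join(fr$markers, fr$markers_dtc,
        by = "marker", suffix = c("_ref", "_dtc")
      )
      if (nrow(shared) > 0) {
        s_ref <- to_body_coords(cbind(shared$x_um_ref, shared$y_um_ref), ax)$s_um
        s_dtc <- to_body_coords(cbind(shared$x_um_dtc, shared$y_um_dtc), ax)$s_um
        s_raw <- correct_ap_offset(s_raw, s_dtc - s_ref)
      }
    }
    stage <- as.character(assign_stage(fr$time_h, ann$timeline))
    marker_s <- NULL
    if (!is.null(fr$markers)) {
      ms <- to_body_coords(cbind(fr$markers$x_um, fr$markers$y_um), ax)$s_um
      marker_s <- tibble(marker = fr$markers$marker, s_um = ms)
    }
    origin <- if (!is.null(marker_s) && stage %in% c(larval_stages, "adult")) {
      reference_origin(marker_s, stage)
    } else {
      0
    }
    tibble(
      cell = ifelse(dtc$name == "DTC_A", "anterior", "posterior"),
      time_h = fr$time_h,
      s_um = s_raw - origin,
      t_um = bc$t_um
    )
  })
}

#' Expression traces of annotated nuclei
#'
#' Otsu-masked mean nuclear intensity (see [nuclear_mean_intensity()]) for
#' each annotated seam-cell nucleus over time, restricted by default to the
#' body side closest to the objective (the only side bright enough to
#' quantify in practice).
#'
#' @param ann A loaded annotation structure.
#' @param frames List of fluorescence image matrices matching `ann$frames`.
#' @param cells Cell names to quantify.
#' @param side Body side to quantify (default "L").
#' @param roi_size_um Nuclear ROI side (default 5).
#' @return A trace tibble: `cell`, `time_h`, `intensity`.
#' @export
annotation_nuclear_traces <- function(ann, frames, cells, side = "L",
                                      roi_size_um = 5) {
  if (length(frames) != length(ann$frames)) {
    abort("`frames` must match the annotation's frame list")
  }
  purrr::map_dfr(seq_along(ann$frames), function(f) {
    fr <- ann$frames[[f]]
    if (is.null(fr$cells)) return(NULL)
    sel <- fr$cells[fr$cells$name %in% cells & fr$cells$side == side, , drop = FALSE]
    if (nrow(sel) == 0) return(NULL)
    purrr::map_dfr(seq_len(nrow(sel)), function(k) {
      val <- tryCatch(
        nuclear_mean_intensity(
          frames[[f]], c(sel$x_um[k], sel$y_um[k]),
          pixel_size = ann$pixel_size_um, roi_size_um = roi_size_um
        )$mean_intensity,
        error = function(e) NA_real_
      )
      tibble(cell = sel$name[k], time_h = fr$time_h, intensity = val)
    })
  })
}
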