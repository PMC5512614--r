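cell_name_vocabulary <- function() {
  c("seam cells: (H1|H2|V1..V6|T)(L|R)[.{a,p}*]", "distal tip cells: DTC_A, DTC_P")
}

valid_cell_name <- function(cell) {
  grepl("^(H1|H2|V[1-6]|T)(L|R)(\\.[ap]+)?$", cell) | cell %in% c("DTC_A", "DTC_P")
}

#' Load a per-animal annotation file
#'
#' Reads the JSON annotation format: per animal, the pixel size, the event
#' list (hatch and four ecdyses), and per frame the timestamp, centre-line
#' points, ventral-marker point, anatomical-marker points, and cell records
#' (name, position, Z-slice, body side), plus annotated division records.
#' All pixel coordinates are converted to micrometres exactly once, here;
#' body-frame quantities are never stored, always derived.
#'
#' @param path Path to the annotation JSON file.
#' @return A list with `animal`, `pixel_size_um`, `timeline`
#'   (a [developmental_timeline()]), `frames` (list: `time_h`,
#'   `centerline_um` matrix, `ventral_um`, `markers` tibble, `markers_dtc`
#'   tibble or NULL, `cells` tibble with positions in micrometres) and
#'   `divisions` (a seam-cell record tibble).
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  ann <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (field in c("schema_version", "animal", "pixel_size_um", "events", "frames")) {
    if (is.null(ann[[field]])) abort(sprintf("annotation schema violation: missing `%s`", field))
  }
  px <- as.numeric(ann$pixel_size_um)
  if (!is.finite(px) || px <= 0) abort("annotation schema violation: `pixel_size_um` must be > 0")
  ev <- ann$events
  if (is.null(ev$hatch_h) || length(ev$ecdysis_h) != 4) {
    abort("annotation schema violation: `events` needs `hatch_h` and 4 `ecdysis_h`")
  }
  tl <- developmental_timeline(as.numeric(ev$hatch_h), as.numeric(unlist(ev$ecdysis_h)))

  last_t <- -Inf
  frames <- lapply(ann$frames, function(fr) {
    if (is.null(fr$time_h) || is.null(fr$centerline_px)) {
      abort("annotation schema violation: frame needs `time_h` and `centerline_px`")
    }
    if (as.numeric(fr$time_h) < last_t) {
      abort("annotation schema violation: frame timestamps must be non-decreasing")
    }
    last_t <<- as.numeric(fr$time_h)
    cl <- do.call(rbind, lapply(fr$centerline_px, function(p) as.numeric(unlist(p))))
    if (is.null(cl) || nrow(cl) < 4) abort("insufficient centre-line points")
    parse_markers <- function(mlist) {
      if (is.null(mlist) || length(mlist) == 0) return(NULL)
      tibble(
        marker = vapply(mlist, function(m) as.character(m$marker), ""),
        x_um = vapply(mlist, function(m) as.numeric(m$x_px), 0) * px,
        y_um = vapply(mlist, function(m) as.numeric(m$y_px), 0) * px
      )
    }
    cells <- NULL
    if (!is.null(fr$cells) && length(fr$cells) > 0) {
      nm <- vapply(fr$cells, function(cc) as.character(cc$name), "")
      bad <- !valid_cell_name(nm)
      if (any(bad)) {
        abort(sprintf(
          "unknown cell name(s) %s; vocabulary: %s",
          paste(unique(nm[bad]), collapse = ", "),
          paste(cell_name_vocabulary(), collapse = "; ")
        ))
      }
      cells <- tibble(
        name = nm,
        x_um = vapply(fr$cells, function(cc) as.numeric(cc$x_px), 0) * px,
        y_um = vapply(fr$cells, function(cc) as.numeric(cc$y_px), 0) * px,
        z = vapply(fr$cells, function(cc) as.integer(cc$z %||% NA_integer_), 1L),
        side = vapply(fr$cells, function(cc) as.character(cc$side %||% NA_character_), "")
      )
    }
    list(
      index = as.integer(fr$index %||% NA_integer_),
      time_h = as.numeric(fr$time_h),
      centerline_um = cl * px,
      ventral_um = as.numeric(unlist(fr$ventral_px)) * px,
      markers = parse_markers(fr$markers),
      markers_dtc = parse_markers(fr$markers_dtc_slice),
      cells = cells
    )
  })

  divisions <- NULL
  if (!is.null(ann$divisions) && length(ann$divisions) > 0) {
    divisions <- seam_cell_records(tibble(
      animal = as.character(ann$animal),
      cell = vapply(ann$divisions, function(d) as.character(d$cell), ""),
      stage = vapply(ann$divisions, function(d) as.character(d$stage), ""),
      division_class = vapply(ann$divisions, function(d) as.integer(d$division_class), 0L),
      division_time_h = vapply(ann$divisions, function(d) as.numeric(d$division_time_h), 0)
    ))
  }

  list(
    animal = as.character(ann$animal),
    schema_version = as.integer(ann$schema_version),
    pixel_size_um = px,
    timeline = tl,
    frames = frames,
    divisions = divisions
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save an annotation structure to JSON
#'
#' Writes the raw annotation list (as produced by [generate_movie()]'s
#' `annotations` element, in pixel coordinates) to the JSON schema that
#' [load_annotations()] reads back.
#'
#' @param annotations Annotation list (schema_version, animal,
#'   pixel_size_um, events, frames, divisions).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_annotations <- function(annotations, path) {
  jsonlite::write_json(annotations, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read and write TIFF image stacks
#'
#' Multi-page TIFF I/O for movie frames. Intensities are stored as 16-bit
#' samples; `scale` maps intensity units to the 16-bit range (a value of
#' `scale` stores as 65535), so arbitrary-unit fluorescence survives the
#' round trip to within one part in 65535 of `scale`.
#'
#' @param frames A matrix or list of matrices (one per page).
#' @param path TIFF file path.
#' @param scale Intensity corresponding to full scale (default 65535, i.e.
#'   raw 16-bit counts).
#' @return `write_image_stack()`: `path`, invisibly. `read_image_stack()`:
#'   a list of matrices in intensity units.
#' @export
write_image_stack <- function(frames, path, scale = 65535) {
  if (is.matrix(frames)) frames <- list(frames)
  lo <- min(vapply(frames, min, 0))
  hi <- max(vapply(frames, max, 0))
  if (lo < 0 || hi > scale) {
    warn(sprintf("intensities clipped to [0, %g] for 16-bit storage", scale))
  }
  norm <- lapply(frames, function(m) pmin(pmax(m / scale, 0), 1))
  tiff::writeTIFF(norm, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path, scale = 65535) {
  if (!file.exists(path)) abort(sprintf("image file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(m) m * scale)
}

#' Export a tibble to CSV
#'
#' Thin wrapper keeping CSV exports uniform (no row names, stable column
#' order); the matching reader is [utils::read.csv()] or `readr::read_csv()`.
#'
#' @param df A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
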