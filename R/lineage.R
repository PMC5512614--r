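#' Parse seam-cell names
#'
#' Seam cells are named by lineage (H1, H2, V1--V6, T), body side (L/R) and
#' a sublineage suffix over \{a, p\} naming the anterior/posterior daughter at
#' each division, e.g. `"V2L.pp"` is the posterior-posterior granddaughter of
#' the left V2 seam cell. The sublineage length equals the generation number.
#'
#' @param cell Character vector of seam-cell names.
#' @return A tibble with columns `cell`, `lineage`, `side`, `sublineage`,
#'   `generation`.
#' @examples
#' parse_seam_cell(c("V2L.pp", "H1R"))
#' @export
parse_seam_cell <- function(cell) {
  m <- regmatches(cell, regexec("^(H1|H2|V[1-6]|T)(L|R)(?:\\.([ap]+))?$", cell))
  bad <- vapply(m, length, 0L) == 0L
  if (any(bad)) {
    abort(sprintf(
      "unknown seam cell name(s): %s; lineage must be one of %s, side L or R, sublineage over {a,p}",
      paste(unique(cell[bad]), collapse = ", "),
      paste(seam_lineages, collapse = ", ")
    ))
  }
  sub <- vapply(m, function(x) if (length(x) >= 4) x[4] else "", "")
  tibble(
    cell = cell,
    lineage = factor(vapply(m, `[`, "", 2), levels = seam_lineages),
    side = vapply(m, `[`, "", 3),
    sublineage = sub,
    generation = nchar(sub)
  )
}

#' Validate a table of seam-cell division records
#'
#' The package represents lineages as one row per seam cell: the animal it
#' belongs to, its name, the larval stage it is assigned to, its division
#' class `d` (0 no division, 1 symmetric -- two seam daughters, 2 asymmetric
#' -- one seam daughter) and, for dividing cells, the division time in hours
#' after hatching.
#'
#' @param records A data frame with columns `animal`, `cell`, `stage`,
#'   `division_class` and `division_time_h`.
#' @return The validated records as a tibble, with parsed `lineage`, `side`,
#'   `sublineage` columns appended.
#' @export
seam_cell_records <- function(records) {
  need <- c("animal", "cell", "stage", "division_class", "division_time_h")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    abort(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  }
  if (!all(records$division_class %in% 0:2)) {
    abort("`division_class` must be 0 (none), 1 (symmetric) or 2 (asymmetric)")
  }
  if (!all(as.character(records$stage) %in% larval_stages)) {
    abort("`stage` must be one of L1, L2, L3, L4")
  }
  if (any(records$division_class > 0 & !is.finite(records$division_time_h))) {
    abort("dividing cells (class 1 or 2) need a finite `division_time_h`")
  }
  parsed <- parse_seam_cell(as.character(records$cell))
  out <- as_tibble(records)
  out$stage <- factor(as.character(out$stage), levels = larval_stages)
  dplyr::bind_cols(
    out[, setdiff(names(out), c("lineage", "side", "sublineage", "generation"))],
    parsed[, c("lineage", "side", "sublineage", "generation")]
  )
}

#' Relative division times within an animal
#'
#' For every division, the division time minus the mean division time over
#' all divisions of the same animal in the same larval stage (the mean is
#' taken over all nine lineages, H1--T, on both body sides). Seam cells at
#' the centre of the body typically divide before those near the head and
#' tail, so centre cells have negative and end cells positive relative
#' times.
#'
#' @param records Seam-cell division records (see [seam_cell_records()]).
#' @param stage Optional stage filter ("L1".."L4").
#' @return The dividing-cell rows with a `delta_t_h` column appended. Within
#'   each animal and stage `delta_t_h` has mean zero.
#' @export
relative_division_time <- function(records, stage = NULL) {
  rec <- seam_cell_records(records)
  rec <- dplyr::filter(rec, .data$division_class > 0)
  if (!is.null(stage)) {
    stage_chr <- match.arg(stage, larval_stages)
    rec <- dplyr::filter(rec, .data$stage == stage_chr)
  }
  dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(rec, .data$animal, .data$stage),
    delta_t_h = .data$division_time_h - mean(.data$division_time_h)
  ))
}

#' Animal-to-animal variability in division time
#'
#' Mean and sample standard deviation (n - 1 denominator) of the division
#' time of each named seam cell across animals, per stage. Wild-type animals
#' show a typical standard deviation of about 0.3 h.
#'
#' @param records Seam-cell division records for a cohort.
#' @param cell Optional single cell name; with it, the function errors if
#'   that cell divides in fewer than 2 animals.
#' @param stage Optional stage filter.
#' @return A tibble with columns `cell`, `stage`, `mean_h`, `sd_h`, `n`
#'   (cells observed dividing in at least 2 animals, unless `cell` is given).
#' @export
division_time_variability <- function(records, cell = NULL, stage = NULL) {
  rec <- seam_cell_records(records)
  rec <- dplyr::filter(rec, .data$division_class > 0)
  if (!is.null(stage)) {
    stage_chr <- match.arg(stage, larval_stages)
    rec <- dplyr::filter(rec, .data$stage == stage_chr)
  }
  out <- dplyr::summarise(
    dplyr::group_by(rec, .data$cell, .data$stage),
    mean_h = mean(.data$division_time_h),
    sd_h = sd(.data$division_time_h),
    n = dplyr::n(),
    .groups = "drop"
  )
  if (!is.null(cell)) {
    out <- dplyr::filter(out, .data$cell == !!cell)
    if (nrow(out) == 0 || any(out$n < 2)) {
      abort(sprintf("cell %s divides in fewer than 2 animals", cell))
    }
    return(out)
  }
  dplyr::filter(out, .data$n >= 2)
}

#' Lineage-error probability P(l, s)
#'
#' Compares mutant seam-cell lineages against a wild-type reference and
#' estimates, for each lineage `l` and larval stage `s`, the probability
#' that a division deviates from the wild-type division class. For each
#' seam cell `i` present in both the reference lineage and mutant animal
#' `w`, the comparison contributes `1 - delta(d_i^WT, d_i^M)` (Kronecker
#' delta on the division class); `P(l, s)` is the mean contribution over all
#' such (animal, cell) pairs of lineage `l` at stage `s`, pooling both body
#' sides.
#'
#' A lineage error is scored only at the first point at which a sublineage
#' deviates: cells created by an upstream error do not exist in the
#' reference lineage and are therefore excluded from the comparison by
#' construction, and cells whose wild-type descendants are missing in the
#' mutant (after a failed division) simply contribute no further
#' comparisons.
#'
#' @param wt Reference (wild-type) records for a single lineage: one row per
#'   seam cell with its stage and division class.
#' @param mutants Records for one or more mutant animals (`animal` column
#'   distinguishes them).
#' @return A `lineage_error` object: `table` (per lineage x stage counts and
#'   probabilities; `p` is `NA` where no shared cells exist), `matrix` (9 x 4
#'   matrix of P(l, s)), `stage_means`, `lineage_means` (means over defined
#'   entries), and overall counts. Supports [tidy()], [glance()] and
#'   `autoplot()`.
#' @export
lineage_error_probability <- function(wt, mutants) {
  wt_rec <- seam_cell_records(wt)
  mut_rec <- seam_cell_records(mutants)
  if (anyDuplicated(wt_rec$cell)) {
    abort("reference lineage has duplicated cell names")
  }
  ref <- dplyr::select(wt_rec, "cell", "lineage", "stage",
    wt_class = "division_class"
  )
  shared <- dplyr::inner_join(
    dplyr::select(mut_rec, "animal", "cell", mut_class = "division_class"),
    ref,
    by = "cell"
  )
  shared$mismatch <- as.integer(shared$wt_class != shared$mut_class)

  grid <- tidyr::expand_grid(
    lineage = factor(seam_lineages, levels = seam_lineages),
    stage = factor(larval_stages, levels = larval_stages)
  )
  tab <- dplyr::summarise(
    dplyr::group_by(shared, .data$lineage, .data$stage),
    n_cells = dplyr::n(),
    n_mismatch = sum(.data$mismatch),
    .groups = "drop"
  )
  tab$stage <- factor(as.character(tab$stage), levels = larval_stages)
  tab <- dplyr::left_join(grid, tab, by = c("lineage", "stage"))
  tab$n_cells[is.na(tab$n_cells)] <- 0L
  tab$n_mismatch[is.na(tab$n_mismatch)] <- 0L
  tab$p <- ifelse(tab$n_cells > 0, tab$n_mismatch / tab$n_cells, NA_real_)

  P <- matrix(tab$p, nrow = length(seam_lineages), byrow = TRUE,
    dimnames = list(seam_lineages, larval_stages)
  )
  structure(
    list(
      table = tab,
      matrix = P,
      stage_means = colMeans(P, na.rm = TRUE),
      lineage_means = rowMeans(P, na.rm = TRUE),
      n_animals = dplyr::n_distinct(mut_rec$animal),
      n_comparisons = sum(tab$n_cells),
      n_errors = sum(tab$n_mismatch)
    ),
    class = "lineage_error"
  )
}

#' @export
print.lineage_error <- function(x, ...) {
  cat(sprintf(
    "<lineage_error> %d mutant animal(s), %d/%d deviating divisions (rate %.3f)\n",
    x$n_animals, x$n_errors, x$n_comparisons,
    if (x$n_comparisons > 0) x$n_errors / x$n_comparisons else NA_real_
  ))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Tidy a lineage-error result
#'
#' @param x A `lineage_error` object.
#' @param ... Unused.
#' @return A tibble with one row per (lineage, stage): `n_cells`,
#'   `n_mismatch`, `p`.
#' @export
tidy.lineage_error <- function(x, ...) x$table

#' One-row summary of a lineage-error result
#'
#' @param x A `lineage_error` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_animals`, `n_comparisons`, `n_errors`,
#'   `error_rate`.
#' @export
glance.lineage_error <- function(x, ...) {
  tibble(
    n_animals = x$n_animals,
    n_comparisons = x$n_comparisons,
    n_errors = x$n_errors,
    error_rate = if (x$n_comparisons > 0) x$n_errors / x$n_comparisons else NA_real_
  )
}

#' Heatmap of P(l, s)
#'
#' @param object A `lineage_error` object.
#' @param ... Unused.
#' @return A ggplot object: lineage x stage tile map coloured by error
#'   probability, undefined entries blank.
#' @export
autoplot.lineage_error <- function(object, ...) {
  ggplot2::ggplot(
    object$table,
    ggplot2::aes(x = .data$stage, y = .data$lineage, fill = .data$p)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_discrete(limits = rev(seam_lineages)) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90") +
    ggplot2::labs(
      x = "larval stage", y = "seam cell lineage",
      fill = "P(l, s)", title = "Lineage-error probability"
    )
}
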