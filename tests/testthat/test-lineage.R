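make_records <- function(...) {
  rows <- list(...)
  tibble::tibble(
    animal = vapply(rows, `[[`, "", 1),
    cell = vapply(rows, `[[`, "", 2),
    stage = vapply(rows, `[[`, "", 3),
    division_class = as.integer(vapply(rows, function(r) r[[4]], 0)),
    division_time_h = vapply(rows, function(r) r[[5]], 0)
  )
}

test_that("seam cell names parse against the fixed vocabulary", {
  p <- parse_seam_cell(c("V2L.pp", "H1R", "TL.ap"))
  expect_equal(as.character(p$lineage), c("V2", "H1", "T"))
  expect_equal(p$side, c("L", "R", "L"))
  expect_equal(p$generation, c(2, 0, 2))
  expect_error(parse_seam_cell("Q1L"), "unknown seam cell")
  expect_error(parse_seam_cell("V1L.px"), "unknown seam cell")
})

test_that("relative division times are centred per animal and stage", {
  one <- make_records(list("a", "V1L", "L1", 2, 12))
  expect_equal(relative_division_time(one)$delta_t_h, 0)

  three <- make_records(
    list("a", "V1L", "L1", 2, 5),
    list("a", "V2L", "L1", 2, 6),
    list("a", "V3L", "L1", 2, 7)
  )
  expect_equal(relative_division_time(three)$delta_t_h, c(-1, 0, 1))

  # zero-mean invariant within every (animal, stage)
  cfg <- worm_config(seed = 2)
  tl <- withr::with_seed(2, generate_timeline(cfg))
  lin <- withr::with_seed(3, generate_lineage(cfg, tl, "a1"))
  rel <- relative_division_time(lin)
  means <- tapply(rel$delta_t_h, rel$stage, mean)
  expect_true(all(abs(means) < 1e-12))
})

test_that("planted centre-early/end-late timing offsets are recovered from a cohort", {
  cfg <- worm_config(seed = 31)
  cohort <- generate_cohort(cfg, n_animals = 16, trace_cells = character())
  rec <- dplyr::bind_rows(lapply(cohort$animals, `[[`, "lineage"))
  rel <- relative_division_time(rec, stage = "L1")
  pop <- dplyr::summarise(
    dplyr::group_by(rel, .data$lineage),
    mean_dt = mean(.data$delta_t_h),
    sem = sd(.data$delta_t_h) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  offsets <- cfg$lineage_offset_h - mean(cfg$lineage_offset_h)
  for (lin in c("V3", "T", "V5")) {
    row <- pop[pop$lineage == lin, ]
    expect_lt(abs(row$mean_dt - offsets[[lin]]), 2 * row$sem + 0.05)
  }
  # the planted ordering: V3 early, T late, V5 first
  expect_lt(pop$mean_dt[pop$lineage == "V5"], min(pop$mean_dt[pop$lineage %in% c("H1", "T")]))
})

test_that("division-time variability is the sample s.d. across animals", {
  rec <- make_records(
    list("a", "V1L", "L1", 2, 10), list("b", "V1L", "L1", 2, 10),
    list("c", "V1L", "L1", 2, 10), list("a", "V2L", "L1", 2, 10),
    list("b", "V2L", "L1", 2, 12)
  )
  v <- division_time_variability(rec)
  expect_equal(v$sd_h[v$cell == "V1L"], 0)
  expect_equal(v$sd_h[v$cell == "V2L"], sqrt(2), tolerance = 1e-9)
  expect_error(division_time_variability(rec[1, ], cell = "V1L"), "fewer than 2")
})

test_that("planted 0.3 h division noise is recovered within chi-square bounds", {
  # isolate cell-level noise: no timeline jitter
  cfg <- worm_config(seed = 41, stage_duration_sd_h = rep(0, 4))
  cohort <- generate_cohort(cfg, n_animals = 20, trace_cells = character())
  rec <- dplyr::bind_rows(lapply(cohort$animals, `[[`, "lineage"))
  v <- division_time_variability(rec, stage = "L3")
  # pooled over many cells, the typical s.d. sits well inside [0.2, 0.4]
  expect_gt(median(v$sd_h), 0.2)
  expect_lt(median(v$sd_h), 0.4)
})

test_that("identity and total-flip mutants give P = 0 and P = 1", {
  cfg <- worm_config(seed = 5)
  tl <- withr::with_seed(5, generate_timeline(cfg))
  wt <- withr::with_seed(6, generate_lineage(cfg, tl, "wt"))
  same <- dplyr::mutate(wt, animal = "m")
  expect_true(all(lineage_error_probability(wt, same)$matrix == 0, na.rm = TRUE))
  flipped <- dplyr::mutate(same, division_class = ifelse(.data$division_class == 2L, 1L, 2L))
  P1 <- lineage_error_probability(wt, flipped)$matrix
  expect_true(all(P1[is.finite(P1)] == 1))
})

test_that("the toy two-cell example gives P = 0.5", {
  wt <- make_records(
    list("wt", "V1L.pa", "L2", 2, 14),
    list("wt", "V1L.pp", "L2", 2, 14.5)
  )
  mut <- make_records(
    list("m1", "V1L.pa", "L2", 2, 14),
    list("m1", "V1L.pp", "L2", 1, 14.5)
  )
  pe <- lineage_error_probability(wt, mut)
  expect_equal(pe$matrix["V1", "L2"], 0.5)
  expect_true(all(is.na(pe$matrix[, c("L1", "L3", "L4")])))
  expect_equal(unname(pe$lineage_means["V1"]), 0.5)
  # matches the enumeration oracle
  expect_equal(pe$matrix, oracle_error_probability(wt, mut))
})

test_that("P(l,s) equals the enumeration oracle on randomized toy lineages", {
  withr::with_seed(99, {
    for (case in 1:30) {
      toy <- random_toy_lineages(n_mutants = sample(1:5, 1), max_gen = 3)
      got <- lineage_error_probability(toy$wt, toy$mutants)$matrix
      want <- oracle_error_probability(toy$wt, toy$mutants)
      expect_equal(got, want)
    }
  })
})

test_that("sublineages downstream of an error are excluded from scoring", {
  wt <- make_records(
    list("wt", "V1L", "L1", 2, 6), # -> V1L.p
    list("wt", "V1L.p", "L2", 2, 14), # -> V1L.pp
    list("wt", "V1L.pp", "L3", 2, 21)
  )
  # mutant converts the L1 division to symmetric: extra daughter V1L.a whose
  # whole subtree must not contribute anywhere
  mut <- make_records(
    list("m", "V1L", "L1", 1, 6),
    list("m", "V1L.a", "L2", 1, 14), # error-created cells, absent from wt
    list("m", "V1L.aa", "L3", 1, 21),
    list("m", "V1L.ap", "L3", 1, 21),
    list("m", "V1L.p", "L2", 2, 14),
    list("m", "V1L.pp", "L3", 2, 21)
  )
  pe <- lineage_error_probability(wt, mut)
  expect_equal(pe$matrix["V1", "L1"], 1) # the conversion itself
  expect_equal(pe$matrix["V1", "L2"], 0) # V1L.p unaffected
  expect_equal(pe$matrix["V1", "L3"], 0) # V1L.pp unaffected; .a* excluded
  expect_equal(glance(pe)$n_comparisons, 3)

  # planting the error must not change generation g+1 contributions
  mut_clean <- make_records(
    list("m", "V1L", "L1", 2, 6),
    list("m", "V1L.p", "L2", 2, 14),
    list("m", "V1L.pp", "L3", 2, 21)
  )
  pe_clean <- lineage_error_probability(wt, mut_clean)
  expect_equal(pe$matrix["V1", "L2"], pe_clean$matrix["V1", "L2"])
  expect_equal(pe$matrix["V1", "L3"], pe_clean$matrix["V1", "L3"])
})

test_that("a stochastic mutant cohort shows the planted error rate and summaries agree", {
  cfg <- worm_config(seed = 61)
  tl <- withr::with_seed(61, generate_timeline(cfg))
  wt <- withr::with_seed(62, generate_lineage(cfg, tl, "wt"))
  muts <- dplyr::bind_rows(lapply(1:6, function(i) {
    withr::with_seed(100 + i, generate_lineage(cfg, tl, paste0("m", i),
      p_symmetric = 62 / 456, p_nodivision = 9 / 456
    ))
  }))
  pe <- lineage_error_probability(wt, muts)
  g <- glance(pe)
  expect_gt(g$error_rate, 0.05)
  expect_lt(g$error_rate, 0.3)
  # row/column summaries are means over defined entries
  expect_equal(unname(pe$stage_means["L3"]), mean(pe$matrix[, "L3"], na.rm = TRUE))
  expect_equal(unname(pe$lineage_means["V6"]), mean(pe$matrix["V6", ], na.rm = TRUE))
  td <- tidy(pe)
  expect_equal(nrow(td), 36)
  expect_equal(sum(td$n_mismatch), g$n_errors)
  expect_s3_class(ggplot2::autoplot(pe), "ggplot")
})
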