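test_that("volume profile places its extremes where requested", {
  curve <- volume_profile(100, 40, 25, 0.4)
  expect_equal(max(curve$volume_ml), 100)
  expect_equal(min(curve$volume_ml), 40)
  expect_equal(which.max(curve$volume_ml), 1)
  expect_equal(which.min(curve$volume_ml), round(0.4 * 25) + 1)

  flat <- volume_profile(80, 80, 10, 0.4)
  expect_true(all(flat$volume_ml == 80))

  expect_error(volume_profile(40, 100, 25, 0.4), "edv")
  expect_error(volume_profile(100, 40, 25, 1.2), "es_phase_fraction")
})

test_that("volume profile is unimodal and its extremes are recovered by phase selection over a parameter grid", {
  for (n in c(12, 25, 33)) {
    for (f in c(0.3, 0.4, 0.5)) {
      curve <- volume_profile(140, 60, n, f)
      ph <- select_phases(curve)
      expect_equal(unname(ph["ed_phase"]), 1)
      expect_equal(unname(ph["es_phase"]),
                   min(max(round(f * n), 1), n - 1) + 1)
      # strictly monotone on both limbs
      es <- unname(ph["es_phase"])
      expect_true(all(diff(curve$volume_ml[1:es]) < 0))
      if (es < n) expect_true(all(diff(curve$volume_ml[es:n]) > 0))
    }
  }
})

test_that("rasterized phantoms hit their target volumes within tolerance and keep structures disjoint", {
  grid <- tiny_grid()
  vox <- 2.2^2 * 8 / 1000
  withr::with_seed(5, {
    for (rep in 1:8) {
      lv_edv <- runif(1, 80, 160)
      rv_edv <- runif(1, 90, 200)
      lv <- volume_profile(lv_edv, lv_edv * runif(1, 0.35, 0.6), 6, 0.4)
      rv <- volume_profile(rv_edv, rv_edv * runif(1, 0.4, 0.65), 6, 0.4)
      vol <- rasterize_phantom(lv, rv, grid)
      for (p in 1:6) {
        # independent voxel-count oracle: per-slice area summation
        for (st in c("LV", "RV")) {
          target <- if (st == "LV") lv$volume_ml[p] else rv$volume_ml[p]
          lab <- if (st == "LV") 1L else 2L
          per_slice <- apply(vol$labels[, , , p] == lab, 3, sum)
          oracle_ml <- sum(per_slice) * vox
          expect_lt(abs(oracle_ml - target) / target, 0.05)
          expect_equal(compute_volume(vol, p, st), oracle_ml)
        }
        # disjoint labels and contiguous slice coverage
        g <- vol$labels[, , , p]
        occ <- which(apply(g != 0L, 3, any))
        expect_equal(occ, min(occ):max(occ))
      }
    }
  })
})

test_that("zero-volume structures are absent from the rendered grid", {
  grid <- tiny_grid()
  lv <- volume_profile(100, 45, 4, 0.5)
  rv <- volume_profile(0, 0, 4, 0.5)
  vol <- rasterize_phantom(lv, rv, grid)
  expect_equal(sum(vol$labels == 2L), 0)
  expect_gt(sum(vol$labels == 1L), 0)
})

test_that("unachievable volumes raise a domain error", {
  grid <- phantom_grid(shape = c(24, 24), n_slices = 4,
                       in_plane_spacing_mm = 1, slice_thickness_mm = 5)
  lv <- volume_profile(500, 400, 3, 0.4)
  rv <- volume_profile(500, 400, 3, 0.4)
  expect_error(rasterize_phantom(lv, rv, grid), "unachievable")
})

test_that("degradation flips exactly its error budget and nothing else", {
  ref <- tiny_phantom()
  spec <- degradation_spec("RV", error_fraction = 0.05, seed = 3)
  auto <- degrade_segmentation(ref, spec, phases = c(1, 6))
  budget <- round(0.05 * sum(phase_labels(ref, 1) == 2L)) +
    round(0.05 * sum(phase_labels(ref, 6) == 2L))
  expect_equal(sum(auto$labels != ref$labels), budget)
  # untouched phases are identical
  for (p in setdiff(1:12, c(1, 6))) {
    expect_identical(auto$labels[, , , p], ref$labels[, , , p])
  }

  none <- degrade_segmentation(ref, degradation_spec("RV", error_fraction = 0),
                               phases = c(1, 6))
  expect_identical(none$labels, ref$labels)
})

test_that("degradation is deterministic for a fixed seed", {
  ref <- tiny_phantom()
  specs <- list(degradation_spec("RV", seed = 9), degradation_spec("LV", seed = 10))
  a <- degrade_segmentation(ref, specs, phases = c(1, 6))
  b <- degrade_segmentation(ref, specs, phases = c(1, 6))
  expect_identical(a$labels, b$labels)
})

test_that("allocation forced to one slice category lands every error there", {
  ref <- tiny_phantom()
  spec <- degradation_spec(
    "RV", error_fraction = 0.04,
    slice_allocation = c(basal = 1, mid = 0, apical = 0, outside = 0),
    seed = 2
  )
  auto <- degrade_segmentation(ref, spec, phases = c(1, 6))
  att <- attribute_errors(auto, ref, "RV", phases = c(1, 6))
  expect_gt(att$total_errors, 0)
  expect_equal(att$basal, 1)
  expect_equal(att$mid + att$apical + att$outside, 0)
})

test_that("cohort group sizes follow deterministic largest-remainder apportionment", {
  cohort <- generate_cohort(cohort_config(n_subjects = 157, seed = 1))
  expect_equal(unname(table(cohort$subjects$group)[c("control", "at_risk", "arvc")]),
               c(54, 66, 37), ignore_attr = TRUE)

  empty <- generate_cohort(cohort_config(n_subjects = 0))
  expect_equal(nrow(empty$subjects), 0)

  expect_error(cohort_config(group_proportions = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(generate_cohort(cohort_config(n_subjects = -3)), "non-negative")
})

test_that("cohorts regenerate bit-identically from the same config and seed", {
  cfg <- tiny_cohort_config(n_subjects = 4, seed = 21)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(cohort_reference(a, 2)$labels, cohort_reference(b, 2)$labels)
})

test_that("measured EF and indexed volumes of reference volumes stay within 3 SD of the group distributions", {
  cfg <- tiny_cohort_config(n_subjects = 9, seed = 31)
  cohort <- generate_cohort(cfg)
  for (i in seq_len(nrow(cohort$subjects))) {
    s <- cohort$subjects[i, ]
    m <- compute_measurements(cohort_reference(cohort, i), s$bsa_m2)
    rv <- m[m$structure == "RV", ]
    gp <- cfg$group_params[[s$group]]
    shift <- if (s$sex == "female") cfg$female_edvi_shift else 0
    expect_lt(abs(rv$ef_percent - gp$rvef[1]), 3 * gp$rvef[2] + 1)
    expect_lt(abs(rv$edvi_ml_m2 - (gp$rvedvi[1] + shift)), 3 * gp$rvedvi[2] + 1)
    # measured values also match this subject's own generator truth closely
    expect_lt(abs(rv$ef_percent - s$rvef_true), 1.5)
    expect_lt(abs(rv$edvi_ml_m2 - s$rvedvi_true) / s$rvedvi_true, 0.02)
  }
})

test_that("rendered images have the configured class structure and reproducible noise", {
  vol <- tiny_phantom(n_phases = 3)
  clean <- render_image(vol, noise_sd = 0, bias_field = FALSE)
  vals <- sort(unique(as.numeric(clean$intensities)))
  expect_true(length(vals) %in% 3:4)

  a <- render_image(vol, noise_sd = 10, seed = 4)
  b <- render_image(vol, noise_sd = 10, seed = 4)
  expect_identical(a$intensities, b$intensities)

  # class-conditional sample means recover the configured intensities
  noisy <- a$intensities
  for (lab in c(1L, 2L)) {
    mask <- vol$labels == lab
    n <- sum(mask)
    mu <- mean(noisy[mask])
    base <- c(180, 170)[lab]
    expect_lt(abs(mu - base), 2 * 10 / sqrt(n) + 0.5)
  }
})

test_that("cohort tables and config round-trip through disk", {
  cohort <- generate_cohort(tiny_cohort_config(n_subjects = 3, seed = 2))
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir, volumes = TRUE)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  expect_true(file.exists(file.path(dir, "cohort_config.json")))
  tab <- readr::read_csv(file.path(dir, "cohort.csv"), show_col_types = FALSE)
  expect_equal(nrow(tab), 3)
  back <- read_cine_nifti(tab$reference_path[1])
  expect_identical(back$labels, cohort_reference(cohort, 1)$labels)
})
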