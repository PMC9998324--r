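#' Experiment configuration
#'
#' Bundles everything [run_experiment()] needs: the cohort generator
#' settings, the per-structure degradation model, whether to pass the
#' rendered images through the toy segmentation network (off by default;
#' the generator's degraded volumes stand in for network output), the
#' basal-correction mode, and the Task Force thresholds.
#'
#' @param cohort a [cohort_config()].
#' @param degradation list of [degradation_spec()]s, one per structure.
#' @param use_network segment rendered images with a toy [seg_model()]
#'   instead of using the degradation model (slow; small cohorts only).
#' @param correction_mode `"basal"` (simulated expert correction of the
#'   most basal slice) or `"none"`.
#' @param thresholds a [tfc_thresholds()].
#' @param seed master seed; overrides the cohort seed so one integer
#'   reproduces the whole experiment.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              degradation = list(degradation_spec("RV"),
                                                 degradation_spec("LV")),
                              use_network = FALSE,
                              correction_mode = c("basal", "none"),
                              thresholds = tfc_thresholds(),
                              seed = 42L) {
  correction_mode <- match.arg(correction_mode)
  cohort$seed <- as.integer(seed)
  structure(
    list(cohort = cohort, degradation = degradation,
         use_network = use_network, correction_mode = correction_mode,
         thresholds = thresholds, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

measure_method <- function(vol, bsa, phases = NULL) {
  compute_measurements(vol, bsa, phases = phases)
}

#' Run the end-to-end synthetic experiment
#'
#' For every subject: build the reference segmentation, derive the
#' automatic-like segmentation (degradation model or toy network), apply
#' the simulated basal correction, compute manual / automatic / corrected
#' measurement sets and Task Force classifications, and aggregate all
#' agreement statistics (Dice and Hausdorff summaries, slice-wise error
#' attribution, Bland-Altman and Pearson agreement of measurements,
#' ED/ES phase agreement, Cohen's kappa, the classification transition
#' table, sensitivity/specificity and the McNemar test). Manual
#' measurements use the generator's ground-truth ED/ES phases; automatic
#' variants select phases from their own volume curves. Subjects whose
#' processing fails are excluded with a logged count, never silently.
#'
#' @param config an [experiment_config()].
#' @param verbose print per-stage progress.
#' @return object of class `arvc_experiment`.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  t0 <- Sys.time()
  cohort <- generate_cohort(config$cohort)
  subjects <- cohort$subjects
  n <- nrow(subjects)
  methods <- c("manual", "automatic",
               if (config$correction_mode == "basal") "automatic_minus_basal")

  meas_rows <- list(); seg_rows <- list(); attr_rows <- list()
  phase_rows <- list(); failed <- character(0)
  model <- if (config$use_network) seg_model(seed = config$seed) else NULL

  for (i in seq_len(n)) {
    s <- subjects[i, ]
    res <- tryCatch({
      ref <- cohort_reference(cohort, i)
      truth_phases <- c(s$ed_phase_true, s$es_phase_true)
      specs <- config$degradation
      for (j in seq_along(specs)) {
        specs[[j]]$seed <- s$degradation_seed + j - 1L
      }
      auto <- if (config$use_network) {
        img <- normalize_intensities(
          render_image(ref, noise_sd = 10, seed = s$degradation_seed)
        )
        segment_volume(model, img, seed = s$degradation_seed,
                       phases = truth_phases)
      } else {
        degrade_segmentation(ref, specs, phases = truth_phases)
      }
      vols <- list(manual = ref, automatic = auto)
      if (config$correction_mode == "basal") {
        vols$automatic_minus_basal <-
          apply_basal_correction(auto, ref, phases = truth_phases)
      }
      out_meas <- list(); out_seg <- list(); out_phase <- list()
      fixed <- list(LV = truth_phases, RV = truth_phases)
      for (m in names(vols)) {
        mm <- measure_method(vols[[m]], s$bsa_m2,
                             phases = if (m == "manual") fixed else NULL)
        out_meas[[m]] <- dplyr::mutate(mm, id = s$id, method = m,
                                       .before = 1)
        if (m != "manual") {
          for (st in c("LV", "RV")) {
            for (k in 1:2) {
              g_ref <- phase_labels(ref, truth_phases[k])
              g_m <- phase_labels(vols[[m]], truth_phases[k])
              sp <- c(ref$in_plane_spacing_mm, ref$slice_thickness_mm)
              out_seg[[paste(m, st, k)]] <- tibble(
                id = s$id, method = m, structure = st,
                phase_type = c("ED", "ES")[k],
                dice = dice3d(g_ref, g_m, st),
                hausdorff_mm = hausdorff3d(g_ref, g_m, st, sp)
              )
            }
            mrow <- out_meas[[m]][out_meas[[m]]$structure == st, ]
            out_phase[[paste(m, st)]] <- tibble(
              id = s$id, method = m, structure = st,
              ed_diff_pct = phase_difference(mrow$ed_phase, s$ed_phase_true,
                                             s$n_phases),
              es_diff_pct = phase_difference(mrow$es_phase, s$es_phase_true,
                                             s$n_phases)
            )
          }
        }
      }
      attr_sub <- dplyr::bind_rows(lapply(c("RV", "LV"), function(st) {
        dplyr::mutate(
          attribute_errors(auto, ref, st, phases = truth_phases),
          id = s$id, .before = 1
        )
      }))
      list(meas = dplyr::bind_rows(out_meas),
           seg = dplyr::bind_rows(out_seg),
           phase = dplyr::bind_rows(out_phase),
           attr = attr_sub)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, s$id)
      warn(sprintf("subject %s failed and was excluded: %s",
                   s$id, conditionMessage(res)))
      next
    }
    meas_rows[[i]] <- res$meas
    seg_rows[[i]] <- res$seg
    phase_rows[[i]] <- res$phase
    attr_rows[[i]] <- res$attr
    if (verbose && i %% 20 == 0) {
      message(sprintf("processed %d/%d subjects", i, n))
    }
  }

  measurements <- dplyr::bind_rows(meas_rows)
  seg_metrics <- dplyr::bind_rows(seg_rows)
  phases <- dplyr::bind_rows(phase_rows)
  attribution <- dplyr::bind_rows(attr_rows)

  tfc <- if (nrow(measurements) > 0) {
    measurements |>
      dplyr::filter(.data$structure == "RV") |>
      dplyr::left_join(
        subjects[, c("id", "sex", "rwma", "noncmr_points")], by = "id"
      ) |>
      dplyr::transmute(
        .data$id, .data$method, sex = .data$sex, rwma = .data$rwma,
        rvef_percent = .data$ef_percent, rvedvi_ml_m2 = .data$edvi_ml_m2,
        noncmr_points = .data$noncmr_points
      ) |>
      score_tfc(thresholds = config$thresholds)
  } else {
    tibble()
  }

  agreement <- aggregate_agreement(measurements, seg_metrics, attribution,
                                   phases, tfc, methods)

  structure(
    list(
      subjects = subjects,
      measurements = measurements,
      seg_metrics = seg_metrics,
      attribution = attribution,
      phases = phases,
      tfc = tfc,
      agreement = agreement,
      n_failed = length(failed),
      failed_ids = failed,
      config = config,
      runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ),
    class = "arvc_experiment"
  )
}

# all cohort-level agreement statistics, Table-2/3/4- and Fig-2/4-style
aggregate_agreement <- function(measurements, seg_metrics, attribution,
                                phases, tfc, methods) {
  auto_methods <- setdiff(methods, "manual")
  if (nrow(measurements) == 0) {
    return(list(
      dice_summary = tibble(), attribution_summary = tibble(),
      measurement_agreement = tibble(), phase_agreement = tibble(),
      kappa = tibble(), transitions = tibble(), diagnostics = tibble(),
      mcnemar = tibble()
    ))
  }
  dice_summary <- seg_metrics |>
    dplyr::group_by(.data$method, .data$structure, .data$phase_type) |>
    dplyr::summarise(
      dice_mean = mean(.data$dice), dice_sd = sd(.data$dice),
      hausdorff_mean = mean(.data$hausdorff_mm),
      hausdorff_sd = sd(.data$hausdorff_mm),
      .groups = "drop"
    )
  attribution_summary <- attribution |>
    dplyr::filter(.data$total_errors > 0) |>
    dplyr::group_by(.data$structure) |>
    dplyr::summarise(
      dplyr::across(c("basal", "mid", "apical", "outside"), mean),
      total_errors = sum(.data$total_errors),
      .groups = "drop"
    )

  manual <- measurements |> dplyr::filter(.data$method == "manual")
  meas_long <- function(df) {
    tidyr::pivot_longer(
      df[, c("id", "structure", "edv_ml", "esv_ml", "sv_ml", "ef_percent")],
      c("edv_ml", "esv_ml", "sv_ml", "ef_percent"),
      names_to = "measure", values_to = "value"
    )
  }
  man_long <- meas_long(manual)
  measurement_agreement <- dplyr::bind_rows(lapply(auto_methods, function(m) {
    aut <- meas_long(measurements |> dplyr::filter(.data$method == m))
    joined <- dplyr::inner_join(aut, man_long,
                                by = c("id", "structure", "measure"),
                                suffix = c("_auto", "_manual"))
    joined |>
      dplyr::group_by(.data$structure, .data$measure) |>
      dplyr::group_modify(function(d, g) {
        ba <- bland_altman(d$value_auto, d$value_manual)
        pr <- if (sd(d$value_manual) > 0 && sd(d$value_auto) > 0) {
          pearson_r(d$value_auto, d$value_manual)
        } else {
          tibble(r = NA_real_, conf_low = NA_real_, conf_high = NA_real_,
                 n = nrow(d))
        }
        dplyr::bind_cols(ba, pr[, c("r", "conf_low", "conf_high")])
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(method = m, .before = 1)
  }))

  phase_agreement <- if (nrow(phases) > 0) {
    phases |>
      tidyr::pivot_longer(c("ed_diff_pct", "es_diff_pct"),
                          names_to = "phase_type", values_to = "diff_pct") |>
      dplyr::mutate(phase_type = ifelse(.data$phase_type == "ed_diff_pct",
                                        "ED", "ES")) |>
      dplyr::group_by(.data$method, .data$structure, .data$phase_type) |>
      dplyr::summarise(
        bias = mean(.data$diff_pct),
        loa_low = mean(.data$diff_pct) - 1.96 * sd(.data$diff_pct),
        loa_high = mean(.data$diff_pct) + 1.96 * sd(.data$diff_pct),
        exact_match = mean(.data$diff_pct == 0),
        .groups = "drop"
      )
  } else {
    tibble()
  }

  man_tfc <- tfc |> dplyr::filter(.data$method == "manual")
  kappa <- dplyr::bind_rows(lapply(auto_methods, function(m) {
    at <- tfc |> dplyr::filter(.data$method == m)
    at <- at[match(man_tfc$id, at$id), ]
    dplyr::mutate(cohens_kappa(man_tfc$cmr_category, at$cmr_category),
                  method = m, .before = 1)
  }))
  trans_method <- if ("automatic_minus_basal" %in% auto_methods) {
    "automatic_minus_basal"
  } else {
    auto_methods[1]
  }
  at <- tfc |> dplyr::filter(.data$method == trans_method)
  at <- at[match(man_tfc$id, at$id), ]
  transitions <- tfc_transition_table(man_tfc$cmr_category, at$cmr_category)

  diagnosis_ref <- man_tfc$definite_diagnosis
  diagnostics <- dplyr::bind_rows(lapply(methods, function(m) {
    mt <- tfc |> dplyr::filter(.data$method == m)
    mt <- mt[match(man_tfc$id, mt$id), ]
    dplyr::bind_rows(
      dplyr::mutate(
        sens_spec(mt$cmr_category %in% c("minor", "major"), diagnosis_ref),
        method = m, criterion = "minor_or_major", .before = 1
      ),
      dplyr::mutate(
        sens_spec(mt$cmr_category == "major", diagnosis_ref),
        method = m, criterion = "major", .before = 1
      )
    )
  }))
  mcnemar <- dplyr::bind_rows(lapply(auto_methods, function(m) {
    mt <- tfc |> dplyr::filter(.data$method == m)
    mt <- mt[match(man_tfc$id, mt$id), ]
    tibble(
      method = m,
      p_value = mcnemar_p(man_tfc$cmr_category %in% c("minor", "major"),
                          mt$cmr_category %in% c("minor", "major"))
    )
  }))

  list(
    dice_summary = dice_summary,
    attribution_summary = attribution_summary,
    measurement_agreement = measurement_agreement,
    phase_agreement = phase_agreement,
    kappa = kappa,
    transitions = transitions,
    diagnostics = diagnostics,
    mcnemar = mcnemar
  )
}

#' @export
print.arvc_experiment <- function(x, ...) {
  cat(sprintf("<arvc_experiment> %d subjects (%d failed), seed %d, %.1f s\n",
              nrow(x$subjects), x$n_failed, x$config$seed, x$runtime_s))
  if (nrow(x$agreement$kappa) > 0) {
    for (i in seq_len(nrow(x$agreement$kappa))) {
      cat(sprintf("  kappa (%s vs manual): %.3f +/- %.3f\n",
                  x$agreement$kappa$method[i], x$agreement$kappa$kappa[i],
                  x$agreement$kappa$se[i]))
    }
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an experiment into per-subject measurement rows
#'
#' @param x an `arvc_experiment`.
#' @param ... unused.
#' @return tibble: one row per subject, method and structure.
#' @export
tidy.arvc_experiment <- function(x, ...) {
  x$measurements
}

#' One-row summary of an experiment
#'
#' @param x an `arvc_experiment`.
#' @param ... unused.
#' @return one-row tibble with cohort size, exclusion count, Dice means,
#'   the RV basal error fraction, and kappa of the corrected automatic
#'   classification against manual.
#' @export
glance.arvc_experiment <- function(x, ...) {
  kap <- x$agreement$kappa
  best <- if (nrow(kap) > 0) kap[nrow(kap), ] else
    tibble(kappa = NA_real_, se = NA_real_)
  attr_rv <- x$agreement$attribution_summary
  attr_rv <- attr_rv[attr_rv$structure == "RV", ]
  tibble(
    n_subjects = nrow(x$subjects),
    n_failed = x$n_failed,
    mean_dice_auto = mean(x$seg_metrics$dice[
      x$seg_metrics$method == "automatic"]),
    mean_dice_corrected = if (any(x$seg_metrics$method ==
                                    "automatic_minus_basal")) {
      mean(x$seg_metrics$dice[x$seg_metrics$method ==
                                "automatic_minus_basal"])
    } else NA_real_,
    rv_basal_error_fraction = if (nrow(attr_rv)) attr_rv$basal else NA_real_,
    kappa = best$kappa,
    kappa_se = best$se
  )
}

#' Render an experiment report as Markdown
#'
#' Tables mirror the standard reporting layout: segmentation performance
#' (Dice/Hausdorff, automatic vs corrected), error attribution by slice
#' location, measurement agreement (bias (SD) and Pearson r), the
#' classification transition table, diagnostic performance and kappa,
#' with the seed and configuration noted.
#'
#' @param x an `arvc_experiment`.
#' @return character vector of Markdown lines.
#' @export
report_markdown <- function(x) {
  fmt_tbl <- function(df) {
    if (nrow(df) == 0) return("*(empty)*")
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) signif(v, 4))
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                            " |"))
    c(header, sep, rows)
  }
  a <- x$agreement
  c(
    "# Synthetic ARVC CMR experiment report",
    "",
    sprintf("Subjects: %d (%d excluded after failures). Seed: %d.",
            nrow(x$subjects), x$n_failed, x$config$seed),
    sprintf("Correction mode: %s. Network stage: %s.",
            x$config$correction_mode,
            if (x$config$use_network) "on" else "off"),
    "",
    "## Segmentation performance (Dice / Hausdorff)",
    fmt_tbl(a$dice_summary),
    "",
    "## Distribution of segmentation errors across slices",
    fmt_tbl(a$attribution_summary),
    "",
    "## Measurement agreement vs manual (bias (SD), Pearson r)",
    fmt_tbl(a$measurement_agreement),
    "",
    "## ED/ES phase agreement (percent of cycle)",
    fmt_tbl(a$phase_agreement),
    "",
    "## CMR TFC classification agreement",
    fmt_tbl(a$kappa),
    "",
    "## Classification transitions (manual rows, automatic columns)",
    fmt_tbl(a$transitions),
    "",
    "## Diagnostic performance vs manual definite diagnosis",
    fmt_tbl(a$diagnostics),
    "",
    "## McNemar comparison of criterion positivity",
    fmt_tbl(a$mcnemar)
  )
}

#' Write the experiment report to disk
#'
#' Emits `report.md`, `report.json` (all agreement tables plus
#' configuration), and per-subject CSVs of measurements and
#' classifications.
#'
#' @param x an `arvc_experiment`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(report_markdown(x), file.path(dir, "report.md"))
  payload <- list(
    seed = x$config$seed,
    n_subjects = nrow(x$subjects),
    n_failed = x$n_failed,
    correction_mode = x$config$correction_mode,
    agreement = lapply(x$agreement, as.data.frame)
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  readr::write_csv(x$measurements, file.path(dir, "measurements.csv"))
  if (nrow(x$tfc) > 0) readr::write_csv(x$tfc, file.path(dir, "tfc.csv"))
  invisible(dir)
}
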