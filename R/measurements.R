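#' Percentile intensity normalization
#'
#' Rescales an intensity image to `[0, 1]` based on its per-scan 1st and
#' 99th percentiles: values below the 1st percentile map to 0, above the
#' 99th to 1, and the range between them linearly.
#'
#' @param image numeric array or a `cine_intensity_volume`.
#' @return the same type with intensities in `[0, 1]`.
#' @export
normalize_intensities <- function(image) {
  if (inherits(image, "cine_intensity_volume")) {
    image$intensities <- normalize_intensities(image$intensities)
    return(image)
  }
  if (length(image) == 0) abort("`image` is empty.")
  p <- quantile(image, c(0.01, 0.99), names = FALSE)
  if (p[2] <= p[1]) {
    warn("constant image: normalization returns all zeros.")
    image[] <- 0
    return(image)
  }
  image[] <- pmin(pmax((image - p[1]) / (p[2] - p[1]), 0), 1)
  image
}

#' Voxel-count volume of one structure at one phase
#'
#' @param labelvol a `cine_label_volume`.
#' @param phase cardiac phase (1-based).
#' @param structure `"LV"` or `"RV"`.
#' @return volume in ml (0 when the structure is absent).
#' @export
compute_volume <- function(labelvol, phase, structure) {
  if (phase < 1 || phase > n_phases(labelvol)) {
    abort("`phase` outside the cine range.")
  }
  n <- sum(labelvol$labels[, , , phase] == structure_label(structure))
  n * voxel_volume_ml(labelvol)
}

#' Volume-time curve of one structure
#'
#' @param labelvol a `cine_label_volume`.
#' @param structure `"LV"` or `"RV"`.
#' @return a `volume_curve` tibble (`phase`, `volume_ml`).
#' @export
volume_curve <- function(labelvol, structure) {
  label <- structure_label(structure)
  vox <- voxel_volume_ml(labelvol)
  v <- vapply(seq_len(n_phases(labelvol)), function(p) {
    sum(labelvol$labels[, , , p] == label) * vox
  }, numeric(1))
  out <- tibble(phase = seq_len(n_phases(labelvol)), volume_ml = v)
  class(out) <- c("volume_curve", class(out))
  attr(out, "structure") <- toupper(structure)
  out
}

#' Automatic ED/ES phase selection
#'
#' End-diastole is the phase with maximal segmented volume, end-systole
#' the phase with minimal volume; ties resolve to the earliest phase.
#'
#' @param curve a `volume_curve` (or any tibble with `volume_ml`).
#' @return named integer vector `c(ed_phase, es_phase)` (1-based).
#' @export
select_phases <- function(curve) {
  v <- curve$volume_ml
  if (length(v) == 0) abort("empty volume curve.")
  if (all(v == 0)) abort("all-zero volume curve: empty segmentation.")
  c(ed_phase = which.max(v), es_phase = which.min(v))
}

#' Most basal occupied slice at one phase
#'
#' Slices are ordered apex to base, so the basal slice is the highest
#' occupied slice index. With `scope = "volume"` (default) occupancy is
#' the union of LV and RV labels over all supplied volumes (e.g. reference
#' and automatic segmentation together); with `scope = "structure"` only
#' the given structure of the first volume counts.
#'
#' @param labelvol a `cine_label_volume`, or a list of them whose union
#'   defines occupancy.
#' @param phase cardiac phase.
#' @param scope `"volume"` or `"structure"`.
#' @param structure required when `scope = "structure"`.
#' @return slice index.
#' @export
basal_slice_index <- function(labelvol, phase, scope = c("volume", "structure"),
                              structure = NULL) {
  scope <- match.arg(scope)
  vols <- if (inherits(labelvol, "cine_label_volume")) list(labelvol) else labelvol
  if (scope == "structure") {
    if (is.null(structure)) abort("`structure` required for structure scope.")
    occ <- occupied_slices(phase_labels(vols[[1]], phase),
                           structure_label(structure))
  } else {
    occ <- integer(0)
    for (v in vols) {
      g <- phase_labels(v, phase)
      occ <- union(occ, which(apply(g != 0L, 3, any)))
    }
  }
  if (length(occ) == 0) abort("no foreground voxels at this phase.")
  max(occ)
}

#' Simulated expert correction of the most basal slice
#'
#' Replaces, at each listed phase, the automatic segmentation of the most
#' basal slice of the CMR volume (union extent of both segmentations and
#' both structures) wholesale with the corresponding manual reference
#' slice. No other voxel is touched. This emulates the clinical scenario
#' in which an expert redraws only the basal slice of an automatic
#' segmentation.
#'
#' @param auto automatic `cine_label_volume`.
#' @param reference manual reference `cine_label_volume` on the same grid.
#' @param phases phases to correct; `NULL` corrects the ED and ES phases
#'   of the reference total-volume curve.
#' @return corrected `cine_label_volume` (the "automatic minus basal"
#'   variant).
#' @export
apply_basal_correction <- function(auto, reference, phases = NULL) {
  if (!identical(dim(auto$labels), dim(reference$labels)) ||
      !isTRUE(all.equal(auto$in_plane_spacing_mm,
                        reference$in_plane_spacing_mm)) ||
      !isTRUE(all.equal(auto$slice_thickness_mm,
                        reference$slice_thickness_mm))) {
    abort("automatic and reference volumes must share grid and spacing.")
  }
  if (is.null(phases)) {
    total <- volume_curve(reference, "LV")$volume_ml +
      volume_curve(reference, "RV")$volume_ml
    phases <- c(which.max(total), which.min(total))
  }
  out <- auto
  for (p in unique(phases)) {
    b <- basal_slice_index(list(reference, auto), p, scope = "volume")
    out$labels[, , b, p] <- reference$labels[, , b, p]
  }
  out
}

#' Clinical measurement set from a cine segmentation
#'
#' Selects ED/ES phases per ventricle independently (each from its own
#' volume curve), then derives EDV, ESV, SV = EDV - ESV,
#' EF = 100 * SV / EDV, and body-surface-area indexed volumes
#' EDVI = EDV / BSA and ESVI = ESV / BSA.
#'
#' @param labelvol a `cine_label_volume`.
#' @param bsa_m2 body surface area in m^2.
#' @param phases optional fixed phase pair, a list like
#'   `list(LV = c(ed, es), RV = c(ed, es))` (e.g. manually selected
#'   phases); `NULL` selects phases automatically per structure.
#' @return tibble of class `measurement_set`, one row per structure, with
#'   columns `structure`, `ed_phase`, `es_phase`, `edv_ml`, `esv_ml`,
#'   `sv_ml`, `ef_percent`, `edvi_ml_m2`, `esvi_ml_m2`.
#' @examples
#' arr <- array(0L, dim = c(16, 16, 4, 4))
#' arr[4:11, 4:11, 2:3, 1] <- 1L # big at phase 1
#' arr[6:9, 6:9, 2:3, 3] <- 1L   # small at phase 3
#' arr[4:5, 4:5, 2, c(2, 4)] <- 1L
#' arr[13:14, 4:8, 2:3, ] <- 2L
#' m <- compute_measurements(cine_label_volume(arr, c(2, 2), 10), bsa_m2 = 1.8)
#' m[m$structure == "LV", c("ef_percent", "edvi_ml_m2")]
#' @export
compute_measurements <- function(labelvol, bsa_m2, phases = NULL) {
  if (bsa_m2 <= 0) abort("`bsa_m2` must be positive.")
  rows <- lapply(c("LV", "RV"), function(s) {
    curve <- volume_curve(labelvol, s)
    ph <- if (is.null(phases)) select_phases(curve) else phases[[s]]
    edv <- curve$volume_ml[ph[1]]
    esv <- curve$volume_ml[ph[2]]
    if (edv <= 0) abort(sprintf("%s end-diastolic volume is 0: EF undefined.", s))
    tibble(
      structure = s,
      ed_phase = as.integer(ph[1]),
      es_phase = as.integer(ph[2]),
      edv_ml = edv,
      esv_ml = esv,
      sv_ml = edv - esv,
      ef_percent = 100 * (edv - esv) / edv,
      edvi_ml_m2 = edv / bsa_m2,
      esvi_ml_m2 = esv / bsa_m2
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("measurement_set", class(out))
  out
}

#' Body surface area
#'
#' Mosteller: `sqrt(height_cm * weight_kg / 3600)`. DuBois:
#' `0.007184 * height_cm^0.725 * weight_kg^0.425`.
#'
#' @param height_cm height in centimetres.
#' @param weight_kg weight in kilograms.
#' @return body surface area in m^2.
#' @examples
#' bsa_mosteller(180, 80) # 2
#' @export
bsa_mosteller <- function(height_cm, weight_kg) {
  if (any(height_cm <= 0) || any(weight_kg <= 0)) {
    abort("height and weight must be positive.")
  }
  sqrt(height_cm * weight_kg / 3600)
}

#' @rdname bsa_mosteller
#' @export
bsa_dubois <- function(height_cm, weight_kg) {
  if (any(height_cm <= 0) || any(weight_kg <= 0)) {
    abort("height and weight must be positive.")
  }
  0.007184 * height_cm^0.725 * weight_kg^0.425
}
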