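#' CMR Task Force Criteria thresholds
#'
#' The 2010 Task Force cutoffs for the CMR (global/regional dysfunction
#' and structural alteration) category. A criterion requires a regional RV
#' wall-motion abnormality *plus* an RV ejection-fraction or sex-specific
#' indexed RV end-diastolic-volume cutoff: major when RVEF <= 40% or
#' RVEDVI >= 110 ml/m^2 (men) / >= 100 ml/m^2 (women); minor when
#' 40 < RVEF <= 45% or RVEDVI in [100, 110) (men) / [90, 100) (women).
#'
#' The female major comparator is `>=` 100 by default (the Methods-style
#' reading); set `female_major_strict = TRUE` for a strict `>` 100
#' comparison. The two readings differ only for an RVEDVI of exactly
#' 100 ml/m^2.
#'
#' @param female_major_strict use `>` instead of `>=` at the female major
#'   RVEDVI cutoff.
#' @return list of class `tfc_thresholds`.
#' @export
tfc_thresholds <- function(female_major_strict = FALSE) {
  structure(
    list(
      rvef_major = 40,
      rvef_minor = 45,
      rvedvi_major = c(male = 110, female = 100),
      rvedvi_minor = c(male = 100, female = 90),
      female_major_strict = female_major_strict,
      diagnosis_points = 4L
    ),
    class = "tfc_thresholds"
  )
}

#' Classify the CMR Task Force criterion
#'
#' Applies the sex-specific 2010 CMR criteria to one or more subjects.
#' Without a regional RV wall-motion abnormality the category is `none`
#' regardless of volumes; otherwise major takes precedence over minor.
#' Volumes are compared at full floating precision.
#'
#' @param sex `"male"` or `"female"` (vectorized).
#' @param rwma logical, regional RV wall-motion abnormality present.
#' @param rvef_percent RV ejection fraction (%).
#' @param rvedvi_ml_m2 indexed RV end-diastolic volume (ml/m^2).
#' @param thresholds a [tfc_thresholds()].
#' @return character vector with levels `none`, `minor`, `major`.
#' @examples
#' classify_cmr("female", TRUE, 55, 102) # major
#' classify_cmr("female", TRUE, 55, 97)  # minor
#' classify_cmr("male", FALSE, 30, 150)  # none: rwma is a prerequisite
#' @export
classify_cmr <- function(sex, rwma, rvef_percent, rvedvi_ml_m2,
                         thresholds = tfc_thresholds()) {
  n <- max(length(sex), length(rwma), length(rvef_percent),
           length(rvedvi_ml_m2))
  sex <- rep(tolower(sex), length.out = n)
  if (!all(sex %in% c("male", "female"))) {
    abort("`sex` must be 'male' or 'female'.")
  }
  rwma <- rep(rwma, length.out = n)
  rvef <- rep(rvef_percent, length.out = n)
  rvedvi <- rep(rvedvi_ml_m2, length.out = n)
  if (any(rvef < 0 | rvef > 100, na.rm = TRUE) || any(rvedvi < 0, na.rm = TRUE)) {
    abort("RVEF must lie in [0, 100] and RVEDVI must be non-negative.")
  }
  maj_cut <- thresholds$rvedvi_major[sex]
  min_cut <- thresholds$rvedvi_minor[sex]
  edvi_major <- ifelse(sex == "female" & thresholds$female_major_strict,
                       rvedvi > maj_cut, rvedvi >= maj_cut)
  major <- rwma & (rvef <= thresholds$rvef_major | edvi_major)
  minor <- rwma & !major &
    ((rvef > thresholds$rvef_major & rvef <= thresholds$rvef_minor) |
       (rvedvi >= min_cut & !edvi_major))
  out <- rep("none", n)
  out[minor] <- "minor"
  out[major] <- "major"
  out
}

#' Total Task Force score and diagnosis
#'
#' Adds the CMR category points (none = 0, minor = 1, major = 2) to the
#' points contributed by the five non-CMR Task Force categories; a
#' definite ARVC diagnosis requires at least four points in total.
#'
#' @param noncmr_points integer in `[0, 10]`, the summed non-CMR category
#'   points (vectorized).
#' @param cmr_category `"none"`, `"minor"` or `"major"`.
#' @param thresholds a [tfc_thresholds()] (supplies the diagnosis cutoff).
#' @return tibble of class `tfc_result` with columns `cmr_category`,
#'   `cmr_points`, `noncmr_points`, `total_points`, `definite_diagnosis`.
#' @examples
#' total_tfc(3, "minor") # 4 points: still a definite diagnosis
#' @export
total_tfc <- function(noncmr_points, cmr_category,
                      thresholds = tfc_thresholds()) {
  n <- max(length(noncmr_points), length(cmr_category))
  noncmr_points <- rep(as.integer(noncmr_points), length.out = n)
  cmr_category <- rep(cmr_category, length.out = n)
  if (any(noncmr_points < 0 | noncmr_points > 10)) {
    abort("`noncmr_points` must lie in [0, 10].")
  }
  if (!all(cmr_category %in% c("none", "minor", "major"))) {
    abort("`cmr_category` must be none, minor or major.")
  }
  pts <- c(none = 0L, minor = 1L, major = 2L)[cmr_category]
  out <- tibble(
    cmr_category = cmr_category,
    cmr_points = unname(pts),
    noncmr_points = noncmr_points,
    total_points = noncmr_points + unname(pts),
    definite_diagnosis = noncmr_points + unname(pts) >=
      thresholds$diagnosis_points
  )
  class(out) <- c("tfc_result", class(out))
  out
}

#' Score the Task Force Criteria for a subject table
#'
#' Data-frame-first wrapper chaining [classify_cmr()] and [total_tfc()]:
#' takes one row per subject with sex, wall-motion flag, RV measurements
#' and non-CMR points, and appends the CMR category, points and diagnosis
#' columns.
#'
#' @param data data frame with columns `sex`, `rwma`, `rvef_percent`,
#'   `rvedvi_ml_m2`, `noncmr_points` (names remappable via arguments).
#' @param sex,rwma,rvef,rvedvi,noncmr column names (strings).
#' @param thresholds a [tfc_thresholds()].
#' @return the input tibble with `cmr_category`, `cmr_points`,
#'   `total_points` and `definite_diagnosis` appended.
#' @export
score_tfc <- function(data, sex = "sex", rwma = "rwma",
                      rvef = "rvef_percent", rvedvi = "rvedvi_ml_m2",
                      noncmr = "noncmr_points",
                      thresholds = tfc_thresholds()) {
  cat_ <- classify_cmr(data[[sex]], data[[rwma]], data[[rvef]],
                       data[[rvedvi]], thresholds)
  res <- total_tfc(data[[noncmr]], cat_, thresholds)
  dplyr::bind_cols(
    as_tibble(data),
    res[, c("cmr_category", "cmr_points", "total_points",
            "definite_diagnosis")]
  )
}

#' Write TFC thresholds as JSON
#'
#' Externalizes the cutoffs for auditability.
#'
#' @param thresholds a [tfc_thresholds()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tfc_thresholds <- function(thresholds, path) {
  x <- unclass(thresholds)
  x$rvedvi_major <- as.list(x$rvedvi_major)
  x$rvedvi_minor <- as.list(x$rvedvi_minor)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
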