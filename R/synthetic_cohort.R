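#' Cyclic ventricular volume curve
#'
#' Builds a smooth, strictly unimodal volume-time curve over one cardiac
#' cycle from end-diastolic and end-systolic volumes. By generator
#' convention end-diastole is the first phase (global maximum); end-systole
#' falls at `round(es_phase_fraction * n_phases)` phases later (global
#' minimum). The two limbs are half-cosines, so the curve is smooth at both
#' extremes and cyclic (phase `n_phases + 1` would return to the ED value).
#'
#' @param edv_ml end-diastolic volume (ml), the curve maximum.
#' @param esv_ml end-systolic volume (ml), the curve minimum;
#'   `esv_ml <= edv_ml` and `esv_ml > 0` unless both are 0.
#' @param n_phases number of cardiac phases (>= 2).
#' @param es_phase_fraction position of end-systole as a fraction of the
#'   cycle, strictly inside (0, 1).
#' @param structure optional structure tag ("LV" or "RV") carried as an
#'   attribute.
#' @return A tibble of class `volume_curve` with columns `phase` (1-based)
#'   and `volume_ml`.
#' @examples
#' curve <- volume_profile(100, 40, 25, 0.4)
#' curve$volume_ml[1]   # 100 at end-diastole
#' min(curve$volume_ml) # 40 at end-systole
#' @export
volume_profile <- function(edv_ml, esv_ml, n_phases, es_phase_fraction = 0.4,
                           structure = NULL) {
  if (edv_ml < esv_ml) abort("`edv_ml` must be >= `esv_ml`.")
  if (esv_ml < 0) abort("volumes must be non-negative.")
  if (n_phases < 2) abort("`n_phases` must be at least 2.")
  if (es_phase_fraction <= 0 || es_phase_fraction >= 1) {
    abort("`es_phase_fraction` must lie strictly inside (0, 1).")
  }
  es0 <- min(max(round(es_phase_fraction * n_phases), 1L), n_phases - 1L)
  p0 <- seq_len(n_phases) - 1L # 0-based phase offsets from ED
  amp <- edv_ml - esv_ml
  v <- ifelse(
    p0 <= es0,
    esv_ml + amp * (1 + cos(pi * p0 / es0)) / 2,
    esv_ml + amp * (1 - cos(pi * (p0 - es0) / (n_phases - es0))) / 2
  )
  out <- tibble(phase = seq_len(n_phases), volume_ml = v)
  class(out) <- c("volume_curve", class(out))
  attr(out, "structure") <- structure
  attr(out, "ed_phase") <- 1L
  attr(out, "es_phase") <- es0 + 1L
  out
}

#' Phantom grid specification
#'
#' Geometry of the synthetic short-axis stack: in-plane matrix size, number
#' of slices, voxel spacing, and the contiguous slice range the ventricles
#' occupy (apex..base). One empty slice is left below the apex and above
#' the base so that out-of-extent segmentation errors have somewhere to
#' live, as they do on real scans where the stack extends past the heart.
#'
#' @param shape in-plane matrix size, length-2 integer (rows, cols).
#' @param n_slices number of short-axis slices.
#' @param in_plane_spacing_mm in-plane voxel spacing (mm), scalar or
#'   length 2.
#' @param slice_thickness_mm slice thickness (mm).
#' @param slice_extent slices occupied by the ventricles, length-2
#'   (most apical, most basal); defaults to `c(2, n_slices - 1)`.
#' @param lv_center in-plane LV centre (row, col); defaults to mid-row and
#'   60% of the columns, with the RV crescent opening toward column 1.
#' @param apical_taper relative cross-sectional area of the most apical
#'   occupied slice (the per-slice area ramps linearly up to 1 at the
#'   base).
#' @return list of class `phantom_grid`.
#' @export
phantom_grid <- function(shape = c(160, 160), n_slices = 12,
                         in_plane_spacing_mm = 1.25, slice_thickness_mm = 8,
                         slice_extent = NULL, lv_center = NULL,
                         apical_taper = 0.5) {
  shape <- as.integer(rep(shape, length.out = 2L))
  if (is.null(slice_extent)) slice_extent <- c(2L, n_slices - 1L)
  if (slice_extent[1] < 1 || slice_extent[2] > n_slices ||
      slice_extent[1] > slice_extent[2]) {
    abort("`slice_extent` must be a valid slice range inside the grid.")
  }
  if (is.null(lv_center)) {
    lv_center <- c(round(shape[1] / 2), round(shape[2] * 0.60))
  }
  structure(
    list(
      shape = shape,
      n_slices = as.integer(n_slices),
      in_plane_spacing_mm = rep(as.numeric(in_plane_spacing_mm),
                                length.out = 2L),
      slice_thickness_mm = as.numeric(slice_thickness_mm),
      slice_extent = as.integer(slice_extent),
      lv_center = as.numeric(lv_center),
      apical_taper = as.numeric(apical_taper)
    ),
    class = "phantom_grid"
  )
}

# In-plane geometry tables reused across slices and phases: pixel orderings
# by distance from the LV centre, for the LV disc and the RV crescent
# candidate wedge (pixels within 110 degrees of the direction the RV opens
# toward).
phantom_geometry <- function(grid) {
  nr <- grid$shape[1]
  nc <- grid$shape[2]
  cr <- grid$lv_center[1]
  cc <- grid$lv_center[2]
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  dr <- rows - cr
  dc <- cols - cc
  d <- sqrt(dr^2 + dc^2)
  ord_lv <- order(d, seq_along(d))
  # RV wedge opens toward decreasing column index
  cosang <- ifelse(d > 0, -dc / d, -1)
  wedge <- cosang > cos(110 * pi / 180)
  cand <- which(wedge)
  cand <- cand[order(d[cand], cand)]
  list(
    lin_by_d = ord_lv,       # all pixels, nearest-first
    d_sorted = d[ord_lv],
    rv_cand = cand,          # wedge pixels, nearest-first
    rv_d_sorted = d[cand]
  )
}

# Split a voxel budget across extent slices with a linear apex-to-base
# area taper, summing exactly to the budget.
slice_voxel_targets <- function(total_vox, n_extent, apical_taper) {
  if (total_vox <= 0) return(integer(n_extent))
  w <- seq(apical_taper, 1, length.out = n_extent)
  cum <- round(cumsum(w) / sum(w) * total_vox)
  diff(c(0L, cum))
}

#' Rasterize LV/RV volume curves into a cine label volume
#'
#' Renders the left ventricle as a disc and the right ventricle as an
#' adjacent crescent partially wrapping it, both tapering from base to
#' apex, such that the voxel-counted volume of each structure at every
#' phase matches the curve target to within half a voxel per slice. A
#' 1.5-voxel background rim separates the structures (a stand-in for the
#' myocardial wall, which is not labelled).
#'
#' @param curve_lv,curve_rv `volume_curve` objects of equal length.
#' @param grid a [phantom_grid()].
#' @return a [cine_label_volume()].
#' @export
rasterize_phantom <- function(curve_lv, curve_rv, grid = phantom_grid()) {
  if (nrow(curve_lv) != nrow(curve_rv)) {
    abort("LV and RV curves must cover the same phases.")
  }
  np <- nrow(curve_lv)
  nr <- grid$shape[1]
  nc <- grid$shape[2]
  nsl <- grid$n_slices
  vox_ml <- prod(grid$in_plane_spacing_mm) * grid$slice_thickness_mm / 1000
  geo <- phantom_geometry(grid)
  ext <- grid$slice_extent[1]:grid$slice_extent[2]
  m <- length(ext)
  gap_vox <- 1.5

  labels <- array(0L, dim = c(nr, nc, nsl, np))
  plane <- nr * nc
  for (p in seq_len(np)) {
    n_lv <- slice_voxel_targets(round(curve_lv$volume_ml[p] / vox_ml), m,
                                grid$apical_taper)
    n_rv <- slice_voxel_targets(round(curve_rv$volume_ml[p] / vox_ml), m,
                                grid$apical_taper)
    for (k in seq_len(m)) {
      s <- ext[k]
      base_off <- (p - 1L) * nsl * plane + (s - 1L) * plane
      if (n_lv[k] > 0) {
        if (n_lv[k] > length(geo$lin_by_d)) {
          abort("LV target volume unachievable on this grid.")
        }
        labels[base_off + geo$lin_by_d[seq_len(n_lv[k])]] <- LV_LABEL
        r_lv <- geo$d_sorted[n_lv[k]]
      } else {
        r_lv <- 0
      }
      if (n_rv[k] > 0) {
        start <- findInterval(r_lv + gap_vox, geo$rv_d_sorted) + 1L
        idx <- start:(start + n_rv[k] - 1L)
        if (max(idx) > length(geo$rv_cand)) {
          abort("RV target volume unachievable on this grid.")
        }
        labels[base_off + geo$rv_cand[idx]] <- RV_LABEL
      }
    }
  }
  cine_label_volume(labels, grid$in_plane_spacing_mm,
                    grid$slice_thickness_mm)
}

#' Slice-location error model for degrading a reference segmentation
#'
#' Describes how many voxels of a reference structure to perturb and where
#' the perturbations land, following the observed distribution of
#' automatic-segmentation errors across slice locations: most errors in
#' the basal slice, some spread over mid-ventricular slices, few at the
#' apex, and a small fraction in slices beyond the structure's extent.
#' Default allocations are structure specific: RV (30.7% basal, 61% mid,
#' 5.4% apical, 2.9% outside) and LV (18.3%, 70%, 7.5%, 4.2%).
#'
#' @param structure "RV" or "LV"; selects the default slice allocation.
#' @param error_fraction fraction of the structure's reference foreground
#'   voxels to perturb per phase, in `[0, 1]`.
#' @param slice_allocation named probability vector over
#'   `c("basal", "mid", "apical", "outside")`, summing to 1; `NULL` uses
#'   the structure default.
#' @param addition_fraction fraction of in-extent perturbations realized
#'   as false-positive additions adjacent to the structure (the remainder
#'   are deletions inside it). Out-of-extent errors are always additions.
#'   The default 0.5 keeps the degraded volume approximately unbiased.
#' @param seed integer seed for the perturbation draws.
#' @return list of class `degradation_spec`.
#' @export
degradation_spec <- function(structure = c("RV", "LV"), error_fraction = 0.05,
                             slice_allocation = NULL, addition_fraction = 0.5,
                             seed = 1L) {
  structure <- match.arg(structure)
  if (is.null(slice_allocation)) {
    slice_allocation <- if (structure == "RV") {
      c(basal = 0.307, mid = 0.610, apical = 0.054, outside = 0.029)
    } else {
      c(basal = 0.183, mid = 0.700, apical = 0.075, outside = 0.042)
    }
  }
  slice_allocation <- slice_allocation[c("basal", "mid", "apical", "outside")]
  if (anyNA(slice_allocation) ||
      abs(sum(slice_allocation) - 1) > 1e-9 || any(slice_allocation < 0)) {
    abort("`slice_allocation` must be non-negative over basal/mid/apical/outside and sum to 1.")
  }
  if (error_fraction < 0 || error_fraction > 1) {
    abort("`error_fraction` must lie in [0, 1].")
  }
  structure(
    list(
      structure = structure,
      error_fraction = error_fraction,
      slice_allocation = slice_allocation,
      addition_fraction = addition_fraction,
      seed = as.integer(seed)
    ),
    class = "degradation_spec"
  )
}

# 8-neighbour in-plane dilation ring of a 2D mask (chebyshev radius r),
# restricted to the plane
dilate_ring <- function(mask, r = 1L) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  out <- mask
  for (dr in -r:r) {
    for (dc in -r:r) {
      if (dr == 0 && dc == 0) next
      src_r <- max(1, 1 - dr):min(nr, nr - dr)
      src_c <- max(1, 1 - dc):min(nc, nc - dc)
      out[src_r + dr, src_c + dc] <- out[src_r + dr, src_c + dc] |
        mask[src_r, src_c]
    }
  }
  out & !mask
}

# Flip `n_flip` voxels of `label` in slice `s` of the working 3D grid:
# a deletion/addition mix per `addition_fraction`. Deletions are sampled
# from the reference structure voxels in the slice, additions from the
# in-plane dilation ring of the reference mask that is still background in
# the working grid. Returns the updated grid.
flip_in_slice <- function(work, ref_slice_mask, s, label, n_flip,
                          addition_fraction) {
  if (n_flip <= 0) return(work)
  n_add <- round(addition_fraction * n_flip)
  n_del <- n_flip - n_add
  del_pool <- which(ref_slice_mask)
  ring <- dilate_ring(ref_slice_mask, 1L)
  add_pool <- which(ring & work[, , s] == 0L)
  if (length(add_pool) < n_add) {
    ring2 <- dilate_ring(ref_slice_mask, 2L)
    add_pool <- which(ring2 & work[, , s] == 0L)
  }
  # rebalance if one pool is short
  if (length(add_pool) < n_add) {
    n_del <- n_del + (n_add - length(add_pool))
    n_add <- length(add_pool)
  }
  if (length(del_pool) < n_del) {
    short <- n_del - length(del_pool)
    n_del <- length(del_pool)
    n_add <- min(n_add + short, length(add_pool))
  }
  sl <- work[, , s]
  if (n_del > 0) sl[sample_exact(del_pool, n_del)] <- 0L
  if (n_add > 0) sl[sample_exact(add_pool, n_add)] <- label
  work[, , s] <- sl
  work
}

# Additions-only out-of-extent errors at slice `s`, placed on the
# footprint (plus ring) of the nearest occupied slice.
add_outside <- function(work, footprint_mask, s, label, n_add) {
  if (n_add <= 0) return(work)
  pool <- which((footprint_mask | dilate_ring(footprint_mask, 2L)) &
                  work[, , s] == 0L)
  n_add <- min(n_add, length(pool))
  if (n_add > 0) {
    sl <- work[, , s]
    sl[sample_exact(pool, n_add)] <- label
    work[, , s] <- sl
  }
  work
}

#' Degrade a reference segmentation with located errors
#'
#' Produces an "automatic-like" segmentation by flipping a controlled
#' number of voxels of the reference, per structure and phase. The error
#' budget is `error_fraction` times the structure's foreground count at
#' that phase; it is allocated across the four slice categories (basal,
#' mid-ventricular, apical, out-of-extent) by a multinomial draw with the
#' spec's probabilities. Within the structure's extent errors are a
#' mixture of deletions and adjacent additions; beyond the extent they are
#' false-positive additions only (above the base and, for a smaller share,
#' below the apex). Out-of-extent errors are split 70/30 between
#' above-base and below-apex when both slices exist.
#'
#' @param reference a `cine_label_volume` with the ground-truth labels.
#' @param specs a single [degradation_spec()] or a list of them (one per
#'   structure to degrade).
#' @param phases integer vector of phases to degrade; `NULL` degrades the
#'   end-diastolic and end-systolic phases of the total (LV + RV) volume
#'   curve, the phases that feed clinical measurements.
#' @param all_phases if `TRUE`, degrade every phase (overrides `phases`).
#' @return a `cine_label_volume` with the same grid and spacing.
#' @export
degrade_segmentation <- function(reference, specs = list(degradation_spec("RV"),
                                                         degradation_spec("LV")),
                                 phases = NULL, all_phases = FALSE) {
  if (inherits(specs, "degradation_spec")) specs <- list(specs)
  if (all_phases) {
    phases <- seq_len(n_phases(reference))
  } else if (is.null(phases)) {
    total <- volume_curve(reference, "LV")$volume_ml +
      volume_curve(reference, "RV")$volume_ml
    phases <- c(which.max(total), which.min(total))
  }
  out <- reference
  nsl <- n_slices(reference)
  for (spec in specs) {
    label <- structure_label(spec$structure)
    with_seed(spec$seed, {
      for (p in phases) {
        ref3d <- phase_labels(reference, p)
        mask3d <- ref3d == label
        slices <- which(apply(mask3d, 3, any))
        fg <- sum(mask3d)
        budget <- round(spec$error_fraction * fg)
        if (budget == 0 || length(slices) == 0) next
        counts <- as.integer(
          rmultinom(1, budget, spec$slice_allocation)
        )
        names(counts) <- names(spec$slice_allocation)
        basal_s <- max(slices)
        apical_s <- min(slices)
        mids <- setdiff(slices, c(basal_s, apical_s))
        if (length(mids) == 0) {
          # too thin for distinct mid slices: fold mid into basal
          counts["basal"] <- counts["basal"] + counts["mid"]
          counts["mid"] <- 0L
        }
        if (apical_s == basal_s) {
          warn("structure occupies a single slice; apical errors reallocated.")
          counts["basal"] <- counts["basal"] + counts["apical"]
          counts["apical"] <- 0L
        }
        above <- basal_s + 1L
        below <- apical_s - 1L
        n_out <- counts["outside"]
        n_above <- round(0.7 * n_out)
        n_below <- n_out - n_above
        if (above > nsl && below >= 1) {
          n_below <- n_out; n_above <- 0L
        } else if (below < 1 && above <= nsl) {
          n_above <- n_out; n_below <- 0L
        } else if (above > nsl && below < 1) {
          warn("no out-of-extent slice available; errors reallocated to mid.")
          counts["mid"] <- counts["mid"] + n_out
          n_above <- 0L; n_below <- 0L
        }

        work <- phase_labels(out, p)
        work <- flip_in_slice(work, mask3d[, , basal_s], basal_s, label,
                              counts["basal"], spec$addition_fraction)
        work <- flip_in_slice(work, mask3d[, , apical_s], apical_s, label,
                              counts["apical"], spec$addition_fraction)
        if (counts["mid"] > 0 && length(mids) > 0) {
          per_slice_fg <- vapply(mids, function(s) sum(mask3d[, , s]),
                                 integer(1))
          mid_counts <- as.integer(
            rmultinom(1, counts["mid"], per_slice_fg / sum(per_slice_fg))
          )
          for (j in seq_along(mids)) {
            work <- flip_in_slice(work, mask3d[, , mids[j]], mids[j], label,
                                  mid_counts[j], spec$addition_fraction)
          }
        }
        if (n_above > 0) {
          work <- add_outside(work, mask3d[, , basal_s], above, label, n_above)
        }
        if (n_below > 0) {
          work <- add_outside(work, mask3d[, , apical_s], below, label,
                              n_below)
        }
        out$labels[, , , p] <- work
      }
    })
  }
  out
}

#' Cohort configuration
#'
#' All tunable parameters of the synthetic cohort: the three study groups
#' (controls, at-risk family members, ARVC patients) with group-level
#' distributions of RV/LV indexed end-diastolic volume (ml/m^2) and
#' ejection fraction (%), the probability of a regional RV wall-motion
#' abnormality, non-CMR Task Force point distributions, demographics, and
#' the imaging geometry ranges. Group volume/function means are plausible
#' clinical values chosen so that roughly 84% of ARVC subjects and 3% of
#' at-risk subjects meet a minor or major CMR criterion; they are
#' calibration targets, not guarantees.
#'
#' @param n_subjects number of subjects.
#' @param group_proportions probabilities over (control, at_risk, arvc)
#'   summing to 1. Defaults are the composition of a 157-subject
#'   evaluation cohort (54/157, 66/157, 37/157).
#' @param exact_group_sizes draw group sizes deterministically by largest
#'   remainder (default) rather than multinomially.
#' @param group_params named list (control/at_risk/arvc) of lists with
#'   elements `rvedvi`, `rvef`, `lvedvi`, `lvef` (each `c(mean, sd)`),
#'   `rwma_prob`, `age` (`c(mean, sd)`), and `noncmr` (probability vector
#'   over 0.. points).
#' @param female_prop probability a subject is female.
#' @param female_edvi_shift additive shift (ml/m^2) of the indexed volume
#'   means for female subjects (women have smaller indexed RV volumes).
#' @param bsa_params list with `male` and `female` `c(mean, sd)` of body
#'   surface area (m^2).
#' @param shape,n_slices in-plane matrix and slice count of the phantom
#'   grid.
#' @param in_plane_range,slice_thickness_range,n_phases_range per-subject
#'   uniform sampling ranges for voxel spacing (mm), slice thickness (mm)
#'   and phase count.
#' @param es_fraction `c(mean, sd)` of the end-systolic phase position as
#'   a fraction of the cycle.
#' @param seed master seed.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 157,
                          group_proportions = c(control = 54, at_risk = 66,
                                                arvc = 37) / 157,
                          exact_group_sizes = TRUE,
                          group_params = default_group_params(),
                          female_prop = 0.59,
                          female_edvi_shift = -8,
                          bsa_params = list(male = c(2.00, 0.15),
                                            female = c(1.75, 0.13)),
                          shape = c(160, 160),
                          n_slices = 12,
                          in_plane_range = c(1.11, 1.45),
                          slice_thickness_range = c(7, 10),
                          n_phases_range = c(25, 40),
                          es_fraction = c(0.40, 0.02),
                          seed = 42L) {
  if (abs(sum(group_proportions) - 1) > 1e-9 || any(group_proportions < 0)) {
    abort("`group_proportions` must be non-negative and sum to 1.")
  }
  if (n_subjects < 0) abort("`n_subjects` must be non-negative.")
  for (g in c("control", "at_risk", "arvc")) {
    gp <- group_params[[g]]
    if (is.null(gp)) abort(sprintf("missing group parameters for '%s'.", g))
    sds <- vapply(gp[c("rvedvi", "rvef", "lvedvi", "lvef", "age")],
                  function(x) x[2], numeric(1))
    if (any(sds < 0)) abort("distribution SDs must be non-negative.")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      group_proportions = group_proportions,
      exact_group_sizes = exact_group_sizes,
      group_params = group_params,
      female_prop = female_prop,
      female_edvi_shift = female_edvi_shift,
      bsa_params = bsa_params,
      shape = as.integer(rep(shape, length.out = 2L)),
      n_slices = as.integer(n_slices),
      in_plane_range = in_plane_range,
      slice_thickness_range = slice_thickness_range,
      n_phases_range = as.integer(n_phases_range),
      es_fraction = es_fraction,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' @rdname cohort_config
#' @export
default_group_params <- function() {
  list(
    control = list(
      rvedvi = c(75, 10), rvef = c(58, 6), lvedvi = c(72, 9), lvef = c(60, 6),
      rwma_prob = 0.05, age = c(42.9, 15.9),
      noncmr = c(`0` = 0.85, `1` = 0.15)
    ),
    at_risk = list(
      rvedvi = c(86, 10), rvef = c(55, 6), lvedvi = c(75, 9), lvef = c(59, 6),
      rwma_prob = 0.20, age = c(30.7, 16.2),
      noncmr = c(`0` = 0.20, `1` = 0.30, `2` = 0.30, `3` = 0.20)
    ),
    arvc = list(
      rvedvi = c(112, 22), rvef = c(40, 8), lvedvi = c(80, 10),
      lvef = c(52, 7), rwma_prob = 0.90, age = c(39.1, 19.0),
      noncmr = c(`2` = 0.15, `3` = 0.30, `4` = 0.30, `5` = 0.15, `6` = 0.10)
    )
  )
}

# Deterministic largest-remainder apportionment of n into groups
largest_remainder_sizes <- function(n, props) {
  raw <- props * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# truncated normal draw: clamp at mean +/- 2.5 sd and a hard floor
rnorm_clamped <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- rnorm(n, mean, sd)
  pmin(pmax(x, pmax(mean - 2.5 * sd, lo)), pmin(mean + 2.5 * sd, hi))
}

#' Generate a synthetic ARVC-evaluation cohort
#'
#' Draws subjects (group, sex, age, body surface area, wall-motion flag,
#' non-CMR Task Force points) and the generator truth behind each
#' subject's reference segmentation: per-structure EDV/ESV, the
#' end-systolic phase, and the imaging geometry. Reference label volumes
#' are rasterized on demand with [cohort_reference()] so that cohorts of
#' hundreds of subjects never hold all 4D volumes in memory at once; the
#' rasterization is deterministic, so repeated access is bit-identical.
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_cohort` with elements `subjects`
#'   (tibble, one row per subject) and `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 2, seed = 1))
#' cohort$subjects$group
#' @export
generate_cohort <- function(config = cohort_config()) {
  n <- config$n_subjects
  groups_lv <- c("control", "at_risk", "arvc")
  with_seed(config$seed, {
    if (n == 0) {
      subjects <- tibble(
        id = character(), sex = character(), age_years = numeric(),
        group = character(), bsa_m2 = numeric(), rwma = logical(),
        noncmr_points = integer()
      )
    } else {
      if (config$exact_group_sizes) {
        sizes <- largest_remainder_sizes(n, config$group_proportions)
        group <- rep(groups_lv, times = sizes)
      } else {
        group <- sample(groups_lv, n, replace = TRUE,
                        prob = config$group_proportions)
      }
      sex <- ifelse(runif(n) < config$female_prop, "female", "male")
      bsa <- vapply(sex, function(s) {
        p <- config$bsa_params[[s]]
        rnorm_clamped(1, p[1], p[2], lo = 1.2)
      }, numeric(1), USE.NAMES = FALSE)
      draw <- function(field, lo, hi = Inf) {
        vapply(seq_len(n), function(i) {
          p <- config$group_params[[group[i]]][[field]]
          shift <- if (field %in% c("rvedvi", "lvedvi") &&
                       sex[i] == "female") config$female_edvi_shift else 0
          rnorm_clamped(1, p[1] + shift, p[2], lo, hi)
        }, numeric(1))
      }
      rvedvi <- draw("rvedvi", lo = 40)
      lvedvi <- draw("lvedvi", lo = 40)
      rvef <- draw("rvef", lo = 15, hi = 75)
      lvef <- draw("lvef", lo = 15, hi = 75)
      age <- draw("age", lo = 16)
      rwma <- vapply(seq_len(n), function(i) {
        runif(1) < config$group_params[[group[i]]]$rwma_prob
      }, logical(1))
      noncmr <- vapply(seq_len(n), function(i) {
        pr <- config$group_params[[group[i]]]$noncmr
        as.integer(sample(names(pr), 1, prob = pr))
      }, integer(1))
      in_plane <- runif(n, config$in_plane_range[1], config$in_plane_range[2])
      thick <- runif(n, config$slice_thickness_range[1],
                     config$slice_thickness_range[2])
      nph <- sample(config$n_phases_range[1]:config$n_phases_range[2], n,
                    replace = TRUE)
      esf <- pmin(pmax(rnorm(n, config$es_fraction[1], config$es_fraction[2]),
                       0.25), 0.55)
      subjects <- tibble(
        id = sprintf("S%03d", seq_len(n)),
        sex = sex,
        age_years = round(age, 1),
        group = group,
        bsa_m2 = round(bsa, 3),
        rwma = rwma,
        noncmr_points = noncmr,
        rvedvi_true = rvedvi,
        rvef_true = rvef,
        lvedvi_true = lvedvi,
        lvef_true = lvef,
        rv_edv_ml = rvedvi * bsa,
        rv_esv_ml = rvedvi * bsa * (1 - rvef / 100),
        lv_edv_ml = lvedvi * bsa,
        lv_esv_ml = lvedvi * bsa * (1 - lvef / 100),
        n_phases = nph,
        in_plane_mm = in_plane,
        slice_thickness_mm = thick,
        es_fraction = esf,
        ed_phase_true = 1L,
        es_phase_true = pmin(pmax(round(esf * nph), 1L), nph - 1L) + 1L,
        degradation_seed = derive_seeds(config$seed + 1L, n)
      )
    }
  })
  structure(list(subjects = subjects, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (seed %d)\n",
              nrow(x$subjects), x$config$seed))
  if (nrow(x$subjects) > 0) print(table(x$subjects$group))
  invisible(x)
}

#' Grid specification for one cohort subject
#' @param cohort a `synthetic_cohort`.
#' @param i subject index.
#' @keywords internal
subject_grid <- function(cohort, i) {
  s <- cohort$subjects[i, ]
  phantom_grid(
    shape = cohort$config$shape,
    n_slices = cohort$config$n_slices,
    in_plane_spacing_mm = s$in_plane_mm,
    slice_thickness_mm = s$slice_thickness_mm
  )
}

#' Reference segmentation of one cohort subject
#'
#' Rebuilds the subject's ground-truth cine label volume from the stored
#' generator parameters. Deterministic: every call returns an identical
#' volume.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param i subject index (row of `cohort$subjects`).
#' @return a `cine_label_volume`.
#' @export
cohort_reference <- function(cohort, i) {
  s <- cohort$subjects[i, ]
  lv <- volume_profile(s$lv_edv_ml, s$lv_esv_ml, s$n_phases, s$es_fraction,
                       structure = "LV")
  rv <- volume_profile(s$rv_edv_ml, s$rv_esv_ml, s$n_phases, s$es_fraction,
                       structure = "RV")
  rasterize_phantom(lv, rv, subject_grid(cohort, i))
}

#' Render a pseudo-MR intensity image from a label volume
#'
#' Assigns per-class base intensities (dark background, bright blood
#' pools, an intermediate thin rim around each ventricle standing in for
#' myocardium), then adds Gaussian noise and, optionally, a smooth
#' multiplicative bias field.
#'
#' @param labelvol a `cine_label_volume`.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param bias_field add a smooth multiplicative bias (20% peak)?
#' @param seed integer seed.
#' @param intensities named vector of class means
#'   (background/rim/LV/RV).
#' @return list of class `cine_intensity_volume` with elements
#'   `intensities` (4D numeric array) and the spacing fields of the input.
#' @export
render_image <- function(labelvol, noise_sd = 10, bias_field = FALSE,
                         seed = 1L,
                         intensities = c(background = 30, rim = 90,
                                         LV = 180, RV = 170)) {
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  d <- dim(labelvol$labels)
  img <- array(intensities[["background"]], dim = d)
  img[labelvol$labels == LV_LABEL] <- intensities[["LV"]]
  img[labelvol$labels == RV_LABEL] <- intensities[["RV"]]
  # one-voxel in-plane rim around each structure
  for (p in seq_len(d[4])) {
    for (s in seq_len(d[3])) {
      sl <- labelvol$labels[, , s, p]
      rim <- dilate_ring(sl != 0L, 1L)
      plane <- img[, , s, p]
      plane[rim] <- intensities[["rim"]]
      img[, , s, p] <- plane
    }
  }
  with_seed(seed, {
    if (bias_field) {
      nr <- d[1]; nc <- d[2]
      b <- 1 + 0.2 * outer(sin(pi * seq_len(nr) / nr),
                           sin(pi * seq_len(nc) / nc))
      img <- img * as.vector(b)
    }
    if (noise_sd > 0) {
      img <- img + rnorm(length(img), 0, noise_sd)
    }
  })
  structure(
    list(
      intensities = img,
      in_plane_spacing_mm = labelvol$in_plane_spacing_mm,
      slice_thickness_mm = labelvol$slice_thickness_mm
    ),
    class = "cine_intensity_volume"
  )
}

#' Write the cohort table and volumes to disk
#'
#' Writes one CSV row per subject and, optionally, every reference (and
#' degraded) volume as 4D NIfTI, plus the configuration as JSON.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @param volumes also write the per-subject reference volumes?
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir, volumes = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- cohort$subjects
  if (volumes && nrow(subjects) > 0) {
    subjects$reference_path <- file.path(dir,
                                         paste0(subjects$id, "_ref.nii.gz"))
    for (i in seq_len(nrow(subjects))) {
      write_cine_nifti(cohort_reference(cohort, i), subjects$reference_path[i])
    }
  }
  readr::write_csv(subjects, file.path(dir, "cohort.csv"))
  cfg <- cohort$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "cohort_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
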