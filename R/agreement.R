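# helpers -------------------------------------------------------------

as_structure_mask <- function(x, structure) {
  if (is.logical(x)) return(x)
  x == structure_label(structure)
}

# boundary voxels of a 3D mask: foreground with at least one 6-neighbour
# background (array edges count as background)
boundary_voxels <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, dim = d)
  shift_and <- function(m, ax, by) {
    out <- array(FALSE, dim = d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    n <- d[ax]
    if (by == 1) {
      idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1)
    } else {
      idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n
    }
    out <- do.call(`[<-`, c(list(out), idx_dst,
                            list(do.call(`[`, c(list(m), idx_src)))))
    out
  }
  for (ax in 1:3) {
    for (by in c(1, -1)) {
      interior <- interior & shift_and(mask, ax, by)
    }
  }
  mask & !interior
}

mask_coords_mm <- function(mask, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(idx[, 1] * spacing[1], idx[, 2] * spacing[2], idx[, 3] * spacing[3])
}

directed_hausdorff <- function(a_xyz, b_xyz) {
  # deterministic stride shuffle of the inner set so the early break in
  # the compiled kernel is effective
  nb <- nrow(b_xyz)
  perm <- ((seq_len(nb) - 1L) * 7919L) %% nb + 1L
  if (anyDuplicated(perm)) perm <- seq_len(nb)
  directed_hausdorff_cpp(a_xyz, b_xyz[perm, , drop = FALSE])
}

# metrics --------------------------------------------------------------

#' 3D Dice overlap coefficient
#'
#' `2|A intersect B| / (|A| + |B|)` on the binarized masks of one
#' structure. Two empty masks agree on absence and score 1; one empty mask
#' scores 0.
#'
#' @param a,b 3D label grids (or logical masks) of identical shape.
#' @param structure `"LV"` or `"RV"` (ignored for logical masks).
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice3d <- function(a, b, structure = "LV") {
  if (!identical(dim(a), dim(b))) abort("mask shapes differ.")
  ma <- as_structure_mask(a, structure)
  mb <- as_structure_mask(b, structure)
  sa <- sum(ma)
  sb <- sum(mb)
  if (sa + sb == 0) return(1)
  2 * sum(ma & mb) / (sa + sb)
}

#' 3D Hausdorff distance in millimetres
#'
#' Symmetric (exact-maximum) Hausdorff distance between the boundary
#' voxels of two masks, with anisotropic voxel spacing applied so the
#' result is in physical millimetres.
#'
#' @param a,b 3D label grids (or logical masks) of identical shape, both
#'   non-empty for the chosen structure.
#' @param structure `"LV"` or `"RV"`.
#' @param spacing length-3 voxel spacing `(row, col, slice)` in mm.
#' @return distance in mm.
#' @export
hausdorff3d <- function(a, b, structure = "LV", spacing = c(1.25, 1.25, 8)) {
  if (!identical(dim(a), dim(b))) abort("mask shapes differ.")
  ma <- as_structure_mask(a, structure)
  mb <- as_structure_mask(b, structure)
  if (!any(ma) || !any(mb)) abort("Hausdorff distance undefined for an empty mask.")
  pa <- mask_coords_mm(boundary_voxels(ma), spacing)
  pb <- mask_coords_mm(boundary_voxels(mb), spacing)
  max(directed_hausdorff(pa, pb), directed_hausdorff(pb, pa))
}

#' Attribute segmentation errors to slice locations
#'
#' Pools the misclassified voxels (symmetric difference of the automatic
#' and reference masks of one structure) over the listed phases and
#' attributes each to one of four slice categories relative to the
#' reference structure's slice extent at that phase: the most basal
#' reference slice, the most apical reference slice, interior
#' (mid-ventricular) slices, or slices beyond the extent (above the base /
#' below the apex).
#'
#' @param auto,reference `cine_label_volume`s on the same grid.
#' @param structure `"LV"` or `"RV"`.
#' @param phases phases to pool; `NULL` pools the reference ED and ES
#'   phases (total-volume extremes).
#' @return one-row tibble of class `error_attribution`: `structure`,
#'   `total_errors`, and fractions `basal`, `mid`, `apical`, `outside`
#'   (all zero when there are no errors).
#' @export
attribute_errors <- function(auto, reference, structure, phases = NULL) {
  if (!identical(dim(auto$labels), dim(reference$labels))) {
    abort("volumes must share a grid.")
  }
  if (is.null(phases)) {
    total <- volume_curve(reference, "LV")$volume_ml +
      volume_curve(reference, "RV")$volume_ml
    phases <- c(which.max(total), which.min(total))
  }
  label <- structure_label(structure)
  counts <- c(basal = 0, mid = 0, apical = 0, outside = 0)
  for (p in unique(phases)) {
    ref <- phase_labels(reference, p) == label
    aut <- phase_labels(auto, p) == label
    occ <- which(apply(ref, 3, any))
    if (length(occ) == 0) {
      warn(sprintf("reference %s empty at phase %d; phase skipped.",
                   structure, p))
      next
    }
    err <- ref != aut
    if (!any(err)) next
    per_slice <- apply(err, 3, sum)
    sl <- which(per_slice > 0)
    for (s in sl) {
      cat_ <- if (s == max(occ)) "basal"
      else if (s == min(occ)) "apical"
      else if (s > min(occ) && s < max(occ)) "mid"
      else "outside"
      counts[cat_] <- counts[cat_] + per_slice[s]
    }
  }
  total <- sum(counts)
  frac <- if (total > 0) counts / total else counts
  out <- tibble(
    structure = toupper(structure),
    total_errors = total,
    basal = frac[["basal"]],
    mid = frac[["mid"]],
    apical = frac[["apical"]],
    outside = frac[["outside"]]
  )
  class(out) <- c("error_attribution", class(out))
  out
}

#' Signed phase difference as a percentage of the cardiac cycle
#'
#' `auto_phase - manual_phase`, wrapped circularly to
#' `(-n_phases/2, n_phases/2]` and expressed as a percentage of the
#' cycle, so a selection one phase late on a 25-phase cine is +4%.
#'
#' @param auto_phase,manual_phase phase indices (any common base).
#' @param n_phases number of phases in the cycle (>= 2).
#' @return signed percentage (vectorized).
#' @export
phase_difference <- function(auto_phase, manual_phase, n_phases) {
  if (any(n_phases < 2)) abort("`n_phases` must be at least 2.")
  d <- (auto_phase - manual_phase) %% n_phases
  d <- ifelse(d > n_phases / 2, d - n_phases, d)
  100 * d / n_phases
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = x - y`; bias is `mean(d)` and the limits of agreement
#' `bias +/- 1.96 * sd(d)` with the sample (n-1) standard deviation.
#'
#' @param x,y paired numeric series of equal length >= 2.
#' @return one-row tibble of class `bland_altman`: `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) abort("series lengths differ.")
  if (length(x) < 2) abort("need at least 2 pairs.")
  d <- x - y
  s <- sd(d)
  out <- tibble(
    bias = mean(d),
    sd_diff = s,
    loa_low = mean(d) - 1.96 * s,
    loa_high = mean(d) + 1.96 * s,
    n = length(d)
  )
  class(out) <- c("bland_altman", class(out))
  out
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y paired numeric series.
#' @param conf_level confidence level (default 0.95).
#' @return one-row tibble: `r`, `conf_low`, `conf_high`, `n`.
#' @export
pearson_r <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) abort("series lengths differ.")
  if (sd(x) == 0 || sd(y) == 0) abort("correlation undefined for a constant series.")
  r <- cor(x, y)
  n <- length(x)
  if (n > 3 && abs(r) < 1) {
    z <- atanh(r)
    se <- 1 / sqrt(n - 3)
    q <- qnorm(1 - (1 - conf_level) / 2)
    ci <- tanh(c(z - q * se, z + q * se))
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  tibble(r = r, conf_low = ci[1], conf_high = ci[2], n = n)
}

#' Cohen's kappa for two categorical series
#'
#' Unweighted kappa `(p_o - p_e) / (1 - p_e)` with the large-sample
#' standard error `sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))`. When both
#' raters use a single identical category throughout, chance agreement is
#' 1 and kappa is undefined; perfect agreement is then reported as 1 with
#' a warning.
#'
#' @param a,b categorical series (character or factor) of equal length
#'   over a shared category set.
#' @return one-row tibble: `kappa`, `se`, `p_o`, `p_e`, `n`.
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b)) abort("series lengths differ.")
  n <- length(a)
  if (n == 0) abort("empty series.")
  levs <- sort(union(unique(as.character(a)), unique(as.character(b))))
  ta <- factor(as.character(a), levels = levs)
  tb <- factor(as.character(b), levels = levs)
  tab <- table(ta, tb) / n
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (1 - p_e < 1e-12) {
    warn("single shared category on both sides: kappa undefined; perfect agreement reported as 1.")
    kap <- if (p_o >= 1 - 1e-12) 1 else NA_real_
    return(tibble(kappa = kap, se = NA_real_, p_o = p_o, p_e = p_e, n = n))
  }
  kap <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
  tibble(kappa = kap, se = se, p_o = p_o, p_e = p_e, n = n)
}

#' Sensitivity and specificity of a binary test
#'
#' Against a reference diagnosis label: sensitivity `TP / (TP + FN)`,
#' specificity `TN / (TN + FP)`. Undefined metrics (no positives or no
#' negatives in the reference) are returned as `NA` with a warning.
#'
#' @param test logical test result (e.g. "meets at least a minor CMR
#'   criterion").
#' @param diagnosis logical reference (definite diagnosis).
#' @return one-row tibble: `sensitivity`, `specificity`, `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
sens_spec <- function(test, diagnosis) {
  if (length(test) != length(diagnosis)) abort("series lengths differ.")
  tp <- sum(test & diagnosis)
  fn <- sum(!test & diagnosis)
  tn <- sum(!test & !diagnosis)
  fp <- sum(test & !diagnosis)
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    warn("no positive reference cases: sensitivity undefined.")
    NA_real_
  }
  spec <- if (tn + fp > 0) tn / (tn + fp) else {
    warn("no negative reference cases: specificity undefined.")
    NA_real_
  }
  tibble(sensitivity = sens, specificity = spec,
         tp = tp, fp = fp, tn = tn, fn = fn)
}

#' McNemar test for paired binary outcomes
#'
#' Exact binomial test on the discordant pairs when there are fewer than
#' 25 of them, otherwise the chi-square test with continuity correction.
#' With no discordant pairs the methods are indistinguishable and p = 1.
#'
#' @param a,b paired logical series.
#' @return p-value.
#' @export
mcnemar_p <- function(a, b) {
  if (length(a) != length(b)) abort("series lengths differ.")
  d10 <- sum(a & !b)
  d01 <- sum(!a & b)
  nd <- d10 + d01
  if (nd == 0) return(1)
  if (nd < 25) {
    return(binom.test(d10, nd, 0.5)$p.value)
  }
  tab <- matrix(c(sum(a & b), d10, d01, sum(!a & !b)), nrow = 2)
  mcnemar.test(tab, correct = TRUE)$p.value
}

#' Category transition table between two raters
#'
#' Cross-tabulates the none/minor/major CMR classification of two methods
#' (e.g. manual vs corrected automatic), the flow diagram of
#' classification changes in matrix form.
#'
#' @param manual,auto character vectors over `none`/`minor`/`major`.
#' @return tibble with `manual`, `auto` and `n` columns (9 rows).
#' @export
tfc_transition_table <- function(manual, auto) {
  levs <- c("none", "minor", "major")
  tab <- table(factor(manual, levels = levs), factor(auto, levels = levs))
  out <- as_tibble(as.data.frame(tab, stringsAsFactors = FALSE))
  names(out) <- c("manual", "auto", "n")
  out$n <- as.integer(out$n)
  out
}
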