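# Small-scale fixtures shared across test files. Everything is generated
# in code; grids are kept coarse (large voxels, few slices/phases) so the
# suite stays fast while exercising the same code paths as full-size
# volumes.

tiny_grid <- function(shape = c(72, 72), n_slices = 8,
                      in_plane = 2.2, thickness = 8) {
  phantom_grid(shape = shape, n_slices = n_slices,
               in_plane_spacing_mm = in_plane, slice_thickness_mm = thickness)
}

tiny_phantom <- function(lv_edv = 120, lv_esv = 50, rv_edv = 150, rv_esv = 75,
                         n_phases = 12, es_frac = 0.4, grid = tiny_grid()) {
  rasterize_phantom(
    volume_profile(lv_edv, lv_esv, n_phases, es_frac, structure = "LV"),
    volume_profile(rv_edv, rv_esv, n_phases, es_frac, structure = "RV"),
    grid
  )
}

tiny_cohort_config <- function(n_subjects = 6, seed = 11, ...) {
  cohort_config(
    n_subjects = n_subjects,
    shape = c(72, 72), n_slices = 8,
    in_plane_range = c(2.0, 2.4), slice_thickness_range = c(8, 8),
    n_phases_range = c(12, 14),
    seed = seed,
    ...
  )
}

# brute-force flood fill used as an oracle for connected components
flood_fill_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  nid <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  idx <- which(mask, arr.ind = TRUE)
  for (v in seq_len(nrow(idx))) {
    p <- idx[v, ]
    if (lab[p[1], p[2], p[3]] != 0L) next
    nid <- nid + 1L
    queue <- list(p)
    lab[p[1], p[2], p[3]] <- nid
    while (length(queue) > 0) {
      q <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        nb <- q + offs[k, ]
        if (any(nb < 1) || any(nb > d)) next
        if (mask[nb[1], nb[2], nb[3]] && lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- nid
          queue[[length(queue) + 1L]] <- nb
        }
      }
    }
  }
  lab
}

# all-pairs Hausdorff oracle over full masks (not just boundaries)
hausdorff_oracle <- function(ma, mb, spacing) {
  pa <- which(ma, arr.ind = TRUE)
  pb <- which(mb, arr.ind = TRUE)
  pa <- sweep(pa, 2, spacing, `*`)
  pb <- sweep(pb, 2, spacing, `*`)
  cross <- function(a, b) {
    vapply(seq_len(nrow(a)), function(i) {
      min(sqrt(colSums((t(b) - a[i, ])^2)))
    }, numeric(1))
  }
  max(max(cross(pa, pb)), max(cross(pb, pa)))
}
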