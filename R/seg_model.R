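# shift a matrix by (dr, dc) with zero padding
shift_mat <- function(x, dr, dc) {
  nr <- nrow(x)
  nc <- ncol(x)
  out <- matrix(0, nr, nc)
  sr <- max(1, 1 - dr):min(nr, nr - dr)
  sc <- max(1, 1 - dc):min(nc, nc - dc)
  if (length(sr) > 0 && length(sc) > 0) {
    out[sr + dr, sc + dc] <- x[sr, sc]
  }
  out
}

#' 2D dilated convolution (3x3 kernel, zero padding)
#'
#' @param x numeric matrix.
#' @param kernel 3x3 numeric kernel.
#' @param dilation integer dilation factor.
#' @return matrix of the same shape as `x`.
#' @keywords internal
conv2d_dilated <- function(x, kernel, dilation = 1L) {
  out <- matrix(0, nrow(x), ncol(x))
  for (a in -1:1) {
    for (b in -1:1) {
      w <- kernel[a + 2, b + 2]
      if (w != 0) out <- out + w * shift_mat(x, a * dilation, b * dilation)
    }
  }
  out
}

#' Soft-Dice of a probability map against a binary reference
#'
#' Differentiable Dice used as a training loss term. The `standard`
#' variant is `2 * sum(R * A) / (sum(R) + sum(A))` (1 at perfect binary
#' overlap); the `as_printed` variant omits the factor 2 (maximum 0.5 at
#' perfect overlap) and is provided because both normalizations circulate.
#'
#' @param A_c probability map in `[0, 1]`.
#' @param R_c binary reference map of the same shape.
#' @param variant `"standard"` (default) or `"as_printed"`.
#' @return scalar soft-Dice; 0 with a warning when both maps are empty.
#' @export
soft_dice <- function(A_c, R_c, variant = c("standard", "as_printed")) {
  variant <- match.arg(variant)
  if (!identical(dim(A_c), dim(R_c)) && length(A_c) != length(R_c)) {
    abort("probability and reference maps must share a shape.")
  }
  if (any(A_c < 0 | A_c > 1)) abort("probabilities must lie in [0, 1].")
  denom <- sum(R_c) + sum(A_c)
  if (denom == 0) {
    warn("both maps empty: soft-Dice defined as 0.")
    return(0)
  }
  num <- sum(R_c * A_c)
  if (variant == "standard") 2 * num / denom else num / denom
}

#' Per-voxel cross-entropy of class probability maps
#'
#' Mean over voxels of `-log p(true class)`, with probabilities clamped at
#' `eps` before the log.
#'
#' @param prob_maps array whose last dimension indexes the classes
#'   (background, LV, RV), or a matrix `[n_voxels, n_classes]`.
#' @param reference integer label map (values `0..n_classes - 1`) with as
#'   many voxels as `prob_maps` has rows.
#' @param eps clamp for log probabilities.
#' @return mean cross-entropy (non-negative scalar).
#' @export
cross_entropy <- function(prob_maps, reference, eps = 1e-7) {
  dm <- dim(prob_maps)
  k <- dm[length(dm)]
  p <- matrix(prob_maps, ncol = k)
  y <- as.integer(reference) + 1L
  if (length(y) != nrow(p)) abort("probability and reference shapes differ.")
  if (any(y < 1 | y > k)) abort("reference labels outside the class range.")
  ptrue <- pmax(p[cbind(seq_along(y), y)], eps)
  -mean(log(ptrue))
}

#' Compact dilated-convolution segmentation model
#'
#' A lightweight CPU-scale segmenter for the synthetic phantoms: a fixed,
#' randomly initialized bank of 3x3 dilated convolution filters (with a
#' residual second stage) turns the image into per-pixel features;
#' a trainable softmax layer maps features to background/LV/RV
#' probabilities. Dropout on the feature activations makes the forward
#' pass stochastic, enabling Monte-Carlo-dropout inference. Normalized
#' in-plane coordinates are included as features so the toy model can
#' exploit the roughly fixed position of the ventricles in the phantom
#' frame.
#'
#' @param n_filters filters per dilation level.
#' @param dilations integer dilation factors of the filter bank.
#' @param dropout_rate dropout probability on feature activations, in
#'   `[0, 1)`.
#' @param include_coords include normalized row/column/radius features.
#' @param seed seed for the fixed filter bank and head initialization.
#' @return object of class `seg_model`.
#' @export
seg_model <- function(n_filters = 4, dilations = c(1L, 2L, 4L),
                      dropout_rate = 0.1, include_coords = TRUE, seed = 1L) {
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort("`dropout_rate` must lie in [0, 1).")
  }
  with_seed(seed, {
    kernels <- array(rnorm(9 * n_filters * length(dilations), sd = sqrt(1 / 3)),
                     dim = c(3, 3, n_filters, length(dilations)))
    k2 <- array(rnorm(9 * 2, sd = sqrt(1 / 3)), dim = c(3, 3, 2))
    n_feat <- 1L + 1L + (if (include_coords) 3L else 0L) +
      n_filters * length(dilations) + 2L
    W <- matrix(rnorm(n_feat * 3, sd = 0.01), nrow = n_feat, ncol = 3)
  })
  structure(
    list(
      kernels = kernels, k2 = k2, dilations = as.integer(dilations),
      n_filters = as.integer(n_filters), include_coords = include_coords,
      dropout_rate = dropout_rate, W = W, log = NULL, seed = as.integer(seed)
    ),
    class = "seg_model"
  )
}

# per-pixel feature matrix [n_pixels, n_features] for one 2D image
seg_features <- function(model, x) {
  nr <- nrow(x)
  nc <- ncol(x)
  feats <- list(matrix(1, nr, nc), x)
  if (model$include_coords) {
    ro <- matrix(rep(seq_len(nr) / nr - 0.5, nc), nr, nc)
    co <- matrix(rep(seq_len(nc) / nc - 0.5, each = nr), nr, nc)
    feats <- c(feats, list(ro, co, sqrt(ro^2 + co^2)))
  }
  relu <- function(m) pmax(m, 0)
  conv_feats <- list()
  for (di in seq_along(model$dilations)) {
    for (j in seq_len(model$n_filters)) {
      conv_feats <- c(conv_feats, list(
        relu(conv2d_dilated(x, model$kernels[, , j, di], model$dilations[di]))
      ))
    }
  }
  h <- Reduce(`+`, conv_feats) / length(conv_feats)
  res <- lapply(1:2, function(j) {
    relu(conv2d_dilated(h, model$k2[, , j], 4L)) + h # residual skip
  })
  feats <- c(feats, conv_feats, res)
  matrix(unlist(feats), ncol = length(feats))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# one stochastic forward pass; `stochastic = FALSE` disables dropout
forward_pass <- function(model, fmat, stochastic = TRUE) {
  p <- model$dropout_rate
  if (stochastic && p > 0) {
    mask <- matrix(rbinom(length(fmat), 1, 1 - p) / (1 - p),
                   nrow = nrow(fmat))
    mask[, 1] <- 1 # never drop the bias feature
    fmat <- fmat * mask
  }
  list(fmat = fmat, probs = softmax_rows(fmat %*% model$W))
}

#' Monte-Carlo-dropout prediction
#'
#' Averages the softmax output of `n_samples` stochastic forward passes
#' (dropout active at inference); the predicted label is the argmax of the
#' mean probability per pixel. With a dropout rate of 0 the forward pass
#' is deterministic and the result equals a single pass for any
#' `n_samples`.
#'
#' @param model a [seg_model()].
#' @param image 2D numeric matrix (a normalized slice).
#' @param n_samples number of stochastic samples (default 15).
#' @param seed seed for the dropout draws.
#' @return list with `prob` (array `[rows, cols, 3]`, mean class
#'   probabilities) and `labels` (integer matrix, 0 = background, 1 = LV,
#'   2 = RV).
#' @export
mc_predict <- function(model, image, n_samples = 15, seed = 1L) {
  if (n_samples < 1) abort("`n_samples` must be at least 1.")
  fmat <- seg_features(model, image)
  acc <- with_seed(seed, {
    total <- 0
    for (k in seq_len(n_samples)) {
      total <- total + forward_pass(model, fmat,
                                    stochastic = model$dropout_rate > 0)$probs
    }
    total / n_samples
  })
  lab <- max.col(acc, ties.method = "first") - 1L
  list(
    prob = array(acc, dim = c(nrow(image), ncol(image), 3)),
    labels = matrix(lab, nrow(image), ncol(image))
  )
}

#' Training configuration for the toy segmentation model
#'
#' Mirrors a standard Adam training recipe (learning rate 0.001 with
#' step decay, weight decay 0.0005, dropout 0.1, 15 Monte-Carlo samples)
#' at sizes suited to a single CPU: small patches and a few hundred
#' iterations.
#'
#' @param iterations optimizer steps.
#' @param batch_size patches per step.
#' @param patch_size square patch side (pixels).
#' @param learning_rate,lr_decay_factor,lr_decay_every Adam step size and
#'   step-decay schedule.
#' @param weight_decay L2 penalty on the softmax head.
#' @param dropout_rate dropout probability during training.
#' @param mc_samples Monte-Carlo samples at inference.
#' @param augment apply 90-degree rotation and gamma augmentations.
#' @param seed seed for sampling, dropout and augmentation.
#' @return list of class `train_config`.
#' @export
train_config <- function(iterations = 200, batch_size = 8, patch_size = 64,
                         learning_rate = 0.001, lr_decay_factor = 0.1,
                         lr_decay_every = 40000, weight_decay = 5e-4,
                         dropout_rate = 0.1, mc_samples = 15, augment = TRUE,
                         seed = 1L) {
  if (mc_samples < 1) abort("`mc_samples` must be >= 1.")
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort("`dropout_rate` must lie in [0, 1).")
  }
  structure(as.list(environment()), class = "train_config")
}

random_patch <- function(image, labels, size) {
  nr <- nrow(image)
  nc <- ncol(image)
  if (nr <= size && nc <= size) return(list(image = image, labels = labels))
  r0 <- sample.int(max(nr - size + 1L, 1L), 1L) - 1L
  c0 <- sample.int(max(nc - size + 1L, 1L), 1L) - 1L
  ri <- (r0 + 1):min(r0 + size, nr)
  ci <- (c0 + 1):min(c0 + size, nc)
  list(image = image[ri, ci], labels = labels[ri, ci])
}

augment_patch <- function(patch) {
  k <- sample(0:3, 1)
  rot90 <- function(m, k) {
    for (i in seq_len(k %% 4)) m <- t(m)[ncol(m):1, , drop = FALSE]
    m
  }
  img <- rot90(patch$image, k)
  lab <- rot90(patch$labels, k)
  gamma <- runif(1, 0.7, 1.4)
  img <- pmin(pmax(img, 0), 1)^gamma
  list(image = img, labels = lab)
}

# combined loss and analytic gradient of the softmax head on one patch
patch_loss_grad <- function(model, fmat_drop, probs, labels) {
  n <- nrow(probs)
  t_onehot <- matrix(0, n, 3)
  t_onehot[cbind(seq_len(n), as.integer(labels) + 1L)] <- 1
  # cross-entropy part
  dZ <- (probs - t_onehot) / n
  ce <- cross_entropy(probs, as.integer(labels))
  # soft-Dice part over the foreground classes
  dP <- matrix(0, n, 3)
  dice_terms <- numeric(0)
  for (cl in 2:3) {
    Rc <- t_onehot[, cl]
    Ac <- probs[, cl]
    S <- sum(Rc) + sum(Ac)
    if (S == 0) next
    I <- sum(Rc * Ac)
    dice_terms <- c(dice_terms, 2 * I / S)
    # d(1 - mean dice)/dA averaged over the two foreground classes
    dP[, cl] <- dP[, cl] - 0.5 * (2 * Rc * S - 2 * I) / S^2
  }
  dice_loss <- 1 - (if (length(dice_terms)) mean(dice_terms) else 0)
  # chain dP through the softmax
  inner <- rowSums(dP * probs)
  dZ <- dZ + probs * (dP - inner)
  list(loss = ce + dice_loss,
       grad_W = crossprod(fmat_drop, dZ))
}

#' Train the toy segmentation model on phantom image/label pairs
#'
#' Minibatch Adam on the softmax head with a combined loss: mean
#' cross-entropy plus one minus the mean foreground soft-Dice (standard
#' variant). The dilated filter bank stays fixed. Aborts with a
#' diagnostic if the loss diverges to NaN.
#'
#' @param dataset list of `list(image =, labels =)` pairs; images should
#'   be normalized to `[0, 1]` (see [normalize_intensities()]), labels
#'   integer matrices over `{0, 1, 2}`.
#' @param config a [train_config()].
#' @param model optional starting [seg_model()]; a fresh one is created
#'   from the config seed otherwise.
#' @return the trained `seg_model`, with a `log` tibble (`iteration`,
#'   `loss`, `lr`) attached.
#' @export
train_seg_model <- function(dataset, config = train_config(), model = NULL) {
  if (length(dataset) == 0) abort("`dataset` must be non-empty.")
  if (is.null(model)) {
    model <- seg_model(dropout_rate = config$dropout_rate, seed = config$seed)
  }
  model$dropout_rate <- config$dropout_rate
  if (config$iterations == 0) {
    model$log <- tibble(iteration = integer(), loss = numeric(),
                        lr = numeric())
    return(model)
  }
  mW <- vW <- matrix(0, nrow(model$W), ncol(model$W))
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  log_it <- integer(0); log_loss <- numeric(0); log_lr <- numeric(0)
  with_seed(config$seed, {
    for (it in seq_len(config$iterations)) {
      lr <- config$learning_rate *
        config$lr_decay_factor^(floor((it - 1) / config$lr_decay_every))
      grad <- matrix(0, nrow(model$W), ncol(model$W))
      loss <- 0
      for (bb in seq_len(config$batch_size)) {
        i <- sample.int(length(dataset), 1)
        patch <- random_patch(dataset[[i]]$image, dataset[[i]]$labels,
                              config$patch_size)
        if (config$augment) patch <- augment_patch(patch)
        fmat <- seg_features(model, patch$image)
        fw <- forward_pass(model, fmat, stochastic = TRUE)
        lg <- patch_loss_grad(model, fw$fmat, fw$probs, patch$labels)
        grad <- grad + lg$grad_W / config$batch_size
        loss <- loss + lg$loss / config$batch_size
      }
      if (!is.finite(loss)) {
        abort(sprintf("training diverged (loss %s at iteration %d).",
                      loss, it))
      }
      grad <- grad + config$weight_decay * model$W
      mW <- b1 * mW + (1 - b1) * grad
      vW <- b2 * vW + (1 - b2) * grad^2
      mhat <- mW / (1 - b1^it)
      vhat <- vW / (1 - b2^it)
      model$W <- model$W - lr * mhat / (sqrt(vhat) + adam_eps)
      log_it <- c(log_it, it); log_loss <- c(log_loss, loss)
      log_lr <- c(log_lr, lr)
    }
  })
  model$log <- tibble(iteration = log_it, loss = log_loss, lr = log_lr)
  model
}

# 26- or 6-connected component labelling of a 3D logical mask;
# returns an integer array (0 = background) with deterministic ids
label_components_3d <- function(mask, connectivity = 26) {
  d <- dim(mask)
  fore <- which(mask)
  out <- array(0L, dim = d)
  if (length(fore) == 0) return(out)
  id_of <- array(0L, dim = d)
  id_of[fore] <- seq_along(fore)
  coords <- arrayInd(fore, d)
  offsets <- expand.grid(dr = -1:1, dc = -1:1, ds = -1:1)
  offsets <- offsets[!(offsets$dr == 0 & offsets$dc == 0 & offsets$ds == 0), ]
  if (connectivity == 6) {
    offsets <- offsets[abs(offsets$dr) + abs(offsets$dc) + abs(offsets$ds) == 1, ]
  } else if (connectivity != 26) {
    abort("`connectivity` must be 6 or 26.")
  }
  # half the offsets suffice for an undirected graph
  keep <- offsets$ds > 0 | (offsets$ds == 0 & offsets$dc > 0) |
    (offsets$ds == 0 & offsets$dc == 0 & offsets$dr > 0)
  offsets <- offsets[keep, ]
  edges <- NULL
  for (k in seq_len(nrow(offsets))) {
    nb <- coords
    nb[, 1] <- nb[, 1] + offsets$dr[k]
    nb[, 2] <- nb[, 2] + offsets$dc[k]
    nb[, 3] <- nb[, 3] + offsets$ds[k]
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
      nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    lin <- (nb[ok, 3] - 1L) * d[1] * d[2] + (nb[ok, 2] - 1L) * d[1] + nb[ok, 1]
    nb_id <- id_of[lin]
    src <- which(ok)[nb_id > 0]
    if (length(src) > 0) {
      edges <- rbind(edges, cbind(src, nb_id[nb_id > 0]))
    }
  }
  g <- igraph::make_empty_graph(n = length(fore), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  out[fore] <- as.integer(memb)
  out
}

#' Retain the largest 3D connected component per class
#'
#' Removes isolated voxel clusters from a predicted label grid: for each
#' foreground class, only the largest 3D connected component
#' (26-connectivity by default) survives; everything else becomes
#' background. Ties between equally large components resolve to the
#' lowest component id of the deterministic labelling. Never adds voxels.
#'
#' @param grid3d 3D integer label grid `[row, col, slice]`.
#' @param connectivity 26 (default) or 6.
#' @return filtered 3D label grid.
#' @export
largest_component_filter <- function(grid3d, connectivity = 26) {
  out <- grid3d
  for (label in c(LV_LABEL, RV_LABEL)) {
    mask <- grid3d == label
    if (!any(mask)) next
    comp <- label_components_3d(mask, connectivity)
    sizes <- tabulate(comp[comp > 0])
    best <- which(sizes == max(sizes))[1]
    out[mask & comp != best] <- 0L
  }
  out
}

#' Segment a rendered cine volume with the toy model
#'
#' Runs Monte-Carlo-dropout inference slice by slice and phase by phase,
#' then applies the largest-connected-component filter per phase.
#'
#' @param model a trained [seg_model()].
#' @param intensity_vol a `cine_intensity_volume` (normalized or raw; raw
#'   input is normalized first).
#' @param n_samples Monte-Carlo samples per slice.
#' @param seed seed for the dropout draws.
#' @param phases phases to segment (default all).
#' @return a `cine_label_volume` (unsegmented phases stay background).
#' @export
segment_volume <- function(model, intensity_vol, n_samples = 15, seed = 1L,
                           phases = NULL) {
  img <- intensity_vol$intensities
  if (max(img) > 1 || min(img) < 0) img <- normalize_intensities(img)
  d <- dim(img)
  if (is.null(phases)) phases <- seq_len(d[4])
  labels <- array(0L, dim = d)
  seeds <- derive_seeds(seed, length(phases) * d[3])
  k <- 0L
  for (p in phases) {
    for (s in seq_len(d[3])) {
      k <- k + 1L
      pred <- mc_predict(model, img[, , s, p], n_samples, seed = seeds[k])
      labels[, , s, p] <- pred$labels
    }
    labels[, , , p] <- largest_component_filter(labels[, , , p])
  }
  cine_label_volume(labels, intensity_vol$in_plane_spacing_mm,
                    intensity_vol$slice_thickness_mm)
}
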