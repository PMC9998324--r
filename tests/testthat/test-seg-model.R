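test_that("soft-Dice matches its closed forms in both variants", {
  R <- matrix(0, 8, 8); R[3:6, 3:6] <- 1
  expect_equal(soft_dice(R, R, "standard"), 1)
  expect_equal(soft_dice(R, R, "as_printed"), 0.5)
  # uniform 0.5 probability on the support: 2*(0.5 S)/(S + 0.5 S) = 2/3
  A <- R * 0.5
  expect_equal(soft_dice(A, R, "standard"), 2 / 3)
  expect_warning(z <- soft_dice(matrix(0, 4, 4), matrix(0, 4, 4)), "empty")
  expect_equal(z, 0)
  expect_error(soft_dice(matrix(2, 2, 2), matrix(1, 2, 2)), "\\[0, 1\\]")
})

test_that("cross-entropy matches per-voxel summation", {
  n <- 16
  perfect <- matrix(0, n, 3)
  y <- rep(c(0L, 1L, 2L), length.out = n)
  perfect[cbind(seq_len(n), y + 1L)] <- 1
  expect_equal(cross_entropy(perfect, y), 0, tolerance = 1e-6)
  uniform <- matrix(1 / 3, n, 3)
  expect_equal(cross_entropy(uniform, y), log(3))
  # explicit per-voxel oracle on random 8x8 maps
  withr::with_seed(2, {
    p <- matrix(runif(64 * 3, 0.05, 1), 64, 3)
    p <- p / rowSums(p)
    yy <- sample(0:2, 64, replace = TRUE)
  })
  oracle <- -mean(log(p[cbind(1:64, yy + 1)]))
  expect_equal(cross_entropy(p, yy), oracle)
  expect_error(cross_entropy(p, yy[1:10]), "shapes differ")
})

test_that("softmax probabilities sum to one per pixel", {
  model <- seg_model(seed = 3)
  img <- matrix(runif(32 * 32), 32, 32)
  pred <- mc_predict(model, img, n_samples = 3, seed = 1)
  sums <- apply(pred$prob, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
})

test_that("Monte-Carlo dropout prediction is reproducible and collapses without dropout", {
  img <- matrix(runif(24 * 24), 24, 24)
  det_model <- seg_model(dropout_rate = 0, seed = 5)
  one <- mc_predict(det_model, img, n_samples = 1, seed = 1)
  many <- mc_predict(det_model, img, n_samples = 7, seed = 99)
  expect_equal(one$prob, many$prob)

  mc_model <- seg_model(dropout_rate = 0.3, seed = 5)
  a <- mc_predict(mc_model, img, n_samples = 5, seed = 8)
  b <- mc_predict(mc_model, img, n_samples = 5, seed = 8)
  expect_identical(a$prob, b$prob)
  c_ <- mc_predict(mc_model, img, n_samples = 5, seed = 9)
  expect_false(identical(a$prob, c_$prob))
  expect_error(mc_predict(mc_model, img, n_samples = 0), "at least 1")
})

test_that("the variance of the MC mean scales like one over the sample count", {
  model <- seg_model(dropout_rate = 0.3, seed = 2)
  img <- matrix(runif(16 * 16, 0.3, 0.8), 16, 16)
  var_at <- function(n_samples, reps = 40) {
    probs <- vapply(seq_len(reps), function(r) {
      mc_predict(model, img, n_samples, seed = 1000 + r)$prob[8, 8, 2]
    }, numeric(1))
    var(probs)
  }
  v1 <- var_at(1)
  v15 <- var_at(15)
  expect_gt(v1, v15)
  # ratio compatible with 1/n scaling (generous band for 40 replicates)
  expect_gt(v1 / v15, 4)
  expect_lt(v1 / v15, 60)
})

test_that("largest-component filtering matches a flood-fill oracle and never adds voxels", {
  # single component untouched
  g <- array(0L, dim = c(8, 8, 3))
  g[2:4, 2:4, 1:2] <- 1L
  expect_identical(largest_component_filter(g), g)

  # 50-voxel component kept, 3-voxel satellite removed
  g2 <- array(0L, dim = c(10, 10, 3))
  g2[1:5, 1:5, 1:2] <- 1L
  g2[9:10, 9, 3] <- 1L
  g2[10, 10, 3] <- 1L
  out <- largest_component_filter(g2)
  expect_equal(sum(out == 1L), 50)
  expect_equal(sum(out[, , 3] == 1L), 0)

  withr::with_seed(6, {
    for (rep in 1:5) {
      sparse <- array(ifelse(runif(10 * 10 * 4) < 0.12, 2L, 0L),
                      dim = c(10, 10, 4))
      res <- largest_component_filter(sparse)
      # never adds voxels
      expect_true(all(res[sparse == 0L] == 0L))
      # the retained voxels are exactly the oracle's largest component
      oracle <- flood_fill_components(sparse == 2L)
      if (max(oracle) > 0) {
        sizes <- tabulate(oracle[oracle > 0])
        expect_equal(sum(res == 2L), max(sizes))
        keep <- which(sizes == max(sizes))[1]
        expect_true(all(res[oracle == keep] == 2L))
      }
    }
  })

  # 6- vs 26-connectivity: diagonal-only touching splits under 6
  diag_g <- array(0L, dim = c(4, 4, 2))
  diag_g[1, 1, 1] <- 1L
  diag_g[2, 2, 2] <- 1L
  expect_equal(sum(largest_component_filter(diag_g, connectivity = 26) == 1L), 2)
  expect_equal(sum(largest_component_filter(diag_g, connectivity = 6) == 1L), 1)
})

test_that("a short training run improves phantom Dice over the untrained head", {
  grid <- phantom_grid(shape = c(48, 48), n_slices = 4,
                       in_plane_spacing_mm = 3, slice_thickness_mm = 8)
  make_pair <- function(seed) {
    vol <- rasterize_phantom(
      volume_profile(55, 25, 2, 0.5), volume_profile(70, 35, 2, 0.5), grid
    )
    img <- normalize_intensities(render_image(vol, noise_sd = 8, seed = seed))
    s <- 3 # a mid slice
    list(image = img$intensities[, , s, 1], labels = vol$labels[, , s, 1])
  }
  dataset <- lapply(1:3, make_pair)

  # a short run needs a larger step size than the full-scale recipe
  cfg <- train_config(iterations = 120, batch_size = 6, patch_size = 48,
                      dropout_rate = 0.1, learning_rate = 0.01, seed = 7)
  init <- seg_model(dropout_rate = 0.1, seed = cfg$seed)
  frozen <- train_seg_model(dataset, train_config(iterations = 0, seed = 7),
                            model = init)
  expect_identical(frozen$W, init$W)

  trained <- train_seg_model(dataset, cfg, model = init)
  expect_equal(nrow(trained$log), 120)
  expect_true(all(is.finite(trained$log$loss)))

  held_out <- make_pair(seed = 99)
  dice_of <- function(model) {
    pred <- mc_predict(model, held_out$image, n_samples = 5, seed = 1)
    mean(c(
      dice3d(array(pred$labels, c(48, 48, 1)),
             array(held_out$labels, c(48, 48, 1)), "LV"),
      dice3d(array(pred$labels, c(48, 48, 1)),
             array(held_out$labels, c(48, 48, 1)), "RV")
    ))
  }
  expect_gt(dice_of(trained), dice_of(init))
  expect_gt(dice_of(trained), 0.5)
})

test_that("segmenting a rendered cine volume yields a valid label volume", {
  grid <- phantom_grid(shape = c(40, 40), n_slices = 3,
                       in_plane_spacing_mm = 3.5, slice_thickness_mm = 8)
  vol <- rasterize_phantom(volume_profile(40, 20, 2, 0.5),
                           volume_profile(50, 25, 2, 0.5), grid)
  img <- normalize_intensities(render_image(vol, noise_sd = 5, seed = 2))
  model <- seg_model(dropout_rate = 0.1, seed = 4)
  seg <- segment_volume(model, img, n_samples = 3, seed = 6, phases = 1)
  expect_s3_class(seg, "cine_label_volume")
  expect_true(all(seg$labels %in% c(0L, 1L, 2L)))
  expect_equal(dim(seg$labels), dim(vol$labels))
})
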