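test_that("Dice handles perfect, disjoint, partial and empty masks", {
  a <- array(0L, dim = c(6, 6, 3))
  a[2:3, 2:3, 1] <- 1L
  expect_equal(dice3d(a, a, "LV"), 1)
  b <- array(0L, dim = c(6, 6, 3))
  b[5:6, 5:6, 2] <- 1L
  expect_equal(dice3d(a, b, "LV"), 0)
  # |A| = |B| = 2 with overlap 1
  a2 <- array(0L, dim = c(4, 4, 1)); a2[1:2, 1, 1] <- 1L
  b2 <- array(0L, dim = c(4, 4, 1)); b2[2:3, 1, 1] <- 1L
  expect_equal(dice3d(a2, b2, "LV"), 0.5)
  # both empty = agreement on absence
  z <- array(0L, dim = c(4, 4, 1))
  expect_equal(dice3d(z, z, "RV"), 1)
  z3 <- array(0L, dim = c(6, 6, 3))
  expect_equal(dice3d(a, z3, "LV"), 0)
  expect_error(dice3d(a, a2, "LV"), "shape")
})

test_that("Hausdorff distance matches arithmetic and an all-pairs oracle", {
  a <- array(FALSE, dim = c(8, 8, 6)); a[4, 4, 2] <- TRUE
  b <- array(FALSE, dim = c(8, 8, 6)); b[4, 4, 5] <- TRUE
  expect_equal(hausdorff3d(a, b, spacing = c(1, 1, 8)), 24)
  expect_equal(hausdorff3d(a, a, spacing = c(1, 1, 8)), 0)
  expect_error(hausdorff3d(a, array(FALSE, dim = c(8, 8, 6))), "empty")

  withr::with_seed(7, {
    for (rep in 1:6) {
      m1 <- array(runif(8 * 8 * 4) < 0.15, dim = c(8, 8, 4))
      m2 <- array(runif(8 * 8 * 4) < 0.15, dim = c(8, 8, 4))
      if (!any(m1) || !any(m2)) next
      sp <- c(1.3, 1.3, 7)
      expect_equal(hausdorff3d(m1, m2, spacing = sp),
                   hausdorff_oracle(m1, m2, sp), tolerance = 1e-10)
      # symmetry
      expect_equal(hausdorff3d(m1, m2, spacing = sp),
                   hausdorff3d(m2, m1, spacing = sp))
    }
  })
})

test_that("error attribution classifies slices relative to the reference extent", {
  ref <- tiny_phantom(n_phases = 4)
  none <- attribute_errors(ref, ref, "RV", phases = c(1, 3))
  expect_equal(none$total_errors, 0)
  expect_equal(none$basal + none$mid + none$apical + none$outside, 0)

  # emptying the top reference slice puts every error in the basal bin
  occ <- occupied <- which(apply(phase_labels(ref, 1) == 2L, 3, any))
  auto <- ref
  auto$labels[, , max(occ), 1][auto$labels[, , max(occ), 1] == 2L] <- 0L
  att <- attribute_errors(auto, ref, "RV", phases = 1)
  expect_equal(att$basal, 1)

  # a false positive above the base lands in the outside bin
  auto2 <- ref
  auto2$labels[30, 30, max(occ) + 1, 1] <- 2L
  att2 <- attribute_errors(auto2, ref, "RV", phases = 1)
  expect_equal(att2$outside, 1)
  expect_equal(att2$total_errors, 1)
})

test_that("attribution fractions sum to one whenever errors exist", {
  ref <- tiny_phantom()
  auto <- degrade_segmentation(
    ref, list(degradation_spec("RV", seed = 1), degradation_spec("LV", seed = 2)),
    phases = c(1, 6)
  )
  for (st in c("RV", "LV")) {
    att <- attribute_errors(auto, ref, st, phases = c(1, 6))
    expect_gt(att$total_errors, 0)
    expect_equal(att$basal + att$mid + att$apical + att$outside, 1,
                 tolerance = 1e-9)
  }
})

test_that("phase differences wrap circularly as a percentage of the cycle", {
  expect_equal(phase_difference(12, 10, 25), 8)
  expect_equal(phase_difference(24, 0, 25), -4)
  expect_equal(phase_difference(0, 24, 25), 4)
  for (k in c(0, 3, 12)) expect_equal(phase_difference(k, k, 25), 0)
  # half-cycle maps to +50, not -50
  expect_equal(phase_difference(12, 0, 24), 50)
  expect_error(phase_difference(1, 1, 1), "at least 2")
})

test_that("Bland-Altman statistics follow the textbook formulas", {
  same <- bland_altman(1:5, 1:5)
  expect_equal(same$bias, 0)
  expect_equal(c(same$loa_low, same$loa_high), c(0, 0))

  d2 <- bland_altman(c(1, -1), c(0, 0))
  expect_equal(d2$bias, 0)
  expect_equal(d2$sd_diff, sqrt(2))
  expect_equal(d2$loa_high, 1.96 * sqrt(2))

  withr::with_seed(9, {
    x <- rnorm(40, 100, 10)
    y <- x + rnorm(40, 2, 3)
    ba <- bland_altman(x, y)
    d <- x - y
    expect_equal(ba$bias, mean(d))
    expect_equal(ba$sd_diff, sd(d))
    expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d))
  })
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("Pearson r and its Fisher interval match the standard implementation", {
  x <- c(1, 2, 4, 7, 11)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  withr::with_seed(3, {
    y <- x + rnorm(5, 0, 2)
  })
  ours <- pearson_r(x, y)
  ref <- cor.test(x, y)
  expect_equal(ours$r, unname(ref$estimate))
  expect_equal(c(ours$conf_low, ours$conf_high), as.numeric(ref$conf.int),
               tolerance = 1e-6)
  expect_error(pearson_r(x, rep(1, 5)), "constant")
})

test_that("Cohen's kappa reproduces hand-computed and reference values", {
  # 2x2 table a=45, b=5, c=5, d=45: p_o = 0.9, p_e = 0.5, kappa = 0.8
  a <- rep(c("x", "x", "y", "y"), times = c(45, 5, 5, 45))
  b <- rep(c("x", "y", "x", "y"), times = c(45, 5, 5, 45))
  k <- cohens_kappa(a, b)
  expect_equal(k$p_o, 0.9)
  expect_equal(k$p_e, 0.5)
  expect_equal(k$kappa, 0.8)
  expect_equal(k$se, sqrt(0.9 * 0.1 / (100 * 0.25)))

  # cross-check against an independent implementation
  if (requireNamespace("e1071", quietly = TRUE)) {
    tab <- table(a, b)
    expect_equal(k$kappa, e1071::classAgreement(tab)$kappa)
  }

  # perfect agreement over >= 2 categories
  expect_equal(cohens_kappa(c("m", "n", "m"), c("m", "n", "m"))$kappa, 1)

  # invariance under category relabeling
  relab <- c(x = "QQ", y = "ZZ")
  expect_equal(cohens_kappa(relab[a], relab[b])$kappa, k$kappa)

  # near-independent labels give kappa near 0
  withr::with_seed(4, {
    u <- sample(c("p", "q"), 4000, replace = TRUE)
    v <- sample(c("p", "q"), 4000, replace = TRUE)
  })
  expect_lt(abs(cohens_kappa(u, v)$kappa), 0.05)

  expect_warning(deg <- cohens_kappa(rep("z", 5), rep("z", 5)), "undefined")
  expect_equal(deg$kappa, 1)
})

test_that("sensitivity and specificity match the contingency table", {
  d <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(unlist(sens_spec(d, d)[, 1:2]), c(sensitivity = 1, specificity = 1))
  expect_equal(unlist(sens_spec(!d, d)[, 1:2]), c(sensitivity = 0, specificity = 0))
  withr::with_seed(5, {
    test <- runif(200) < 0.4
    truth <- runif(200) < 0.3
  })
  ss <- sens_spec(test, truth)
  expect_equal(ss$sensitivity, sum(test & truth) / sum(truth))
  expect_equal(ss$specificity, sum(!test & !truth) / sum(!truth))
  expect_warning(nd <- sens_spec(test, rep(FALSE, 200)), "sensitivity undefined")
  expect_true(is.na(nd$sensitivity))
})

test_that("McNemar p-values follow the exact small-sample rule", {
  a <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(mcnemar_p(a, a), 1)
  # discordant pairs (2, 8): exact binomial oracle
  x <- rep(c(TRUE, TRUE, FALSE), times = c(2, 10, 8))
  y <- rep(c(FALSE, TRUE, TRUE), times = c(2, 10, 8))
  expect_equal(mcnemar_p(x, y), binom.test(2, 10, 0.5)$p.value)
  # symmetric discordants (10, 10) -> p = 1
  x2 <- rep(c(TRUE, FALSE), times = c(10, 10))
  y2 <- rep(c(FALSE, TRUE), times = c(10, 10))
  expect_equal(mcnemar_p(x2, y2), 1)
  # large-sample branch agrees with the chi-square test
  x3 <- rep(c(TRUE, FALSE, TRUE), times = c(20, 15, 30))
  y3 <- rep(c(FALSE, TRUE, TRUE), times = c(20, 15, 30))
  tab <- matrix(c(30, 20, 15, 0), nrow = 2)
  expect_equal(mcnemar_p(x3, y3), mcnemar.test(tab)$p.value)
})

test_that("transition tables count every subject exactly once", {
  m <- c("none", "none", "minor", "major", "major")
  a <- c("none", "minor", "minor", "minor", "major")
  tab <- tfc_transition_table(m, a)
  expect_equal(sum(tab$n), 5)
  expect_equal(tab$n[tab$manual == "major" & tab$auto == "minor"], 1)
  # row sums equal the per-method category counts
  rows <- tapply(tab$n, tab$manual, sum)
  expect_equal(as.vector(rows[c("none", "minor", "major")]), c(2, 1, 2))
})
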