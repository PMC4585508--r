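test_that("sphere membership matches brute-force lattice enumeration", {
  grid <- volume_grid(array(0, c(21, 21, 21)), c(1, 1, 1))
  # radius 0: exactly the voxel containing the centre
  expect_length(make_sphere_roi(c(0, 0, 0), 0, grid)$voxel_index, 1)
  # radius 1 on a 1-mm grid centred on a voxel centre: centre + 6 faces
  expect_length(make_sphere_roi(c(0, 0, 0), 1, grid)$voxel_index, 7)
  # radius 6: brute force over the whole grid
  roi <- make_sphere_roi(c(0, 0, 0), 6, grid)
  mm <- voxel_to_mm(grid, as.matrix(expand.grid(1:21, 1:21, 1:21)))
  brute <- sum(rowSums(mm^2) <= 36)
  expect_length(roi$voxel_index, brute)
  expect_error(make_sphere_roi(c(100, 0, 0), 6, grid), "outside the grid")
})

test_that("roi voxel count is monotone nondecreasing in radius", {
  grid <- volume_grid(array(0, c(15, 15, 15)), c(2, 2, 2))
  counts <- vapply(seq(0, 12, by = 1.5), function(r)
    length(make_sphere_roi(c(3, -2, 5), r, grid)$voxel_index), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("extraction averages the roi columns per subject", {
  grid <- volume_grid(array(1, c(10, 10, 10)), c(2, 2, 2))
  mask <- seq_len(1000)
  set.seed(30)
  Y <- matrix(rnorm(5000), 5, 1000)
  mat <- cohort_matrix(Y, mask, grid, "GM")
  roi <- make_sphere_roi(c(0, 0, 0), 4, grid)
  m <- extract_roi_means(mat, roi)
  expect_equal(unname(m), rowMeans(Y[, roi$voxel_index]))
  # constant map -> the constant; single-voxel roi -> that voxel
  matc <- cohort_matrix(matrix(3, 5, 1000), mask, grid, "GM")
  expect_equal(unname(extract_roi_means(matc, roi)), rep(3, 5))
  roi1 <- make_sphere_roi(c(0, 0, 0), 0, grid)
  expect_equal(unname(extract_roi_means(mat, roi1)),
               Y[, roi1$voxel_index])
  # roi voxels outside the mask are dropped with a message
  mat2 <- cohort_matrix(Y[, 1:500], mask[1:500], grid, "GM")
  roi_out <- make_sphere_roi(c(8, 8, 8), 6, grid)
  if (any(roi_out$voxel_index > 500) && any(roi_out$voxel_index <= 500))
    expect_message(extract_roi_means(mat2, roi_out), "dropped")
})

test_that("the roi group test matches the textbook pooled t", {
  set.seed(31)
  x <- rnorm(24); g <- factor(rep(c("a", "b"), each = 12))
  res <- roi_group_test(x, g)
  oracle <- t.test(x[g == "a"], x[g == "b"], var.equal = TRUE)
  expect_equal(res$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$p, oracle$p.value, tolerance = 1e-12)
  expect_equal(res$df, 22)
  # identical groups: t = 0, d = 0
  res0 <- roi_group_test(rep(x[1:12], 2), g)
  expect_equal(res0$t, 0)
  expect_equal(res0$d, 0)
})

test_that("an embedded subcortical reduction reproduces the delay < no-delay direction", {
  spec <- cohort_spec(
    n_per_group = c(ASC_delay = 15, ASC_nodelay = 15),
    effect_blobs = list(list(center_mm = c(-18, -8, 0), radius_mm = 16,
                             amplitude = 0.1, sign = -1,
                             groups = "ASC_delay", tissue = "GM")),
    latent_spatial_pattern = list(), global_gm_offset = 0, seed = 33)
  co <- generate_cohort(spec)
  prep <- prepare_cohort(co)
  roi <- make_sphere_roi(c(-18, -8, 0), 6, prep$gm$grid)
  vals <- extract_roi_means(prep$gm, roi)
  res <- roi_group_test(vals, factor(prep$subjects$group,
                                     levels = c("ASC_nodelay", "ASC_delay")))
  # second level (delay) has the smaller mean: positive t for nodelay - delay
  expect_lt(res$groups$ASC_delay$mean, res$groups$ASC_nodelay$mean)
  expect_lt(res$p, 0.05)
})

test_that("the Hotelling-Lawley MANCOVA matches stats::manova", {
  set.seed(32)
  n <- 40
  Y <- matrix(rnorm(n * 3), n, 3)
  g <- factor(rep(c("a", "b"), each = n / 2))
  age <- rnorm(n, 30, 5)
  center <- factor(sample(c("c1", "c2", "c3"), n, replace = TRUE))
  res <- mancova_hotelling(Y, g, data.frame(age = age, center = center))
  fit <- summary(stats::manova(Y ~ age + center + g),
                 test = "Hotelling-Lawley")
  row <- fit$stats["g", ]
  expect_equal(res$trace, unname(row["Hotelling-Lawley"]), tolerance = 1e-10)
  expect_equal(res$F, unname(row["approx F"]), tolerance = 1e-10)
  expect_equal(res$p, unname(row["Pr(>F)"]), tolerance = 1e-10)
  # identical groups -> trace 0
  Y2 <- rbind(Y[1:20, ], Y[1:20, ])
  res0 <- mancova_hotelling(Y2, g)
  expect_equal(res0$trace, 0, tolerance = 1e-12)
  # one response reduces to the squared partial t
  res1 <- mancova_hotelling(Y[, 1, drop = FALSE], g,
                            data.frame(age = age, center = center))
  lmfit <- summary(lm(Y[, 1] ~ age + center + g))
  expect_equal(res1$F, unname(lmfit$coefficients["gb", "t value"]^2),
               tolerance = 1e-10)
})

test_that("bundled roi tables load with the documented shape", {
  pub <- published_delay_rois()
  expect_equal(nrow(pub), 6)
  expect_setequal(unique(pub$tissue), c("GM", "WM"))
  lang <- canonical_language_rois()
  expect_equal(nrow(lang), 13)
  expect_true(all(c("label", "x", "y", "z") %in% names(lang)))
})
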