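test_that("the correlation stack matches hand-computed Pearson correlations", {
  brain <- list(GM = matrix(c(1, 2, 4, 1, 0, 2), 3, 2))
  behavior <- matrix(c(2, 1, 6), 3, 1, dimnames = list(NULL, "m"))
  stack <- build_correlation_stack(brain, behavior)
  hand <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(as.numeric(stack),
               c(hand(behavior[, 1], brain$GM[, 1]),
                 hand(behavior[, 1], brain$GM[, 2])))
  expect_equal(dim(stack), c(1, 2))
})

test_that("blocks stack by group and condition; zero-variance voxels are zeroed", {
  set.seed(20)
  brain <- list(GM = matrix(rnorm(30), 6, 5), WM = matrix(rnorm(30), 6, 5))
  brain$GM[, 3] <- 7  # constant voxel
  behavior <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("a", "b")))
  groups <- factor(rep(c("g1", "g2"), each = 3))
  stack <- build_correlation_stack(brain, behavior, groups)
  expect_equal(dim(stack), c(2 * 2 * 2, 5))  # measures x conditions x groups
  expect_true(all(stack[grepl("GM", rownames(stack)), 3] == 0))
  expect_equal(attr(stack, "zero_variance"), 2)  # one voxel in two GM blocks
})

test_that("under the null all stack entries stay within sampling error", {
  set.seed(21)
  brain <- list(GM = matrix(rnorm(40 * 200), 40, 200))
  behavior <- matrix(rnorm(40 * 3), 40, 3,
                     dimnames = list(NULL, c("a", "b", "c")))
  stack <- build_correlation_stack(brain, behavior)
  expect_lt(max(abs(stack)), 6 / sqrt(40))
})

test_that("the SVD decomposition matches the eigendecomposition oracle", {
  set.seed(22)
  stack <- matrix(rnorm(15), 3, 5)
  model <- fit_pls(stack)
  ev <- eigen(stack %*% t(stack))
  expect_equal(model$singular_values, sqrt(ev$values), tolerance = 1e-10)
  for (i in 1:3)
    expect_equal(abs(cor(model$behavior_saliences[, i], ev$vectors[, i])), 1,
                 tolerance = 1e-8)
  # saliences are unit norm, singular values nonincreasing,
  # covariance explained sums to 1
  expect_equal(colSums(model$brain_saliences^2), rep(1, 3))
  expect_true(all(diff(model$singular_values) <= 0))
  expect_equal(sum(model$covariance_explained), 1)
})

test_that("rank-1 stacks and simple singular values behave as expected", {
  stack <- matrix(c(3, 4), 1, 2)  # single correlation row
  model <- fit_pls(stack)
  expect_equal(model$singular_values[1], 5)
  expect_equal(model$covariance_explained[1], 1)
  expect_equal(abs(as.numeric(model$brain_saliences)), c(0.6, 0.8))
  m2 <- fit_pls(diag(c(2, 1))) # singular values (2, 1) -> 80% / 20%
  expect_equal(m2$covariance_explained, c(0.8, 0.2))
  expect_error(fit_pls(matrix(0, 2, 3)), "all-zero")
})

test_that("brain scores are the projection of centred voxel data on saliences", {
  set.seed(23)
  dat <- latent_data(n = 30, v = 40)
  brain <- list(GM = dat$brain)
  stack <- build_correlation_stack(brain, dat$behavior)
  model <- fit_pls(stack, brain)
  expect_equal(model$brain_scores$GM[, 1],
               as.numeric(scale(dat$brain, scale = FALSE) %*%
                            model$brain_saliences[, 1]))
})

test_that("permutation inference flags an embedded LV and respects the bound", {
  set.seed(24)
  dat <- latent_data(n = 60, v = 300, snr = 2)
  perm <- pls_permutation(list(GM = dat$brain), dat$behavior, n_perm = 200)
  expect_lte(perm$perm_p[1], 1 / 200)
  expect_equal(dim(perm$null), c(200, 3))
})

test_that("bootstrap ratios scale saliences by their resampling SE", {
  set.seed(25)
  dat <- latent_data(n = 50, v = 60, snr = 2)
  brain <- list(GM = cbind(dat$brain, 5))  # last voxel constant
  boot <- pls_bootstrap(brain, dat$behavior, n_boot = 120)
  expect_equal(dim(boot$bootstrap_ratio), c(61, 3))
  # constant voxel: zero salience in every resample -> BR 0
  expect_equal(boot$bootstrap_ratio[61, 1], 0)
  # embedded-pattern voxels are reliably flagged relative to background
  br1 <- abs(boot$bootstrap_ratio[1:60, 1])
  expect_gt(mean(br1[dat$pattern == 1] >= 2.5),
            mean(br1[dat$pattern == 0] >= 2.5))
  # score-correlation overview has calibrated observed r within the CI
  sc <- boot$score_correlations
  expect_true(all(sc$lower <= sc$r & sc$r <= sc$upper))
})

test_that("1-group and 2-group variants agree for statistically identical groups", {
  set.seed(26)
  dat <- latent_data(n = 80, v = 400, snr = 2)
  groups <- factor(rep(c("g1", "g2"), each = 40))
  m1 <- fit_pls(build_correlation_stack(list(GM = dat$brain), dat$behavior))
  m2 <- fit_pls(build_correlation_stack(list(GM = dat$brain), dat$behavior,
                                        groups))
  expect_gt(abs(cor(m1$brain_saliences[, 1], m2$brain_saliences[, 1])), 0.9)
})

test_that("visualization thresholding keeps only large suprathreshold clusters", {
  dims <- c(12, 12, 12)
  grid <- volume_grid(array(0, dims))
  mask <- seq_len(prod(dims))
  br <- rep(0, prod(dims))
  big <- as.matrix(expand.grid(2:6, 2:6, 2:6))       # 125 voxels
  small <- as.matrix(expand.grid(9:11, 9:11, 9:11))  # 27 voxels
  lin <- function(m) m[, 1] + 12 * (m[, 2] - 1) + 144 * (m[, 3] - 1)
  br[lin(big)] <- 3; br[lin(small)] <- -3
  out <- pls_visualize_threshold(br, mask, grid, br_cut = 2.5,
                                 min_cluster = 100)
  expect_equal(sum(out$values != 0), 125)  # 27-voxel cluster dropped
  none <- pls_visualize_threshold(rep(1, prod(dims)), mask, grid,
                                  br_cut = 2.5, min_cluster = 10)
  expect_true(all(none$values == 0))
})
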