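test_that("voxel-wise GLM matches the per-voxel regression oracle", {
  co <- cached_cohort("tiny", tiny_spec())
  asc <- co$subjects$diagnosis == "ASC"
  prep <- prepare_cohort(co, subset = asc)
  des <- vbm_design(factor(prep$subjects$group,
                           levels = c("ASC_nodelay", "ASC_delay")),
                    age = prep$subjects$age, center = prep$subjects$center)
  stat <- fit_voxelwise_glm(prep$gm, des)
  set.seed(5)
  for (v in sample(ncol(prep$gm$data), 50)) {
    fit <- lm(prep$gm$data[, v] ~ 0 + des$X)
    expect_equal(stat$t[v],
                 summary(fit)$coefficients["des$Xgroup", "t value"],
                 tolerance = 1e-8)
  }
  expect_equal(stat$df, sum(asc) - ncol(des$X))
})

test_that("identical groups give t = 0 and a single voxel matches the pooled t", {
  M <- matrix(rnorm(5 * 20), 5, 20)
  Y <- rbind(M, M)
  g <- factor(rep(c("a", "b"), each = 5))
  grid <- volume_grid(array(1, c(5, 2, 2)))
  mat <- cohort_matrix(Y, seq_len(20), grid, "GM")
  expect_lt(max(abs(fit_voxelwise_glm(mat, vbm_design(g))$t)), 1e-10)

  set.seed(6)
  y <- rnorm(14)
  g2 <- factor(rep(c("a", "b"), each = 7))
  grid1 <- volume_grid(array(1, c(1, 1, 1) * c(1, 1, 1)))
  mat1 <- cohort_matrix(matrix(y, 14, 1), 1L, grid1, "GM")
  stat <- fit_voxelwise_glm(mat1, vbm_design(g2))
  oracle <- t.test(y[g2 == "b"], y[g2 == "a"], var.equal = TRUE)
  expect_equal(stat$t[1], unname(oracle$statistic), tolerance = 1e-12)
})

test_that("rank-deficient designs fail naming the collinear column", {
  g <- factor(rep(c("a", "b"), each = 6))
  des <- vbm_design(g, age = rnorm(12))
  des$X <- cbind(des$X, age_dup = des$X[, "age"])
  grid <- volume_grid(array(1, c(2, 2, 2)))
  mat <- cohort_matrix(matrix(rnorm(12 * 8), 12, 8), 1:8, grid, "GM")
  expect_error(fit_voxelwise_glm(mat, des, c(0, 1, 0, 0)),
               "collinear.*age")
})

test_that("cluster formation respects 18-connectivity", {
  dims <- c(8, 8, 8)
  t0 <- rep(0, prod(dims))
  stat <- make_stat(t0, dims)
  expect_equal(nrow(form_clusters(stat, 0.025)), 0)   # empty table allowed

  # one isolated suprathreshold voxel
  t1 <- t0; idx <- function(i, j, k) i + 8 * (j - 1) + 64 * (k - 1)
  t1[idx(4, 4, 4)] <- 10
  tab <- form_clusters(make_stat(t1, dims), 0.025)
  expect_equal(tab$extent, 1)
  expect_equal(tab$peak_t, 10)

  # edge neighbours (offset 1,1,0) join under 18-connectivity
  t2 <- t0; t2[idx(4, 4, 4)] <- 10; t2[idx(5, 5, 4)] <- 9
  expect_equal(form_clusters(make_stat(t2, dims), 0.025)$extent, 2)

  # corner neighbours (offset 1,1,1) do not
  t3 <- t0; t3[idx(4, 4, 4)] <- 10; t3[idx(5, 5, 5)] <- 9
  expect_equal(sort(form_clusters(make_stat(t3, dims), 0.025)$extent),
               c(1, 1))
})

test_that("cluster extents sum to the suprathreshold voxel count", {
  set.seed(7)
  tv <- rnorm(12^3)
  stat <- make_stat(tv, c(12, 12, 12))
  tab <- form_clusters(stat, 0.025)
  expect_equal(sum(tab$extent), sum(stat_p(stat, "positive") < 0.025))
})

test_that("peak coordinates map through the affine to mm", {
  dims <- c(8, 8, 8)
  tv <- rep(0, prod(dims))
  tv[1] <- 10  # voxel (1,1,1)
  stat <- make_stat(tv, dims, voxel = 2)
  tab <- form_clusters(stat, 0.025)
  expect_equal(c(tab$peak_x, tab$peak_y, tab$peak_z),
               as.numeric(voxel_to_mm(stat$grid, c(1, 1, 1))))
})

test_that("permutation cluster FDR bounds, ties and direction symmetry", {
  spec <- tiny_spec(effect_blobs = list(list(
    center_mm = c(0, 0, 0), radius_mm = 22, amplitude = 0.3,
    sign = 1, groups = "ASC_delay", tissue = "GM")), seed = 21)
  co <- generate_cohort(spec)
  asc <- co$subjects$diagnosis == "ASC"
  prep <- prepare_cohort(co, subset = asc)
  des <- vbm_design(factor(prep$subjects$group,
                           levels = c("ASC_nodelay", "ASC_delay")),
                    age = prep$subjects$age, center = prep$subjects$center)
  stat <- fit_voxelwise_glm(prep$gm, des)
  tab <- form_clusters(stat, 0.025, "positive")
  expect_gt(nrow(tab), 0)
  set.seed(1)
  tab <- cluster_fdr(stat, tab, prep$gm, des, n_perm = 200)
  # a huge embedded effect attains the smallest attainable p = 1/n_perm
  expect_equal(min(tab$p), 1 / 200)
  expect_true(tab$significant[1])
  # equal extents share p and q
  if (any(duplicated(tab$extent))) {
    d <- tab$extent[duplicated(tab$extent)][1]
    expect_length(unique(tab$p[tab$extent == d]), 1)
    expect_length(unique(tab$q[tab$extent == d]), 1)
  }
  # relabeling the groups flips the contrast direction only
  des2 <- vbm_design(factor(prep$subjects$group,
                            levels = c("ASC_delay", "ASC_nodelay")),
                     age = prep$subjects$age, center = prep$subjects$center)
  stat2 <- fit_voxelwise_glm(prep$gm, des2)
  expect_equal(stat2$t, -stat$t, tolerance = 1e-10)
  tab2 <- form_clusters(stat2, 0.025, "negative")
  expect_equal(sort(tab2$extent), sort(tab$extent))
})

test_that("too few distinct permutations triggers the exhaustive set", {
  set.seed(8)
  g <- factor(rep(c("a", "b"), each = 3))
  grid <- volume_grid(array(1, c(3, 3, 3)))
  mat <- cohort_matrix(matrix(rnorm(6 * 27, sd = 1) +
                                outer(as.numeric(g) - 1.5, rep(4, 27)),
                              6, 27), 1:27, grid, "GM")
  des <- vbm_design(g)
  stat <- fit_voxelwise_glm(mat, des)
  tab <- form_clusters(stat, 0.025, "positive")
  expect_warning(res <- cluster_fdr(stat, tab, mat, des, n_perm = 100),
                 "exhaustive")
  expect_length(attr(res, "null_max"), choose(6, 3))
})
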