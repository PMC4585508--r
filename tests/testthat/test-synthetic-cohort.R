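test_that("language delay classification follows the milestone rule", {
  # boundary: exactly 24 / 33 months is not delay (strict 'later than')
  expect_equal(classify_delay(24, 33), "no_delay")
  expect_equal(classify_delay(25, 20), "delay")   # words disjunct
  expect_equal(classify_delay(12, 34), "delay")   # phrases disjunct
  expect_equal(classify_delay(NA, 34), "delay")
  expect_equal(classify_delay(20, NA), "no_delay")
  expect_equal(classify_delay(NA, NA), "undetermined")
  expect_error(classify_delay(-1, 10), "nonnegative")
  expect_equal(classify_delay(c(24, 25, 12), c(33, 20, 34)),
               c("no_delay", "delay", "delay"))
})

test_that("generated milestones are consistent with the group label", {
  co <- cached_cohort("tiny", tiny_spec())
  asc <- co$subjects[co$subjects$diagnosis == "ASC", ]
  expect_equal(classify_delay(asc$first_words_months, asc$first_phrases_months),
               asc$delay_status)
  expect_true(all(is.na(co$subjects$delay_status[co$subjects$group == "NT"])))
})

test_that("fixing the seed fixes every output", {
  a <- generate_cohort(tiny_spec(seed = 9))
  b <- generate_cohort(tiny_spec(seed = 9))
  expect_identical(a$gm, b$gm)
  expect_identical(a$wm, b$wm)
  expect_identical(a$subjects, b$subjects)
  c <- generate_cohort(tiny_spec(seed = 10))
  expect_false(identical(a$gm, c$gm))
})

test_that("the null generator with zero noise yields identical maps and zero t", {
  spec <- null_spec(noise_sd = 0, age_slope = 0,
                    centers = c(KCL = 0, Cambridge = 0, Oxford = 0))
  co <- generate_cohort(spec)
  expect_true(all(apply(co$gm, 2, function(x) diff(range(x)) == 0)))
  prep <- prepare_cohort(co, subset = co$subjects$diagnosis == "ASC")
  des <- vbm_design(factor(prep$subjects$group))
  stat <- fit_voxelwise_glm(prep$gm, des)
  expect_true(all(stat$t == 0))
})

test_that("maps are nonnegative and the delay subgroup carries the GM offset", {
  co <- cached_cohort("tiny", tiny_spec())
  expect_true(all(co$gm >= 0) && all(co$wm >= 0))
  # Monte-Carlo check of the expected total-GM ratio over replicate cohorts
  ratios <- vapply(1:200, function(r) {
    spec <- cohort_spec(n_per_group = c(ASC_delay = 10, ASC_nodelay = 10),
                        grid_shape = c(8, 8, 8), voxel_size = c(6, 6, 6),
                        global_gm_offset = 0.05, effect_blobs = list(),
                        latent_spatial_pattern = list(),
                        noise_sd = 0.02, seed = 1000 + r)
    co <- generate_cohort(spec)
    d <- co$subjects$group == "ASC_delay"
    mean(co$subjects$total_gm_cm3[d]) / mean(co$subjects$total_gm_cm3[!d])
  }, numeric(1))
  expect_equal(mean(ratios), 1.05, tolerance = 0.01)
})

test_that("degenerate grids and out-of-grid blobs are rejected", {
  expect_error(cohort_spec(grid_shape = c(6, 12, 12)), ">= 8")
  bad <- tiny_spec(effect_blobs = list(list(center_mm = c(500, 0, 0),
                                            radius_mm = 10, amplitude = 0.1,
                                            sign = 1, groups = "ASC_delay",
                                            tissue = "GM")))
  expect_error(generate_cohort(bad), "outside the grid")
})

test_that("behavioral scores follow the latent model", {
  spec <- cohort_spec(n_per_group = c(ASC = 400), grid_shape = c(8, 8, 8),
                      voxel_size = c(6, 6, 6), effect_blobs = list(),
                      latent_spatial_pattern = list(),
                      latent_loadings = c(VIQ = 0.6, FAS = 0.6, NWR = 0.5),
                      seed = 77)
  co <- generate_cohort(spec)
  # sample correlation between each score and the true factor near its loading
  for (m in c("VIQ", "FAS", "NWR"))
    expect_lt(abs(cor(co$subjects[[m]], co$factor) -
                    spec$latent_loadings[[m]]), 0.1)
  # scores live on the instruments' scales
  expect_equal(mean(co$subjects$VIQ), 108.7, tolerance = 3)
  expect_equal(sd(co$subjects$VIQ), 14.3, tolerance = 2.5)
})

test_that("cohorts round-trip through NIfTI and CSV on disk", {
  co <- cached_cohort("tiny", tiny_spec())
  dir <- tempfile("cohort_")
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$subjects$id, co$subjects$id)
  expect_equal(back$gm, co$gm, tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(file.exists(file.path(dir, "cohort_spec.yaml")))
  unlink(dir, recursive = TRUE)
})
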