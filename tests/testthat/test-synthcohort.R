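# Synthetic cohort generator: reproducibility, geometry, texture scaling,
# clinical table structure, outcome model.

test_that("lesion masks are seeded-reproducible and singly connected", {
  for (s in c(3L, 17L)) {
    m1 <- make_lesion_mask(c(30, 30, 16), c(1.5, 1.5, 3), 8, 0.5, seed = s)
    m2 <- make_lesion_mask(c(30, 30, 16), c(1.5, 1.5, 3), 8, 0.5, seed = s)
    expect_identical(m1$data, m2$data)
    lab <- strokeradiomics:::label_components_26(m1$data)
    expect_equal(max(lab), 1L)
    expect_gte(sum(m1$data), 10)
  }
})

test_that("irregularity 0 gives exactly the digital ball", {
  m <- make_lesion_mask(c(24, 24, 24), c(1, 1, 1), 5, 0, seed = 1)
  ax <- (1:24) - 12.5
  expected <- sum(outer(outer(ax^2, ax^2, "+"), ax^2, "+") <= 25)
  expect_equal(sum(m$data), expected)
})

test_that("oversized radius and degenerate inputs fail loudly", {
  expect_error(make_lesion_mask(c(10, 10, 10), c(1, 1, 1), 20, 0, seed = 1),
               "too large")
  expect_error(make_lesion_mask(c(30, 30, 30), c(1, 1, 1), 5, 1.5, seed = 1),
               "irregularity")
})

test_that("texture volumes are reproducible and h = 0 is homogeneous", {
  m <- make_lesion_mask(c(24, 24, 24), c(1, 1, 1), 7, 0, seed = 2)
  v1 <- make_texture_volume(m, 0.5, seed = 9)
  v2 <- make_texture_volume(m, 0.5, seed = 9)
  expect_identical(v1$data, v2$data)
  v0 <- make_texture_volume(m, 0, seed = 9)
  expect_lt(var(v0$data[m$data == 1]), 400)  # documented threshold 20^2
  empty <- roi_mask(array(0L, c(4, 4, 4)), c(1, 1, 1))
  expect_error(make_texture_volume(empty, 0.5, seed = 1), "empty")
})

test_that("within-mask variance increases monotonically with h", {
  set.seed(42)
  hs <- rep(seq(0.02, 0.98, length.out = 10), each = 5)
  vs <- vapply(seq_along(hs), function(i) {
    m <- make_lesion_mask(c(22, 22, 22), c(1, 1, 1), 6, 0.3, seed = 100 + i)
    v <- make_texture_volume(m, hs[i], seed = 200 + i)
    var(v$data[m$data == 1])
  }, numeric(1))
  expect_gt(cor(hs, vs, method = "spearman"), 0.9)
})

test_that("clinical table has 23 columns and calibrated missingness", {
  cl0 <- make_clinical(50, missing_rate = 0, seed = 4)
  expect_equal(ncol(cl0), 23)
  expect_false(anyNA(cl0))
  expect_true(all(cl0$aspects %in% 0:10))
  expect_true(all(cl0$nihss_baseline >= 0 & cl0$nihss_baseline <= 42))
  expect_true(all(cl0$nihss_24h >= 0 & cl0$nihss_24h <= 42))

  cl <- make_clinical(200, missing_rate = 0.05, seed = 4)
  ncell <- 200 * 23
  obs <- sum(is.na(cl))
  bounds <- qbinom(c(0.005, 0.995), ncell, 0.05)
  expect_gte(obs, bounds[1])
  expect_lte(obs, bounds[2])
})

test_that("clinical schema must have 23 uniquely named covariates", {
  bad <- default_clinical_schema()[1:20, ]
  expect_error(make_clinical(10, schema = bad, seed = 1), "23")
})

test_that("outcome model: prevalence, effect direction, mRS strata", {
  n <- 500
  set.seed(7)
  h <- runif(n); vol <- runif(n, 100, 5000)
  age <- rnorm(n, 70, 10); nihss <- rpois(n, 12)
  zero <- c(b0 = 0, b_het = 0, b_vol = 0, b_age = 0, b_nihss = 0)
  out0 <- make_outcome(h, vol, age, nihss, zero, seed = 5)
  bounds <- qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(sum(out0$binary), bounds[1])
  expect_lte(sum(out0$binary), bounds[2])

  het <- c(b0 = 0, b_het = 2, b_vol = 0, b_age = 0, b_nihss = 0)
  out1 <- make_outcome(h, vol, age, nihss, het, seed = 5)
  expect_gt(cor(h, out1$binary), 0)

  expect_true(all(out1$mrs90[out1$binary == 1] %in% 3:6))
  expect_true(all(out1$mrs90[out1$binary == 0] %in% 0:2))
  expect_identical(out1$binary, as.integer(out1$mrs90 >= 3))

  expect_error(make_outcome(h, vol, age, nihss,
                            c(b0 = NaN, b_het = 0, b_vol = 0, b_age = 0,
                              b_nihss = 0), seed = 1),
               "finite")
})

test_that("cohorts are bit-identical under a fixed seed", {
  cfg <- cohort_config(n_patients = 4, grid_shape = c(20, 20, 12),
                       voxel_spacing_mm = c(1.5, 1.5, 3),
                       lesion_radius_range_mm = c(4, 7), seed = 11L)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$patients[[2]]$dwi$data, c2$patients[[2]]$dwi$data)
  expect_identical(c1$patients[[3]]$flair_mask$data, c2$patients[[3]]$flair_mask$data)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$outcome, c2$outcome)
})

test_that("cohort write/read round-trips arrays, tables and the seed", {
  cfg <- cohort_config(n_patients = 3, grid_shape = c(18, 18, 10),
                       voxel_spacing_mm = c(1.5, 1.5, 3),
                       lesion_radius_range_mm = c(4, 6), seed = 21L)
  coh <- simulate_cohort(cfg)
  dir <- file.path(tempdir(), "cohort_rt")
  unlink(dir, recursive = TRUE)
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$patients[[1]]$dwi$data, coh$patients[[1]]$dwi$data,
               tolerance = 1e-6)
  expect_identical(back$patients[[2]]$dwi_mask$data, coh$patients[[2]]$dwi_mask$data)
  expect_equal(back$clinical, coh$clinical, tolerance = 1e-9)
  expect_equal(back$outcome$mrs90, coh$outcome$mrs90)
  expect_equal(back$manifest$seed, 21L)
  expect_equal(nrow(utils::read.csv(file.path(dir, "clinical.csv"))), 3)
  unlink(dir, recursive = TRUE)
})
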