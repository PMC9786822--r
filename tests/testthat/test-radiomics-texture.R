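# The five texture families: hand-worked micro-examples, degenerate
# conventions, and exact equality with brute-force enumeration oracles on
# random small ROIs.

.line_disc <- function(levels_vec) {
  lev <- array(levels_vec, c(1, 1, length(levels_vec)))
  disc_from_levels(lev)
}

test_that("GLCM on a single row matches hand-counted co-occurrences", {
  d <- .line_disc(c(1, 1, 2, 2))
  mats <- strokeradiomics:::glcm_matrices(d)
  # only the in-row direction pairs up
  expect_length(mats, 1)
  P <- mats[[1]] / sum(mats[[1]])
  expect_equal(P, matrix(c(2, 1, 1, 2) / 6, 2, 2))
  f <- glcm_features(d)
  expect_equal(unname(f["Contrast"]), 1 / 3)
})

test_that("constant ROI gives the degenerate single-cell GLCM", {
  lev <- array(1L, c(3, 3, 3))
  f <- glcm_features(disc_from_levels(lev))
  expect_equal(unname(f["JointEnergy"]), 1)
  expect_equal(unname(f["Contrast"]), 0)
  expect_equal(unname(f["MaximumProbability"]), 1)
  expect_equal(unname(f["Correlation"]), 1)   # documented fallback
})

test_that("GLCM matrices equal the brute-force pair-counting oracle", {
  for (s in 1:20) {
    lev <- random_small_roi(s)
    d <- disc_from_levels(lev)
    mats <- strokeradiomics:::glcm_matrices(d)
    dirs <- strokeradiomics:::unique_directions()
    oracle <- list()
    for (r in seq_len(nrow(dirs))) {
      M <- oracle_glcm(lev, dirs[r, ])
      if (sum(M) > 0) oracle[[length(oracle) + 1]] <- M
    }
    expect_equal(mats, oracle, info = paste("seed", s))
  }
})

test_that("GLRLM runs on a single row match hand enumeration", {
  d <- .line_disc(c(1, 1, 2, 2, 2))
  M <- strokeradiomics:::.glrlm_one_direction(d, c(0, 0, 1))
  expect_equal(M, rbind(c(0, 1, 0), c(0, 0, 1)))
  feats <- strokeradiomics:::.rl_sz_features(M, Np = 5)
  expect_equal(unname(feats["SmallEmphasis"]), (1 / 4 + 1 / 9) / 2)
  # constant line: one run of length N
  d5 <- .line_disc(rep(1, 5))
  M5 <- strokeradiomics:::.glrlm_one_direction(d5, c(0, 0, 1))
  expect_equal(M5, matrix(c(0, 0, 0, 0, 1), 1, 5))
  expect_equal(unname(strokeradiomics:::.rl_sz_features(M5, 5)["Percentage"]),
               1 / 5)
})

test_that("GLRLM matrices equal the brute-force run enumeration oracle", {
  for (s in 1:20) {
    lev <- random_small_roi(s + 100)
    d <- disc_from_levels(lev)
    dirs <- strokeradiomics:::unique_directions()
    for (r in seq_len(nrow(dirs))) {
      M <- strokeradiomics:::.glrlm_one_direction(d, dirs[r, ])
      O <- oracle_glrlm(lev, dirs[r, ])
      # trim trailing all-zero columns before comparing
      expect_equal(M[, seq_len(max(which(colSums(M) > 0))), drop = FALSE],
                   O[, seq_len(max(which(colSums(O) > 0))), drop = FALSE],
                   info = paste("seed", s, "dir", r))
    }
  }
})

test_that("GLSZM zones match flood-fill labelling", {
  # two disjoint equal-level blobs of sizes 3 and 5
  lev <- array(NA_integer_, c(10, 3, 3))
  lev[1:3, 1, 1] <- 1L
  lev[6:10, 1, 1] <- 1L
  M <- strokeradiomics:::glszm_matrix(disc_from_levels(lev))
  expect_equal(M[1, 3], 1)
  expect_equal(M[1, 5], 1)
  expect_equal(sum(M), 2)
  # constant ROI: a single zone of size N
  levc <- array(2L, c(3, 3, 2)) - 1L
  Mc <- strokeradiomics:::glszm_matrix(disc_from_levels(levc))
  expect_equal(sum(Mc), 1)
  expect_equal(Mc[1, 18], 1)
})

test_that("GLSZM agrees with the oracle, including on checkerboards", {
  # 3D checkerboard: 26-connectivity merges same-level diagonal neighbours,
  # so the oracle decides the expected zone structure
  d3 <- c(4, 4, 4)
  lev <- array(1L + (outer(outer(1:4, 1:4, "+"), 1:4, "+") %% 2L), d3)
  expect_equal(strokeradiomics:::glszm_matrix(disc_from_levels(lev)),
               oracle_glszm(lev))
  for (s in 1:20) {
    lev <- random_small_roi(s + 200)
    expect_equal(strokeradiomics:::glszm_matrix(disc_from_levels(lev)),
                 oracle_glszm(lev), info = paste("seed", s))
  }
})

test_that("NGTDM table matches direct neighbourhood enumeration", {
  d <- .line_disc(c(1, 2, 1))
  tb <- strokeradiomics:::ngtdm_table(d)
  expect_equal(tb$s, c(2, 1))   # ends: |1-2| each; middle: |2-1|
  expect_equal(tb$n, c(2, 1))
  f <- ngtdm_features(d)
  expect_equal(sum(tb$n / tb$Nvp), 1)
  for (s in 1:20) {
    lev <- random_small_roi(s + 300)
    tb <- strokeradiomics:::ngtdm_table(disc_from_levels(lev))
    ob <- oracle_ngtdm(lev)
    expect_equal(tb$n, ob$n, info = paste("seed", s))
    expect_equal(tb$s, ob$s, info = paste("seed", s))
  }
})

test_that("NGTDM degenerate conventions on a constant ROI", {
  lev <- array(1L, c(3, 3, 3))
  f <- ngtdm_features(disc_from_levels(lev))
  expect_equal(unname(f["Strength"]), 0)
  expect_equal(unname(f["Busyness"]), 0)
  expect_equal(unname(f["Coarseness"]), 1e6)   # documented cap
})

test_that("GLDM dependence sizes count the centre voxel", {
  d <- .line_disc(c(1, 1, 1))
  M <- strokeradiomics:::gldm_matrix(d, alpha = 0)
  # dependent-neighbour counts (1, 2, 1) -> sizes (2, 3, 2)
  expect_equal(M[1, ], c(0, 2, 1))
  expect_equal(sum(M), 3)
})

test_that("GLDM matrices sum to the voxel count and match the oracle", {
  for (s in 1:20) {
    lev <- random_small_roi(s + 400)
    for (alpha in c(0, 1)) {
      M <- strokeradiomics:::gldm_matrix(disc_from_levels(lev), alpha)
      expect_equal(M, oracle_gldm(lev, alpha), info = paste("seed", s, alpha))
      expect_equal(sum(M), sum(!is.na(lev)))
    }
  }
})

test_that("GLDM DNN on uniform blocks matches the combinatorial closed form", {
  # on a uniform k-cube all neighbours are dependent, so dependence sizes
  # are fixed by position: corners 8, edge voxels 12, face voxels 18,
  # interior 27; DNN follows by direct counting (it is NOT monotone in k:
  # it falls from the tiny-block limit of 1 and rises back towards 1 as the
  # interior dominates)
  dnn_closed <- function(k) {
    (8^2 + (12 * (k - 2))^2 + (6 * (k - 2)^2)^2 + ((k - 2)^3)^2) / k^6
  }
  dnn <- vapply(c(2, 3, 5, 8), function(k) {
    lev <- array(1L, c(k, k, k))
    unname(gldm_features(disc_from_levels(lev))["DependenceNonUniformityNormalized"])
  }, numeric(1))
  expect_equal(dnn, vapply(c(2, 3, 5, 8), dnn_closed, numeric(1)))
  expect_equal(dnn[1], 1)               # every voxel has dependence size 8
  expect_lt(dnn[2], dnn[1])             # falls away from the degenerate limit
})

test_that("probability-normalised matrices sum to one", {
  lev <- random_small_roi(999)
  d <- disc_from_levels(lev)
  for (M in strokeradiomics:::glcm_matrices(d)) {
    expect_equal(sum(M / sum(M)), 1, tolerance = 1e-9)
  }
  tb <- strokeradiomics:::ngtdm_table(d)
  expect_equal(sum(tb$n / tb$Nvp), 1, tolerance = 1e-9)
})

test_that("direction-averaged features are invariant to axis permutation", {
  lev <- random_small_roi(7, max_dim = 6)
  perms <- list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))
  base <- c(glcm_features(disc_from_levels(lev)),
            glrlm_features(disc_from_levels(lev)),
            glszm_features(disc_from_levels(lev)),
            ngtdm_features(disc_from_levels(lev)),
            gldm_features(disc_from_levels(lev)))
  for (pm in perms) {
    lv2 <- aperm(lev, pm)
    got <- c(glcm_features(disc_from_levels(lv2)),
             glrlm_features(disc_from_levels(lv2)),
             glszm_features(disc_from_levels(lv2)),
             ngtdm_features(disc_from_levels(lv2)),
             gldm_features(disc_from_levels(lv2)))
    expect_equal(got, base, tolerance = 1e-9)
  }
})
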