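# Texture features against brute-force oracles, hand-enumerated examples,
# invariant bounds, shape and first-order statistics.

run_dv <- function(values, dims = c(1, 1, length(values)), ng = max(values)) {
  labels <- array(as.integer(values), dims)
  structure(list(labels = labels, ng = as.integer(ng),
                 mask = array(TRUE, dims), spacing = c(1, 1, 1)),
            class = "discretized_volume")
}
dir_z <- matrix(c(0L, 0L, 1L), 1)

test_that("hand-enumerated 1x1x4 run reproduces the textbook matrices", {
  dv <- run_dv(c(1, 1, 2, 2))
  p <- glcm_matrix(dv, directions = dir_z)
  expect_equal(p, matrix(c(1/3, 1/6, 1/6, 1/3), 2), tolerance = 1e-12)
  f <- glcm_features(p)
  expect_equal(unname(f["Idmn"]), 14 / 15, tolerance = 1e-12)
  expect_equal(unname(f["InverseVariance"]), 1 / 3, tolerance = 1e-12)

  R <- glrlm_matrix(dv, directions = dir_z)
  expect_equal(R[1, 2], 1)
  expect_equal(R[2, 2], 1)
  expect_equal(sum(R), 2)
  expect_equal(unname(glrlm_features(R, 4, 1)["RunEntropy"]), 1, tolerance = 1e-12)
})

test_that("degenerate single-level volumes hit the documented conventions", {
  dv <- run_dv(c(1, 1, 1, 1), ng = 1)
  p <- glcm_matrix(dv, directions = dir_z)
  expect_equal(p, matrix(1, 1, 1))
  f <- glcm_features(p)
  expect_equal(unname(f["Idmn"]), 1)
  expect_equal(unname(f["ClusterShade"]), 0)
  expect_equal(unname(f["InverseVariance"]), 0)
  expect_equal(unname(f["Imc1"]), 0)
  expect_equal(unname(f["Imc2"]), 0)
  expect_equal(unname(glrlm_features(glrlm_matrix(dv, directions = dir_z),
                                     4, 1)["RunEntropy"]), 0)

  # 1x1x3 constant: end voxels have one dependent neighbour, the middle two
  dv3 <- run_dv(c(1, 1, 1), ng = 1)
  de <- gldm_features(gldm_matrix(dv3))
  expect_equal(unname(de["DependenceEntropy"]),
               -(2/3) * log2(2/3) - (1/3) * log2(1/3), tolerance = 1e-12)

  # single in-mask voxel
  dv1 <- run_dv(1, dims = c(1, 1, 1), ng = 1)
  expect_equal(unname(gldm_features(gldm_matrix(dv1))["DependenceEntropy"]), 0)
})

test_that("texture matrices equal exhaustive brute-force oracles", {
  for (seed in c(7, 11, 13, 101:107)) {
    dv <- random_dv(seed)
    expect_equal(glcm_matrix(dv), oracle_glcm(dv$labels, dv$ng),
                 tolerance = 1e-9, info = paste("glcm seed", seed))
    expect_equal(glrlm_matrix(dv), oracle_glrlm(dv$labels, dv$ng),
                 tolerance = 1e-9, info = paste("glrlm seed", seed))
    expect_equal(gldm_matrix(dv), oracle_gldm(dv$labels, dv$ng),
                 tolerance = 1e-9, info = paste("gldm seed", seed))
  }
})

test_that("feature values respect their analytic ranges", {
  for (seed in 201:215) {
    dv <- random_dv(seed, dims = c(5, 5, 5), ng = 5)
    f <- glcm_features(glcm_matrix(dv))
    expect_gt(f[["Idmn"]], 0); expect_lte(f[["Idmn"]], 1)
    expect_gte(f[["Imc2"]], 0); expect_lt(f[["Imc2"]], 1)
    expect_gte(f[["InverseVariance"]], 0)
    r <- glrlm_features(glrlm_matrix(dv), sum(dv$mask))
    expect_gte(r[["RunEntropy"]], 0)
  }
})

test_that("features ignore voxels outside the mask", {
  dv <- random_dv(55, dims = c(5, 5, 5), ng = 4, p_mask = 0.6)
  dv2 <- dv
  # relabel out-of-mask voxels arbitrarily: labels there are 0 by contract,
  # so rebuild from a cube whose out-of-mask intensities are scrambled
  cube <- volume3d(array(runif(125), c(5, 5, 5)))
  mask <- volume3d(array(as.numeric(dv$mask), c(5, 5, 5)))
  d1 <- discretize(cube, mask, 4)
  cube2 <- cube
  cube2$data[!dv$mask] <- 99
  d2 <- discretize(cube2, mask, 4)
  expect_identical(d1$labels, d2$labels)
  expect_equal(feature_vector(cube, mask), feature_vector(cube2, mask))
})

test_that("discretization bins the in-mask range evenly", {
  cube <- volume3d(array(withr::with_seed(3, runif(8000)), c(20, 20, 20)))
  mask <- volume3d(array(1, c(20, 20, 20)))
  dv <- discretize(cube, mask, 4)
  occ <- tabulate(dv$labels[dv$mask], 4) / sum(dv$mask)
  expect_true(all(abs(occ - 0.25) < 0.03))
  expect_equal(discretize(volume3d(array(5, c(4, 4, 4))),
                          volume3d(array(1, c(4, 4, 4))))$ng, 1L)
  two <- discretize(volume3d(array(c(0.1, 0.9), c(2, 1, 1))),
                    volume3d(array(1, c(2, 1, 1))), 2)
  expect_identical(sort(unique(as.integer(two$labels))), c(1L, 2L))
  expect_error(discretize(cube, volume3d(array(0, c(20, 20, 20)))), "empty mask")
})

test_that("shape features recover ellipsoid geometry in physical units", {
  sphere_mask <- function(dims, semi, sp = c(1, 1, 1)) {
    ax <- lapply(1:3, function(k) ((seq_len(dims[k]) - 1) * sp[k] -
                                     (dims[k] - 1) * sp[k] / 2) / semi[k])
    r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
    volume3d(array(as.numeric(r2 <= 1), dims), sp)
  }
  s <- shape_features(sphere_mask(c(24, 24, 24), c(8, 8, 8)))
  expect_lt(abs(s[["Elongation"]] - 1), 0.02)

  e <- shape_features(sphere_mask(c(28, 28, 28), c(10, 5, 5)))
  expect_lt(abs(e[["Elongation"]] - 0.5), 0.03)

  # anisotropic spacing with compensating voxel counts: same physical object
  iso <- sphere_mask(c(30, 30, 30), c(10, 6, 6), sp = c(1, 1, 1))
  ani <- sphere_mask(c(30, 30, 60), c(10, 6, 6), sp = c(1, 1, 0.5))
  si <- shape_features(iso); sa <- shape_features(ani)
  expect_lt(abs(si[["Elongation"]] - sa[["Elongation"]]), 0.02)
  expect_lt(abs(si[["VoxelVolume"]] - sa[["VoxelVolume"]]) / si[["VoxelVolume"]], 0.05)

  one <- volume3d(array(c(1, rep(0, 26)), c(3, 3, 3)))
  expect_equal(shape_features(one)[["Elongation"]], 1)
})

test_that("first-order statistics match direct formulas", {
  cube <- volume3d(array(c(0, 0, 1, 1), c(4, 1, 1)))
  mask <- volume3d(array(1, c(4, 1, 1)))
  f <- firstorder_features(cube, mask)
  expect_equal(f[["Mean"]], 0.5)
  expect_equal(f[["Variance"]], 0.25) # population convention

  v <- withr::with_seed(8, runif(500))
  cube2 <- volume3d(array(v, c(5, 10, 10)))
  f2 <- firstorder_features(cube2, volume3d(array(1, c(5, 10, 10))))
  expect_equal(f2[["Mean"]], mean(v), tolerance = 1e-12)
  expect_equal(f2[["Variance"]], mean((v - mean(v))^2), tolerance = 1e-12)
  expect_equal(f2[["Skewness"]],
               mean((v - mean(v))^3) / mean((v - mean(v))^2)^1.5,
               tolerance = 1e-12)
  cf <- firstorder_features(volume3d(array(2, c(3, 3, 3))),
                            volume3d(array(1, c(3, 3, 3))))
  expect_equal(cf[["Variance"]], 0)
  expect_equal(cf[["Entropy"]], 0)
})

test_that("the feature table is complete, finite and reproducible", {
  coh <- generate_cohort(generator_config(n_lesions = 10, seed = 21,
                                          image_shape = 48,
                                          spacing_mm = c(1, 1, 1)))
  ft <- extract_feature_table(coh$cases[1:3])
  expect_equal(nrow(ft), 3)
  expect_true(all(is.finite(as.matrix(ft[, -1]))))
  expect_true(all(core_selected_features() %in% names(ft)))

  # duplicated lesion gives an identical feature row
  ft2 <- extract_feature_table(coh$cases[c(1, 1)])
  expect_equal(unlist(ft2[1, -1]), unlist(ft2[2, -1]))
})
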