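test_that("voxel correlations match hand-computed values", {
  b <- four_voxel_bold()
  r1 <- voxel_correlation_row(b, 1)
  expect_equal(r1, c(1, 1, -1, 0.8), tolerance = 1e-12)

  # affine rescaling of any series leaves correlations unchanged
  b2 <- b
  b2$data[2, ] <- 3.7 * b2$data[2, ] + 12
  expect_equal(voxel_correlation_row(b2, 1), r1, tolerance = 1e-12)

  expect_error(voxel_correlation_row(b, 9), "outside")
  bz <- b
  bz$data[3, ] <- 5
  expect_error(voxel_correlation_row(bz, 1), "zero variance")
})

test_that("the four-voxel worked example gives the hand-derived degrees", {
  b <- four_voxel_bold()
  expect_equal(compute_dc(b, r0 = 0.25, variant = "weighted")$values,
               c(1.8, 1.8, 0, 1.6), tolerance = 1e-12)
  expect_equal(compute_dc(b, r0 = 0.25, variant = "binary")$values,
               c(2, 2, 0, 2))
  expect_equal(compute_dc(b, r0 = 0.999, variant = "weighted")$values,
               c(1, 1, 0, 0), tolerance = 1e-12)
  expect_error(compute_dc(b, r0 = 1.5), "r0")
  expect_error(compute_dc(b, r0 = 0), "r0")
})

test_that("chunked degree equals the dense brute-force computation", {
  b <- random_bold(150, 30, seed = 21)
  set.seed(22)
  r0s <- runif(5, 0.05, 0.9)
  for (r0 in r0s) {
    for (variant in c("weighted", "binary")) {
      oracle <- dense_dc_oracle(b, r0, variant)
      for (cs in c(1L, 7L, 64L, 150L, 4096L)) {
        got <- compute_dc(b, r0 = r0, variant = variant,
                          chunk_size = cs)$values
        expect_lt(max(abs(got - oracle)), 1e-10)
      }
    }
  }
})

test_that("degree is invariant to affine series rescaling", {
  b <- random_bold(60, 25, seed = 5)
  base <- compute_dc(b, 0.25)$values
  b$data[13, ] <- 3.7 * b$data[13, ] + 12
  expect_lt(max(abs(compute_dc(b, 0.25)$values - base)), 1e-10)
})

test_that("raising the threshold never raises any voxel's degree", {
  b <- random_bold(50, 20, seed = 9)
  r0s <- sort(runif(6, 0.05, 0.95))
  for (variant in c("weighted", "binary")) {
    prev <- compute_dc(b, r0s[1], variant)$values
    for (r0 in r0s[-1]) {
      cur <- compute_dc(b, r0, variant)$values
      expect_true(all(cur <= prev + 1e-12))
      prev <- cur
    }
  }
})

test_that("Fisher r-to-z values are correct and flow through the degree sum", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.8), atanh(0.8), tolerance = 1e-12)
  expect_equal(round(fisher_z(0.8), 4), 1.0986)

  b <- random_bold(30, 20, seed = 2)
  mf <- compute_dc(b, 0.3, r_transform = "fisher")
  expect_equal(mf$stage, "z_transformed")
  r <- cor(t(b$data)); diag(r) <- 0
  oracle <- rowSums((r > 0.3) * atanh(pmin(r, 1 - 1e-7)))
  expect_lt(max(abs(mf$values - oracle)), 1e-10)

  raw <- compute_dc(b, 0.3)
  via_to_z <- to_z_map(raw, "fisher_rz", bold = b)
  expect_equal(via_to_z$values, mf$values)
})

test_that("map standardization yields a zero-mean unit-SD zDC map", {
  b <- random_bold(80, 25, seed = 3)
  z <- to_z_map(compute_dc(b, 0.25))
  expect_lt(abs(mean(z$values)), 1e-12)
  expect_lt(abs(sd(z$values) - 1), 1e-12)
  expect_equal(z$stage, "z_transformed")

  degen <- compute_dc(four_voxel_bold(), 0.25)
  degen$values <- rep(2, 4)
  expect_error(to_z_map(degen), "sd is 0")
})

test_that("smoothing matches a direct Gaussian kernel evaluation", {
  g <- generate_toy_geometry(c(15, 15, 15), mask_rule = "central_sphere",
                             radius_voxels = 7)
  b <- masked_bold(matrix(rnorm(g$n_voxels * 10), g$n_voxels, 10), g)
  zm <- to_z_map(compute_dc(b, 0.25))

  # impulse at the mask center
  ctr <- c(8L, 8L, 8L)
  coords <- which(g$mask, arr.ind = TRUE)
  i_ctr <- which(coords[, 1] == ctr[1] & coords[, 2] == ctr[2] &
                   coords[, 3] == ctr[3])
  zm$values[] <- 0
  zm$values[i_ctr] <- 1
  sm <- smooth_map(zm, fwhm_mm = 6)
  sigma_vox <- 6 / (2 * sqrt(2 * log(2))) / 3
  oracle_vol <- gaussian_impulse_oracle(c(15, 15, 15), ctr, rep(sigma_vox, 3))
  expect_lt(max(abs(sm$values - oracle_vol[g$mask])), 1e-8)
})

test_that("fwhm 0 is the identity and renormalized smoothing preserves constants", {
  g <- generate_toy_geometry(c(8, 8, 8), mask_rule = "central_sphere",
                             radius_voxels = 3.5)
  b <- masked_bold(matrix(rnorm(g$n_voxels * 12), g$n_voxels, 12), g)
  zm <- to_z_map(compute_dc(b, 0.25))
  expect_identical(smooth_map(zm, 0)$values, zm$values)
  expect_error(smooth_map(zm, -1), ">= 0")

  zc <- zm
  zc$values[] <- 2.5
  smc <- smooth_map(zc, fwhm_mm = 9, renormalize = TRUE)
  expect_lt(max(abs(smc$values - 2.5)), 1e-10)
})

test_that("the end-to-end map records its provenance and stage", {
  g <- generate_toy_geometry(c(4, 4, 4), mask_rule = "all_in")
  b2 <- masked_bold(matrix(rnorm(64 * 20), 64, 20), g)
  m <- dc_pipeline(b2, r0 = 0.3, variant = "binary", fwhm_mm = 4)
  expect_equal(m$stage, "smoothed")
  expect_equal(m$variant, "binary")
  expect_equal(m$r0, 0.3)
  expect_equal(m$fwhm_mm, 4)
  expect_equal(m$z_method, "map_standardize")
})

test_that("a noise-free one-region recording smooths to a flat z map", {
  g <- generate_toy_geometry(c(6, 6, 6), mask_rule = "central_sphere",
                             radius_voxels = 2.5)
  a <- generate_toy_atlas(g, 1L, seed = 1)
  rec <- simulate_subject(g, a, 2L, cohort_spec(n_timepoints = 24L,
                                                noise_sd = 0),
                          subject_seed = 4L)
  m <- dc_pipeline(rec$bold, z_method = "fisher_rz", fwhm_mm = 6,
                   renormalize = TRUE)
  expect_lt(diff(range(m$values)), 1e-8 * max(abs(m$values)))
})

test_that("higher-coupling regions have higher mean raw degree", {
  g <- generate_toy_geometry(c(6, 6, 6), mask_rule = "all_in")
  a <- generate_toy_atlas(g, 2L, seed = 14)
  lab <- mask_labels_for_test(a, g)
  hits <- vapply(1:100, function(rep) {
    spec <- cohort_spec(n_timepoints = 240L, effect_regions = 1L,
                        effect_size = 0.5, seed = rep)
    rec <- simulate_subject(g, a, 1L, spec, subject_seed = derive_seed(rep, 1))
    dc <- compute_dc(rec$bold, 0.25)$values
    mean(dc[lab == 1L]) > mean(dc[lab == 2L])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
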