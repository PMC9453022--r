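test_that("toy geometry masks match brute-force voxel enumeration", {
  g <- generate_toy_geometry(c(12, 12, 12), mask_rule = "all_in")
  expect_equal(g$n_voxels, 1728L)

  g2 <- generate_toy_geometry(c(12, 12, 12), mask_rule = "central_sphere",
                              radius_voxels = 5)
  ctr <- (c(12, 12, 12) + 1) / 2
  cnt <- 0L
  for (i in 1:12) for (j in 1:12) for (k in 1:12)
    if (sqrt(sum((c(i, j, k) - ctr)^2)) <= 5) cnt <- cnt + 1L
  expect_equal(g2$n_voxels, cnt)

  expect_error(generate_toy_geometry(c(8, 8, 8), mask_rule = "central_sphere",
                                     radius_voxels = 0.1),
               "central_sphere")
  expect_error(generate_toy_geometry(c(3, 8, 8)), ">= 4")
})

test_that("smallest supported geometry flows through the DC engine", {
  g <- generate_toy_geometry(c(4, 4, 4), mask_rule = "all_in")
  a <- generate_toy_atlas(g, 2L, seed = 1)
  rec <- simulate_subject(g, a, group = 1L, cohort_spec(n_timepoints = 24L),
                          subject_seed = 5L)
  m <- dc_pipeline(rec$bold)
  expect_equal(m$stage, "smoothed")
  expect_length(m$values, 64L)
})

test_that("toy atlas is a deterministic nonempty partition of the mask", {
  g <- generate_toy_geometry(c(12, 12, 12), mask_rule = "all_in")

  a1 <- generate_toy_atlas(g, 1L, seed = 2)
  expect_true(all(a1$labels[g$mask] == 1L))

  a10 <- generate_toy_atlas(g, 10L, seed = 2)
  counts <- table(a10$labels[a10$labels > 0])
  expect_length(counts, 10L)
  expect_true(all(counts >= 1))
  expect_equal(sum(counts), 1728L)
  expect_true(all(a10$labels[!g$mask] == 0L))

  a10b <- generate_toy_atlas(g, 10L, seed = 2)
  expect_identical(a10$labels, a10b$labels)
  expect_error(generate_toy_atlas(g, 0L), ">= 1")
  expect_error(generate_toy_atlas(g, 2000L), "exceeds")
})

test_that("shared-signal-only voxels are perfectly correlated within region", {
  g <- generate_toy_geometry(c(4, 4, 4), mask_rule = "all_in")
  a <- generate_toy_atlas(g, 1L, seed = 1)
  spec <- cohort_spec(n_timepoints = 40L, noise_sd = 0)
  rec <- simulate_subject(g, a, group = 2L, spec, subject_seed = 9L)
  r <- cor(t(rec$bold$data))
  expect_true(all(abs(r - 1) < 1e-10))
})

test_that("within-region correlation matches the variance decomposition", {
  # with coupling w and noise sd s, expected pairwise r = w^2 / (w^2 + s^2)
  g <- generate_toy_geometry(c(4, 4, 4), mask_rule = "all_in")
  a <- generate_toy_atlas(g, 1L, seed = 1)
  spec <- cohort_spec(n_timepoints = 2000L, base_coupling = 1, noise_sd = 1)
  rec <- simulate_subject(g, a, group = 2L, spec, subject_seed = 31L)
  r <- cor(t(rec$bold$data))
  mean_r <- mean(r[upper.tri(r)])
  expect_lt(abs(mean_r - 0.5), 0.05)
})

test_that("band-limited latents keep power only inside the requested band", {
  g <- generate_toy_geometry(c(4, 4, 4), mask_rule = "all_in")
  a <- generate_toy_atlas(g, 1L, seed = 1)
  spec <- cohort_spec(n_timepoints = 240L, noise_sd = 0,
                      signal_band_hz = c(0.01, 0.08),
                      sampling_interval_s = 2)
  rec <- simulate_subject(g, a, group = 2L, spec, subject_seed = 3L)
  x <- rec$bold$data[1, ]
  spec_power <- Mod(fft(x))^2
  f <- (seq_along(x) - 1) / (length(x) * 2)
  f <- pmin(f, 1 / 2 - f)
  out_of_band <- f > 0.085 | f < 0.005
  expect_lt(sum(spec_power[out_of_band]), 1e-12 * sum(spec_power))
})

test_that("null cohorts carry no group signal in the effect regions", {
  # p-values of the group comparison should be uniform under effect_size = 0
  g <- generate_toy_geometry(c(5, 5, 5), mask_rule = "all_in")
  a <- generate_toy_atlas(g, 3L, seed = 4)
  ps <- vapply(1:200, function(rep) {
    spec <- cohort_spec(n_group1 = 3L, n_group2 = 3L, n_timepoints = 24L,
                        effect_regions = 1L, effect_size = 0, seed = rep)
    co <- simulate_cohort(g, a, spec)
    dc1 <- vapply(co$recordings, function(r) {
      m <- compute_dc(r$bold, r0 = 0.25)
      mean(m$values[mask_labels_for_test(a, g) == 1L])
    }, numeric(1))
    t.test(dc1[co$participants$group == 1], dc1[co$participants$group == 2])$p.value
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("large planted effects raise group-1 degree in effect regions", {
  g <- generate_toy_geometry(c(5, 5, 5), mask_rule = "all_in")
  a <- generate_toy_atlas(g, 3L, seed = 4)
  hits <- vapply(1:100, function(rep) {
    spec <- cohort_spec(n_group1 = 3L, n_group2 = 3L, n_timepoints = 240L,
                        effect_regions = 1L, effect_size = 1, seed = 1000 + rep)
    co <- simulate_cohort(g, a, spec)
    dc1 <- vapply(co$recordings, function(r) {
      m <- compute_dc(r$bold, r0 = 0.25)
      mean(m$values[mask_labels_for_test(a, g) == 1L])
    }, numeric(1))
    mean(dc1[co$participants$group == 1]) > mean(dc1[co$participants$group == 2])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("MoCA scores respect the impairment threshold by group", {
  g <- generate_toy_geometry(c(4, 4, 4), mask_rule = "all_in")
  a <- generate_toy_atlas(g, 2L, seed = 1)
  spec <- cohort_spec(n_group1 = 5L, n_group2 = 5L, n_timepoints = 24L,
                      seed = 77L)
  co <- simulate_cohort(g, a, spec)
  moca <- co$participants$moca
  grp <- co$participants$group
  expect_true(all(moca[grp == 1] < 26))
  expect_true(all(moca[grp == 2] >= 26))
})

test_that("cohort simulation is reproducible and writes the participant TSV", {
  g <- generate_toy_geometry(c(4, 4, 4), mask_rule = "all_in")
  a <- generate_toy_atlas(g, 2L, seed = 1)
  spec <- cohort_spec(n_group1 = 5L, n_group2 = 5L, n_timepoints = 24L,
                      seed = 12L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  c1 <- simulate_cohort(g, a, spec, out_dir = d1)
  c2 <- simulate_cohort(g, a, spec, out_dir = d2)
  expect_equal(length(c1$recordings), 10L)
  expect_equal(nrow(c1$participants), 10L)
  expect_identical(c1$recordings[[3]]$bold$data, c2$recordings[[3]]$bold$data)
  expect_identical(readLines(file.path(d1, "participants.tsv")),
                   readLines(file.path(d2, "participants.tsv")))
})

test_that("feature tables reproduce the printed group Gaussians", {
  params <- table2_params()
  expect_equal(nrow(params), 10L)

  ft <- simulate_feature_table(params, n1 = 10000L, n2 = 10000L, seed = 8L)
  v10 <- ft$matrix[ft$labels == "MCI", "Vemis 10"]
  expect_lt(abs(mean(v10) - (-0.399)), 0.01)
  v10n <- ft$matrix[ft$labels == "nMCI", "Vemis 10"]
  expect_lt(abs(mean(v10n) - (-0.503)), 0.01)

  # degenerate-SD override pins every draw at the group mean
  p0 <- params
  p0$mci_sd <- 0; p0$nmci_sd <- 0
  ft0 <- simulate_feature_table(p0, n1 = 3L, n2 = 3L, seed = 1L)
  expect_true(all(ft0$matrix[1, ] == params$mci_mean))
  expect_true(all(ft0$matrix[6, ] == params$nmci_mean))

  expect_identical(simulate_feature_table(params, 5, 5, seed = 3)$matrix,
                   simulate_feature_table(params, 5, 5, seed = 3)$matrix)
  expect_error(
    simulate_feature_table(params[, setdiff(names(params), "mci_sd")],
                           5, 5, 1),
    "missing")
})
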