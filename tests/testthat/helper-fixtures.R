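# Fixtures and independent oracles used across the suite. Oracles here are
# deliberately naive (dense matrices, explicit loops) so they stay
# independent of the package's chunked / vectorized code paths.

four_voxel_bold <- function() {
  masked_bold(rbind(v1 = c(1, 2, 3, 4), v2 = c(2, 4, 6, 8),
                    v3 = c(4, 3, 2, 1), v4 = c(1, 3, 2, 4)))
}

random_bold <- function(n_voxels, n_time, seed) {
  set.seed(seed)
  masked_bold(matrix(rnorm(n_voxels * n_time), n_voxels, n_time))
}

# Dense brute-force degree centrality: full N x N correlation matrix,
# explicit thresholding.
dense_dc_oracle <- function(bold, r0, variant = "weighted") {
  r <- cor(t(bold$data))
  diag(r) <- 0
  keep <- r > r0
  if (variant == "binary") rowSums(keep) else rowSums(r * keep)
}

# Direct evaluation of a separable truncated discrete Gaussian centered at
# `center` (voxel coords), matching kernel truncation at 4 sigma per axis
# with per-axis normalization.
gaussian_impulse_oracle <- function(shape, center, sigma_vox) {
  axis_kernel <- function(sigma, n, c0) {
    half <- max(1L, ceiling(4 * sigma))
    x <- (-half):half
    k <- exp(-x^2 / (2 * sigma^2))
    k <- k / sum(k)
    out <- numeric(n)
    pos <- c0 + x
    ok <- pos >= 1 & pos <= n
    out[pos[ok]] <- k[ok]
    out
  }
  kx <- axis_kernel(sigma_vox[1], shape[1], center[1])
  ky <- axis_kernel(sigma_vox[2], shape[2], center[2])
  kz <- axis_kernel(sigma_vox[3], shape[3], center[3])
  outer(outer(kx, ky), kz)
}

# n x p matrix whose empirical correlation matrix is exactly `sigma`
# (columns standardized), for constructing pruning examples.
matrix_with_correlation <- function(n, sigma, seed) {
  set.seed(seed)
  p <- ncol(sigma)
  z <- matrix(rnorm(n * p), n, p)
  z <- qr.Q(qr(scale(z, center = TRUE, scale = FALSE)))  # orthonormal cols
  x <- z %*% chol(sigma)
  scale(x) / sqrt(1 / (n - 1))  # unit-variance columns, exact correlation
}

# Pairwise Mann-Whitney AUC with half-credit ties, by explicit enumeration.
auc_pairwise_oracle <- function(score, truth) {
  sp <- score[truth == "MCI"]
  sn <- score[truth == "nMCI"]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Labels-from-confusion helper: builds truth/pred vectors realizing the
# given (TP, FN, FP, TN).
vectors_from_confusion <- function(tp, fn, fp, tn) {
  truth <- rep(c("MCI", "nMCI"), c(tp + fn, fp + tn))
  pred <- c(rep(c("MCI", "nMCI"), c(tp, fn)), rep(c("MCI", "nMCI"), c(fp, tn)))
  list(truth = truth, pred = pred)
}

mask_labels_for_test <- function(atlas, geometry) {
  as.integer(atlas$labels[geometry$mask])
}

null_features <- function(n, p, seed) {
  set.seed(seed)
  feature_table(matrix(rnorm(n * p), n, p),
                subject_ids = sprintf("s%02d", seq_len(n)),
                labels = rep(c("MCI", "nMCI"), length.out = n))
}
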