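#' Bind a voxel x time matrix to a geometry
#'
#' The unit of degree-centrality computation: one subject's in-mask voxel
#' time series, with a bijection between matrix rows and 3D mask
#' coordinates. With `geometry = NULL` a detached container is returned
#' (usable for correlation/degree computation but not for smoothing or
#' NIfTI export).
#'
#' @param data numeric matrix, in-mask voxels x time points (>= 4 time
#'   points; realistic series are much longer).
#' @param geometry a [generate_toy_geometry()] object whose in-mask voxel
#'   count equals `nrow(data)`, or `NULL`.
#' @return an object of class `masked_bold`.
#' @export
masked_bold <- function(data, geometry = NULL) {
  data <- as.matrix(data)
  if (ncol(data) < 4L) stopf("need at least 4 time points")
  if (!is.null(geometry)) {
    stopifnot(inherits(geometry, "toy_geometry"))
    if (nrow(data) != geometry$n_voxels)
      stopf("data has %d rows but the mask has %d voxels",
            nrow(data), geometry$n_voxels)
    vi <- mask_coords(geometry)
  } else {
    vi <- cbind(seq_len(nrow(data)), 1L, 1L)
  }
  structure(list(data = data, geometry = geometry, voxel_index = vi),
            class = "masked_bold")
}

#' @export
print.masked_bold <- function(x, ...) {
  cat(sprintf("<masked_bold> %d voxels x %d time points\n",
              nrow(x$data), ncol(x$data)))
  invisible(x)
}

## Row-standardize a voxel x time matrix so that tcrossprod gives Pearson
## correlations. Errors (naming the voxel coordinate) on zero-variance rows.
standardize_rows <- function(bold) {
  x <- bold$data - rowMeans(bold$data)
  ss <- sqrt(rowSums(x^2))
  bad <- which(ss == 0 | !is.finite(ss))
  if (length(bad)) {
    co <- bold$voxel_index[bad[1], ]
    stopf("voxel at (%d, %d, %d) has zero variance", co[1], co[2], co[3])
  }
  x / ss
}

#' Correlations between one voxel and all others
#'
#' Returns the Pearson correlation between voxel `i`'s time series and every
#' in-mask voxel (the self-entry is 1 and is excluded from any degree sum
#' downstream). Invariant to per-voxel affine rescaling of the series.
#'
#' @param bold a `masked_bold`.
#' @param i voxel row index (1-based, in mask row order).
#' @return numeric vector of length N with entry `i` equal to 1.
#' @export
voxel_correlation_row <- function(bold, i) {
  n <- nrow(bold$data)
  if (i < 1L || i > n) stopf("voxel index %d outside 1..%d", i, n)
  xs <- standardize_rows(bold)
  as.numeric(xs %*% xs[i, ])
}

#' Compute a voxel-level degree-centrality map
#'
#' For each in-mask voxel i, degree centrality over the thresholded positive
#' correlation graph:
#' \deqn{Dc(i) = \sum_{j \ne i,\, r_{ij} > r_0} r_{ij}}
#' (weighted variant) or the count of such j (binary variant). Negative and
#' weak edges are excluded by the threshold `r0 > 0`. The correlation matrix
#' is processed in row chunks, so the full N x N matrix is never held in
#' memory; the result is identical to the dense computation.
#'
#' @param bold a `masked_bold`.
#' @param r0 correlation threshold, strictly inside (0, 1).
#' @param variant `"weighted"` (sum of supra-threshold r) or `"binary"`
#'   (edge count).
#' @param r_transform `"none"` or `"fisher"`: with `"fisher"`, each
#'   supra-threshold r is replaced by `atanh(r)` (r clipped to 1 - 1e-7)
#'   before the weighted sum, giving a Fisher r-to-z degree map. Ignored by
#'   the binary variant.
#' @param chunk_size voxel rows per chunk (any value >= 1 gives the same map).
#' @return a `dc_map` with `stage = "raw_degree"` (`"z_transformed"` when
#'   `r_transform = "fisher"`, since the z transformation is then already
#'   embedded in the sum).
#' @examples
#' b <- masked_bold(rbind(c(1, 2, 3, 4), c(2, 4, 6, 8),
#'                        c(4, 3, 2, 1), c(1, 3, 2, 4)))
#' compute_dc(b, r0 = 0.25)$values  # 1.8 1.8 0.0 1.6
#' @export
compute_dc <- function(bold, r0 = 0.25,
                       variant = c("weighted", "binary"),
                       r_transform = c("none", "fisher"),
                       chunk_size = 512L) {
  variant <- match.arg(variant)
  r_transform <- match.arg(r_transform)
  if (!is.finite(r0) || r0 <= 0 || r0 >= 1)
    stopf("`r0` must lie strictly inside (0, 1); got %s", format(r0))
  n <- nrow(bold$data)
  if (n < 2L) stopf("need at least 2 in-mask voxels")
  chunk_size <- max(1L, as.integer(chunk_size))

  xs <- standardize_rows(bold)
  values <- numeric(n)
  starts <- seq.int(1L, n, by = chunk_size)
  for (s in starts) {
    idx <- s:min(s + chunk_size - 1L, n)
    r <- xs[idx, , drop = FALSE] %*% t(xs)   # |idx| x N correlations
    r[cbind(seq_along(idx), idx)] <- 0       # exclude self
    keep <- r > r0
    values[idx] <- if (variant == "binary") {
      rowSums(keep)
    } else if (r_transform == "fisher") {
      rowSums(keep * atanh(pmin(r, 1 - 1e-7)))
    } else {
      rowSums(keep * r)
    }
  }
  new_dc_map(values, bold,
             stage = if (r_transform == "fisher") "z_transformed" else "raw_degree",
             variant = variant, r0 = r0,
             z_method = if (r_transform == "fisher") "fisher_rz" else NA_character_)
}

new_dc_map <- function(values, bold, stage, variant, r0,
                       z_method = NA_character_, fwhm_mm = NA_real_) {
  structure(list(values = as.numeric(values), stage = stage,
                 variant = variant, r0 = r0, z_method = z_method,
                 fwhm_mm = fwhm_mm, geometry = bold$geometry,
                 voxel_index = bold$voxel_index),
            class = "dc_map")
}

#' @export
print.dc_map <- function(x, ...) {
  cat(sprintf("<dc_map> %d voxels | stage=%s variant=%s r0=%g%s%s\n",
              length(x$values), x$stage, x$variant, x$r0,
              if (!is.na(x$z_method)) paste0(" z=", x$z_method) else "",
              if (!is.na(x$fwhm_mm)) paste0(" fwhm=", x$fwhm_mm, "mm") else ""))
  invisible(x)
}

#' Transform a raw degree map to a z map
#'
#' Two readings of "transform to a z-score map" are supported:
#' `"map_standardize"` (default) standardizes the finished degree map over
#' in-mask voxels, giving each subject a zero-mean unit-SD zDC map;
#' `"fisher_rz"` instead applies the Fisher r-to-z transform to each
#' correlation before summation, which requires the original series — pass
#' `bold`, and the map is recomputed via
#' [compute_dc()] with `r_transform = "fisher"`.
#'
#' @param dc_map a `dc_map` with `stage = "raw_degree"`.
#' @param method `"map_standardize"` or `"fisher_rz"`.
#' @param bold the originating `masked_bold`, required for `"fisher_rz"`.
#' @return a `dc_map` with `stage = "z_transformed"`.
#' @export
to_z_map <- function(dc_map, method = c("map_standardize", "fisher_rz"),
                     bold = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(dc_map, "dc_map"))
  if (method == "fisher_rz") {
    if (is.null(bold))
      stopf("method 'fisher_rz' acts on correlations pre-sum; supply `bold`")
    return(compute_dc(bold, r0 = dc_map$r0, variant = dc_map$variant,
                      r_transform = "fisher"))
  }
  if (dc_map$stage != "raw_degree")
    stopf("map_standardize expects a raw_degree map, got stage '%s'",
          dc_map$stage)
  s <- stats::sd(dc_map$values)
  if (!is.finite(s) || s == 0) stopf("degenerate degree map: sd is 0")
  out <- dc_map
  out$values <- (dc_map$values - mean(dc_map$values)) / s
  out$stage <- "z_transformed"
  out$z_method <- "map_standardize"
  out
}

## 1D Gaussian convolution along one axis of a 3D array, zero padded.
conv_axis <- function(vol, kern, axis) {
  half <- (length(kern) - 1L) / 2L
  d <- dim(vol)
  out <- array(0, d)
  for (k in seq_along(kern)) {
    off <- k - 1L - half
    src <- seq_len(d[axis]) + off
    ok <- src >= 1L & src <= d[axis]
    if (!any(ok)) next
    dst <- which(ok)
    idx_src <- idx_dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx_src[[axis]] <- src[ok]
    idx_dst[[axis]] <- dst
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] +
      kern[k] * vol[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  }
  out
}

gauss_kernel <- function(sigma_vox) {
  if (sigma_vox == 0) return(1)
  half <- max(1L, ceiling(4 * sigma_vox))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

#' Gaussian-smooth a z map
#'
#' Values are scattered to the 3D grid (zero outside the mask), convolved
#' with a separable isotropic Gaussian of the given full width at half
#' maximum, then re-masked — the behavior of common volumetric smoothing
#' tools. `sigma = fwhm / (2 sqrt(2 ln 2))` per axis in mm, converted to
#' voxel units via the geometry's voxel size. `fwhm_mm = 0` is the identity.
#'
#' @param dc_map a `dc_map` with `stage = "z_transformed"`.
#' @param fwhm_mm kernel FWHM in mm (>= 0); 6 mm is the conventional default.
#' @param renormalize if `TRUE`, divide by the smoothed mask indicator so
#'   in-mask values are a weighted average of in-mask neighbors only.
#' @return a `dc_map` with `stage = "smoothed"`.
#' @export
smooth_map <- function(dc_map, fwhm_mm = 6, renormalize = FALSE) {
  stopifnot(inherits(dc_map, "dc_map"))
  if (dc_map$stage != "z_transformed")
    stopf("smoothing expects a z_transformed map, got stage '%s'", dc_map$stage)
  if (!is.finite(fwhm_mm) || fwhm_mm < 0) stopf("`fwhm_mm` must be >= 0")
  if (is.null(dc_map$geometry))
    stopf("smoothing needs a map bound to a geometry")
  out <- dc_map
  out$stage <- "smoothed"
  out$fwhm_mm <- fwhm_mm
  if (fwhm_mm == 0) return(out)

  geom <- dc_map$geometry
  vol <- array(0, geom$shape)
  vol[geom$mask] <- dc_map$values
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / geom$voxel_size_mm
  for (ax in 1:3) vol <- conv_axis(vol, gauss_kernel(sigma_vox[ax]), ax)
  if (renormalize) {
    w <- array(0, geom$shape)
    w[geom$mask] <- 1
    for (ax in 1:3) w <- conv_axis(w, gauss_kernel(sigma_vox[ax]), ax)
    vol <- vol / pmax(w, .Machine$double.eps)
  }
  out$values <- vol[geom$mask]
  out
}

#' Full degree-centrality mapping pipeline for one recording
#'
#' Thresholded correlation degree, z transformation, Gaussian smoothing.
#' Stage tags advance `raw_degree -> z_transformed -> smoothed` and the
#' parameters used are recorded on the returned map.
#'
#' @inheritParams compute_dc
#' @param z_method `"map_standardize"` or `"fisher_rz"` (see [to_z_map()]).
#' @param fwhm_mm smoothing kernel FWHM in mm.
#' @param renormalize see [smooth_map()].
#' @return a smoothed `dc_map`.
#' @export
dc_pipeline <- function(bold, r0 = 0.25, variant = "weighted",
                        z_method = "map_standardize", fwhm_mm = 6,
                        chunk_size = 512L, renormalize = FALSE) {
  zmap <- if (z_method == "fisher_rz") {
    compute_dc(bold, r0 = r0, variant = variant, r_transform = "fisher",
               chunk_size = chunk_size)
  } else {
    to_z_map(compute_dc(bold, r0 = r0, variant = variant,
                        chunk_size = chunk_size),
             method = z_method)
  }
  smooth_map(zmap, fwhm_mm = fwhm_mm, renormalize = renormalize)
}

#' Fisher r-to-z transform
#'
#' `atanh(r)` with `|r|` clipped to `1 - 1e-7` so perfect correlations stay
#' finite.
#' @param r correlation value(s).
#' @export
fisher_z <- function(r) atanh(pmax(pmin(r, 1 - 1e-7), -(1 - 1e-7)))
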