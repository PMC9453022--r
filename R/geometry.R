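#' Build a toy brain geometry
#'
#' A geometry is a voxel grid plus a binary "gray matter" mask. It stands in
#' for a whole-brain gray-matter template at desk scale; the full-resolution
#' template used in resting-state studies (61 x 73 x 61 at 3 mm, ~67k in-mask
#' voxels) is reachable by passing a larger `shape`, but the default toy
#' scale keeps the voxel graph small enough for exhaustive testing.
#'
#' @param shape integer vector of length 3, voxels per axis (each >= 4).
#' @param voxel_size_mm numeric vector of length 3, voxel edge lengths in mm.
#'   Defaults to 3 mm isotropic.
#' @param mask_rule `"all_in"` (every voxel in the mask) or `"central_sphere"`
#'   (voxels whose center lies within `radius_voxels` of the volume center).
#' @param radius_voxels sphere radius in voxel units for `"central_sphere"`.
#' @return an object of class `toy_geometry`: list with `shape`,
#'   `voxel_size_mm`, `mask` (logical 3D array) and `n_voxels` (in-mask count).
#' @examples
#' g <- generate_toy_geometry(c(12, 12, 12), mask_rule = "all_in")
#' g$n_voxels  # 1728
#' @export
generate_toy_geometry <- function(shape = c(16L, 16L, 16L),
                                  voxel_size_mm = c(3, 3, 3),
                                  mask_rule = c("central_sphere", "all_in"),
                                  radius_voxels = min(shape) / 2 - 0.2) {
  mask_rule <- match.arg(mask_rule)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L))
    stopf("`shape` must be 3 integers, each >= 4")
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stopf("`voxel_size_mm` must be 3 positive reals")

  mask <- switch(mask_rule,
    all_in = array(TRUE, dim = shape),
    central_sphere = {
      ctr <- (shape + 1) / 2
      cx <- slice.index(array(0, shape), 1) - ctr[1]
      cy <- slice.index(array(0, shape), 2) - ctr[2]
      cz <- slice.index(array(0, shape), 3) - ctr[3]
      sqrt(cx^2 + cy^2 + cz^2) <= radius_voxels
    })
  n <- sum(mask)
  if (n < 2L) stopf("mask rule '%s' produced %d in-mask voxels (need >= 2)",
                    mask_rule, n)
  structure(list(shape = shape, voxel_size_mm = as.numeric(voxel_size_mm),
                 mask = mask, n_voxels = n),
            class = "toy_geometry")
}

#' @export
print.toy_geometry <- function(x, ...) {
  cat(sprintf("<toy_geometry> %s voxels at %s mm, %d in mask\n",
              paste(x$shape, collapse = "x"),
              paste(x$voxel_size_mm, collapse = "x"), x$n_voxels))
  invisible(x)
}

## in-mask voxel coordinates, fixed row order (column-major, as which() gives)
mask_coords <- function(geometry) {
  which(geometry$mask, arr.ind = TRUE)
}

#' Partition a geometry's mask into a toy parcellation atlas
#'
#' In-mask voxels are assigned to their nearest of `n_regions` randomly
#' chosen seed voxels (a Voronoi partition), giving contiguous-ish, nonempty
#' regions. This is a desk-scale stand-in for an anatomical parcellation such
#' as the 116-region AAL map; any labeled volume with the same grid can be
#' used in its place downstream.
#'
#' @param geometry a [generate_toy_geometry()] object.
#' @param n_regions number of regions (1 <= n_regions <= in-mask voxels).
#' @param seed integer seed; the partition is deterministic given the seed.
#' @return an object of class `toy_atlas`: `labels` (integer 3D array,
#'   0 = background), `region_ids`, `region_names`.
#' @export
generate_toy_atlas <- function(geometry, n_regions, seed = 1L) {
  stopifnot(inherits(geometry, "toy_geometry"))
  n_regions <- as.integer(n_regions)
  if (n_regions < 1L) stopf("`n_regions` must be >= 1")
  coords <- mask_coords(geometry)
  if (n_regions > nrow(coords))
    stopf("`n_regions` (%d) exceeds in-mask voxel count (%d)",
          n_regions, nrow(coords))

  labels <- array(0L, dim = geometry$shape)
  if (n_regions == 1L) {
    labels[geometry$mask] <- 1L
  } else {
    centers <- with_seed(seed, coords[sample.int(nrow(coords), n_regions), ,
                                      drop = FALSE])
    ## squared distance of every in-mask voxel to every center
    d2 <- outer(rowSums(coords^2), rowSums(centers^2), "+") -
      2 * coords %*% t(centers)
    assign_ <- max.col(-d2, ties.method = "first")
    labels[geometry$mask] <- as.integer(assign_)
  }
  ids <- seq_len(n_regions)
  structure(list(labels = labels, region_ids = ids,
                 region_names = sprintf("region_%02d", ids)),
            class = "toy_atlas")
}

#' @export
print.toy_atlas <- function(x, ...) {
  cat(sprintf("<toy_atlas> %d regions over %d labeled voxels\n",
              length(x$region_ids), sum(x$labels > 0)))
  invisible(x)
}

## region label for each mask row of `geometry`, in mask row order
mask_labels <- function(atlas, geometry) {
  as.integer(atlas$labels[geometry$mask])
}

validate_atlas <- function(atlas, geometry) {
  if (!identical(dim(atlas$labels), as.integer(geometry$shape)))
    stopf("atlas and geometry grids differ")
  lab <- mask_labels(atlas, geometry)
  missing <- setdiff(atlas$region_ids, unique(lab[lab > 0L]))
  if (length(missing))
    stopf("region(s) %s have no in-mask voxels",
          paste(missing, collapse = ", "))
  stray <- setdiff(unique(lab[lab > 0L]), atlas$region_ids)
  if (length(stray))
    stopf("label value(s) %s not listed in region_ids",
          paste(stray, collapse = ", "))
  invisible(TRUE)
}
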