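#' Write / read geometry, atlas, recordings and maps as NIfTI-1
#'
#' Images are written via the RNifti library: masks and atlases as 3D
#' volumes, recordings as 4D volumes (time in the 4th dimension), zDC maps
#' as 3D volumes with zeros outside the mask. Voxel sizes come from the
#' geometry; the repetition time (seconds) is stored in the 4th pixdim of
#' 4D images.
#'
#' @param geometry a `toy_geometry`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @name nifti_io
NULL

nifti_3d <- function(arr, voxel_size_mm) {
  img <- RNifti::asNifti(arr)
  RNifti::`pixdim<-`(img, voxel_size_mm)
}

#' @rdname nifti_io
#' @export
write_mask_nifti <- function(geometry, path) {
  img <- nifti_3d(array(as.integer(geometry$mask), geometry$shape),
                  geometry$voxel_size_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname nifti_io
#' @param atlas a `toy_atlas`.
#' @export
write_atlas_nifti <- function(atlas, geometry, path) {
  img <- nifti_3d(atlas$labels, geometry$voxel_size_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname nifti_io
#' @param bold a `masked_bold` bound to a geometry.
#' @param tr_s repetition time in seconds.
#' @export
write_bold_nifti <- function(bold, path, tr_s = 2) {
  geom <- bold$geometry
  if (is.null(geom)) stopf("recording is not bound to a geometry")
  nt <- ncol(bold$data)
  vol <- array(0, c(geom$shape, nt))
  idx <- which(geom$mask)
  nvol <- prod(geom$shape)
  for (t in seq_len(nt)) vol[idx + (t - 1) * nvol] <- bold$data[, t]
  img <- RNifti::asNifti(vol)
  img <- RNifti::`pixdim<-`(img, c(geom$voxel_size_mm, tr_s))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname nifti_io
#' @param mask_path path to the 3D binary mask image.
#' @param voxel_size_mm fallback voxel size if the header lacks one.
#' @return `read_bold_nifti()` returns a `masked_bold`.
#' @export
read_bold_nifti <- function(path, mask_path, voxel_size_mm = NULL) {
  img <- RNifti::readNifti(path)
  msk <- RNifti::readNifti(mask_path)
  d <- dim(img)
  if (length(d) != 4L) stopf("expected a 4D image, got %d dims", length(d))
  if (!identical(dim(msk)[1:3], d[1:3]))
    stopf("mask grid does not match the 4D image")
  vs <- voxel_size_mm %||% RNifti::pixdim(img)[1:3]
  geom <- structure(list(shape = as.integer(d[1:3]),
                         voxel_size_mm = as.numeric(vs),
                         mask = array(msk > 0, d[1:3]),
                         n_voxels = sum(msk > 0)),
                    class = "toy_geometry")
  mat <- matrix(img[rep(geom$mask, d[4])], ncol = d[4])
  masked_bold(mat, geom)
}

#' @rdname nifti_io
#' @param dc_map a `dc_map` bound to a geometry.
#' @export
write_map_nifti <- function(dc_map, path) {
  geom <- dc_map$geometry
  if (is.null(geom)) stopf("map is not bound to a geometry")
  vol <- array(0, geom$shape)
  vol[geom$mask] <- dc_map$values
  RNifti::writeNifti(nifti_3d(vol, geom$voxel_size_mm), path)
  invisible(path)
}

#' @rdname nifti_io
#' @param geometry_path path to the mask defining the geometry.
#' @return `read_map_nifti()` returns a `dc_map` (provenance fields from the
#'   JSON sidecar if present).
#' @export
read_map_nifti <- function(path, geometry_path) {
  img <- RNifti::readNifti(path)
  msk <- RNifti::readNifti(geometry_path)
  d <- dim(img)
  geom <- structure(list(shape = as.integer(d),
                         voxel_size_mm = as.numeric(RNifti::pixdim(img)[1:3]),
                         mask = array(msk > 0, d), n_voxels = sum(msk > 0)),
                    class = "toy_geometry")
  side <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
  prov <- if (file.exists(side)) jsonlite::read_json(side) else list()
  structure(list(values = as.numeric(img[geom$mask]),
                 stage = prov$stage %||% "smoothed",
                 variant = prov$variant %||% "weighted",
                 r0 = prov$r0 %||% NA_real_,
                 z_method = prov$z_method %||% NA_character_,
                 fwhm_mm = prov$fwhm_mm %||% NA_real_,
                 geometry = geom, voxel_index = mask_coords(geom)),
            class = "dc_map")
}

## JSON provenance sidecar for a written map
write_map_sidecar <- function(dc_map, path, chunk_size = NA) {
  side <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
  jsonlite::write_json(list(
    stage = dc_map$stage, variant = dc_map$variant, r0 = dc_map$r0,
    z_method = dc_map$z_method, fwhm_mm = dc_map$fwhm_mm,
    chunk_size = chunk_size,
    software = paste0("neurodc ", as.character(utils::packageVersion("neurodc")))
  ), side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(side)
}
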