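#' Region-mean values of a zDC map
#'
#' The atlas reduction used for feature extraction: for each region id, the
#' arithmetic mean of the (smoothed) zDC values over in-mask voxels carrying
#' that label. Output is in `region_ids` order.
#'
#' @param zdc_map a `dc_map` bound to a geometry.
#' @param atlas a `toy_atlas` (or any labeled volume with the same grid).
#' @return named numeric vector, one mean per region.
#' @export
extract_region_means <- function(zdc_map, atlas) {
  stopifnot(inherits(zdc_map, "dc_map"))
  geom <- zdc_map$geometry
  if (is.null(geom)) stopf("map is not bound to a geometry")
  validate_atlas(atlas, geom)
  lab <- mask_labels(atlas, geom)
  out <- vapply(atlas$region_ids, function(id) {
    v <- zdc_map$values[lab == id]
    if (!length(v)) stopf("region %d has no in-mask voxels", id)
    mean(v)
  }, numeric(1))
  names(out) <- atlas$region_names
  out
}

#' Construct a subjects x regions feature table
#'
#' @param matrix numeric subjects x regions matrix (no missing values);
#'   column names are region names.
#' @param subject_ids character vector, one id per row.
#' @param labels per-subject class, `"MCI"` or `"nMCI"`.
#' @return an object of class `feature_table` with fields `matrix`,
#'   `subject_ids`, `region_names`, `labels`.
#' @export
feature_table <- function(matrix, subject_ids, labels) {
  matrix <- as.matrix(matrix)
  if (anyNA(matrix) || any(!is.finite(matrix)))
    stopf("feature matrix contains missing or non-finite values")
  if (length(subject_ids) != nrow(matrix) || length(labels) != nrow(matrix))
    stopf("subject_ids/labels length must match the matrix rows")
  if (!all(labels %in% c("MCI", "nMCI")))
    stopf("labels must be 'MCI' or 'nMCI'")
  if (is.null(colnames(matrix)))
    colnames(matrix) <- sprintf("feature_%02d", seq_len(ncol(matrix)))
  rownames(matrix) <- subject_ids
  structure(list(matrix = matrix, subject_ids = as.character(subject_ids),
                 region_names = colnames(matrix),
                 labels = as.character(labels)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d subjects x %d regions (%d MCI / %d nMCI)\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$labels == "MCI"),
              sum(x$labels == "nMCI")))
  invisible(x)
}

#' Assemble the cohort feature table from per-subject zDC maps
#'
#' Rows follow the participant table order; the class label is `MCI` iff
#' MoCA < 26 (a score of exactly 26 is unimpaired).
#'
#' @param zdc_maps named list of smoothed `dc_map`s, names = subject ids.
#' @param atlas atlas shared by all maps.
#' @param participants data.frame with `subject_id` and `moca` columns.
#' @return a `feature_table`.
#' @export
build_feature_table <- function(zdc_maps, atlas, participants) {
  stopifnot(is.data.frame(participants),
            all(c("subject_id", "moca") %in% names(participants)))
  ids <- participants$subject_id
  missing_maps <- setdiff(ids, names(zdc_maps))
  extra_maps <- setdiff(names(zdc_maps), ids)
  if (length(missing_maps) || length(extra_maps))
    stopf("subject id mismatch between maps and participants%s%s",
          if (length(missing_maps))
            paste0("; missing maps: ", paste(missing_maps, collapse = ", "))
          else "",
          if (length(extra_maps))
            paste0("; unmatched maps: ", paste(extra_maps, collapse = ", "))
          else "")
  mat <- t(vapply(ids, function(id) extract_region_means(zdc_maps[[id]], atlas),
                  numeric(length(atlas$region_ids))))
  feature_table(mat, subject_ids = ids,
                labels = ifelse(participants$moca < 26, "MCI", "nMCI"))
}

#' Write / read a feature table as TSV
#'
#' Columns: `subject_id`, `label`, then one column per region. Numeric
#' values are written with 10 significant digits, so a write/read cycle
#' round-trips the file representation exactly.
#'
#' @param ft a `feature_table`.
#' @param path file path.
#' @export
write_feature_table <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  df <- data.frame(subject_id = ft$subject_ids, label = ft$labels,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_len(ncol(ft$matrix)))
    df[[ft$region_names[j]]] <-
      formatC(ft$matrix[, j], digits = 10, format = "g")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("subject_id", "label") %in% names(df)))
  mat <- as.matrix(df[, setdiff(names(df), c("subject_id", "label")),
                      drop = FALSE])
  storage.mode(mat) <- "double"
  feature_table(mat, subject_ids = df$subject_id, labels = df$label)
}
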