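#' Default desk-scale run configuration
#'
#' All analysis constants default to the study conventions (correlation
#' threshold 0.25, weighted degree, map standardization, 6 mm FWHM, prune
#' threshold 0.75, the 46-point alpha grid, 10-fold selection CV, LOOCV);
#' the cohort itself defaults to a small synthetic one so a full run
#' finishes on a desk machine. `study_scale = TRUE` switches the cohort to
#' the study design (groups of 51 and 48, 240 time points, 5000
#' permutations).
#'
#' @param seed master seed.
#' @param study_scale use study-sized cohort settings.
#' @return a nested list (class `run_config`).
#' @export
default_run_config <- function(seed = 1L, study_scale = FALSE) {
  cfg <- list(
    seed = as.integer(seed),
    geometry = list(shape = c(12L, 12L, 12L), voxel_size_mm = c(3, 3, 3),
                    mask_rule = "central_sphere", radius_voxels = 5.5),
    atlas = list(n_regions = 8L),
    cohort = list(n_group1 = 10L, n_group2 = 10L, n_timepoints = 240L,
                  effect_regions = c(1L, 2L, 3L, 4L), effect_size = 0.12,
                  base_coupling = 1, noise_sd = 1),
    dc = list(r0 = 0.25, variant = "weighted", z_method = "map_standardize",
              fwhm_mm = 6, chunk_size = 512L),
    selection = list(prune_threshold = 0.75, n_folds = 5L),
    classification = list(models = c("svm_linear", "random_forest",
                                     "logistic_regression"),
                          inner_folds = 3L, n_permutations = 0L),
    out_dir = "neurodc_run")
  if (study_scale) {
    cfg$geometry <- list(shape = c(16L, 16L, 16L), voxel_size_mm = c(3, 3, 3),
                         mask_rule = "central_sphere", radius_voxels = 7.8)
    cfg$cohort$n_group1 <- 51L
    cfg$cohort$n_group2 <- 48L
    cfg$selection$n_folds <- 10L
    cfg$classification$inner_folds <- 5L
    cfg$classification$n_permutations <- 5000L
  }
  structure(cfg, class = "run_config")
}

config_schema <- function() {
  list(
    seed = "integer",
    geometry = list(shape = "integer3", voxel_size_mm = "numeric3",
                    mask_rule = "character", radius_voxels = "numeric"),
    atlas = list(n_regions = "integer"),
    cohort = list(n_group1 = "integer", n_group2 = "integer",
                  n_timepoints = "integer", effect_regions = "integerN",
                  effect_size = "numeric", base_coupling = "numeric",
                  noise_sd = "numeric"),
    dc = list(r0 = "numeric", variant = "character", z_method = "character",
              fwhm_mm = "numeric", chunk_size = "integer"),
    selection = list(prune_threshold = "numeric", n_folds = "integer"),
    classification = list(models = "characterN", inner_folds = "integer",
                          n_permutations = "integer"),
    out_dir = "character")
}

check_type <- function(x, type) {
  switch(type,
    integer = length(x) == 1L && is.numeric(x) && x == round(x),
    numeric = length(x) == 1L && is.numeric(x) && is.finite(x),
    character = length(x) == 1L && is.character(x),
    integer3 = length(x) == 3L && is.numeric(x) && all(x == round(x)),
    numeric3 = length(x) == 3L && is.numeric(x) && all(is.finite(x)),
    integerN = is.numeric(x) && all(x == round(x)) || length(x) == 0L,
    characterN = is.character(x) && length(x) >= 1L,
    FALSE)
}

#' Validate a run configuration
#'
#' Accepts a YAML file path or a nested list. All violations — unknown
#' keys, missing required keys, type mismatches and out-of-range values —
#' are collected and reported together, not first-failure.
#'
#' @param config path to a YAML file, or a list.
#' @return a validated `run_config` (defaults filled in; the cohort group
#'   sizes have no default and must be stated); errors with the full list of
#'   problems otherwise.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file '%s' not found", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("config must be a list or a YAML file path")
  schema <- config_schema()
  base <- unclass(default_run_config())
  errors <- character()

  walk <- function(cfg, sch, def, prefix) {
    unknown <- setdiff(names(cfg), names(sch))
    for (u in unknown)
      errors <<- c(errors, sprintf("unknown key `%s%s`", prefix, u))
    for (k in names(sch)) {
      key <- paste0(prefix, k)
      if (is.list(sch[[k]])) {
        sub <- cfg[[k]] %||% list()
        if (!is.list(sub)) {
          errors <<- c(errors, sprintf("`%s` must be a mapping", key))
          next
        }
        def[[k]] <- walk(sub, sch[[k]], def[[k]], paste0(key, "."))
      } else if (!is.null(cfg[[k]])) {
        if (!check_type(cfg[[k]], sch[[k]]))
          errors <<- c(errors, sprintf("`%s` has wrong type/shape", key))
        else def[[k]] <- cfg[[k]]
      }
    }
    def
  }
  out <- walk(config, schema, base, "")

  ## group sizes define the experiment and must be stated explicitly
  for (k in c("n_group1", "n_group2"))
    if (is.null(config$cohort[[k]]))
      errors <- c(errors, sprintf("missing required key `cohort.%s`", k))

  ## range checks run unconditionally so all problems surface together
  {
    if (out$dc$r0 <= 0 || out$dc$r0 >= 1)
      errors <- c(errors, "`dc.r0` must lie strictly inside (0, 1)")
    if (!out$dc$variant %in% c("weighted", "binary"))
      errors <- c(errors, "`dc.variant` must be 'weighted' or 'binary'")
    if (!out$dc$z_method %in% c("map_standardize", "fisher_rz"))
      errors <- c(errors,
                  "`dc.z_method` must be 'map_standardize' or 'fisher_rz'")
    if (out$dc$fwhm_mm < 0) errors <- c(errors, "`dc.fwhm_mm` must be >= 0")
    if (out$selection$prune_threshold <= 0 || out$selection$prune_threshold > 1)
      errors <- c(errors, "`selection.prune_threshold` must lie in (0, 1]")
    if (out$cohort$n_group1 < 2 || out$cohort$n_group2 < 2)
      errors <- c(errors, "`cohort.n_group1`/`n_group2` must be >= 2")
    if (out$cohort$effect_size < 0)
      errors <- c(errors, "`cohort.effect_size` must be >= 0")
    bad <- setdiff(out$classification$models,
                   c("svm_linear", "random_forest", "logistic_regression"))
    if (length(bad))
      errors <- c(errors, sprintf("`classification.models`: unknown model %s",
                                  paste(bad, collapse = ", ")))
  }
  if (length(errors))
    stopf("invalid configuration:\n%s",
          paste0("  - ", errors, collapse = "\n"))
  structure(out, class = "run_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulation -> per-subject degree-centrality mapping -> atlas region-mean
#' feature extraction -> two-stage feature selection -> three-classifier
#' LOOCV evaluation -> demographics table. All tabular artifacts (TSV/JSON)
#' are deterministic functions of the configuration; a stage whose outputs
#' already exist is skipped unless `force = TRUE`, so deleted intermediates
#' are regenerated identically.
#'
#' @param config a `run_config` (or anything [validate_config()] accepts).
#' @param out_dir output directory (overrides the config's).
#' @param force recompute stages whose outputs already exist.
#' @param write_images also write mask/atlas/per-subject NIfTI images
#'   (slower; the tabular pipeline does not need them).
#' @return invisibly, a list with `features`, `selection`, `models`
#'   (reports + comparison), `demographics`, and the output paths.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL,
                         force = FALSE, write_images = FALSE) {
  cfg <- validate_config(unclass(config))
  out <- out_dir %||% cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    participants = file.path(out, "participants.tsv"),
    features = file.path(out, "features.tsv"),
    selection = file.path(out, "selection.json"),
    comparison = file.path(out, "model_comparison.tsv"),
    demographics = file.path(out, "demographics.tsv"),
    provenance = file.path(out, "provenance.json"))

  geometry <- generate_toy_geometry(cfg$geometry$shape,
                                    cfg$geometry$voxel_size_mm,
                                    cfg$geometry$mask_rule,
                                    cfg$geometry$radius_voxels)
  atlas <- generate_toy_atlas(geometry, cfg$atlas$n_regions,
                              seed = derive_seed(cfg$seed, 1L))
  spec <- cohort_spec(cfg$cohort$n_group1, cfg$cohort$n_group2,
                      cfg$cohort$n_timepoints, cfg$cohort$effect_regions,
                      cfg$cohort$effect_size, cfg$cohort$base_coupling,
                      cfg$cohort$noise_sd, seed = derive_seed(cfg$seed, 2L))

  ## stage 1-3: simulate, map, extract (regenerated together)
  if (force || !file.exists(paths$features) ||
      !file.exists(paths$participants)) {
    cohort <- simulate_cohort(geometry, atlas, spec)
    if (write_images) {
      img_dir <- file.path(out, "images")
      dir.create(img_dir, showWarnings = FALSE)
      write_mask_nifti(geometry, file.path(img_dir, "mask.nii.gz"))
      write_atlas_nifti(atlas, geometry, file.path(img_dir, "atlas.nii.gz"))
    }
    maps <- lapply(cohort$recordings, function(rec) {
      m <- dc_pipeline(rec$bold, r0 = cfg$dc$r0, variant = cfg$dc$variant,
                       z_method = cfg$dc$z_method, fwhm_mm = cfg$dc$fwhm_mm,
                       chunk_size = cfg$dc$chunk_size)
      if (write_images) {
        p <- file.path(out, "images", paste0(rec$subject_id, "_zdc.nii.gz"))
        write_map_nifti(m, p)
        write_map_sidecar(m, p, chunk_size = cfg$dc$chunk_size)
      }
      m
    })
    names(maps) <- cohort$participants$subject_id
    features <- build_feature_table(maps, atlas, cohort$participants)
    write_participants(cohort$participants, paths$participants)
    write_feature_table(features, paths$features)
  }
  ## downstream stages always consume the on-disk table, so a stage rerun
  ## from regenerated intermediates is bit-identical to the original
  features <- read_feature_table(paths$features)
  participants <- read_participants(paths$participants)

  ## stage 4: feature selection
  if (force || !file.exists(paths$selection)) {
    selection <- select_features(features,
                                 prune_threshold = cfg$selection$prune_threshold,
                                 n_folds = cfg$selection$n_folds,
                                 seed = derive_seed(cfg$seed, 3L))
    write_selection_result(selection, paths$selection)
  } else {
    selection <- jsonlite::read_json(paths$selection, simplifyVector = TRUE)
  }
  selected <- names(selection$nonzero_features)
  if (is.null(selected) || !length(selected))
    selected <- selection$kept_after_prune  # degenerate null fit: keep pruned set

  ## stage 5: classification
  if (force || !file.exists(paths$comparison)) {
    models <- run_all_models(
      features$matrix[, selected, drop = FALSE], features$labels,
      seed = derive_seed(cfg$seed, 4L),
      n_permutations = cfg$classification$n_permutations,
      inner_folds = cfg$classification$inner_folds)
    df <- models$comparison
    df[-1] <- lapply(df[-1], function(x) formatC(x, digits = 10, format = "g"))
    utils::write.table(df, paths$comparison, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    for (m in names(models$reports))
      write_model_report(models$reports[[m]],
                         file.path(out, paste0("report_", m, ".json")))
  } else {
    models <- NULL
  }

  ## stage 6: demographics on the simulated participant table
  if (force || !file.exists(paths$demographics)) {
    demo <- demographics_table(participants, "moca")
    utils::write.table(demo, paths$demographics, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    demo <- utils::read.delim(paths$demographics)
  }

  jsonlite::write_json(list(
    config = unclass(cfg),
    software = paste0("neurodc ", as.character(utils::packageVersion("neurodc"))),
    outputs = {
      ps <- paths[names(paths) != "provenance"]
      lapply(ps[file.exists(unlist(ps))],
             function(p) unname(tools::md5sum(p)))
    }
  ), paths$provenance, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(features = features, selection = selection, models = models,
                 demographics = demo, paths = paths))
}
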