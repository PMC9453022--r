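#' Specify a two-group synthetic cohort
#'
#' Collects the generative parameters for a cohort of BOLD-like recordings
#' with a planted degree-centrality difference. Each voxel's series is a
#' region-shared latent signal scaled by a coupling weight plus iid Gaussian
#' noise; in `effect_regions` the coupling is raised by `effect_size` for
#' group 1 only, so group 1 has denser within-region correlation there and
#' hence higher voxel degree.
#'
#' Defaults mirror a two-group resting-state study design: 240 time points
#' per recording and (for study-scale runs) groups of 51 and 48.
#'
#' @param n_group1,n_group2 subjects per group (each >= 2). Group 1 is the
#'   cognitively impaired (MCI) group.
#' @param n_timepoints time points per recording (>= 8).
#' @param effect_regions integer region ids receiving the planted effect.
#' @param effect_size increment to the coupling weight in `effect_regions`
#'   for group 1 (>= 0; 0 = null cohort).
#' @param base_coupling coupling weight shared by all voxels.
#' @param noise_sd iid noise standard deviation (>= 0; 0 leaves only the
#'   region-shared signal).
#' @param signal_band_hz optional length-2 band (Hz) to band-limit the latent
#'   region signals, e.g. `c(0.01, 0.08)`; `NULL` (default) leaves them white.
#' @param sampling_interval_s repetition time in seconds (used only when
#'   band-limiting).
#' @param seed master seed; per-subject seeds derive from it via
#'   [derive_seed()].
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_group1 = 51L, n_group2 = 48L, n_timepoints = 240L,
                        effect_regions = integer(), effect_size = 0,
                        base_coupling = 1, noise_sd = 1,
                        signal_band_hz = NULL, sampling_interval_s = 2,
                        seed = 1L) {
  if (n_group1 < 2L || n_group2 < 2L) stopf("need >= 2 subjects per group")
  if (n_timepoints < 8L) stopf("`n_timepoints` must be >= 8")
  if (!is.finite(effect_size) || effect_size < 0)
    stopf("`effect_size` must be finite and >= 0")
  if (!is.finite(base_coupling) || !is.finite(noise_sd) || noise_sd < 0)
    stopf("`base_coupling` must be finite and `noise_sd` >= 0")
  if (!is.null(signal_band_hz) &&
      (length(signal_band_hz) != 2L || any(!is.finite(signal_band_hz)) ||
       signal_band_hz[1] >= signal_band_hz[2]))
    stopf("`signal_band_hz` must be c(low, high) with low < high")
  structure(list(n_group1 = as.integer(n_group1),
                 n_group2 = as.integer(n_group2),
                 n_timepoints = as.integer(n_timepoints),
                 effect_regions = as.integer(effect_regions),
                 effect_size = effect_size, base_coupling = base_coupling,
                 noise_sd = noise_sd, signal_band_hz = signal_band_hz,
                 sampling_interval_s = sampling_interval_s,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

## FFT band-pass: zero all frequency bins outside [low, high] Hz, then
## rescale to unit variance so coupling weights keep their meaning.
band_limit <- function(x, band_hz, tr_s) {
  n <- length(x)
  f <- (seq_len(n) - 1) / (n * tr_s)
  f <- pmin(f, 1 / tr_s - f)  # two-sided frequency axis
  keep <- f >= band_hz[1] & f <= band_hz[2]
  if (!any(keep)) stopf("band %s Hz contains no resolvable frequency",
                        paste(band_hz, collapse = "-"))
  y <- Re(stats::fft(stats::fft(x) * keep, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) stopf("band-limited signal degenerated to a constant")
  y / s
}

#' Simulate one subject's masked BOLD recording
#'
#' Every in-mask voxel's series is
#' `w * latent(region) + noise_sd * noise`, where each region has its own
#' iid N(0,1) latent series (optionally band-limited) and `w` is
#' `base_coupling`, plus `effect_size` if the subject is in group 1 and the
#' voxel lies in an effect region. Series are mean-centered per voxel.
#' A MoCA score is drawn consistent with the group under the "< 26 means
#' impairment" rule: uniform on \[18, 25\] for group 1, \[26, 30\] for group 2.
#'
#' @param geometry,atlas toy geometry and atlas (or compatible objects).
#' @param group 1 (MCI) or 2 (nMCI).
#' @param spec a [cohort_spec()].
#' @param subject_seed integer seed for this subject's random stream.
#' @param subject_id optional id string.
#' @return a `subject_recording`: list with `subject_id`, `group`, `moca`
#'   and `bold` (a `masked_bold`: `data` is the in-mask voxel x time matrix,
#'   rows ordered as `voxel_index`).
#' @export
simulate_subject <- function(geometry, atlas, group, spec, subject_seed,
                             subject_id = sprintf("sub-%03d", subject_seed %% 1000L)) {
  stopifnot(inherits(spec, "cohort_spec"), group %in% c(1L, 2L))
  validate_atlas(atlas, geometry)
  if (length(spec$effect_regions) &&
      !all(spec$effect_regions %in% atlas$region_ids))
    stopf("effect_regions outside the atlas region ids")

  lab <- mask_labels(atlas, geometry)
  nt <- spec$n_timepoints
  nv <- geometry$n_voxels

  data <- with_seed(subject_seed, {
    latents <- sapply(atlas$region_ids, function(r) {
      z <- stats::rnorm(nt)
      if (!is.null(spec$signal_band_hz))
        z <- band_limit(z, spec$signal_band_hz, spec$sampling_interval_s)
      z
    })  # nt x n_regions
    w <- rep(spec$base_coupling, nv)
    if (group == 1L && length(spec$effect_regions))
      w[lab %in% spec$effect_regions] <- spec$base_coupling + spec$effect_size
    x <- latents[, lab, drop = FALSE]          # nt x nv, shared signals
    x <- t(x) * w                              # nv x nt
    x + spec$noise_sd * matrix(stats::rnorm(nv * nt), nv, nt)
  })
  data <- data - rowMeans(data)

  moca <- with_seed(derive_seed(subject_seed, 999L),
                    if (group == 1L) stats::runif(1, 18, 25)
                    else stats::runif(1, 26, 30))

  bold <- structure(list(data = data, geometry = geometry,
                         voxel_index = mask_coords(geometry)),
                    class = "masked_bold")
  structure(list(subject_id = subject_id, group = as.integer(group),
                 moca = moca, bold = bold),
            class = "subject_recording")
}

#' Simulate a full two-group cohort
#'
#' Generates `n_group1 + n_group2` recordings with per-subject seeds derived
#' reproducibly from the cohort's master seed, plus a participant table. If
#' `out_dir` is given, the participant table is written as
#' `participants.tsv` (columns `subject_id`, `group`, `moca`).
#'
#' @param geometry,atlas as in [simulate_subject()].
#' @param spec a [cohort_spec()].
#' @param out_dir optional directory for the participant TSV.
#' @return list with `recordings` (list of `subject_recording`) and
#'   `participants` (data.frame).
#' @export
simulate_cohort <- function(geometry, atlas, spec, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_group1 + spec$n_group2
  groups <- rep(c(1L, 2L), c(spec$n_group1, spec$n_group2))
  ids <- sprintf("sub-%03d", seq_len(n))
  recordings <- lapply(seq_len(n), function(i)
    simulate_subject(geometry, atlas, groups[i], spec,
                     subject_seed = derive_seed(spec$seed, i),
                     subject_id = ids[i]))
  participants <- data.frame(
    subject_id = ids, group = groups,
    moca = vapply(recordings, `[[`, numeric(1), "moca"),
    stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_participants(participants, file.path(out_dir, "participants.tsv"))
  }
  list(recordings = recordings, participants = participants)
}

#' Write / read a participant table
#'
#' Tab-separated with header `subject_id\tgroup\tmoca` (plus any extra
#' covariate columns present).
#' @param participants data.frame with at least those columns.
#' @param path file path.
#' @export
write_participants <- function(participants, path) {
  stopifnot(all(c("subject_id", "group", "moca") %in% names(participants)))
  df <- participants
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "group"
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 10, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_participants
#' @export
read_participants <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Printed per-group feature distribution parameters
#'
#' Loads the shipped table of 10 selected zDC features with per-group
#' mean/SD (and the reported per-model weights), used to parameterize
#' [simulate_feature_table()].
#'
#' @return data.frame with columns `id`, `feature`, `network`, `mci_mean`,
#'   `mci_sd`, `nmci_mean`, `nmci_sd`, `weight_svm`, `weight_lr`, `weight_rf`.
#' @export
table2_params <- function() {
  path <- system.file("extdata", "table2_features.tsv", package = "neurodc",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) != 10L) stopf("feature parameter fixture must have 10 rows")
  if (any(df$mci_sd <= 0) || any(df$nmci_sd <= 0))
    stopf("feature parameter SDs must be positive")
  df
}

#' Draw a tabular feature set from per-group Gaussian parameters
#'
#' Each subject's value for each feature is drawn independently from the
#' Gaussian with that feature's group mean and SD. Labels are `MCI` for
#' group 1 and `nMCI` for group 2.
#'
#' @param params a data.frame shaped like [table2_params()] (columns
#'   `feature`, `mci_mean`, `mci_sd`, `nmci_mean`, `nmci_sd`).
#' @param n1,n2 subjects per group (each >= 2).
#' @param seed integer seed.
#' @return a `feature_table` (see [feature_table()]).
#' @export
simulate_feature_table <- function(params = table2_params(), n1 = 51L,
                                   n2 = 48L, seed = 1L) {
  need <- c("feature", "mci_mean", "mci_sd", "nmci_mean", "nmci_sd")
  if (!all(need %in% names(params)))
    stopf("`params` is missing column(s): %s",
          paste(setdiff(need, names(params)), collapse = ", "))
  if (n1 < 2L || n2 < 2L) stopf("need >= 2 subjects per group")
  p <- nrow(params)
  mat <- with_seed(seed, {
    g1 <- sapply(seq_len(p), function(j)
      stats::rnorm(n1, params$mci_mean[j], params$mci_sd[j]))
    g2 <- sapply(seq_len(p), function(j)
      stats::rnorm(n2, params$nmci_mean[j], params$nmci_sd[j]))
    rbind(matrix(g1, nrow = n1), matrix(g2, nrow = n2))
  })
  colnames(mat) <- params$feature
  feature_table(mat,
                subject_ids = sprintf("sub-%03d", seq_len(n1 + n2)),
                labels = rep(c("MCI", "nMCI"), c(n1, n2)))
}
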