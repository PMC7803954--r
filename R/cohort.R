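#' Specify a synthetic cohort
#'
#' Subject-level structure: abilities drawn uniformly over a wide range
#' (emulating a sample selected for a broad spread of voice-recognition
#' skill) and a coupling parameter tying each subject's neural pattern
#' amplitude to their ability. With coupling c, the neural effect is
#' `(1 - c) * g + c * ability` with `g` an independent uniform draw over the
#' same range, so c = 0 gives a clean null (no brain-behaviour association)
#' and c = 1 a deterministic one.
#'
#' @param n_subjects cohort size (default 40).
#' @param ability_range lower/upper bound of the uniform ability law.
#' @param coupling scalar in `[0, 1]`.
#' @param miss_rate,error_kernel passed to each subject's [behavior_model()].
#' @param seed optional integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 40L, ability_range = c(0.35, 0.95),
                        coupling = 1, miss_rate = 0.05, error_kernel = NULL,
                        seed = NULL) {
  vl_assert(is_count(n_subjects) && n_subjects >= 2,
            "n_subjects must be a count >= 2")
  vl_assert(coupling >= 0 && coupling <= 1, "coupling must lie in [0, 1]")
  vl_assert(length(ability_range) == 2 &&
              ability_range[1] >= 0 && ability_range[2] <= 1 &&
              ability_range[1] < ability_range[2],
            "ability_range must be an increasing pair inside [0, 1]")
  structure(list(n_subjects = as.integer(n_subjects),
                 ability_range = ability_range, coupling = coupling,
                 miss_rate = miss_rate, error_kernel = error_kernel,
                 seed = seed),
            class = "cohort_spec")
}

#' Draw the subject-level truth for a cohort
#'
#' @param cohort a [cohort_spec()].
#' @param seed overrides `cohort$seed` when non-NULL.
#' @return Data frame with `subject`, `ability`, `g` (the independent draw)
#'   and `subject_effect`.
#' @export
draw_cohort_truth <- function(cohort, seed = NULL) {
  stopifnot(inherits(cohort, "cohort_spec"))
  seed <- if (is.null(seed)) cohort$seed else seed
  with_seed(seed, {
    n <- cohort$n_subjects
    ability <- stats::runif(n, cohort$ability_range[1], cohort$ability_range[2])
    g <- stats::runif(n, cohort$ability_range[1], cohort$ability_range[2])
    effect <- (1 - cohort$coupling) * g + cohort$coupling * ability
    data.frame(subject = sprintf("sub-%02d", seq_len(n)),
               ability = ability, g = g, subject_effect = effect)
  })
}

#' Generate a synthetic multi-subject dataset on disk
#'
#' For every subject: a fresh event design, simulated button presses with
#' the subject's ability, and 4D BOLD phantoms with speaker-pattern
#' amplitude `subject_effect`, written in a BIDS-inspired layout
#' (`sub-XX/func/sub-XX_task-speaker_run-0N_bold.nii.gz` plus an events TSV)
#' with a dataset-level JSON provenance sidecar recording the specs, seeds
#' and per-subject ground truth.
#'
#' @param cohort a [cohort_spec()].
#' @param design a [design_spec()].
#' @param phantom a [phantom_spec()].
#' @param out_dir output directory (created if needed).
#' @param seed master seed; per-subject seeds are derived from it.
#' @return Invisibly, the provenance list (with the truth table).
#' @export
generate_cohort <- function(cohort, design, phantom, out_dir, seed = NULL) {
  stopifnot(inherits(design, "design_spec"), inherits(phantom, "phantom_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(seed)) cohort$seed else seed
  vl_assert(!is.null(seed), "generate_cohort needs a seed for reproducibility")
  truth <- draw_cohort_truth(cohort, seed = seed)
  sub_seeds <- subject_seeds(seed, cohort$n_subjects)
  for (i in seq_len(cohort$n_subjects)) {
    sub <- truth$subject[i]
    func_dir <- file.path(out_dir, sub, "func")
    dir.create(func_dir, recursive = TRUE, showWarnings = FALSE)
    events <- generate_design(design, seed = sub_seeds[i])
    model <- behavior_model(ability = truth$ability[i],
                            miss_rate = cohort$miss_rate,
                            error_kernel = cohort$error_kernel)
    events <- simulate_responses(events, model, seed = sub_seeds[i] + 1L)
    patterns <- make_speaker_patterns(phantom, design$speakers,
                                      seed = sub_seeds[i] + 2L)
    runs <- simulate_bold(events, phantom,
                          subject_effect = truth$subject_effect[i],
                          patterns = patterns, seed = sub_seeds[i] + 3L)
    for (r in seq_along(runs)) {
      path <- file.path(func_dir,
                        sprintf("%s_task-speaker_run-%02d_bold.nii.gz", sub, r))
      write_volume(runs[[r]], path, voxel_size_mm = phantom$voxel_size_mm)
      ev <- events[events$run == r, , drop = FALSE]
      write_events(ev, file.path(
        func_dir, sprintf("%s_task-speaker_run-%02d_events.tsv", sub, r)))
    }
  }
  prov <- list(generator = "voicelight::generate_cohort",
               seed = seed,
               cohort = unclass(cohort), design = unclass(design),
               phantom = list(grid_shape = phantom$grid_shape,
                              voxel_size_mm = phantom$voxel_size_mm,
                              baseline_amplitude = phantom$baseline_amplitude,
                              noise_sigma = phantom$noise_sigma,
                              drift_amplitude = phantom$drift_amplitude,
                              drift_cutoff = phantom$drift_cutoff,
                              n_informative_rois =
                                length(phantom$informative_rois)),
               truth = truth)
  jsonlite::write_json(prov, file.path(out_dir, "dataset_provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prov)
}

# Distinct, reproducible per-subject seed streams under one master seed.
subject_seeds <- function(seed, n) {
  as.integer(seed) + 10000L * seq_len(n)
}
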