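#' Specify a BOLD phantom
#'
#' Geometry and signal model for synthetic 4D runs: a sound-responsive mask
#' of active voxels, a subset of "informative" regions carrying multivoxel
#' speaker patterns, white Gaussian noise, and low-frequency drift built from
#' cosines below the high-pass cutoff (so the first-level filter can remove
#' it). The default is a 12^3 grid of 2-mm voxels with a central
#' sound-responsive block containing one informative cube.
#'
#' @param grid_shape 3 voxel counts.
#' @param voxel_size_mm per-axis spacing in mm.
#' @param informative_rois list of `list(mask = <3D logical>, amplitude =
#'   <sd of the per-voxel speaker pattern, signal units>)`. NULL builds a
#'   default 4x4x4 cube with amplitude 1.
#' @param sound_responsive_mask 3D logical superset of all informative ROIs;
#'   NULL builds a default central block.
#' @param baseline_amplitude common evoked response of sound-responsive
#'   voxels (signal units per trial).
#' @param noise_sigma sd of iid Gaussian noise.
#' @param drift_amplitude sd of the random per-voxel cosine-drift weights.
#' @param drift_cutoff drifts use cosine periods longer than this (seconds);
#'   match the GLM's `hp_cutoff` so the filter absorbs them.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(12L, 12L, 12L),
                         voxel_size_mm = c(2, 2, 2),
                         informative_rois = NULL,
                         sound_responsive_mask = NULL,
                         baseline_amplitude = 1,
                         noise_sigma = 0.5,
                         drift_amplitude = 1,
                         drift_cutoff = 128) {
  grid_shape <- as.integer(grid_shape)
  vl_assert(length(grid_shape) == 3 && all(grid_shape >= 1),
            "grid_shape must be 3 positive counts")
  vl_assert(length(voxel_size_mm) == 3 && all(voxel_size_mm > 0),
            "voxel_size_mm must be 3 positive spacings")
  vl_assert(noise_sigma >= 0, "noise_sigma must be >= 0")
  if (is.null(sound_responsive_mask)) {
    sound_responsive_mask <- block_mask(grid_shape, inset = 2L)
  }
  vl_assert(all(dim(sound_responsive_mask) == grid_shape),
            "sound_responsive_mask grid mismatch")
  if (is.null(informative_rois)) {
    lo <- pmax(1L, floor(grid_shape / 2) - 1L)
    hi <- pmin(grid_shape, lo + 3L)
    roi <- array(FALSE, grid_shape)
    roi[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    informative_rois <- list(list(mask = roi, amplitude = 1))
  }
  for (roi in informative_rois) {
    vl_assert(all(dim(roi$mask) == grid_shape),
              "informative ROI grid mismatch")
    if (any(roi$mask & !sound_responsive_mask)) {
      vl_error("informative ROI extends outside the sound-responsive mask",
               "voicelight_geometry_error")
    }
    vl_assert(roi$amplitude >= 0, "ROI amplitude must be >= 0")
  }
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 informative_rois = informative_rois,
                 sound_responsive_mask = sound_responsive_mask != 0,
                 baseline_amplitude = baseline_amplitude,
                 noise_sigma = noise_sigma,
                 drift_amplitude = drift_amplitude,
                 drift_cutoff = drift_cutoff),
            class = "phantom_spec")
}

block_mask <- function(grid_shape, inset = 2L) {
  m <- array(FALSE, grid_shape)
  lo <- pmin(grid_shape, inset + 1L)
  hi <- pmax(lo, grid_shape - inset)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  m
}

#' Draw a subject's multivoxel speaker patterns
#'
#' One pattern per speaker: iid Gaussian voxel weights (sd = the ROI's
#' amplitude) inside each informative ROI, zero elsewhere. Patterns are drawn
#' once per subject and reused across runs, which is what makes decoding
#' across runs possible.
#'
#' @param phantom a [phantom_spec()].
#' @param speakers speaker labels.
#' @param seed optional integer seed.
#' @return Matrix n_speakers x n_voxels (full grid, zero outside ROIs), with
#'   speakers as row names.
#' @export
make_speaker_patterns <- function(phantom, speakers, seed = NULL) {
  stopifnot(inherits(phantom, "phantom_spec"))
  n_vox <- prod(phantom$grid_shape)
  with_seed(seed, {
    P <- matrix(0, length(speakers), n_vox,
                dimnames = list(speakers, NULL))
    for (roi in phantom$informative_rois) {
      idx <- which(roi$mask)
      P[, idx] <- P[, idx] +
        matrix(stats::rnorm(length(speakers) * length(idx),
                            sd = roi$amplitude),
               length(speakers))
    }
    P
  })
}

#' Simulate 4D BOLD runs for one subject
#'
#' Forward model: per voxel, the sum over trials of the HRF-convolved boxcar
#' times a trial amplitude (common sound-evoked baseline inside the
#' sound-responsive mask, plus `subject_effect` times the presented speaker's
#' pattern inside informative ROIs), plus cosine drift and white noise.
#' The trial regressors are the same ones [build_design_matrix()] builds, so
#' a noiseless simulation is recovered exactly by the GLM.
#'
#' @param design multi- or single-run `event_table`.
#' @param phantom a [phantom_spec()].
#' @param subject_effect scalar scaling the speaker patterns (0 = no
#'   decodable signal).
#' @param patterns speaker-pattern matrix from [make_speaker_patterns()];
#'   NULL draws one (then varies with `seed`).
#' @param hrf an [hrf_params()].
#' @param seed optional integer seed.
#' @return Named list of 4D arrays (x, y, z, time), one per run.
#' @export
simulate_bold <- function(design, phantom, subject_effect = 1,
                          patterns = NULL, hrf = hrf_params(), seed = NULL) {
  stopifnot(inherits(design, "event_table"), inherits(phantom, "phantom_spec"))
  speakers <- attr(design, "speakers")
  tr <- attr(design, "tr")
  n_vol <- attr(design, "n_volumes_per_run")
  dims <- phantom$grid_shape
  n_vox <- prod(dims)
  with_seed(seed, {
    if (is.null(patterns)) patterns <- make_speaker_patterns(phantom, speakers)
    vl_assert(ncol(patterns) == n_vox && nrow(patterns) == length(speakers),
              "patterns dimension mismatch")
    base <- phantom$baseline_amplitude * as.numeric(phantom$sound_responsive_mask)
    run_ids <- sort(unique(design$run))
    n_drift <- max(0L, floor(2 * n_vol * tr / phantom$drift_cutoff))
    dct <- dct_highpass_basis(n_vol, tr, phantom$drift_cutoff)
    out <- lapply(run_ids, function(r) {
      ev <- design[design$run == r, , drop = FALSE]
      X <- trial_regressors(ev$onset, ev$duration, n_vol, tr, hrf)
      spk_idx <- match(ev$speaker, speakers)
      # trial-by-voxel amplitudes
      A <- matrix(base, nrow(ev), n_vox, byrow = TRUE) +
        subject_effect * patterns[spk_idx, , drop = FALSE]
      Y <- X %*% A
      if (phantom$drift_amplitude > 0 && n_drift > 0) {
        W <- matrix(stats::rnorm(n_drift * n_vox,
                                 sd = phantom$drift_amplitude), n_drift)
        Y <- Y + dct %*% W
      }
      if (phantom$noise_sigma > 0) {
        Y <- Y + stats::rnorm(length(Y), sd = phantom$noise_sigma)
      }
      array(t(Y), c(dims, n_vol))
    })
    names(out) <- paste0("run-", run_ids)
    out
  })
}
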