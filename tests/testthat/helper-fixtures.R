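# Shared fixtures and independent oracles, built in code at test time.

# Tiny all-informative phantom on an n^3 grid.
tiny_phantom <- function(n = 6L, noise_sigma = 0.5, drift_amplitude = 1,
                         amplitude = 1) {
  full <- array(TRUE, c(n, n, n))
  phantom_spec(grid_shape = c(n, n, n), noise_sigma = noise_sigma,
               drift_amplitude = drift_amplitude,
               sound_responsive_mask = full,
               informative_rois = list(list(mask = full,
                                            amplitude = amplitude)))
}

# Beta series built directly (no GLM): speaker patterns + optional
# word-specific nuisance + noise, for decoding-level tests.
synthetic_betas <- function(n_runs = 4, n_words = 12, n_speakers = 3,
                            n_voxels = 30, effect = 1, word_effect = 0,
                            noise = 1, seed = 1) {
  withr::with_seed(seed, {
    speakers <- paste0("s", seq_len(n_speakers))
    words <- sprintf("w%02d", seq_len(n_words))
    meta <- expand.grid(word = words, speaker = speakers, run = seq_len(n_runs),
                        stringsAsFactors = FALSE)
    spk_pat <- matrix(rnorm(n_speakers * n_voxels), n_speakers)
    wrd_pat <- matrix(rnorm(n_words * n_voxels), n_words)
    X <- effect * spk_pat[match(meta$speaker, speakers), ] +
      word_effect * wrd_pat[match(meta$word, words), ] +
      noise * matrix(rnorm(nrow(meta) * n_voxels), nrow(meta))
    mask <- array(FALSE, c(n_voxels, 1, 1))
    mask[seq_len(n_voxels), 1, 1] <- TRUE
    structure(list(betas = X, meta = meta, mask = mask,
                   grid = list(shape = c(n_voxels, 1L, 1L),
                               voxel_size = c(1, 1, 1)),
                   voxel_index = which(mask),
                   dropped_columns = character(0)),
              class = "beta_series")
  })
}

# In-memory cohort run at reduced grid: full 4-run, 36-trial design per
# subject; returns per-subject ROI decoding accuracy and behavioural PC.
run_reduced_cohort <- function(n_subjects, coupling, seed,
                               grid_n = 4L, noise_sigma = 8) {
  design <- design_spec()
  dims <- rep(grid_n, 3)
  full <- array(TRUE, dims)
  roi <- array(FALSE, dims)
  roi[1:2, 1:2, 1:2] <- TRUE
  phantom <- phantom_spec(grid_shape = dims, noise_sigma = noise_sigma,
                          sound_responsive_mask = full,
                          informative_rois = list(list(mask = roi,
                                                       amplitude = 1)))
  cohort <- cohort_spec(n_subjects = n_subjects, coupling = coupling)
  truth <- draw_cohort_truth(cohort, seed = seed)
  acc <- numeric(n_subjects)
  pc <- numeric(n_subjects)
  for (i in seq_len(n_subjects)) {
    s0 <- seed + 1000L * i
    ev <- generate_design(design, seed = s0)
    ev <- simulate_responses(ev, behavior_model(ability = truth$ability[i]),
                             seed = s0 + 1L)
    pat <- make_speaker_patterns(phantom, design$speakers, seed = s0 + 2L)
    runs <- simulate_bold(ev, phantom,
                          subject_effect = truth$subject_effect[i],
                          patterns = pat, seed = s0 + 3L)
    betas <- fit_beta_series(runs, ev, tr = design$tr)
    acc[i] <- roi_accuracy(betas, roi)$accuracy
    pc[i] <- percent_correct(ev)$pc_overall
  }
  list(accuracy = acc, pc = pc, truth = truth)
}

# Independent OvO oracle: plain loops over class pairs and a hand vote tally.
oracle_ovo <- function(train_x, train_y, test_x, C = 1) {
  classes <- sort(unique(train_y))
  tally <- matrix(0, nrow(test_x), length(classes),
                  dimnames = list(NULL, classes))
  for (i in seq_len(length(classes) - 1)) {
    for (j in (i + 1):length(classes)) {
      pair <- classes[c(i, j)]
      sel <- train_y %in% pair
      fit <- e1071::svm(train_x[sel, , drop = FALSE],
                        factor(train_y[sel], levels = pair),
                        type = "C-classification", kernel = "linear",
                        cost = C, scale = FALSE)
      p <- as.character(predict(fit, test_x))
      for (k in seq_len(nrow(test_x))) tally[k, p[k]] <- tally[k, p[k]] + 1
    }
  }
  apply(tally, 1, function(v) names(v)[which.max(v)])
}

# Independent CV-accuracy oracle: explicit fold loop, pooled predictions.
oracle_cv_accuracy <- function(features, meta, key) {
  groups <- meta[[key]]
  preds <- character(nrow(features))
  for (g in sort(unique(groups))) {
    test <- groups == g
    preds[test] <- oracle_ovo(features[!test, , drop = FALSE],
                              as.character(meta$speaker)[!test],
                              features[test, , drop = FALSE])
  }
  mean(preds == as.character(meta$speaker))
}

# Three well-separated Gaussian clouds in 2D (margin >> spread).
separable_clouds <- function(n_per = 8, spread = 0.05, seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE)
    x <- do.call(rbind, lapply(1:3, function(k) {
      cbind(rnorm(n_per, centers[k, 1], spread),
            rnorm(n_per, centers[k, 2], spread))
    }))
    list(x = x, y = rep(c("a", "b", "c"), each = n_per))
  })
}
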