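test_that("sphere membership matches the lattice-point enumeration oracle", {
  m <- array(TRUE, c(31, 31, 31))
  ctr <- c(16L, 16L, 16L)
  # oracle: direct enumeration of integer offsets
  g <- expand.grid(-8:8, -8:8, -8:8)
  d2 <- rowSums((g * 2)^2)   # 2 mm voxels
  expect_equal(length(sphere_members(m, ctr, 12, boundary = "exclusive")),
               sum(d2 < 144))   # 895
  expect_equal(length(sphere_members(m, ctr, 12, boundary = "inclusive")),
               sum(d2 <= 144))  # 925
  expect_equal(sum(d2 < 144), 895)
  expect_equal(sum(d2 <= 144), 925)
  # r = 0 (inclusive) keeps only the center
  only <- sphere_members(m, ctr, 0, boundary = "inclusive")
  expect_equal(only, voicelight:::ijk_to_lin(matrix(ctr, 1), dim(m)))
  m2 <- m; m2[16, 16, 16] <- FALSE
  expect_error(sphere_members(m2, ctr), class = "voicelight_geometry_error")
})

test_that("one-vs-one voting is unanimous, tie-broken, and separable", {
  toy <- separable_clouds(n_per = 8, seed = 2)
  test_pts <- matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE)
  pred <- ovo_predict(toy$x, toy$y, test_pts)
  expect_equal(pred, c("a", "b", "c"))  # unanimity near each center

  # held-out points from the same clouds: 100% accuracy
  toy2 <- separable_clouds(n_per = 6, seed = 3)
  expect_equal(mean(ovo_predict(toy$x, toy$y, toy2$x) == toy2$y), 1)

  # constructed 3-cycle: at this test point the three pairwise classifiers
  # each vote for a different class (verified below by inspecting the
  # votes), so the tally is 1-1-1 and the tie must break to "a".
  tr_x <- matrix(c(1.830, 1.473,
                   1.874, 0.269,
                   0.572, 1.314,
                   1.661, 1.410,
                   1.283, 0.915,
                   1.038, 1.438), ncol = 2, byrow = TRUE)
  tr_y <- rep(c("a", "b", "c"), each = 2)
  cand <- c(1.55, 1.30)
  votes <- vapply(list(c("a", "b"), c("b", "c"), c("a", "c")), function(p) {
    sel <- tr_y %in% p
    f <- e1071::svm(tr_x[sel, ], factor(tr_y[sel], p),
                    type = "C-classification", kernel = "linear",
                    cost = 1, scale = FALSE)
    as.character(predict(f, rbind(cand)))
  }, character(1))
  expect_setequal(votes, c("a", "b", "c"))  # genuine 1-1-1 cycle
  expect_equal(ovo_predict(tr_x, tr_y, rbind(cand)), "a")
})

test_that("ovo_predict rejects classes with under 2 training samples", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(ovo_predict(x, c("a", "a", "b", "b", "c"), x),
               class = "voicelight_data_error")
})

test_that("cross-validation produces the scheme's fold counts", {
  bs <- synthetic_betas(effect = 1, noise = 0.5, seed = 4)
  loro <- cross_validated_accuracy(bs, scheme = cv_scheme("loro"))
  lowo <- cross_validated_accuracy(bs, scheme = cv_scheme("lowo"))
  expect_equal(loro$n_folds, 4)
  expect_equal(lowo$n_folds, 12)
  expect_equal(cross_validated_accuracy(bs,
    scheme = cv_scheme("leave_one_word_out"))$n_folds, 12)
})

test_that("accuracy equals the confusion-trace identity and labels shuffle with rows", {
  bs <- synthetic_betas(effect = 0.8, noise = 1, seed = 5)
  cv <- cross_validated_accuracy(bs)
  counts <- unclass(cv$confusion) * attr(cv$confusion, "n_trials") / 100
  expect_equal(sum(diag(counts)) / sum(counts), cv$accuracy, tolerance = 1e-12)
  # permuting trials within runs leaves the result unchanged
  withr::with_seed(6, ord <- unlist(lapply(split(seq_len(nrow(bs$meta)),
                                                 bs$meta$run), sample)))
  bs2 <- bs
  bs2$betas <- bs$betas[ord, ]
  bs2$meta <- bs$meta[ord, ]
  cv2 <- cross_validated_accuracy(bs2)
  expect_equal(cv2$accuracy, cv$accuracy)
})

test_that("label permutation gives chance-level accuracy on average", {
  bs <- synthetic_betas(n_voxels = 5, effect = 1, noise = 0.3, seed = 7)
  accs <- withr::with_seed(8, {
    vapply(seq_len(200), function(i) {
      b <- bs
      # permute labels within each run (keeps folds balanced) independently
      # of the features: exactly the no-information null
      for (r in unique(b$meta$run)) {
        sel <- b$meta$run == r
        b$meta$speaker[sel] <- sample(b$meta$speaker[sel])
      }
      cross_validated_accuracy(b)$accuracy
    }, numeric(1))
  })
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 1 / 3), 2 * se + 0.01)
})

test_that("duplicated features do not change linear-SVM predictions on separable toys", {
  toy <- separable_clouds(n_per = 8, seed = 9)
  toy2 <- separable_clouds(n_per = 5, seed = 10)
  p1 <- ovo_predict(toy$x, toy$y, toy2$x)
  p2 <- ovo_predict(cbind(toy$x, toy$x), toy$y, cbind(toy2$x, toy2$x))
  expect_equal(p1, p2)
})

test_that("missing classes in a training fold raise a fold error", {
  bs <- synthetic_betas(n_runs = 2, n_words = 2, seed = 11)
  bs$meta$speaker[bs$meta$run == 1] <- "s1"  # run 2 train set loses s2, s3
  expect_error(cross_validated_accuracy(bs),
               class = "voicelight_fold_error")
})

test_that("searchlight voxels match per-sphere recomputation and detect structure", {
  spec <- design_spec(n_runs = 4, words = sprintf("w%d", 1:4), seed = 20)
  ev <- generate_design(spec, seed = 20)
  n <- 5
  roi <- array(FALSE, c(n, n, n)); roi[1:2, 1:2, 1:2] <- TRUE
  full <- array(TRUE, c(n, n, n))
  ph <- phantom_spec(grid_shape = c(n, n, n), noise_sigma = 0.4,
                     drift_amplitude = 0, sound_responsive_mask = full,
                     informative_rois = list(list(mask = roi, amplitude = 2)))
  pat <- make_speaker_patterns(ph, spec$speakers, seed = 21)
  runs <- simulate_bold(ev, ph, subject_effect = 1, patterns = pat, seed = 22)
  bs <- fit_beta_series(runs, ev, tr = spec$tr)
  am <- run_searchlight(bs, radius_mm = 4, voxel_size_mm = c(2, 2, 2),
                        min_sphere_voxels = 1L)
  # informative corner should decode better than the opposite corner
  expect_gt(am[1, 1, 1], am[n, n, n] + 0.1)
  # spot-check three voxels against an independent recomputation
  for (ctr in list(c(1L, 1L, 1L), c(3L, 3L, 3L), c(n, n, n))) {
    idx <- sphere_members(full, ctr, 4, boundary = "exclusive")
    cols <- match(idx, bs$voxel_index)
    oracle <- oracle_cv_accuracy(bs$betas[, cols, drop = FALSE], bs$meta, "run")
    expect_equal(am[ctr[1], ctr[2], ctr[3]], oracle)
  }
})

test_that("word-confusable features make leave-one-word-out the harder test", {
  diffs <- vapply(1:12, function(s) {
    bs <- synthetic_betas(n_words = 6, n_voxels = 20, effect = 0.4,
                          word_effect = 1.2, noise = 0.6, seed = 100 + s)
    loro <- cross_validated_accuracy(bs, scheme = cv_scheme("loro"))$accuracy
    lowo <- cross_validated_accuracy(bs, scheme = cv_scheme("lowo"))$accuracy
    loro - lowo
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("roi_accuracy matches direct cross-validation on the ROI voxels", {
  spec <- design_spec(n_runs = 4, words = sprintf("w%d", 1:3), seed = 23)
  ev <- generate_design(spec, seed = 23)
  ph <- tiny_phantom(4, noise_sigma = 0.5)
  runs <- simulate_bold(ev, ph, subject_effect = 1, seed = 24)
  bs <- fit_beta_series(runs, ev, tr = spec$tr)
  roi <- array(FALSE, c(4, 4, 4)); roi[1:2, 1:2, 1:2] <- TRUE
  r <- roi_accuracy(bs, roi)
  cols <- match(which(roi), bs$voxel_index)
  direct <- cross_validated_accuracy(bs$betas[, cols], bs$meta)
  expect_equal(r$accuracy, direct$accuracy)
})

test_that("scheme comparison and chance tests reproduce hand-computed t values", {
  expect_equal(scheme_comparison(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(scheme_comparison(c(1, 2, 3), c(1, 2, 3))$p, 1)
  z <- one_sample_vs_chance(rep(1 / 3, 4), chance = 1 / 3)
  expect_equal(z$t, 0)
  acc <- c(40, 30, 50, 40)
  ht <- one_sample_vs_chance(acc, chance = 100 / 3, alternative = "two.sided")
  expect_equal(ht$t, (mean(acc) - 100 / 3) / (sd(acc) / 2), tolerance = 1e-12)
  expect_equal(ht$t, 1.633, tolerance = 1e-3)
})
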