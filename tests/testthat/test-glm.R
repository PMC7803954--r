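test_that("the canonical HRF has the expected shape", {
  h <- canonical_hrf()
  t <- attr(h, "times")
  expect_equal(h[1], 0)                       # zero at the origin
  expect_gt(t[which.max(h)], 4)               # peak between 4 and 7 s
  expect_lt(t[which.max(h)], 7)
  # trapezoidal integration oracle: net area is positive
  expect_gt(sum(diff(t) * (head(h, -1) + tail(h, -1)) / 2), 0)
  expect_error(hrf_params(peak_delay = -1),
               class = "voicelight_parameter_error")
})

test_that("design matrices have the documented column structure", {
  spec <- design_spec(seed = 1)
  ev <- generate_design(spec, seed = 1)
  ev <- simulate_responses(ev, behavior_model(miss_rate = 0), seed = 2)
  run1 <- ev[ev$run == 1, ]
  nuis <- matrix(rnorm(366 * 3), 366, 3)
  dm <- build_design_matrix(run1, 366, 0.955, nuisance = nuis)
  n_dct <- ncol(dct_highpass_basis(366, 0.955, 128))
  expect_equal(ncol(dm$X), 36 + 1 + 3 + n_dct + 1)
  expect_equal(dm$trial_columns, 1:36)
  expect_false(anyDuplicated(dm$names) > 0)

  empty <- run1[0, ]
  dm0 <- build_design_matrix(empty, 366, 0.955)
  expect_equal(ncol(dm0$X), n_dct + 1)

  late <- run1
  late$onset[1] <- 1000
  expect_error(build_design_matrix(late, 366, 0.955),
               class = "voicelight_design_error")
})

test_that("the discrete cosine high-pass block is orthonormal", {
  B <- dct_highpass_basis(366, 0.955, 128)
  expect_gt(ncol(B), 0)
  expect_lt(max(abs(crossprod(B) - diag(ncol(B)))), 1e-10)
})

test_that("noiseless forward simulations are recovered exactly", {
  spec <- design_spec(n_runs = 1, seed = 11)
  ev <- generate_design(spec, seed = 11)
  ph <- tiny_phantom(5, noise_sigma = 0, drift_amplitude = 0)
  pat <- make_speaker_patterns(ph, spec$speakers, seed = 2)
  runs <- simulate_bold(ev, ph, subject_effect = 1.3, patterns = pat)
  bs <- fit_beta_series(runs, ev, tr = spec$tr)
  truth <- 1 + 1.3 * pat[match(ev$speaker, spec$speakers), ]
  expect_lt(max(abs(bs$betas - truth)), 1e-8)
})

test_that("residuals are orthogonal to the design columns", {
  spec <- design_spec(n_runs = 1, seed = 12)
  ev <- generate_design(spec, seed = 12)
  ph <- tiny_phantom(4, noise_sigma = 0.8, drift_amplitude = 1)
  runs <- simulate_bold(ev, ph, subject_effect = 1, seed = 3)
  dm <- build_design_matrix(ev, spec$n_volumes_per_run, spec$tr)
  Y <- matrix(aperm(runs[[1]], c(4, 1, 2, 3)), spec$n_volumes_per_run)
  coef <- qr.coef(qr(dm$X), Y)
  res <- Y - dm$X %*% coef
  rel <- max(abs(crossprod(dm$X, res))) / max(abs(crossprod(dm$X, Y)))
  expect_lt(rel, 1e-6)
})

test_that("OLS beta variance matches the (X'X)^-1 sigma^2 oracle", {
  spec <- design_spec(n_runs = 1, words = sprintf("w%d", 1:4), seed = 13)
  ev <- generate_design(spec, seed = 13)
  dm <- build_design_matrix(ev, 150, 0.955, hp_cutoff = NULL)
  X <- dm$X
  sigma <- 1.5
  XtXinv <- solve(crossprod(X))
  n_rep <- 4000  # sampling sd of a variance ratio ~ sqrt(2/n): ~2.2% here
  withr::with_seed(21, {
    Y <- matrix(rnorm(nrow(X) * n_rep, sd = sigma), nrow(X))
    B <- qr.coef(qr(X), Y)[dm$trial_columns, ]
  })
  emp <- apply(B, 1, var)
  theo <- sigma^2 * diag(XtXinv)[dm$trial_columns]
  expect_true(all(abs(emp / theo - 1) < 0.10))
})

test_that("trial betas are invariant to nuisance-spanned contamination", {
  spec <- design_spec(n_runs = 1, seed = 14)
  ev <- generate_design(spec, seed = 14)
  ph <- tiny_phantom(4, noise_sigma = 0.5)
  runs <- simulate_bold(ev, ph, subject_effect = 1, seed = 4)
  nuis <- matrix(rnorm(spec$n_volumes_per_run * 2), ncol = 2)
  dm <- build_design_matrix(ev, spec$n_volumes_per_run, spec$tr,
                            nuisance = nuis)
  b1 <- fit_betas(runs[[1]], dm)
  contaminated <- runs[[1]]
  add <- nuis %*% c(3, -2)
  for (v in seq_len(dim(contaminated)[4])) {
    contaminated[, , , v] <- contaminated[, , , v] + add[v]
  }
  b2 <- fit_betas(contaminated, dm)
  expect_lt(max(abs(b1$betas - b2$betas)), 1e-8)
})

test_that("the high-pass basis absorbs simulated drift (bias < 1%)", {
  spec <- design_spec(n_runs = 1, seed = 15)
  ev <- generate_design(spec, seed = 15)
  ph <- tiny_phantom(4, noise_sigma = 0.1, drift_amplitude = 3)
  pat <- make_speaker_patterns(ph, spec$speakers, seed = 5)
  runs <- simulate_bold(ev, ph, subject_effect = 1, patterns = pat, seed = 6)
  bs <- fit_beta_series(runs, ev, tr = spec$tr, hp_cutoff = 128)
  truth <- 1 + pat[match(ev$speaker, spec$speakers), ]
  # regression of estimates on truth: slope within 1% of unity
  fit <- stats::lm.fit(cbind(1, as.numeric(truth)), as.numeric(bs$betas))
  expect_lt(abs(fit$coefficients[2] - 1), 0.01)
})

test_that("rank-deficient designs are flagged with dropped columns", {
  spec <- design_spec(n_runs = 1, words = sprintf("w%d", 1:3), seed = 16)
  ev <- generate_design(spec, seed = 16)
  nuis <- matrix(1, 150, 1)  # duplicates the constant column
  dm <- build_design_matrix(ev, 150, 0.955, hp_cutoff = NULL, nuisance = nuis)
  run <- array(rnorm(2 * 2 * 2 * 150), c(2, 2, 2, 150))
  expect_warning(b <- fit_betas(run, dm), "rank-deficient")
  expect_gt(length(b$dropped_columns), 0)
})

test_that("one-sample t maps match hand computation and flag degeneracy", {
  dims <- c(2, 2, 2)
  vols <- lapply(c(1, 2, 3), function(v) array(v, dims))
  tm <- one_sample_contrast_tmap(vols)
  expect_equal(tm[1, 1, 1], 2 / (1 / sqrt(3)), tolerance = 1e-12)
  neg <- one_sample_contrast_tmap(lapply(vols, function(v) -v))
  expect_equal(as.numeric(neg), -as.numeric(tm))
  expect_warning(z <- one_sample_contrast_tmap(list(array(0, dims),
                                                    array(0, dims))))
  expect_true(all(is.nan(z)))
})

test_that("threshold masks nest and flip at the critical value", {
  withr::with_seed(31, tmap <- array(rnorm(1000, sd = 2), c(10, 10, 10)))
  attr(tmap, "df") <- 20
  strict <- threshold_mask(tmap, p_uncorrected = 1e-4)
  loose <- threshold_mask(tmap, p_uncorrected = 0.01)
  expect_true(all(!strict | loose))          # stricter p => subset
  crit <- qt(1 - 0.001, df = 20)
  just <- array(c(crit - 1e-6, crit + 1e-6, rep(0, 6)), c(2, 2, 2))
  m <- threshold_mask(just, df = 20, p_uncorrected = 0.001)
  expect_false(m[1, 1, 1])
  expect_true(m[2, 1, 1])
  expect_false(any(threshold_mask(array(0, c(2, 2, 2)), df = 5)))
})
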