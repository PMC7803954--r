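#' Build a single-trial (beta-series) design matrix for one run
#'
#' One HRF-convolved boxcar regressor per trial — the "least squares all"
#' single-trial model in which each stimulus presentation gets its own column
#' — plus one zero-duration stick regressor at the response instants, any
#' supplied nuisance columns, an orthonormal discrete-cosine high-pass basis
#' for periods above `hp_cutoff`, and a constant. Regressors are constructed
#' at the HRF microtime resolution and resampled at volume acquisition times.
#'
#' @param events single-run `event_table` (rows with `onset`, `duration`;
#'   `response_time`/`missing` add the response regressor when present).
#' @param n_volumes volumes in the run.
#' @param tr repetition time, seconds.
#' @param hrf an [hrf_params()].
#' @param hp_cutoff high-pass cutoff period in seconds (cosines with longer
#'   periods are included); NULL disables the basis.
#' @param nuisance optional numeric matrix with `n_volumes` rows.
#' @return An object of class `design_matrix`: list with `X` (matrix),
#'   `names`, `trial_columns`, `hp_cutoff`, `tr`.
#' @export
build_design_matrix <- function(events, n_volumes, tr, hrf = hrf_params(),
                                hp_cutoff = 128, nuisance = NULL) {
  stopifnot(is.data.frame(events))
  if (length(unique(events$run)) > 1) {
    vl_error("build_design_matrix expects a single run", "voicelight_design_error")
  }
  run_len <- n_volumes * tr
  if (nrow(events) > 0 &&
      any(events$onset < 0 | events$onset + events$duration > run_len)) {
    vl_error("event onsets/durations fall outside the run",
             "voicelight_design_error")
  }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    vl_assert(nrow(nuisance) == n_volumes,
              "nuisance must have n_volumes rows")
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- sprintf("nuisance%02d", seq_len(ncol(nuisance)))
  }

  n_trials <- nrow(events)
  trial_X <- trial_regressors(events$onset, events$duration,
                              n_volumes, tr, hrf)
  cols <- list()
  nm <- character(0)
  trial_columns <- integer(0)
  if (n_trials > 0) {
    cols <- c(cols, list(trial_X))
    nm <- c(nm, sprintf("trial%03d", seq_len(n_trials)))
    trial_columns <- seq_len(n_trials)
  }

  has_resp <- "response_time" %in% names(events) &&
    any(!is.na(events$response_time))
  if (has_resp) {
    answered <- !is.na(events$response_time)
    resp_t <- events$onset[answered] + events$response_time[answered]
    resp <- stick_regressor(resp_t, n_volumes, tr, hrf)
    cols <- c(cols, list(resp))
    nm <- c(nm, "response")
  }
  if (!is.null(nuisance) && ncol(nuisance) > 0) {
    cols <- c(cols, list(nuisance))
    nm <- c(nm, colnames(nuisance))
  }
  if (!is.null(hp_cutoff)) {
    dct <- dct_highpass_basis(n_volumes, tr, hp_cutoff)
    if (ncol(dct) > 0) {
      cols <- c(cols, list(dct))
      nm <- c(nm, sprintf("dct%02d", seq_len(ncol(dct))))
    }
  }
  cols <- c(cols, list(matrix(1, n_volumes, 1)))
  nm <- c(nm, "constant")

  X <- do.call(cbind, cols)
  colnames(X) <- nm
  zero_cols <- which(colSums(abs(X)) == 0)
  if (length(zero_cols)) {
    vl_error(paste("all-zero design column(s):",
                   paste(nm[zero_cols], collapse = ", ")),
             "voicelight_design_error")
  }
  structure(list(X = X, names = nm, trial_columns = trial_columns,
                 hp_cutoff = hp_cutoff, tr = tr),
            class = "design_matrix")
}

# Convolve boxcars (one column per onset) with the canonical HRF at microtime
# resolution, then sample at volume acquisition times t = (0:(n-1)) * tr.
# All trials are convolved in one batched FFT.
trial_regressors <- function(onsets, durations, n_volumes, tr, hrf) {
  dt <- hrf$sampling_dt
  h <- canonical_hrf(hrf)
  n_micro <- ceiling(n_volumes * tr / dt) + length(h)
  if (length(onsets) == 0) return(matrix(0, n_volumes, 0))
  U <- matrix(0, n_micro, length(onsets))
  for (j in seq_along(onsets)) {
    a <- floor(onsets[j] / dt) + 1L
    b <- max(a, ceiling((onsets[j] + durations[j]) / dt))
    U[a:b, j] <- 1
  }
  conv <- batch_convolve(U, h)
  vol_idx <- floor((0:(n_volumes - 1)) * tr / dt) + 1L
  conv[vol_idx, , drop = FALSE]
}

# Linear convolution of every column of U with kernel h via batched FFT.
batch_convolve <- function(U, h) {
  n <- nrow(U)
  L <- stats::nextn(n + length(h) - 1L, 2)
  Hf <- stats::fft(c(h, numeric(L - length(h))))
  Up <- rbind(U, matrix(0, L - n, ncol(U)))
  conv <- Re(stats::mvfft(stats::mvfft(Up) * Hf, inverse = TRUE)) / L
  conv[seq_len(n), , drop = FALSE]
}

# Zero-duration events: unit impulses at the event instants.
stick_regressor <- function(times, n_volumes, tr, hrf) {
  dt <- hrf$sampling_dt
  h <- canonical_hrf(hrf)
  n_micro <- ceiling(n_volumes * tr / dt) + length(h)
  u <- numeric(n_micro)
  idx <- floor(times / dt) + 1L
  for (i in idx) u[i] <- u[i] + 1
  conv <- convolve_open(u, h)
  vol_idx <- floor((0:(n_volumes - 1)) * tr / dt) + 1L
  conv[vol_idx]
}

convolve_open <- function(u, h) {
  out <- stats::convolve(u, rev(h), type = "open")
  out[seq_along(u)]
}

#' Orthonormal discrete-cosine high-pass basis
#'
#' Cosine regressors with periods longer than `cutoff` seconds (the constant
#' term is excluded; the basis has identity Gram matrix).
#'
#' @param n_volumes,tr run length specification.
#' @param cutoff high-pass period in seconds.
#' @return `n_volumes` x K matrix (K possibly 0).
#' @export
dct_highpass_basis <- function(n_volumes, tr, cutoff) {
  n <- n_volumes
  K <- floor(2 * n * tr / cutoff)
  if (K < 1) return(matrix(0, n, 0))
  t <- 0:(n - 1)
  B <- vapply(seq_len(K), function(k) {
    sqrt(2 / n) * cos(pi * (2 * t + 1) * k / (2 * n))
  }, numeric(n))
  B
}

#' Fit per-voxel ordinary least squares and extract trial betas
#'
#' Estimates the single-trial model voxelwise on unsmoothed data and returns
#' only the trial-regressor coefficients, the features downstream decoding
#' consumes. Rank-deficient designs are fitted on the retained pivots and
#' flagged with the dropped column names.
#'
#' @param run 4D numeric array (x, y, z, time).
#' @param design a [build_design_matrix()] result.
#' @param mask logical/0-1 3D array; NULL fits every voxel.
#' @param meta optional per-trial data frame (speaker, word, run) aligned
#'   with the trial columns.
#' @param ar1 if TRUE, prewhiten with a pooled lag-1 autoregressive estimate
#'   before the final fit.
#' @return An object of class `beta_series`: `betas` (n_trials x n_voxels),
#'   `meta`, `mask`, `grid` (shape, voxel sizes), `voxel_index` (linear
#'   indices of mask voxels), `dropped_columns`.
#' @export
fit_betas <- function(run, design, mask = NULL, meta = NULL, ar1 = FALSE) {
  stopifnot(inherits(design, "design_matrix"))
  dims <- dim(run)
  vl_assert(length(dims) == 4, "run must be a 4D array")
  X <- design$X
  vl_assert(dims[4] == nrow(X), "time axis must match the design")
  if (is.null(mask)) mask <- array(TRUE, dims[1:3])
  vl_assert(all(dim(mask) == dims[1:3]), "mask grid must match the run")
  vox <- which(mask != 0)
  Y <- matrix(aperm(run, c(4, 1, 2, 3)), dims[4])[, vox, drop = FALSE]

  fit <- ols_fit(X, Y)
  if (ar1) {
    res <- Y - X %*% fit$coef
    rho <- mean(vapply(seq_len(ncol(res)), function(j) {
      r <- res[, j]
      sum(r[-1] * r[-length(r)]) / sum(r^2)
    }, numeric(1)))
    W_Y <- Y[-1, , drop = FALSE] - rho * Y[-nrow(Y), , drop = FALSE]
    W_X <- X[-1, , drop = FALSE] - rho * X[-nrow(X), , drop = FALSE]
    fit <- ols_fit(W_X, W_Y)
    attr(fit, "ar1_rho") <- rho
  }
  betas <- fit$coef[design$trial_columns, , drop = FALSE]
  structure(list(betas = betas, meta = meta, mask = mask,
                 grid = list(shape = dims[1:3], voxel_size = rep(1, 3)),
                 voxel_index = vox,
                 dropped_columns = fit$dropped),
            class = "beta_series")
}

# QR least squares for many right-hand sides; detects rank deficiency.
ols_fit <- function(X, Y) {
  qr_x <- qr(X)
  dropped <- character(0)
  if (qr_x$rank < ncol(X)) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    warning("rank-deficient design; dropped: ",
            paste(dropped, collapse = ", "))
    coef_kept <- qr.coef(qr(X[, keep, drop = FALSE]), Y)
    coef <- matrix(0, ncol(X), ncol(Y),
                   dimnames = list(colnames(X), NULL))
    coef[keep, ] <- coef_kept
  } else {
    coef <- qr.coef(qr_x, Y)
    rownames(coef) <- colnames(X)
  }
  list(coef = coef, dropped = dropped)
}

#' Fit the single-trial model across runs and stack the beta series
#'
#' Convenience wrapper: builds one design matrix per run, fits each run, and
#' concatenates trial betas with aligned metadata — the feature store for
#' searchlight decoding.
#'
#' @param runs list of 4D arrays, one per run, in run order.
#' @param events multi-run `event_table` (with responses when available).
#' @param mask 3D mask shared by all runs.
#' @param tr,hrf,hp_cutoff,nuisance as in [build_design_matrix()];
#'   `nuisance` may be a list (one matrix per run).
#' @inheritParams fit_betas
#' @return A `beta_series` covering all trials of all runs.
#' @export
fit_beta_series <- function(runs, events, mask = NULL, tr = attr(events, "tr"),
                            hrf = hrf_params(), hp_cutoff = 128,
                            nuisance = NULL, ar1 = FALSE) {
  run_ids <- sort(unique(events$run))
  vl_assert(length(runs) == length(run_ids),
            "one 4D array per run is required")
  pieces <- lapply(seq_along(run_ids), function(i) {
    ev <- events[events$run == run_ids[i], , drop = FALSE]
    nv <- dim(runs[[i]])[4]
    nui <- if (is.list(nuisance)) nuisance[[i]] else nuisance
    dm <- build_design_matrix(ev, nv, tr, hrf, hp_cutoff, nui)
    fit_betas(runs[[i]], dm, mask,
              meta = ev[, c("speaker", "word", "run"), drop = FALSE],
              ar1 = ar1)
  })
  out <- pieces[[1]]
  out$betas <- do.call(rbind, lapply(pieces, `[[`, "betas"))
  out$meta <- do.call(rbind, lapply(pieces, `[[`, "meta"))
  rownames(out$meta) <- NULL
  out
}

#' One-sample t map across subjects
#'
#' Voxelwise t = mean / (sd / sqrt(n)) with df = n - 1. Voxels with zero
#' variance get signed infinity and are flagged.
#'
#' @param vols list of co-registered 3D arrays, one per subject.
#' @return 3D t array with attributes `df` and `degenerate` (logical array).
#' @export
one_sample_contrast_tmap <- function(vols) {
  vl_assert(length(vols) >= 2, "need at least 2 subjects")
  dims <- dim(vols[[1]])
  vl_assert(all(vapply(vols, function(v) all(dim(v) == dims), logical(1))),
            "subject volumes must share one grid")
  n <- length(vols)
  M <- vapply(vols, as.numeric, numeric(prod(dims)))
  mu <- rowMeans(M)
  sd_v <- sqrt(rowSums((M - mu)^2) / (n - 1))
  t_v <- ifelse(sd_v == 0, sign(mu) * Inf, mu / (sd_v / sqrt(n)))
  t_v[sd_v == 0 & mu == 0] <- NaN
  out <- array(t_v, dims)
  attr(out, "df") <- n - 1
  attr(out, "degenerate") <- array(sd_v == 0, dims)
  if (any(sd_v == 0)) warning("zero-variance voxels flagged in t map")
  out
}

#' Threshold a t map at an uncorrected one-sided p
#'
#' @param tmap 3D t array.
#' @param df degrees of freedom (defaults to the map's `df` attribute).
#' @param p_uncorrected one-sided significance level (default 0.001).
#' @return Logical 3D mask of voxels with one-sided p below the threshold.
#' @export
threshold_mask <- function(tmap, df = attr(tmap, "df"),
                           p_uncorrected = 0.001) {
  vl_assert(!is.null(df) && df >= 1, "df must be >= 1")
  crit <- stats::qt(1 - p_uncorrected, df)
  out <- array(!is.na(tmap) & tmap > crit, dim(tmap))
  out
}
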