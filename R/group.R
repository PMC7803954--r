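#' Subtract the chance level from an accuracy map
#'
#' @param map `accuracy_map` or plain 3D array.
#' @param chance accuracy under no information (1/3 for balanced 3-class).
#' @return Map of the same shape with `chance` subtracted where defined.
#' @export
subtract_chance <- function(map, chance = 1 / 3) {
  out <- map - chance
  attributes(out) <- attributes(map)
  out
}

#' Gaussian spatial smoothing with mask renormalization
#'
#' Separable Gaussian filter with sigma = fwhm / (2 * sqrt(2 * log(2))) per
#' axis. At mask edges the kernel is renormalized over the voxels actually
#' present (smoothing `map * w` and dividing by smoothed `w`), so a constant
#' map stays constant and no signal bleeds in from outside the mask.
#'
#' @param volume 3D array; NA voxels are treated as outside the mask.
#' @param fwhm_mm full width at half maximum in mm (0 = identity).
#' @param voxel_size_mm per-axis voxel spacing.
#' @param mask optional 3D logical array restricting the support.
#' @return Smoothed 3D array, NA outside the support.
#' @export
gaussian_smooth <- function(volume, fwhm_mm = 8, voxel_size_mm = c(2, 2, 2),
                            mask = NULL) {
  vl_assert(fwhm_mm >= 0, "fwhm_mm must be >= 0")
  dims <- dim(volume)
  if (is.null(mask)) mask <- !is.na(volume)
  support <- mask & !is.na(volume)
  if (fwhm_mm == 0) {
    out <- volume
    out[!support] <- NA_real_
    return(out)
  }
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / voxel_size_mm
  v <- volume
  v[!support] <- 0
  w <- array(as.numeric(support), dims)
  for (ax in 1:3) {
    k <- gauss_kernel_1d(sigma_vox[ax])
    v <- conv_axis(v, k, ax)
    w <- conv_axis(w, k, ax)
  }
  out <- array(NA_real_, dims)
  out[support] <- v[support] / w[support]
  out
}

gauss_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Convolve along one axis of a 3D array (zero boundary), via a banded matrix.
conv_axis <- function(a, k, axis) {
  if (length(k) == 1) return(a * k)
  dims <- dim(a)
  n <- dims[axis]
  r <- (length(k) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (d in -r:r) {
    i <- seq_len(n)
    j <- i + d
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- k[d + r + 1L]
  }
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- K %*% matrix(ap, n)
  aperm(array(m, dims[perm]), order(perm))
}

new_group_stat_map <- function(stat, p_fwe, n_permutations, seed, mask,
                               extra = list()) {
  structure(c(list(stat = stat, p_fwe = p_fwe,
                   n_permutations = n_permutations, seed = seed,
                   mask = mask), extra),
            class = "group_stat_map")
}

#' @export
print.group_stat_map <- function(x, ...) {
  nv <- sum(x$mask != 0)
  cat("Permutation group statistic map:", nv, "voxels,",
      x$n_permutations, "permutations\n")
  pm <- x$p_fwe[x$mask != 0]
  cat("  min FWE-corrected p:", format(min(pm), digits = 4),
      "; voxels with p <= 0.05:", sum(pm <= 0.05), "\n")
  invisible(x)
}

# Stack subject maps into an n_subjects x n_voxels matrix over mask voxels.
stack_maps <- function(maps, mask) {
  dims <- dim(maps[[1]])
  vl_assert(all(vapply(maps, function(m) all(dim(m) == dims), logical(1))),
            "subject maps must share one grid")
  defined <- Reduce(`&`, lapply(maps, function(m) !is.na(m)))
  if (is.null(mask)) mask <- defined
  vl_assert(all(dim(mask) == dims), "mask grid mismatch")
  mask <- mask != 0 & defined
  vox <- which(mask != 0)
  vl_assert(length(vox) > 0, "mask is empty")
  M <- t(vapply(maps, function(m) as.numeric(m)[vox], numeric(length(vox))))
  list(M = M, vox = vox, dims = dims, mask = array(seq_len(prod(dims)) %in% vox, dims))
}

# One-sample t statistics for many sign patterns at once. S: n_pat x n rows
# of +/-1; M: n x v data. Squares are flip-invariant, so only the mean moves.
t_for_flips <- function(S, M) {
  n <- ncol(S)
  ss <- colSums(M^2)
  means <- (S %*% M) / n
  var_v <- sweep(-n * means^2, 2, ss, `+`) / (n - 1)
  var_v[var_v < 0] <- 0
  means / sqrt(var_v / n)
}

#' One-sample sign-flip permutation test with max-statistic FWE
#'
#' Tests whether subject maps (accuracy minus chance) are positive on
#' average. The observed statistic is the voxelwise one-sample t; the null is
#' built by randomly negating each subject's whole map and recomputing t, and
#' voxel-level family-wise error corrected p-values compare each observed t
#' with the permutation distribution of the mask-wide maximum t. The identity
#' flip is always included, so p >= 1 / n_permutations.
#'
#' @param maps list of co-registered 3D subject maps (chance already
#'   subtracted for the above-chance test).
#' @param n_permutations permutations including the identity (default 5000).
#' @param seed integer seed for the flips.
#' @param mask optional 3D analysis mask (defaults to voxels defined in all
#'   subjects).
#' @param alternative "greater" (default) for a one-sided test of positive
#'   mean; "two.sided" uses |t|.
#' @param block_size permutations processed per block (memory control).
#' @return A `group_stat_map` with fields `stat`, `p_fwe`, `max_null` (the
#'   permutation distribution of the maximum), `df`.
#' @export
signflip_onesample <- function(maps, n_permutations = 5000, seed = NULL,
                               mask = NULL, alternative = c("greater",
                                                            "two.sided"),
                               block_size = 1000L) {
  alternative <- match.arg(alternative)
  vl_assert(is_count(n_permutations) && n_permutations >= 1,
            "n_permutations must be a count >= 1")
  vl_assert(length(maps) >= 2, "need at least 2 subjects")
  st <- stack_maps(maps, mask)
  n <- nrow(st$M)
  obs <- drop(t_for_flips(matrix(1, 1, n), st$M))
  obs_stat <- if (alternative == "two.sided") abs(obs) else obs
  max_null <- numeric(n_permutations)
  with_seed(seed, {
    done <- 0L
    first <- TRUE
    while (done < n_permutations) {
      nb <- min(block_size, n_permutations - done)
      S <- matrix(sample(c(-1, 1), nb * n, replace = TRUE), nb, n)
      if (first) {
        S[1, ] <- 1  # identity permutation always included
        first <- FALSE
      }
      Tm <- t_for_flips(S, st$M)
      if (alternative == "two.sided") Tm <- abs(Tm)
      max_null[done + seq_len(nb)] <- apply(Tm, 1, max)
      done <- done + nb
    }
  })
  # the identity entry is exactly the observed maximum (avoids spurious
  # p < 1/n_permutations from floating-point differences in the two paths)
  max_null[1] <- max(obs_stat)
  p_vox <- vapply(obs_stat, function(t0) mean(max_null >= t0), numeric(1))
  stat3 <- array(NA_real_, st$dims); stat3[st$vox] <- obs
  p3 <- array(NA_real_, st$dims); p3[st$vox] <- p_vox
  new_group_stat_map(stat3, p3, n_permutations, seed, st$mask,
                     extra = list(max_null = max_null, df = n - 1,
                                  alternative = alternative))
}

# Slope t statistics for many covariate orderings at once.
# C: n_pat x n covariate rows; M: n x v data.
t_for_covariates <- function(C, M) {
  n <- ncol(C)
  Cc <- C - rowMeans(C)
  scc <- rowSums(Cc^2)
  ssy <- colSums(M^2) - n * colMeans(M)^2
  b <- (Cc %*% M) / scc
  rss <- sweep(-(b^2) * scc, 2, ssy, `+`)
  rss[rss < 0] <- 0
  sigma2 <- rss / (n - 2)
  b / sqrt(sigma2 / scc)
}

#' Permutation regression of subject maps on one covariate
#'
#' Voxelwise slope t of the map values on a single subject-level covariate
#' (with intercept). The null is built by permuting the covariate across
#' subjects; voxel-level FWE corrected p-values use the permutation
#' distribution of the mask-wide maximum t. The identity ordering is always
#' included. The Spearman rank correlation squared is reported descriptively
#' per voxel.
#'
#' @param maps list of co-registered 3D subject maps.
#' @param covariate numeric vector, one value per subject (non-constant).
#' @inheritParams signflip_onesample
#' @return A `group_stat_map` with additional field `spearman_r2`.
#' @export
permutation_regression <- function(maps, covariate, n_permutations = 5000,
                                   seed = NULL, mask = NULL,
                                   alternative = c("greater", "two.sided"),
                                   block_size = 1000L) {
  alternative <- match.arg(alternative)
  n <- length(maps)
  vl_assert(n >= 3, "need at least 3 subjects")
  vl_assert(length(covariate) == n, "one covariate value per subject")
  if (stats::sd(covariate) == 0) {
    vl_error("covariate is constant", "voicelight_degenerate_covariate")
  }
  vl_assert(is_count(n_permutations) && n_permutations >= 1,
            "n_permutations must be a count >= 1")
  st <- stack_maps(maps, mask)
  obs <- drop(t_for_covariates(matrix(covariate, 1), st$M))
  obs_stat <- if (alternative == "two.sided") abs(obs) else obs
  max_null <- numeric(n_permutations)
  with_seed(seed, {
    done <- 0L
    first <- TRUE
    while (done < n_permutations) {
      nb <- min(block_size, n_permutations - done)
      C <- t(vapply(seq_len(nb), function(i) sample(covariate), covariate))
      if (first) {
        C[1, ] <- covariate  # identity ordering always included
        first <- FALSE
      }
      Tm <- t_for_covariates(C, st$M)
      if (alternative == "two.sided") Tm <- abs(Tm)
      max_null[done + seq_len(nb)] <- apply(Tm, 1, max)
      done <- done + nb
    }
  })
  max_null[1] <- max(obs_stat)
  p_vox <- vapply(obs_stat, function(t0) mean(max_null >= t0), numeric(1))
  rk_c <- rank(covariate)
  rho <- suppressWarnings(
    stats::cor(rk_c, apply(st$M, 2, rank), method = "pearson"))
  stat3 <- array(NA_real_, st$dims); stat3[st$vox] <- obs
  p3 <- array(NA_real_, st$dims); p3[st$vox] <- p_vox
  r2 <- array(NA_real_, st$dims); r2[st$vox] <- drop(rho)^2
  new_group_stat_map(stat3, p3, n_permutations, seed, st$mask,
                     extra = list(max_null = max_null, df = n - 2,
                                  alternative = alternative,
                                  spearman_r2 = r2))
}

#' Restrict a map to an explicit mask
#'
#' Pure restriction of support: no statistic is recomputed. To let the mask
#' shrink the max-statistic null (and hence the corrected p-values), pass the
#' mask to [signflip_onesample()] / [permutation_regression()] instead, which
#' applies it before the permutation maximum is taken.
#'
#' @param statmap a `group_stat_map`, `accuracy_map`, or 3D array.
#' @param sound_mask 3D logical array on the same grid.
#' @return Object of the same kind with support intersected with the mask.
#' @export
apply_explicit_mask <- function(statmap, sound_mask) {
  restrict3 <- function(a) {
    vl_assert(all(dim(a) == dim(sound_mask)), "mask grid mismatch")
    a[sound_mask == 0] <- NA_real_
    a
  }
  if (inherits(statmap, "group_stat_map")) {
    new_support <- statmap$mask != 0 & sound_mask != 0 & !is.na(statmap$stat)
    if (!any(new_support)) {
      vl_error("explicit mask does not intersect the map support",
               "voicelight_geometry_error")
    }
    statmap$stat <- restrict3(statmap$stat)
    statmap$p_fwe <- restrict3(statmap$p_fwe)
    statmap$mask <- statmap$mask != 0 & sound_mask != 0
    return(statmap)
  }
  out <- restrict3(statmap)
  if (!any(!is.na(out))) {
    vl_error("explicit mask does not intersect the map support",
             "voicelight_geometry_error")
  }
  attributes(out) <- attributes(statmap)
  out
}

#' Clusters and local peaks of a thresholded statistic map
#'
#' Suprathreshold voxels are grouped into 26-connectivity clusters; clusters
#' below the extent threshold are discarded; within each cluster local maxima
#' are picked greedily in descending statistic order subject to a minimum
#' pairwise separation (peaks closer than that to an already accepted peak
#' merge into it).
#'
#' @param statmap 3D statistic array or `group_stat_map` (its `stat` field).
#' @param voxel_threshold report voxels with statistic above this value.
#' @param min_cluster_mm3 extent threshold in mm^3 (e.g. 20).
#' @param min_peak_separation_mm peaks within a cluster must be farther apart
#'   than this (default 8 mm).
#' @param voxel_size_mm voxel spacing in mm.
#' @return Data frame (class `peak_table`) with columns `cluster_id`,
#'   `x_mm`, `y_mm`, `z_mm`, `statistic`, `cluster_size_voxels`. Empty when
#'   nothing survives.
#' @export
cluster_peaks <- function(statmap, voxel_threshold, min_cluster_mm3 = 0,
                          min_peak_separation_mm = 8,
                          voxel_size_mm = c(2, 2, 2)) {
  stat <- if (inherits(statmap, "group_stat_map")) statmap$stat else statmap
  dims <- dim(stat)
  supra <- which(!is.na(stat) & stat > voxel_threshold)
  empty <- data.frame(cluster_id = integer(0), x_mm = numeric(0),
                      y_mm = numeric(0), z_mm = numeric(0),
                      statistic = numeric(0), cluster_size_voxels = integer(0))
  class(empty) <- c("peak_table", "data.frame")
  if (length(supra) == 0) return(empty)
  labels <- label_components_26(supra, dims)
  vox_mm3 <- prod(voxel_size_mm)
  rows <- list()
  cid_out <- 0L
  for (cid in seq_len(max(labels))) {
    members <- supra[labels == cid]
    if (length(members) * vox_mm3 < min_cluster_mm3) next
    cid_out <- cid_out + 1L
    ijk <- lin_to_ijk(members, dims)
    mm <- sweep(ijk - 1, 2, voxel_size_mm, `*`)
    vals <- stat[members]
    ord <- order(vals, decreasing = TRUE)
    peaks <- integer(0)
    for (i in ord) {
      if (length(peaks) == 0) { peaks <- i; next }
      d <- sqrt(rowSums(sweep(mm[peaks, , drop = FALSE], 2, mm[i, ])^2))
      if (all(d > min_peak_separation_mm)) peaks <- c(peaks, i)
    }
    rows[[cid_out]] <- data.frame(cluster_id = cid_out,
                                  x_mm = mm[peaks, 1], y_mm = mm[peaks, 2],
                                  z_mm = mm[peaks, 3], statistic = vals[peaks],
                                  cluster_size_voxels = length(members))
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("peak_table", "data.frame")
  out
}

# Connected components (26-neighbourhood) over a set of linear voxel indices.
label_components_26 <- function(supra, dims) {
  in_set <- integer(prod(dims))
  in_set[supra] <- seq_along(supra)
  labels <- integer(length(supra))
  nbr <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nbr <- nbr[rowSums(abs(nbr)) > 0, ]
  cur <- 0L
  ijk_all <- lin_to_ijk(supra, dims)
  for (s in seq_along(supra)) {
    if (labels[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    labels[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      pts <- sweep(nbr, 2, ijk_all[v, ], `+`)
      ok <- pts[, 1] >= 1 & pts[, 1] <= dims[1] &
        pts[, 2] >= 1 & pts[, 2] <= dims[2] &
        pts[, 3] >= 1 & pts[, 3] <= dims[3]
      lin <- ijk_to_lin(pts[ok, , drop = FALSE], dims)
      hits <- in_set[lin]
      hits <- hits[hits > 0]
      hits <- hits[labels[hits] == 0L]
      if (length(hits)) {
        labels[hits] <- cur
        queue <- c(queue, hits)
      }
    }
  }
  labels
}
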