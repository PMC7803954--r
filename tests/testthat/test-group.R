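test_that("chance subtraction is exact and invertible", {
  m <- array(1 / 3, c(3, 3, 3))
  z <- subtract_chance(m)
  expect_lt(max(abs(z)), 1e-12)
  expect_equal(subtract_chance(array(0.5, c(2, 2, 2)))[1], 0.5 - 1 / 3)
  m2 <- array(runif(27), c(3, 3, 3))
  expect_equal(subtract_chance(m2, 0.2) + 0.2, m2)
})

test_that("Gaussian smoothing preserves constants and matches the impulse oracle", {
  v <- array(rnorm(6^3), c(6, 6, 6))
  expect_equal(gaussian_smooth(v, fwhm_mm = 0), v)

  const <- array(2.5, c(7, 7, 7))
  s <- gaussian_smooth(const, fwhm_mm = 8)
  expect_lt(max(abs(s - 2.5)), 1e-10)

  # unit impulse on a large grid: center value = product of per-axis peaks
  imp <- array(0, c(41, 41, 41))
  imp[21, 21, 21] <- 1
  s2 <- gaussian_smooth(imp, fwhm_mm = 8, voxel_size_mm = c(2, 2, 2))
  sigma <- (8 / (2 * sqrt(2 * log(2)))) / 2
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  expect_equal(s2[21, 21, 21], max(k)^3, tolerance = 1e-12)
})

test_that("sign-flip inference isolates the all-positive flip on identical maps", {
  base <- array(seq(0.1, 0.9, length.out = 27), c(3, 3, 3))
  maps <- replicate(4, base, simplify = FALSE)
  n_perm <- 2000
  g <- signflip_onesample(maps, n_permutations = n_perm, seed = 5)
  # identical subjects: zero variance -> observed t = +Inf at every voxel;
  # only all-plus flips reach it, so p ~= P(all four signs positive) = 1/16
  expect_true(all(is.infinite(g$stat[!is.na(g$stat)])))
  p <- g$p_fwe[2, 2, 2]
  expect_gte(p, 1 / n_perm)
  expect_lt(abs(p - 1 / 16), 4 * sqrt((1 / 16) * (15 / 16) / n_perm))
  # independent enumeration oracle over all 16 sign patterns
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 4)))
  max_t <- apply(signs, 1, function(s) {
    v <- s * rep(1, 4)
    tt <- mean(v * base[2, 2, 2]) / (sd(v * base[2, 2, 2]) / 2)
    if (is.nan(tt)) tt <- sign(mean(v)) * Inf
    tt
  })
  expect_equal(mean(max_t >= Inf), 1 / 16)
})

test_that("negating all maps negates the observed statistic", {
  withr::with_seed(6, maps <- replicate(6, array(rnorm(27, 0.5), c(3, 3, 3)),
                                        simplify = FALSE))
  g1 <- signflip_onesample(maps, 200, seed = 7)
  g2 <- signflip_onesample(lapply(maps, function(m) -m), 200, seed = 7)
  expect_equal(g2$stat, -g1$stat)
})

test_that("corrected p is monotone non-increasing in the observed statistic", {
  withr::with_seed(8, maps <- replicate(8, array(rnorm(125, 0.2), c(5, 5, 5)),
                                        simplify = FALSE))
  g <- signflip_onesample(maps, 500, seed = 9)
  ok <- !is.na(g$stat)
  ord <- order(g$stat[ok])
  expect_true(all(diff(g$p_fwe[ok][ord]) <= 1e-12))
  expect_true(all(g$p_fwe[ok] >= 1 / 500))
})

test_that("a covariate matching one voxel's values makes that voxel the maximum", {
  dims <- c(3, 3, 3)
  withr::with_seed(10, {
    M <- matrix(rnorm(5 * 27), 5)
    covariate <- M[, 14]  # center voxel's subject values
    maps <- lapply(seq_len(5), function(i) array(M[i, ], dims))
  })
  g <- permutation_regression(maps, covariate, n_permutations = 2000, seed = 11)
  expect_equal(which.max(g$stat), 14L)
  # n = 5: 120 orderings; the identity realizes the maximum, so the
  # exhaustive p is near (# orderings at least as extreme) / 120
  expect_lt(g$p_fwe[2, 2, 2], 0.1)
  expect_gte(g$p_fwe[2, 2, 2], 1 / 2000)
})

test_that("slope-t inference is invariant to affine covariate maps", {
  withr::with_seed(12, {
    maps <- replicate(8, array(rnorm(27), c(3, 3, 3)), simplify = FALSE)
    covariate <- rnorm(8)
  })
  g1 <- permutation_regression(maps, covariate, 300, seed = 13)
  g2 <- permutation_regression(maps, 5 + 2 * covariate, 300, seed = 13)
  expect_equal(g1$p_fwe, g2$p_fwe)
  expect_equal(g1$stat, g2$stat, tolerance = 1e-10)
  expect_error(permutation_regression(maps, rep(1, 8), 100, seed = 1),
               class = "voicelight_degenerate_covariate")
})

test_that("explicit masking restricts support and can only lower corrected p", {
  withr::with_seed(14, maps <- replicate(10, array(rnorm(216, 0.3), c(6, 6, 6)),
                                         simplify = FALSE))
  full <- array(TRUE, c(6, 6, 6))
  half <- array(FALSE, c(6, 6, 6)); half[1:3, , ] <- TRUE
  g_full <- signflip_onesample(maps, 500, seed = 15)
  g_half <- signflip_onesample(maps, 500, seed = 15, mask = half)
  idx <- which(half & !is.na(g_full$p_fwe))
  expect_true(all(g_half$p_fwe[idx] <= g_full$p_fwe[idx] + 1e-12))

  # restriction-only operator
  r <- apply_explicit_mask(g_full, half)
  expect_true(all(is.na(r$stat[!half])))
  expect_equal(r$stat[half], g_full$stat[half])
  id <- apply_explicit_mask(g_full, full)
  expect_equal(id$stat, g_full$stat)
  none <- array(FALSE, c(6, 6, 6))
  expect_error(apply_explicit_mask(g_full, none),
               class = "voicelight_geometry_error")
})

test_that("group statistics are seed-deterministic", {
  withr::with_seed(16, maps <- replicate(5, array(rnorm(64, 0.4), c(4, 4, 4)),
                                         simplify = FALSE))
  a <- signflip_onesample(maps, 200, seed = 17)
  b <- signflip_onesample(maps, 200, seed = 17)
  expect_identical(a$p_fwe, b$p_fwe)
  r1 <- permutation_regression(maps, c(1, 3, 2, 5, 4), 200, seed = 18)
  r2 <- permutation_regression(maps, c(1, 3, 2, 5, 4), 200, seed = 18)
  expect_identical(r1$p_fwe, r2$p_fwe)
})

test_that("cluster extraction separates blobs and merges nearby maxima", {
  dims <- c(20, 20, 20)
  st <- array(0, dims)
  st[5, 5, 5] <- 10
  pk <- cluster_peaks(st, 5, voxel_size_mm = c(2, 2, 2))
  expect_equal(nrow(pk), 1)
  expect_equal(pk$cluster_size_voxels, 1)

  # two blobs 20 mm apart -> two clusters
  st2 <- array(0, dims)
  st2[5:6, 5, 5] <- c(9, 8)
  st2[15:16, 5, 5] <- c(7, 6)   # 10 voxels * 2 mm = 20 mm away
  pk2 <- cluster_peaks(st2, 5, voxel_size_mm = c(2, 2, 2))
  expect_equal(length(unique(pk2$cluster_id)), 2)

  # two maxima 6 mm apart within one blob -> a single reported peak
  st3 <- array(0, dims)
  st3[5:8, 5, 5] <- c(9, 6, 6, 8.5)   # maxima at x=5 and x=8: 6 mm apart
  pk3 <- cluster_peaks(st3, 5, voxel_size_mm = c(2, 2, 2))
  expect_equal(nrow(pk3), 1)
  expect_equal(pk3$statistic, 9)

  # extent threshold: the 2-voxel clusters are 16 mm3 and drop at 17 mm3
  pk4 <- cluster_peaks(st2, 5, min_cluster_mm3 = 17,
                       voxel_size_mm = c(2, 2, 2))
  expect_equal(nrow(pk4), 0)
  pk5 <- cluster_peaks(st2, 5, min_cluster_mm3 = 16,
                       voxel_size_mm = c(2, 2, 2))
  expect_equal(length(unique(pk5$cluster_id)), 2)
  expect_equal(nrow(cluster_peaks(array(0, dims), 5)), 0)
})
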